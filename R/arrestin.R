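# Receptor-arrestin pose post-processing: anchor-distance filtering of
# docked arrestin poses (conserved DRY arginine of the receptor vs the
# arrestin finger loop) and the tilt/rot indices describing the arrestin's
# orientation relative to the receptor.

#' Arrestin filter configuration
#'
#' Distance rule for receptor-arrestin docking poses: the Calpha of the
#' receptor's conserved DRY arginine (residue 132 of the D2 receptor) must
#' lie within `max_distance_A` of the Calpha of the arrestin finger-loop
#' anchor (residue 71). The cutoff value itself is an operational choice
#' (12 Angstrom by default, wide enough to admit finger-loop engagement
#' geometries) and should be treated as a tunable.
#'
#' @param receptor_anchor_resno receptor anchor residue number (default 132).
#' @param arrestin_anchor_resno arrestin anchor residue number (default 71).
#' @param max_distance_A Calpha-Calpha cutoff (default 12).
#' @param receptor_chain,arrestin_chain optional chain restriction (`NULL` =
#'   first matching residue in any chain).
#' @return list of class `arrestin_filter_config`.
#' @export
arrestin_filter_config <- function(receptor_anchor_resno = 132L,
                                   arrestin_anchor_resno = 71L,
                                   max_distance_A = 12,
                                   receptor_chain = NULL,
                                   arrestin_chain = NULL) {
  .check_scalar(receptor_anchor_resno, "receptor_anchor_resno",
                positive = TRUE, integer = TRUE)
  .check_scalar(arrestin_anchor_resno, "arrestin_anchor_resno",
                positive = TRUE, integer = TRUE)
  .check_scalar(max_distance_A, "max_distance_A", positive = TRUE)
  structure(list(receptor_anchor_resno = as.integer(receptor_anchor_resno),
                 arrestin_anchor_resno = as.integer(arrestin_anchor_resno),
                 max_distance_A = max_distance_A,
                 receptor_chain = receptor_chain,
                 arrestin_chain = arrestin_chain),
            class = "arrestin_filter_config")
}

# Calpha of a given residue; explicit failure naming the residue
.anchor_ca <- function(model, resno, chain = NULL, what = "anchor") {
  a <- model$atoms
  sel <- a$atom == "CA" & a$resno == resno
  if (!is.null(chain)) sel <- sel & a$chain == chain
  if (!any(sel))
    stop(sprintf("%s residue %d%s has no Calpha in the supplied structure",
                 what, resno,
                 if (is.null(chain)) "" else paste0(" (chain ", chain, ")")),
         call. = FALSE)
  as.numeric(a[which(sel)[1], c("x", "y", "z")])
}

#' Filter receptor-arrestin poses by the anchor-distance rule
#'
#' Applies each pose to the arrestin anchor Calpha and keeps poses whose
#' anchor-to-anchor distance is at most `max_distance_A`; the measured
#' distance is attached to every retained pose as `anchor_distance_A`.
#'
#' @param poses list of [dock_pose()] placing the arrestin probe.
#' @param receptor the fixed receptor [structure_model()].
#' @param arrestin the arrestin probe `structure_model` in its reference
#'   frame.
#' @param config an [arrestin_filter_config()].
#' @return The accepted poses (score order preserved), each with
#'   `anchor_distance_A` added.
#' @export
arrestin_pose_filter <- function(poses, receptor, arrestin,
                                 config = arrestin_filter_config()) {
  stopifnot(inherits(config, "arrestin_filter_config"))
  rec <- .anchor_ca(receptor, config$receptor_anchor_resno,
                    config$receptor_chain, "receptor anchor")
  arr <- .anchor_ca(arrestin, config$arrestin_anchor_resno,
                    config$arrestin_chain, "arrestin anchor")
  out <- list()
  for (p in .rank_poses(poses)) {
    placed <- as.numeric(p$rotation %*% arr + p$translation)
    d <- sqrt(sum((placed - rec)^2))
    if (d <= config$max_distance_A) {
      p$anchor_distance_A <- d
      out[[length(out) + 1L]] <- p
    }
  }
  out
}

#' Tilt and Rot indices of a posed arrestin
#'
#' Operationalizes the two angles used to compare receptor-arrestin
#' architectures: the Tilt index is the inclination of the arrestin
#' principal axis with respect to the receptor main axis (taken as the
#' membrane normal, +z, of the receptor frame); the Rot index is the signed
#' rotation, measured about +z, of the xy-projection of the arrestin axis
#' relative to a receptor in-plane reference vector (from the Calpha of the
#' receptor anchor residue towards the receptor Calpha centroid).
#'
#' The arrestin principal axis is the dominant principal component of its
#' Calpha cloud, sign-fixed to point towards the centroid of the N-domain
#' (residues `<= n_domain_max_resno`). These conventions make the indices
#' self-consistent across poses; absolute values depend on the convention.
#'
#' @param receptor the receptor [structure_model()] in its membrane frame.
#' @param arrestin the posed arrestin `structure_model`.
#' @param receptor_anchor_resno receptor reference residue (default 132).
#' @param receptor_chain optional receptor chain for the anchor.
#' @param n_domain_max_resno last residue number counted as arrestin
#'   N-domain for the sign fix (default 180).
#' @return list of class `tilt_rot_result` with `tilt_index_deg` in
#'   `[0, 180]` and `rot_index_deg` in `(-180, 180]` (`NA` with a warning
#'   when the axis is parallel to z and the projection is degenerate).
#' @export
tilt_rot_indices <- function(receptor, arrestin,
                             receptor_anchor_resno = 132L,
                             receptor_chain = NULL,
                             n_domain_max_resno = 180L) {
  ca <- ca_coords(arrestin)
  if (nrow(ca) < 3L)
    stop("arrestin structure has too few Calpha atoms", call. = FALSE)
  cen <- colMeans(ca)
  ev <- eigen(stats::cov(ca), symmetric = TRUE)
  if ((ev$values[1] - ev$values[2]) / ev$values[1] < 1e-6)
    stop("degenerate principal axis: arrestin Calpha cloud is isotropic",
         call. = FALSE)
  axis <- ev$vectors[, 1]
  # sign fix: towards the N-domain centroid
  ca_atoms <- arrestin$atoms[arrestin$atoms$atom == "CA", , drop = FALSE]
  ndom <- ca_atoms$resno <= n_domain_max_resno
  if (any(ndom)) {
    ncen <- colMeans(as.matrix(ca_atoms[ndom, c("x", "y", "z")]))
    if (sum(axis * (ncen - cen)) < 0) axis <- -axis
  }
  tilt <- acos(.clamp(axis[3], -1, 1)) * 180 / pi
  anchor <- .anchor_ca(receptor, receptor_anchor_resno, receptor_chain,
                       "receptor anchor")
  vref <- ca_centroid(receptor) - anchor
  axy <- axis[1:2]; rxy <- vref[1:2]
  if (sqrt(sum(axy^2)) < 1e-9 || sqrt(sum(rxy^2)) < 1e-9) {
    warning("rot index undefined: degenerate xy-projection")
    rot <- NA_real_
  } else {
    # signed angle from the receptor reference vector to the arrestin axis
    # projection, about +z
    rot <- unname(atan2(rxy[1] * axy[2] - rxy[2] * axy[1],
                        sum(rxy * axy))) * 180 / pi
    if (rot <= -180) rot <- rot + 360
  }
  structure(list(tilt_index_deg = tilt, rot_index_deg = rot),
            class = "tilt_rot_result")
}

#' @export
print.tilt_rot_result <- function(x, ...) {
  cat(sprintf("<tilt_rot_result> tilt %.2f deg, rot %s deg\n",
              x$tilt_index_deg,
              if (is.na(x$rot_index_deg)) "NA"
              else sprintf("%.2f", x$rot_index_deg)))
  invisible(x)
}
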