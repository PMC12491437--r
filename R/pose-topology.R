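# Membrane-topology post-processing of rigid-body docking poses: each pose
# is a rigid transform of a probe protomer against a fixed, membrane-framed
# target.  Poses whose probe tilts away from the membrane normal or slides
# along it beyond thresholds are discarded, exactly as a membrane-topology
# filter applied after docking.

#' Construct a docking pose
#'
#' A rigid-body docking solution: a proper rotation and a translation (in
#' Angstrom) taking the probe protomer from its reference membrane frame to
#' its docked placement, plus a docking score (higher is better).
#'
#' @param pose_id integer identifier.
#' @param rotation 3 x 3 orthonormal matrix with determinant +1.
#' @param translation length-3 numeric vector (Angstrom).
#' @param score docking score (higher = better).
#' @return An object of class `dock_pose`.
#' @export
dock_pose <- function(pose_id, rotation, translation, score) {
  if (!.is_rotation(rotation))
    stop("rotation must be orthonormal with det +1", call. = FALSE)
  if (length(translation) != 3L || !all(is.finite(translation)))
    stop("translation must be a finite length-3 vector", call. = FALSE)
  .check_scalar(score, "score")
  structure(list(pose_id = as.integer(pose_id),
                 rotation = unname(rotation),
                 translation = as.numeric(translation),
                 score = score),
            class = "dock_pose")
}

#' @export
print.dock_pose <- function(x, ...) {
  cat(sprintf("<dock_pose> id %d, score %.3f\n", x$pose_id, x$score))
  invisible(x)
}

#' Topology filter configuration
#'
#' @param tilt_max_rad maximum allowed tilt angle of the probe away from the
#'   membrane normal (default 0.4 rad).
#' @param z_offset_max_A maximum allowed absolute displacement of the probe
#'   geometric center along the membrane normal (default 6.0 Angstrom).
#' @param keep_best number of top-scored solutions retained before the
#'   topology filter (default 4000).
#' @return A list of class `topology_filter_config`.
#' @export
topology_filter_config <- function(tilt_max_rad = 0.4, z_offset_max_A = 6.0,
                                   keep_best = 4000L) {
  .check_scalar(tilt_max_rad, "tilt_max_rad", positive = TRUE)
  .check_scalar(z_offset_max_A, "z_offset_max_A", positive = TRUE)
  .check_scalar(keep_best, "keep_best", positive = TRUE, integer = TRUE)
  structure(list(tilt_max_rad = tilt_max_rad,
                 z_offset_max_A = z_offset_max_A,
                 keep_best = as.integer(keep_best)),
            class = "topology_filter_config")
}

#' Tilt and z-offset of a pose
#'
#' The tilt angle is the deviation of the probe's rotated z axis from the
#' membrane normal, `acos((R z) . z)`; the z-offset is the displacement of
#' the probe's Calpha geometric center along the membrane normal,
#' `(R c + t - c)[3]`.
#'
#' @param pose a [dock_pose()].
#' @param probe the probe [structure_model()] in its reference membrane
#'   frame.
#' @return list with `tilt_rad` (in `[0, pi]`) and `z_offset_A` (signed).
#' @export
compute_topology <- function(pose, probe) {
  stopifnot(inherits(pose, "dock_pose"))
  cen <- ca_centroid(probe)
  tilt <- acos(.clamp(pose$rotation[3, 3], -1, 1))
  zoff <- as.numeric(pose$rotation %*% cen + pose$translation - cen)[3]
  list(tilt_rad = tilt, z_offset_A = zoff)
}

# rank poses: score descending, ties broken by pose_id ascending
.rank_poses <- function(poses) {
  sc <- vapply(poses, `[[`, numeric(1), "score")
  id <- vapply(poses, `[[`, integer(1), "pose_id")
  poses[order(-sc, id)]
}

#' Filter poses by membrane topology
#'
#' Retains the `keep_best` top-scored solutions (ties broken by pose id
#' ascending), then keeps those with tilt `<= tilt_max_rad` and absolute
#' z-offset `<= z_offset_max_A`. Output preserves score order; topology
#' metrics are attached to every retained pose.
#'
#' @param poses list of [dock_pose()].
#' @param probe the probe [structure_model()].
#' @param config a [topology_filter_config()].
#' @return A list of accepted poses, each with elements `tilt_rad` and
#'   `z_offset_A` added, carrying attribute `n_considered` (after the
#'   keep-best cut) for logging.
#' @export
filter_poses <- function(poses, probe, config = topology_filter_config()) {
  stopifnot(inherits(config, "topology_filter_config"))
  if (!length(poses)) {
    message("filter_poses: empty input")
    return(structure(list(), n_considered = 0L))
  }
  ranked <- .rank_poses(poses)
  ranked <- ranked[seq_len(min(length(ranked), config$keep_best))]
  out <- list()
  for (p in ranked) {
    m <- compute_topology(p, probe)
    if (m$tilt_rad <= config$tilt_max_rad &&
        abs(m$z_offset_A) <= config$z_offset_max_A) {
      p$tilt_rad <- m$tilt_rad
      p$z_offset_A <- m$z_offset_A
      out[[length(out) + 1L]] <- p
    }
  }
  structure(out, n_considered = length(ranked))
}

#' Pose table I/O
#'
#' Poses serialize to/from a TSV with columns
#' `pose_id,score,r11..r33,tx,ty,tz` (rotation in row-major order).
#'
#' @param poses list of [dock_pose()].
#' @param path TSV path.
#' @return `write_pose_table()` returns `path` invisibly;
#'   `read_pose_table()` returns a list of `dock_pose`.
#' @export
write_pose_table <- function(poses, path) {
  rows <- lapply(poses, function(p) {
    data.frame(pose_id = p$pose_id, score = p$score,
               t(as.vector(t(p$rotation))),
               tx = p$translation[1], ty = p$translation[2],
               tz = p$translation[3])
  })
  df <- do.call(rbind, rows)
  names(df)[3:11] <- c("r11", "r12", "r13", "r21", "r22", "r23",
                       "r31", "r32", "r33")
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pose_table
#' @export
read_pose_table <- function(path) {
  df <- utils::read.delim(path)
  lapply(seq_len(nrow(df)), function(i) {
    R <- matrix(as.numeric(df[i, c("r11", "r12", "r13", "r21", "r22", "r23",
                                   "r31", "r32", "r33")]),
                nrow = 3, byrow = TRUE)
    dock_pose(df$pose_id[i], R,
              c(df$tx[i], df$ty[i], df$tz[i]), df$score[i])
  })
}
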