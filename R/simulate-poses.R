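# Ground-truth-labelled simulator for docking pose sets: each pose is
# built from a sampled tilt angle (rotation about a random in-plane axis
# composed with a random spin about z) and a sampled z-offset, so the
# topology filter can be checked against the exact latent values.

#' Pose simulation configuration
#'
#' @param n_poses number of poses to generate.
#' @param tilt_range length-1 or length-2 numeric: fixed tilt or uniform
#'   sampling range in radians (within `[0, pi]`).
#' @param zoffset_range length-1 or length-2 numeric: fixed z-offset or
#'   uniform range in Angstrom.
#' @param xy_jitter_A in-plane translation jitter, uniform in
#'   `[-xy_jitter_A, xy_jitter_A]` per axis (default 5).
#' @param score_fun monotone map from pose index to docking score; default
#'   `n_poses - index + 1` so earlier poses score higher.
#' @param seed integer seed (required).
#' @return list of class `pose_sim_config`.
#' @export
pose_sim_config <- function(n_poses, tilt_range, zoffset_range,
                            xy_jitter_A = 5,
                            score_fun = NULL, seed) {
  .check_scalar(n_poses, "n_poses", positive = TRUE, integer = TRUE)
  if (!length(tilt_range) %in% 1:2 || any(tilt_range < 0) ||
      any(tilt_range > pi))
    stop("tilt_range must be 1 or 2 values in [0, pi]", call. = FALSE)
  if (!length(zoffset_range) %in% 1:2)
    stop("zoffset_range must be 1 or 2 values", call. = FALSE)
  .check_scalar(xy_jitter_A, "xy_jitter_A", nonneg = TRUE)
  if (is.null(score_fun)) score_fun <- function(i, n) n - i + 1
  structure(list(n_poses = as.integer(n_poses),
                 tilt_range = as.numeric(tilt_range),
                 zoffset_range = as.numeric(zoffset_range),
                 xy_jitter_A = xy_jitter_A,
                 score_fun = score_fun,
                 seed = .check_seed(seed)),
            class = "pose_sim_config")
}

.sample_range <- function(n, rng) {
  if (length(rng) == 1L) rep(rng, n) else stats::runif(n, rng[1], rng[2])
}

#' Simulate docking poses with known topology
#'
#' Each pose's rotation is `Rz(psi) %*% Raxis(u, tilt)` with `psi` a random
#' spin about z and `u` a random in-plane axis, so the rotated z axis
#' deviates from the membrane normal by exactly the sampled tilt. The
#' translation's z component is chosen so the probe's Calpha center moves
#' along z by exactly the sampled z-offset (the in-plane components are
#' jittered). Ground truth records tilt, z-offset and the acceptance flag
#' at the supplied thresholds.
#'
#' @param config a [pose_sim_config()].
#' @param probe the probe [structure_model()] the poses will be applied to.
#' @param tilt_max_rad,z_offset_max_A thresholds used to label the truth
#'   acceptance flag (defaults 0.4 rad, 6.0 Angstrom).
#' @return list of class `pose_sim`: `poses` (list of [dock_pose()]) and
#'   `truth` (data.frame `pose_id, score, tilt_rad, z_offset_A, accept`).
#' @export
simulate_poses <- function(config, probe,
                           tilt_max_rad = 0.4, z_offset_max_A = 6.0) {
  stopifnot(inherits(config, "pose_sim_config"))
  cen <- ca_centroid(probe)
  .with_seed(config$seed, {
    n <- config$n_poses
    tilt <- .sample_range(n, config$tilt_range)
    zoff <- .sample_range(n, config$zoffset_range)
    psi <- stats::runif(n, 0, 2 * pi)
    phi <- stats::runif(n, 0, 2 * pi)
    tx <- stats::runif(n, -config$xy_jitter_A, config$xy_jitter_A)
    ty <- stats::runif(n, -config$xy_jitter_A, config$xy_jitter_A)
    poses <- vector("list", n)
    for (i in seq_len(n)) {
      R <- rot_z(psi[i]) %*% rot_axis(c(cos(phi[i]), sin(phi[i]), 0),
                                      tilt[i])
      # pick tz so the Calpha center displacement along z equals the
      # sampled z-offset for this probe
      tz <- zoff[i] - as.numeric(R %*% cen - cen)[3]
      poses[[i]] <- dock_pose(i, R, c(tx[i], ty[i], tz),
                              config$score_fun(i, n))
    }
    truth <- data.frame(
      pose_id = seq_len(n),
      score = vapply(poses, `[[`, numeric(1), "score"),
      tilt_rad = tilt, z_offset_A = zoff,
      accept = tilt <= tilt_max_rad & abs(zoff) <= z_offset_max_A)
    structure(list(poses = poses, truth = truth, config = config),
              class = "pose_sim")
  })
}

#' @export
print.pose_sim <- function(x, ...) {
  cat(sprintf("<pose_sim> %d poses, %d pass topology truth\n",
              nrow(x$truth), sum(x$truth$accept)))
  invisible(x)
}
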