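# Leader clustering of docking poses under a Calpha RMSD cutoff.  The
# target protomer fixes the frame, so RMSD is computed on transformed probe
# Calpha coordinates with no re-superposition: pose differences are
# physical displacements, and a pure translation by d gives RMSD exactly d.

.pose_ca <- function(pose, ca) {
  sweep(ca %*% t(pose$rotation), 2, pose$translation, "+")
}

#' Calpha RMSD between two poses of the same probe
#'
#' RMSD over probe Calpha coordinates after applying each rigid transform,
#' without re-superposition (the docking target fixes the frame). The
#' metric is symmetric and zero iff the transforms place the probe
#' identically on its Calpha set.
#'
#' @param a,b [dock_pose()]s of the same probe.
#' @param probe the probe [structure_model()].
#' @return RMSD in Angstrom.
#' @export
pose_rmsd <- function(a, b, probe) {
  ca <- ca_coords(probe)
  A <- .pose_ca(a, ca); B <- .pose_ca(b, ca)
  sqrt(mean(rowSums((A - B)^2)))
}

#' Leader clustering of poses by Calpha RMSD
#'
#' Greedy leader clustering on the score-ranked pose list: the best-scored
#' unclustered pose becomes a cluster center and absorbs every unclustered
#' pose within `rmsd_cutoff_A` of it; repeat until all poses are assigned.
#' Centers are therefore pairwise at least the cutoff apart (in formation
#' order), every member is within the cutoff of its center, and the result
#' is deterministic given the score order (ties broken by pose id).
#'
#' @param poses list of [dock_pose()] (ranked or not; ranked internally by
#'   score descending, pose id ascending).
#' @param probe the probe [structure_model()].
#' @param rmsd_cutoff_A clustering cutoff (default 3 Angstrom).
#' @return An object of class `cluster_set`: list with `clusters` (list of
#'   `center_pose_id` + `member_pose_ids`), `assignment` (data.frame
#'   `pose_id, score, cluster_id, is_center`), and `rmsd_cutoff_A`.
#' @export
cluster_poses <- function(poses, probe, rmsd_cutoff_A = 3.0) {
  .check_scalar(rmsd_cutoff_A, "rmsd_cutoff_A", positive = TRUE)
  poses <- .rank_poses(poses)
  n <- length(poses)
  ca <- ca_coords(probe)
  if (n == 0L)
    return(structure(list(clusters = list(),
                          assignment = data.frame(pose_id = integer(0),
                                                  score = numeric(0),
                                                  cluster_id = integer(0),
                                                  is_center = logical(0)),
                          rmsd_cutoff_A = rmsd_cutoff_A),
                     class = "cluster_set"))
  coords <- lapply(poses, .pose_ca, ca = ca)
  cid <- integer(n)
  clusters <- list()
  k <- 0L
  for (i in seq_len(n)) {
    if (cid[i] != 0L) next
    k <- k + 1L
    free <- which(cid == 0L)
    rms <- vapply(free, function(j)
      sqrt(mean(rowSums((coords[[j]] - coords[[i]])^2))), numeric(1))
    members <- free[rms <= rmsd_cutoff_A]
    cid[members] <- k
    clusters[[k]] <- list(
      center_pose_id = poses[[i]]$pose_id,
      member_pose_ids = vapply(poses[members], `[[`, integer(1), "pose_id"))
  }
  assignment <- data.frame(
    pose_id = vapply(poses, `[[`, integer(1), "pose_id"),
    score = vapply(poses, `[[`, numeric(1), "score"),
    cluster_id = cid,
    is_center = vapply(seq_len(n), function(i)
      poses[[i]]$pose_id == clusters[[cid[i]]]$center_pose_id, logical(1)))
  structure(list(clusters = clusters, assignment = assignment,
                 rmsd_cutoff_A = rmsd_cutoff_A),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d clusters over %d poses (cutoff %.1f A)\n",
              length(x$clusters), nrow(x$assignment), x$rmsd_cutoff_A))
  invisible(x)
}
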