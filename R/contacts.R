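# Interface contacts and steric clash counting on heavy atoms.  Hydrogens
# are ignored in every distance operation.

#' Residue-residue interface contacts
#'
#' Lists every (target residue, probe residue) pair whose minimum
#' heavy-atom distance is at or below the cutoff, sorted by that distance.
#'
#' @param target the fixed [structure_model()].
#' @param probe the posed probe `structure_model` (already transformed; use
#'   [apply_pose()] first if needed).
#' @param cutoff_A contact cutoff on the minimum heavy-atom distance
#'   (default 4.5 Angstrom).
#' @return An object of class `contact_map`: data.frame with columns
#'   `target_chain, target_resno, target_resid, probe_chain, probe_resno,
#'   probe_resid, min_dist_A`, with attribute `cutoff_A`.
#' @export
interface_contacts <- function(target, probe, cutoff_A = 4.5) {
  .check_scalar(cutoff_A, "cutoff_A", positive = TRUE)
  ta <- .heavy(target); pa <- .heavy(probe)
  empty <- data.frame(target_chain = character(0), target_resno = integer(0),
                      target_resid = character(0), probe_chain = character(0),
                      probe_resno = integer(0), probe_resid = character(0),
                      min_dist_A = numeric(0))
  if (!nrow(ta) || !nrow(pa))
    return(structure(empty, cutoff_A = cutoff_A, class = c("contact_map",
                                                           "data.frame")))
  A <- as.matrix(ta[, c("x", "y", "z")])
  B <- as.matrix(pa[, c("x", "y", "z")])
  # full pairwise distances; structures at this stage are <= a few
  # thousand atoms, so the matrix is affordable
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  hit <- which(d2 <= cutoff_A^2, arr.ind = TRUE)
  if (!nrow(hit))
    return(structure(empty, cutoff_A = cutoff_A, class = c("contact_map",
                                                           "data.frame")))
  df <- data.frame(
    target_chain = ta$chain[hit[, 1]], target_resno = ta$resno[hit[, 1]],
    target_resid = ta$resid[hit[, 1]],
    probe_chain = pa$chain[hit[, 2]], probe_resno = pa$resno[hit[, 2]],
    probe_resid = pa$resid[hit[, 2]],
    dist = sqrt(d2[hit]))
  key <- paste(df$target_chain, df$target_resno, df$probe_chain,
               df$probe_resno, sep = "|")
  mins <- tapply(df$dist, key, min)
  first <- df[!duplicated(key), , drop = FALSE]
  first$min_dist_A <- as.numeric(mins[paste(first$target_chain,
                                            first$target_resno,
                                            first$probe_chain,
                                            first$probe_resno, sep = "|")])
  first$dist <- NULL
  first <- first[order(first$min_dist_A), , drop = FALSE]
  rownames(first) <- NULL
  structure(first, cutoff_A = cutoff_A, class = c("contact_map",
                                                  "data.frame"))
}

#' Steric clash check for stoichiometry analysis
#'
#' Counts heavy-atom pairs closer than `clash_distance_A` between every
#' pair of effector copies and between each copy and the receptor dimer.
#' Used to ask whether two effector molecules (e.g. two G-protein
#' heterotrimers) can dock on a receptor dimer simultaneously: a pair count
#' above `pair_threshold` marks the arrangement as clashing.
#'
#' @param dimer the receptor dimer [structure_model()].
#' @param copies list of posed effector `structure_model`s (at least one).
#' @param clash_distance_A heavy-atom clash distance (default 2.5 A; pairs
#'   strictly below it count).
#' @param pair_threshold verdict is `"clashing"` iff the clash-pair count
#'   exceeds this (default 10).
#' @return list of class `clash_report` with `n_clashing_pairs`,
#'   `clash_distance_A`, `pair_threshold`, `verdict`
#'   (`"compatible"`/`"clashing"`) and the per-component counts.
#' @export
clash_check <- function(dimer, copies, clash_distance_A = 2.5,
                        pair_threshold = 10L) {
  .check_scalar(clash_distance_A, "clash_distance_A", positive = TRUE)
  .check_scalar(pair_threshold, "pair_threshold", nonneg = TRUE,
                integer = TRUE)
  if (!length(copies))
    stop("clash_check: need at least one effector copy", call. = FALSE)
  count_pairs <- function(ma, mb) {
    A <- as.matrix(.heavy(ma)[, c("x", "y", "z")])
    B <- as.matrix(.heavy(mb)[, c("x", "y", "z")])
    if (!nrow(A) || !nrow(B)) return(0L)
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    sum(d2 < clash_distance_A^2)
  }
  inter_copy <- 0L
  if (length(copies) > 1L) {
    for (i in seq_len(length(copies) - 1L))
      for (j in (i + 1L):length(copies))
        inter_copy <- inter_copy + count_pairs(copies[[i]], copies[[j]])
  }
  copy_dimer <- sum(vapply(copies, count_pairs, numeric(1), mb = dimer))
  n <- inter_copy + copy_dimer
  structure(list(n_clashing_pairs = as.integer(n),
                 inter_copy_pairs = as.integer(inter_copy),
                 copy_dimer_pairs = as.integer(copy_dimer),
                 clash_distance_A = clash_distance_A,
                 pair_threshold = as.integer(pair_threshold),
                 verdict = if (n > pair_threshold) "clashing"
                 else "compatible"),
            class = "clash_report")
}

#' @export
print.clash_report <- function(x, ...) {
  cat(sprintf(
    "<clash_report> %d heavy-atom pairs < %.2f A (threshold %d) -> %s\n",
    x$n_clashing_pairs, x$clash_distance_A, x$pair_threshold, x$verdict))
  invisible(x)
}
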