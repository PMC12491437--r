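# Independent brute-force oracles and toy fixtures.  Each oracle is a
# literal, unoptimized transcription of the rule it checks, written
# separately from the package implementation.

# Greedy fixed-radius assignment, brute force: visit points in the given
# canonical order; an unassigned point opens a complex and claims every
# unassigned point at distance <= r, recomputing distances one at a time.
oracle_greedy_assign <- function(x, y, r) {
  n <- length(x)
  cid <- rep(NA_integer_, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (!is.na(cid[i])) next
    k <- k + 1L
    cid[i] <- k
    for (j in seq_len(n)) {
      if (is.na(cid[j])) {
        if (sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2) <= r) cid[j] <- k
      }
    }
  }
  cid
}

# Single-linkage components, brute force: start from singletons and merge
# any two groups containing a within-radius pair until nothing changes.
oracle_single_linkage <- function(x, y, r) {
  n <- length(x)
  cid <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (cid[i] != cid[j] &&
          sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2) <= r) {
        cid[cid == cid[j]] <- cid[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(cid, unique(cid))
}

# Duplicate discounting, brute force on pre-sorted points: each surviving
# point discounts later points strictly within r of it.
oracle_dedup_keep <- function(x, y, r) {
  n <- length(x)
  removed <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (removed[i]) next
    for (j in seq_len(n)) {
      if (j > i && !removed[j] &&
          sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2) < r)
        removed[j] <- TRUE
    }
  }
  !removed
}

# canonical complex-size multiset from an id labelling
sizes_of <- function(cid) sort(as.integer(table(cid)))

# toy structure: CA-only chain along given coordinates
toy_structure <- function(xyz, chain = "A", resno = NULL, element = "C",
                          atom = "CA", resid = "ALA") {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  structure_model(data.frame(
    chain = chain, resno = resno %||% seq_len(n), resid = resid,
    atom = atom, element = element,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# five-atom asymmetric probe used in RMSD/topology tests
toy_probe <- function() {
  toy_structure(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0),
                      c(0, 0, 5), c(1, 2, 3)))
}

# write a minimal, synthetic PDB file (fixed-format ATOM records)
write_toy_pdb <- function(model, path) {
  a <- model$atoms
  lines <- vapply(seq_len(nrow(a)), function(i) {
    sprintf("ATOM  %5d  %-3s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            i, a$atom[i], a$resid[i], a$chain[i], a$resno[i],
            a$x[i], a$y[i], a$z[i], a$element[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

# identity pose helper
identity_pose <- function(id = 1L, score = 1) {
  dock_pose(id, diag(3), c(0, 0, 0), score)
}

# pure-translation pose
translate_pose <- function(t, id = 1L, score = 1) {
  dock_pose(id, diag(3), t, score)
}
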