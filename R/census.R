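# Oligomer census from 2D localization maps: duplicate discounting at a
# fixed radius, fixed-radius neighborhood assignment without double
# counting (greedy seeded aggregation, with single-linkage as a labelled
# alternative), size tables and receptor-density stratification.

#' Census configuration
#'
#' Parameters of the localization-census pipeline. Defaults follow the
#' published procedure: duplicates discounted within 20 nm, neighborhood
#' search radius 50 nm, receptor-density split at 100 receptors/um^2.
#'
#' @param dedup_radius_nm duplicate-discount radius; points strictly closer
#'   than this are treated as re-blinks of one receptor.
#' @param search_radius_nm fixed neighborhood radius for complex assignment
#'   (membership uses distance `<=` radius).
#' @param assignment_mode `"greedy_seed"` (default; a seed receptor collects
#'   its unassigned neighbors and all are retired from further searches) or
#'   `"single_linkage"` (complexes are connected components of the
#'   within-radius graph), provided for sensitivity analysis.
#' @param density_threshold_per_um2 density above which (strictly) an ROI is
#'   classed `"high"`.
#' @param max_reported_size sizes `>= max_reported_size` are pooled into one
#'   reporting bin.
#' @return A list of class `census_config`.
#' @export
census_config <- function(dedup_radius_nm = 20,
                          search_radius_nm = 50,
                          assignment_mode = c("greedy_seed", "single_linkage"),
                          density_threshold_per_um2 = 100,
                          max_reported_size = 10) {
  .check_scalar(dedup_radius_nm, "dedup_radius_nm", positive = TRUE)
  .check_scalar(search_radius_nm, "search_radius_nm", positive = TRUE)
  if (dedup_radius_nm >= search_radius_nm)
    stop("dedup_radius_nm must be < search_radius_nm", call. = FALSE)
  .check_scalar(density_threshold_per_um2, "density_threshold_per_um2",
                positive = TRUE)
  .check_scalar(max_reported_size, "max_reported_size", positive = TRUE,
                integer = TRUE)
  structure(list(dedup_radius_nm = dedup_radius_nm,
                 search_radius_nm = search_radius_nm,
                 assignment_mode = match.arg(assignment_mode),
                 density_threshold_per_um2 = density_threshold_per_um2,
                 max_reported_size = as.integer(max_reported_size)),
            class = "census_config")
}

#' Discount duplicate localizations
#'
#' Greedy duplicate removal: points are visited in canonical order (frame,
#' then x, then y, then input index); each surviving point discounts every
#' not-yet-visited point strictly within `dedup_radius_nm` of it. The rule
#' is deliberately non-transitive (a discounted point does not discount its
#' own neighbors), so a chain at 0, 15, 30 nm keeps the points at 0 and 30.
#' The output is in canonical order and independent of input row order.
#'
#' @param map a [localization_map()].
#' @param dedup_radius_nm discount radius in nm (default 20).
#' @return A deduplicated `localization_map`.
#' @export
deduplicate <- function(map, dedup_radius_nm = 20) {
  stopifnot(inherits(map, "localization_map"))
  .check_scalar(dedup_radius_nm, "dedup_radius_nm", positive = TRUE)
  pts <- map$points
  n <- nrow(pts)
  if (n == 0L) return(map)
  pts <- pts[.canonical_order(pts), , drop = FALSE]
  x <- pts$x_nm; y <- pts$y_nm
  r2 <- dedup_radius_nm^2
  removed <- logical(n)
  for (i in seq_len(n)) {
    if (removed[i]) next
    if (i == n) break
    j <- (i + 1L):n
    j <- j[!removed[j]]
    if (length(j)) {
      d2 <- (x[j] - x[i])^2 + (y[j] - y[i])^2
      removed[j[d2 < r2]] <- TRUE
    }
  }
  localization_map(pts[!removed, , drop = FALSE],
                   map$roi_width_nm, map$roi_height_nm)
}

#' Assign localizations to receptor complexes
#'
#' Fixed-radius neighborhood assignment of (deduplicated) localizations to
#' monomer/di/oligomer complexes, without double counting.
#'
#' In `greedy_seed` mode points are visited in canonical order; each
#' unassigned point becomes a seed, collects every still-unassigned point
#' within `search_radius_nm` (inclusive) of it, and the whole group is
#' retired from further searches. A seed with no free neighbor is a monomer.
#' In `single_linkage` mode complexes are the connected components of the
#' graph linking points within the search radius; it can only merge groups
#' relative to greedy seeding, never split them.
#'
#' The map is assumed to be deduplicated already; this operation does not
#' re-deduplicate.
#'
#' @param map a [localization_map()] (already deduplicated).
#' @param config a [census_config()].
#' @return An object of class `oligomer_assignment`: list with `points`
#'   (data.frame `x_nm,y_nm,frame,complex_id,complex_size`) and `sizes`
#'   (integer complex size per complex id).
#' @export
assign_complexes <- function(map, config = census_config()) {
  stopifnot(inherits(map, "localization_map"),
            inherits(config, "census_config"))
  pts <- map$points
  n <- nrow(pts)
  if (n == 0L) {
    out <- cbind(pts, complex_id = integer(0), complex_size = integer(0))
    return(structure(list(points = out, sizes = integer(0),
                          mode = config$assignment_mode),
                     class = "oligomer_assignment"))
  }
  pts <- pts[.canonical_order(pts), , drop = FALSE]
  x <- pts$x_nm; y <- pts$y_nm
  r2 <- config$search_radius_nm^2
  cid <- integer(n)
  if (config$assignment_mode == "greedy_seed") {
    k <- 0L
    for (i in seq_len(n)) {
      if (cid[i] != 0L) next
      k <- k + 1L
      free <- which(cid == 0L)
      d2 <- (x[free] - x[i])^2 + (y[free] - y[i])^2
      cid[free[d2 <= r2]] <- k
    }
  } else {
    # union-find over all within-radius pairs (transitive linkage)
    parent <- seq_len(n)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    for (i in seq_len(n - 1L)) {
      j <- (i + 1L):n
      d2 <- (x[j] - x[i])^2 + (y[j] - y[i])^2
      for (jj in j[d2 <= r2]) {
        ri <- find(i); rj <- find(jj)
        if (ri != rj) parent[rj] <- ri
      }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    cid <- match(roots, unique(roots))
  }
  sizes <- as.integer(table(factor(cid, levels = seq_len(max(cid)))))
  pts$complex_id <- cid
  pts$complex_size <- sizes[cid]
  rownames(pts) <- NULL
  structure(list(points = pts, sizes = sizes,
                 mode = config$assignment_mode),
            class = "oligomer_assignment")
}

#' @export
print.oligomer_assignment <- function(x, ...) {
  cat(sprintf("<oligomer_assignment> %d points, %d complexes (%s)\n",
              nrow(x$points), length(x$sizes), x$mode))
  invisible(x)
}

#' Oligomer census
#'
#' Summarizes an assignment into the monomer/di/oligomer census: number of
#' complexes per size (sizes `>= max_reported_size` pooled), the percentage
#' of total receptors in each size class (receptor basis, not complex
#' basis), percent monomeric/associated, and the receptor surface density
#' with its high/low class (strictly greater than the threshold is high).
#'
#' @param assignment an [assign_complexes()] result.
#' @param map the `localization_map` the assignment was computed on (supplies
#'   the ROI area for the density).
#' @param config a [census_config()].
#' @return An object of class `oligomer_census`.
#' @export
census <- function(assignment, map, config = census_config()) {
  stopifnot(inherits(assignment, "oligomer_assignment"),
            inherits(map, "localization_map"))
  sizes <- assignment$sizes
  total <- sum(sizes)
  if (total != nrow(map$points))
    stop("assignment and map are inconsistent", call. = FALSE)
  maxs <- config$max_reported_size
  pooled <- pmin(sizes, maxs)
  lev <- seq_len(maxs)
  cnt <- as.integer(table(factor(pooled, levels = lev)))
  names(cnt) <- c(as.character(lev[-maxs]), paste0(maxs, "+"))
  # receptor-basis percentages: receptors in complexes of each (pooled)
  # size over total receptors; the pooled bin uses true sizes.
  rec_by_bin <- vapply(lev, function(s) {
    if (s < maxs) sum(sizes[sizes == s]) else sum(sizes[sizes >= maxs])
  }, numeric(1))
  pct <- if (total > 0) 100 * rec_by_bin / total else rep(0, maxs)
  names(pct) <- names(cnt)
  area_um2 <- (map$roi_width_nm / 1000) * (map$roi_height_nm / 1000)
  density <- total / area_um2
  structure(list(
    total_receptors = total,
    count_by_size = cnt,
    pct_by_size = pct,
    pct_monomer = unname(pct[1]),
    pct_associated = if (total > 0) 100 - unname(pct[1]) else 0,
    density_per_um2 = density,
    density_class = if (density > config$density_threshold_per_um2)
      "high" else "low",
    n_complexes = length(sizes),
    assignment_mode = assignment$mode
  ), class = "oligomer_census")
}

#' @export
print.oligomer_census <- function(x, ...) {
  cat(sprintf(
    "<oligomer_census> %d receptors in %d complexes | monomer %.1f%% / associated %.1f%% | %.1f receptors/um^2 (%s)\n",
    x$total_receptors, x$n_complexes, x$pct_monomer, x$pct_associated,
    x$density_per_um2, x$density_class))
  nz <- x$count_by_size[x$count_by_size > 0]
  if (length(nz)) {
    tab <- data.frame(size = names(nz), n_complexes = as.integer(nz),
                      pct_receptors = round(x$pct_by_size[names(nz)], 2))
    print(tab, row.names = FALSE)
  }
  invisible(x)
}

#' Census as a tidy table
#'
#' @param x an `oligomer_census`.
#' @param ... unused.
#' @return data.frame with columns `size`, `n_complexes`, `pct_receptors`.
#' @export
as.data.frame.oligomer_census <- function(x, ...) {
  data.frame(size = names(x$count_by_size),
             n_complexes = as.integer(x$count_by_size),
             pct_receptors = as.numeric(x$pct_by_size),
             row.names = NULL)
}

#' Stratify censuses by receptor density class
#'
#' Groups a set of per-ROI censuses by their high/low receptor-density
#' class and summarizes the monomeric and associated percentages per class.
#'
#' @param censuses list of [census()] results (at least one).
#' @return data.frame with one row per density class present: `n_roi`, mean
#'   and sd of `pct_monomer` and `pct_associated`, mean density.
#' @export
stratify_by_density <- function(censuses) {
  if (!length(censuses))
    stop("stratify_by_density: need at least one census", call. = FALSE)
  stopifnot(all(vapply(censuses, inherits, logical(1), "oligomer_census")))
  df <- data.frame(
    density_class = vapply(censuses, `[[`, character(1), "density_class"),
    pct_monomer = vapply(censuses, `[[`, numeric(1), "pct_monomer"),
    pct_associated = vapply(censuses, `[[`, numeric(1), "pct_associated"),
    density = vapply(censuses, `[[`, numeric(1), "density_per_um2"))
  out <- do.call(rbind, lapply(split(df, df$density_class), function(g) {
    data.frame(density_class = g$density_class[1],
               n_roi = nrow(g),
               mean_pct_monomer = mean(g$pct_monomer),
               sd_pct_monomer = if (nrow(g) > 1) stats::sd(g$pct_monomer) else NA_real_,
               mean_pct_associated = mean(g$pct_associated),
               sd_pct_associated = if (nrow(g) > 1) stats::sd(g$pct_associated) else NA_real_,
               mean_density_per_um2 = mean(g$density))
  }))
  rownames(out) <- NULL
  out
}

#' Write census tables
#'
#' Writes the size table as TSV (`size,n_complexes,pct_receptors`) and the
#' scalar summary (totals, density, class) as JSON.
#'
#' @param cen an `oligomer_census`.
#' @param tsv_path,json_path output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_census <- function(cen, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(cen, "oligomer_census"))
  if (!is.null(tsv_path))
    utils::write.table(as.data.frame(cen), tsv_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  if (!is.null(json_path)) {
    s <- cen[c("total_receptors", "n_complexes", "pct_monomer",
               "pct_associated", "density_per_um2", "density_class",
               "assignment_mode")]
    jsonlite::write_json(s, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(tsv = tsv_path, json = json_path))
}
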