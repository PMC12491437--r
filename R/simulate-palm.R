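# Ground-truth-labelled simulator for single-molecule localization maps:
# complexes of known size are scattered over the ROI, each receptor emits a
# primary localization plus Poisson blink duplicates, and every latent
# quantity (complex membership, true positions) is recorded.

#' PALM simulation configuration
#'
#' Describes a synthetic localization experiment with known ground truth.
#' Complex centers are uniform over the ROI (optionally with a minimum
#' pairwise separation); each complex of size s places s true receptors
#' uniformly in a disc of `cluster_radius_nm` around its center; each true
#' receptor emits one primary localization (Gaussian error
#' `loc_error_sd_nm`) plus `Poisson(blink_rate)` blink duplicates (spread
#' `blink_sd_nm`). Emitted points falling outside the ROI are re-drawn so
#' density stays interpretable as count/area.
#'
#' @param counts_per_size named list/vector mapping oligomer size to the
#'   number of complexes of that size, e.g. `c("1" = 50, "2" = 30)`.
#' @param roi_width_nm,roi_height_nm ROI dimensions (default 7000 x 7000 nm,
#'   the 7 x 7 um census window).
#' @param cluster_radius_nm disc radius for receptor placement within a
#'   complex (default 10 nm; radii `<=` 15 nm keep intra-complex distances
#'   below the 50 nm search radius).
#' @param loc_error_sd_nm Gaussian localization error of the primary
#'   emission (default 10 nm, a stand-in consistent with sub-10 nm
#'   localization precision; the actual precision of the dye/instrument is
#'   not published).
#' @param blink_rate mean number of extra localizations per receptor
#'   (Poisson; default 0 = no blinking).
#' @param blink_sd_nm Gaussian spread of blink duplicates around the true
#'   receptor position (default 10 nm).
#' @param min_center_sep_nm optional minimum pairwise separation between
#'   complex centers (well-separated mode); `NULL` disables it.
#' @param seed integer seed (required); fixing it makes the output
#'   bit-identical across runs.
#' @return A list of class `palm_sim_config`.
#' @export
palm_sim_config <- function(counts_per_size,
                            roi_width_nm = 7000, roi_height_nm = 7000,
                            cluster_radius_nm = 10,
                            loc_error_sd_nm = 10,
                            blink_rate = 0, blink_sd_nm = 10,
                            min_center_sep_nm = NULL,
                            seed) {
  counts <- unlist(counts_per_size)
  if (is.null(names(counts)) || any(names(counts) == ""))
    stop("counts_per_size must be named by oligomer size", call. = FALSE)
  sizes <- as.integer(names(counts))
  if (any(is.na(sizes)) || any(sizes < 1))
    stop("counts_per_size names must be integer sizes >= 1", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts_per_size values must be non-negative integers",
         call. = FALSE)
  .check_scalar(roi_width_nm, "roi_width_nm", positive = TRUE)
  .check_scalar(roi_height_nm, "roi_height_nm", positive = TRUE)
  .check_scalar(cluster_radius_nm, "cluster_radius_nm", positive = TRUE)
  .check_scalar(loc_error_sd_nm, "loc_error_sd_nm", nonneg = TRUE)
  .check_scalar(blink_rate, "blink_rate", nonneg = TRUE)
  .check_scalar(blink_sd_nm, "blink_sd_nm", positive = TRUE)
  if (!is.null(min_center_sep_nm))
    .check_scalar(min_center_sep_nm, "min_center_sep_nm", positive = TRUE)
  structure(list(counts_per_size = stats::setNames(as.integer(counts),
                                                   as.character(sizes)),
                 roi_width_nm = roi_width_nm, roi_height_nm = roi_height_nm,
                 cluster_radius_nm = cluster_radius_nm,
                 loc_error_sd_nm = loc_error_sd_nm,
                 blink_rate = blink_rate, blink_sd_nm = blink_sd_nm,
                 min_center_sep_nm = min_center_sep_nm,
                 seed = .check_seed(seed)),
            class = "palm_sim_config")
}

# uniform point in a disc of radius r around (cx, cy)
.runif_disc <- function(n, cx, cy, r) {
  th <- stats::runif(n, 0, 2 * pi)
  rad <- r * sqrt(stats::runif(n))
  cbind(cx + rad * cos(th), cy + rad * sin(th))
}

# draw a point by rejection until it falls inside the ROI
.emit_inside <- function(x0, y0, sd, w, h, max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    x <- x0 + stats::rnorm(1, 0, sd)
    y <- y0 + stats::rnorm(1, 0, sd)
    if (x >= 0 && x < w && y >= 0 && y < h) return(c(x, y))
  }
  stop("could not place an emission inside the ROI", call. = FALSE)
}

#' Simulate a localization map with ground truth
#'
#' @param config a [palm_sim_config()].
#' @return A list of class `palm_sim` with elements:
#'   \describe{
#'     \item{map}{a [localization_map()]; frames are the emission order.}
#'     \item{truth}{list with `receptors` (data.frame `receptor_id,
#'       complex_id, size, x_nm, y_nm`), `localizations` (data.frame
#'       `receptor_id, complex_id, is_blink` parallel to the map rows in
#'       generation order) and `counts_per_size`.}
#'   }
#' @export
simulate_localizations <- function(config) {
  stopifnot(inherits(config, "palm_sim_config"))
  .with_seed(config$seed, {
    counts <- config$counts_per_size
    sizes <- as.integer(names(counts))
    complex_sizes <- rep(sizes, counts)
    n_complex <- length(complex_sizes)
    w <- config$roi_width_nm; h <- config$roi_height_nm
    # complex centers, optionally with a minimum pairwise separation
    centers <- matrix(numeric(0), ncol = 2)
    if (n_complex > 0) {
      if (is.null(config$min_center_sep_nm)) {
        centers <- cbind(stats::runif(n_complex, 0, w),
                         stats::runif(n_complex, 0, h))
      } else {
        sep2 <- config$min_center_sep_nm^2
        centers <- matrix(NA_real_, n_complex, 2)
        for (i in seq_len(n_complex)) {
          placed <- FALSE
          for (try in seq_len(2000L)) {
            cand <- c(stats::runif(1, 0, w), stats::runif(1, 0, h))
            if (i == 1L ||
                min((centers[seq_len(i - 1L), 1] - cand[1])^2 +
                    (centers[seq_len(i - 1L), 2] - cand[2])^2) >= sep2) {
              centers[i, ] <- cand; placed <- TRUE; break
            }
          }
          if (!placed)
            stop(sprintf(
              "could not place %d complex centers with min separation %g nm",
              n_complex, config$min_center_sep_nm), call. = FALSE)
        }
      }
    }
    rec <- list(); loc <- list()
    rid <- 0L
    for (ci in seq_len(n_complex)) {
      s <- complex_sizes[ci]
      pos <- .runif_disc(s, centers[ci, 1], centers[ci, 2],
                         config$cluster_radius_nm)
      # receptor true positions must themselves lie in the ROI
      for (k in seq_len(s)) {
        while (pos[k, 1] < 0 || pos[k, 1] >= w ||
               pos[k, 2] < 0 || pos[k, 2] >= h) {
          pos[k, ] <- .runif_disc(1, centers[ci, 1], centers[ci, 2],
                                  config$cluster_radius_nm)
        }
      }
      for (k in seq_len(s)) {
        rid <- rid + 1L
        rec[[rid]] <- data.frame(receptor_id = rid, complex_id = ci,
                                 size = s, x_nm = pos[k, 1], y_nm = pos[k, 2])
        n_blink <- stats::rpois(1, config$blink_rate)
        p <- .emit_inside(pos[k, 1], pos[k, 2], config$loc_error_sd_nm, w, h)
        emis <- list(data.frame(receptor_id = rid, complex_id = ci,
                                is_blink = FALSE, x_nm = p[1], y_nm = p[2]))
        if (n_blink > 0) {
          for (b in seq_len(n_blink)) {
            p <- .emit_inside(pos[k, 1], pos[k, 2], config$blink_sd_nm, w, h)
            emis[[b + 1L]] <- data.frame(receptor_id = rid, complex_id = ci,
                                         is_blink = TRUE,
                                         x_nm = p[1], y_nm = p[2])
          }
        }
        loc[[rid]] <- do.call(rbind, emis)
      }
    }
    receptors <- if (rid > 0) do.call(rbind, rec) else
      data.frame(receptor_id = integer(0), complex_id = integer(0),
                 size = integer(0), x_nm = numeric(0), y_nm = numeric(0))
    locs <- if (length(loc)) do.call(rbind, loc) else
      data.frame(receptor_id = integer(0), complex_id = integer(0),
                 is_blink = logical(0), x_nm = numeric(0), y_nm = numeric(0))
    rownames(receptors) <- rownames(locs) <- NULL
    map <- localization_map(
      data.frame(x_nm = locs$x_nm, y_nm = locs$y_nm,
                 frame = seq_len(nrow(locs))), w, h)
    structure(list(
      map = map,
      truth = list(receptors = receptors,
                   localizations = locs[, c("receptor_id", "complex_id",
                                            "is_blink")],
                   counts_per_size = counts),
      config = config), class = "palm_sim")
  })
}

#' @export
print.palm_sim <- function(x, ...) {
  cat(sprintf(
    "<palm_sim> %d localizations from %d receptors in %d complexes\n",
    n_points(x$map), nrow(x$truth$receptors),
    length(unique(x$truth$receptors$complex_id))))
  invisible(x)
}
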