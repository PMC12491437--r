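# LocalizationMap: an ordered 2D point set inside a rectangular ROI, the
# input to the oligomer census.  Coordinates are in nm; the ROI is the
# half-open rectangle [0, width) x [0, height).

#' Construct a localization map
#'
#' A localization map is an ordered set of 2D single-molecule localizations
#' (nm) inside a rectangular region of interest, as produced by sub-pixel
#' particle localization of PALM/TIRF movies. Coordinates live in the
#' half-open interval `[0, roi_width_nm)` x `[0, roi_height_nm)`.
#'
#' @param points data.frame with columns `x_nm`, `y_nm` and optionally
#'   `frame`; row order is preserved.
#' @param roi_width_nm,roi_height_nm ROI dimensions in nm (default 7000,
#'   the 7 x 7 um census window).
#' @return An object of class `localization_map` with elements `points`,
#'   `roi_width_nm`, `roi_height_nm`.
#' @seealso [read_localizations()], [deduplicate()], [assign_complexes()]
#' @export
localization_map <- function(points, roi_width_nm = 7000,
                             roi_height_nm = 7000) {
  .check_scalar(roi_width_nm, "roi_width_nm", positive = TRUE)
  .check_scalar(roi_height_nm, "roi_height_nm", positive = TRUE)
  if (is.null(points) || nrow(points) == 0L) {
    points <- data.frame(x_nm = numeric(0), y_nm = numeric(0),
                         frame = integer(0))
  }
  if (!all(c("x_nm", "y_nm") %in% names(points)))
    stop("`points` must have columns x_nm and y_nm", call. = FALSE)
  # A missing frame column becomes a constant so the canonical order
  # (frame, x, y) stays independent of input row order.
  if (is.null(points$frame)) points$frame <- rep(0L, nrow(points))
  points <- points[, c("x_nm", "y_nm", "frame")]
  if (nrow(points) && (!all(is.finite(points$x_nm)) ||
                       !all(is.finite(points$y_nm))))
    stop("non-finite coordinates in localization map", call. = FALSE)
  if (nrow(points) && (any(points$x_nm < 0) || any(points$x_nm >= roi_width_nm) ||
                       any(points$y_nm < 0) || any(points$y_nm >= roi_height_nm)))
    stop("coordinates outside the half-open ROI [0, width) x [0, height)",
         call. = FALSE)
  rownames(points) <- NULL
  structure(list(points = points,
                 roi_width_nm = roi_width_nm,
                 roi_height_nm = roi_height_nm),
            class = "localization_map")
}

#' @export
print.localization_map <- function(x, ...) {
  cat(sprintf("<localization_map> %d points in %g x %g nm ROI\n",
              nrow(x$points), x$roi_width_nm, x$roi_height_nm))
  invisible(x)
}

#' Number of localizations in a map
#'
#' @param map a [localization_map()].
#' @return integer count.
#' @export
n_points <- function(map) nrow(map$points)

#' Read a localization CSV
#'
#' Reads a `x_nm,y_nm[,frame]` CSV into a [localization_map()]. Rows whose
#' coordinates fall outside the half-open ROI are dropped with a message
#' reporting how many were rejected (the boundary `x == roi_width_nm` is
#' outside).
#'
#' @param path CSV file path.
#' @param roi_width_nm,roi_height_nm ROI dimensions in nm.
#' @return A `localization_map`. An empty file (header only) yields an empty
#'   map, not an error.
#' @export
read_localizations <- function(path, roi_width_nm = 7000,
                               roi_height_nm = 7000) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("x_nm", "y_nm") %in% names(df)))
    stop(sprintf("'%s': expected header x_nm,y_nm[,frame]", path),
         call. = FALSE)
  if (nrow(df)) {
    bad <- !is.finite(df$x_nm) | !is.finite(df$y_nm)
    if (any(bad))
      stop(sprintf("'%s': malformed row(s) at line(s) %s", path,
                   paste(which(bad) + 1L, collapse = ", ")), call. = FALSE)
    inside <- df$x_nm >= 0 & df$x_nm < roi_width_nm &
      df$y_nm >= 0 & df$y_nm < roi_height_nm
    if (any(!inside))
      message(sprintf("read_localizations: dropped %d point(s) outside ROI",
                      sum(!inside)))
    df <- df[inside, , drop = FALSE]
  }
  localization_map(df, roi_width_nm, roi_height_nm)
}

#' Write a localization map as CSV
#'
#' @param map a [localization_map()].
#' @param path output CSV path (`x_nm,y_nm,frame` header).
#' @return `path`, invisibly.
#' @export
write_localizations <- function(map, path) {
  stopifnot(inherits(map, "localization_map"))
  utils::write.csv(map$points, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Canonical point order used by the dedup and assignment passes: frame,
# then x, then y, then original row index.  Makes both passes independent
# of input row order.
.canonical_order <- function(points) {
  order(points$frame, points$x_nm, points$y_nm, seq_len(nrow(points)))
}
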