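# Raw BRET processing: dual-emission ratios, donor-only subtraction, and
# ligand-induced traces.  Readings arrive as long-format data with one row
# per well per cycle: em475 (donor channel) and em535 (acceptor channel).

.check_readings <- function(readings) {
  if (!all(c("em475", "em535") %in% names(readings)))
    stop("readings need columns em475 and em535", call. = FALSE)
  bad <- !is.finite(readings$em475) | readings$em475 <= 0 |
    !is.finite(readings$em535) | readings$em535 <= 0
  if (any(bad)) {
    message(sprintf("net_bret: rejected %d row(s) with non-positive emission",
                    sum(bad)))
    readings <- readings[!bad, , drop = FALSE]
  }
  if (!nrow(readings))
    stop("no valid readings after filtering", call. = FALSE)
  readings
}

#' Net BRET from dual-emission readings
#'
#' Computes the BRET ratio (535 nm / 475 nm) per cycle, averages it per
#' condition, and subtracts the mean ratio of the donor-only negative
#' control measured in the same session. Rows with zero/negative donor
#' emission are rejected with a message.
#'
#' @param sample data.frame of sample readings with columns `em475`,
#'   `em535` and optionally `condition` (one net value per condition).
#' @param donor_only data.frame of donor-only control readings (same
#'   columns; conditions ignored, pooled into one control mean).
#' @return data.frame with `condition`, `n_cycles`, `mean_ratio`,
#'   `donor_ratio` and `net_bret`.
#' @export
net_bret <- function(sample, donor_only) {
  sample <- .check_readings(sample)
  donor_only <- .check_readings(donor_only)
  donor_ratio <- mean(donor_only$em535 / donor_only$em475)
  cond <- if (is.null(sample$condition)) rep("sample", nrow(sample))
          else sample$condition
  ratio <- sample$em535 / sample$em475
  out <- do.call(rbind, lapply(split(seq_along(ratio), cond), function(idx) {
    data.frame(condition = cond[idx[1]], n_cycles = length(idx),
               mean_ratio = mean(ratio[idx]), donor_ratio = donor_ratio,
               net_bret = mean(ratio[idx]) - donor_ratio)
  }))
  rownames(out) <- NULL
  out
}

#' Net acceptor expression
#'
#' Acceptor (Venus) fluorescence minus the mean of the donor-only control;
#' the acceptor-side analogue of [net_bret()].
#'
#' @param venus numeric acceptor-fluorescence readings.
#' @param donor_only_venus numeric donor-only acceptor readings.
#' @return numeric vector of net values.
#' @export
net_venus <- function(venus, donor_only_venus) {
  venus - mean(donor_only_venus)
}

#' Ligand-induced BRET trace
#'
#' Subtracts the mean basal BRET ratio (measured before agonist addition)
#' from the post-agonist ratio time series, with `t = 0` at agonist
#' addition. An optional vehicle-control trace measured on the same grid is
#' subtracted point-wise.
#'
#' @param basal_ratio numeric basal BRET ratios (pre-agonist).
#' @param time_s numeric time stamps (seconds after addition, strictly
#'   increasing).
#' @param post_ratio numeric BRET ratios after agonist addition, parallel
#'   to `time_s`.
#' @param vehicle_trace optional numeric vehicle-control ligand-induced
#'   trace on the same time grid, subtracted from the result.
#' @return data.frame of class `kinetics_trace` with columns `time_s`, `y`.
#' @export
ligand_induced_trace <- function(basal_ratio, time_s, post_ratio,
                                 vehicle_trace = NULL) {
  if (!length(basal_ratio) || !all(is.finite(basal_ratio)))
    stop("missing or non-finite basal readings", call. = FALSE)
  if (length(time_s) != length(post_ratio))
    stop("time_s and post_ratio lengths differ", call. = FALSE)
  if (any(diff(time_s) <= 0))
    stop("time stamps must be strictly increasing", call. = FALSE)
  y <- post_ratio - mean(basal_ratio)
  if (!is.null(vehicle_trace)) {
    if (length(vehicle_trace) != length(y))
      stop("vehicle trace must match the time grid", call. = FALSE)
    y <- y - vehicle_trace
  }
  structure(data.frame(time_s = time_s, y = y),
            class = c("kinetics_trace", "data.frame"))
}
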