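# Nonlinear fits for the three BRET readouts, all via bounded
# Levenberg-Marquardt least squares (minpack.lm::nlsLM): one-site-specific
# binding for saturation curves, one-phase association for recruitment
# kinetics, and a fixed- or variable-slope logistic for dose-response.
# Convergence tolerance 1e-8 on parameters, at most 1000 iterations.

.nls_ctrl <- function() minpack.lm::nls.lm.control(ptol = 1e-8,
                                                   ftol = 1e-8,
                                                   maxiter = 1000)

.try_fit <- function(expr) {
  tryCatch(suppressWarnings(expr), error = function(e) NULL)
}

#' Fit a BRET saturation curve (one-site-specific binding)
#'
#' Least-squares fit of `y = BRETmax * x / (BRET50 + x)` with
#' non-negativity bounds. Initialization: `BRETmax0 = max(y)`, `BRET50` at
#' the x value whose response is closest to half-maximal.
#'
#' @param x acceptor/donor expression ratios (net Venus / Rluc8), `>= 4`
#'   distinct values.
#' @param y net BRET values.
#' @return list of class `saturation_fit`: `BRETmax`, `BRET50`, standard
#'   errors `se`, residual sum of squares `rss`, `converged`. A flat/zero
#'   response is flagged (`converged = FALSE`, `BRETmax = 0`).
#' @export
fit_saturation <- function(x, y) {
  if (length(unique(x)) < 4L)
    stop("fit_saturation: need >= 4 distinct x values", call. = FALSE)
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (max(abs(y)) < 1e-12 || stats::sd(y) < 1e-12) {
    return(structure(list(BRETmax = 0, BRET50 = NA_real_,
                          se = c(BRETmax = NA_real_, BRET50 = NA_real_),
                          rss = sum(y^2), converged = FALSE),
                     class = "saturation_fit"))
  }
  bmax0 <- max(y)
  b500 <- x[which.min(abs(y - bmax0 / 2))]
  if (b500 <= 0) b500 <- max(x) / 4
  fit <- .try_fit(minpack.lm::nlsLM(
    y ~ BRETmax * x / (BRET50 + x),
    start = list(BRETmax = bmax0, BRET50 = b500),
    lower = c(0, 1e-12), control = .nls_ctrl()))
  if (is.null(fit)) {
    return(structure(list(BRETmax = NA_real_, BRET50 = NA_real_,
                          se = c(BRETmax = NA_real_, BRET50 = NA_real_),
                          rss = NA_real_, converged = FALSE),
                     class = "saturation_fit"))
  }
  co <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(BRETmax = NA_real_,
                                       BRET50 = NA_real_))
  structure(list(BRETmax = unname(co["BRETmax"]),
                 BRET50 = unname(co["BRET50"]),
                 se = se, rss = sum(stats::resid(fit)^2),
                 converged = fit$convInfo$isConv %||% TRUE),
            class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat(sprintf("<saturation_fit> BRETmax %.4g, BRET50 %.4g (%s)\n",
              x$BRETmax, x$BRET50,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

#' Fit one-phase association kinetics
#'
#' Least-squares fit of `y = plateau * (1 - exp(-k * t))` to a
#' ligand-induced BRET trace, with `y0` fixed at 0 (the trace construction
#' subtracts basal BRET, forcing the curve through the origin); set
#' `free_y0 = TRUE` to fit `y = y0 + (plateau - y0) * (1 - exp(-k t))` on
#' raw ratios instead. Derived quantities are computed exactly from the
#' fitted parameters: halftime `= ln(2)/k`, span `= plateau - y0`, initial
#' rate `= k * span`.
#'
#' @param trace a [ligand_induced_trace()] result, or any data.frame with
#'   columns `time_s`, `y`.
#' @param free_y0 fit a free intercept (default `FALSE`).
#' @return list of class `kinetics_fit`: `k_per_s`, `plateau`, `y0`,
#'   `span`, `halftime_s`, `initial_rate`, `se`, `rss`, `converged`. Fits
#'   ending at `k <= 0` are flagged not converged. A warning is issued when
#'   fewer than 8 points are supplied or the trace spans less than two
#'   fitted halftimes.
#' @export
fit_kinetics <- function(trace, free_y0 = FALSE) {
  if (!all(c("time_s", "y") %in% names(trace)))
    stop("trace needs columns time_s and y", call. = FALSE)
  t <- trace$time_s; y <- trace$y
  if (length(t) < 8L)
    warning("fit_kinetics: fewer than 8 time points")
  plateau0 <- max(y)
  if (plateau0 <= 0) plateau0 <- max(abs(y), 1e-6)
  # crude halftime guess: first time the trace crosses half its maximum
  i_half <- which(y >= plateau0 / 2)[1]
  k0 <- if (!is.na(i_half) && t[i_half] > 0) log(2) / t[i_half] else
    1 / max(t)
  fml <- if (free_y0)
    y ~ y0 + (plateau - y0) * (1 - exp(-k * t))
  else
    y ~ plateau * (1 - exp(-k * t))
  start <- if (free_y0)
    list(k = k0, plateau = plateau0, y0 = y[1])
  else list(k = k0, plateau = plateau0)
  lower <- if (free_y0) c(1e-12, 0, -Inf) else c(1e-12, 0)
  fit <- .try_fit(minpack.lm::nlsLM(fml, data = data.frame(t = t, y = y),
                                    start = start, lower = lower,
                                    control = .nls_ctrl()))
  bad <- structure(list(k_per_s = NA_real_, plateau = NA_real_,
                        y0 = if (free_y0) NA_real_ else 0,
                        span = NA_real_, halftime_s = NA_real_,
                        initial_rate = NA_real_, se = NULL, rss = NA_real_,
                        converged = FALSE), class = "kinetics_fit")
  if (is.null(fit)) return(bad)
  co <- stats::coef(fit)
  k <- unname(co["k"]); plateau <- unname(co["plateau"])
  y0 <- if (free_y0) unname(co["y0"]) else 0
  if (!is.finite(k) || k <= 1e-12) return(bad)
  span <- plateau - y0
  if (t[length(t)] < 2 * log(2) / k)
    warning("fit_kinetics: trace spans less than two fitted halftimes")
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) NULL)
  structure(list(k_per_s = k, plateau = plateau, y0 = y0, span = span,
                 halftime_s = log(2) / k,
                 initial_rate = k * span,
                 se = se, rss = sum(stats::resid(fit)^2),
                 converged = fit$convInfo$isConv %||% TRUE),
            class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf(
    "<kinetics_fit> k %.4g /s, plateau %.4g, halftime %.4g s, initial rate %.4g /s (%s)\n",
    x$k_per_s, x$plateau, x$halftime_s, x$initial_rate,
    if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

#' Fit a concentration-response curve
#'
#' Least-squares fit of
#' `y = baseline + (Emax - baseline) / (1 + (EC50 / conc)^hill)` with the
#' Hill slope fixed at 1 by default (`variable_slope = TRUE` frees it).
#' EC50 is fitted on the log10 scale for stability. Reports `-log10(EC50)`
#' alongside the raw parameters.
#'
#' @param conc molar concentrations (`>= 5` distinct values spanning the
#'   transition).
#' @param y responses.
#' @param variable_slope free Hill slope (default `FALSE`).
#' @return list of class `dose_response_fit`: `logEC50` (log10 M),
#'   `neg_log_ec50`, `EC50_M`, `Emax`, `baseline`, `hill`, `se`, `rss`,
#'   `converged`. A constant response is flagged degenerate.
#' @export
fit_dose_response <- function(conc, y, variable_slope = FALSE) {
  if (length(unique(conc)) < 5L)
    stop("fit_dose_response: need >= 5 distinct concentrations",
         call. = FALSE)
  if (any(conc <= 0)) stop("concentrations must be > 0", call. = FALSE)
  bad <- structure(list(logEC50 = NA_real_, neg_log_ec50 = NA_real_,
                        EC50_M = NA_real_, Emax = NA_real_,
                        baseline = NA_real_, hill = NA_real_, se = NULL,
                        rss = NA_real_, converged = FALSE),
                   class = "dose_response_fit")
  if (stats::sd(y) < 1e-12) return(bad)
  base0 <- min(y); emax0 <- max(y)
  lec0 <- log10(conc[which.min(abs(y - (base0 + emax0) / 2))])
  df <- data.frame(lc = log10(conc), y = y)
  if (variable_slope) {
    fit <- .try_fit(minpack.lm::nlsLM(
      y ~ baseline + (Emax - baseline) / (1 + 10^(hill * (logEC50 - lc))),
      data = df,
      start = list(baseline = base0, Emax = emax0, logEC50 = lec0,
                   hill = 1),
      lower = c(-Inf, -Inf, log10(min(conc)) - 6, 0.1),
      upper = c(Inf, Inf, log10(max(conc)) + 6, 10),
      control = .nls_ctrl()))
  } else {
    fit <- .try_fit(minpack.lm::nlsLM(
      y ~ baseline + (Emax - baseline) / (1 + 10^(logEC50 - lc)),
      data = df,
      start = list(baseline = base0, Emax = emax0, logEC50 = lec0),
      lower = c(-Inf, -Inf, log10(min(conc)) - 6),
      upper = c(Inf, Inf, log10(max(conc)) + 6),
      control = .nls_ctrl()))
  }
  if (is.null(fit)) return(bad)
  co <- stats::coef(fit)
  lec <- unname(co["logEC50"])
  emax <- unname(co["Emax"]); basel <- unname(co["baseline"])
  if (emax < basel) return(bad)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) NULL)
  structure(list(logEC50 = lec, neg_log_ec50 = -lec, EC50_M = 10^lec,
                 Emax = emax, baseline = basel,
                 hill = if (variable_slope) unname(co["hill"]) else 1,
                 se = se, rss = sum(stats::resid(fit)^2),
                 converged = fit$convInfo$isConv %||% TRUE),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(
    "<dose_response_fit> -logEC50 %.3f, Emax %.4g, baseline %.4g (%s)\n",
    x$neg_log_ec50, x$Emax, x$baseline,
    if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

#' Emax/EC50 bias factors
#'
#' Computes the per-pathway bias factor `Emax / EC50` and its fold change
#' versus a designated reference condition, pathway by pathway. Used to
#' compare e.g. G-protein vs beta-arrestin responses across receptor
#' variants.
#'
#' @param fit_table data.frame with columns `condition`, `pathway`, `Emax`,
#'   `EC50_M` (one row per converged fit).
#' @param reference the reference condition label (must be present for
#'   every pathway).
#' @return data.frame with `condition`, `pathway`, `emax_over_ec50`,
#'   `fold_change` (1 for the reference itself).
#' @export
bias_factor <- function(fit_table, reference) {
  need <- c("condition", "pathway", "Emax", "EC50_M")
  if (!all(need %in% names(fit_table)))
    stop("fit_table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(fit_table$EC50_M <= 0) || any(!is.finite(fit_table$Emax)))
    stop("bias_factor is defined only for converged fits", call. = FALSE)
  fit_table$emax_over_ec50 <- fit_table$Emax / fit_table$EC50_M
  out <- do.call(rbind, lapply(split(fit_table, fit_table$pathway),
                               function(g) {
    ref <- g$emax_over_ec50[g$condition == reference]
    if (length(ref) != 1L)
      stop(sprintf("reference condition '%s' missing for pathway '%s'",
                   reference, g$pathway[1]), call. = FALSE)
    g$fold_change <- g$emax_over_ec50 / ref
    g
  }))
  rownames(out) <- NULL
  out[, c("condition", "pathway", "emax_over_ec50", "fold_change")]
}
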