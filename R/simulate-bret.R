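# Ground-truth-labelled simulator for BRET readouts in the three modes the
# quantification stage consumes: saturation (one-site binding), kinetics
# (one-phase association) and dose-response (EC50 logistic, Hill slope 1).

#' BRET simulation configuration
#'
#' Defines a synthetic BRET experiment with known curve parameters:
#' \describe{
#'   \item{saturation}{`y = BRETmax * x / (BRET50 + x)`, `x` the
#'     acceptor/donor expression ratio.}
#'   \item{kinetics}{`y = plateau * (1 - exp(-k * t))`, `t` seconds after
#'     agonist addition.}
#'   \item{dose_response}{`y = baseline + (Emax - baseline) /
#'     (1 + EC50 / conc)`.}
#' }
#' Gaussian noise of sd `noise_sd` is added independently per point and
#' replicate.
#'
#' @param mode `"saturation"`, `"kinetics"` or `"dose_response"`.
#' @param params named list of true parameters for the mode:
#'   `BRETmax, BRET50` / `k_per_s, plateau` / `EC50_M, Emax, baseline`.
#' @param grid strictly increasing sampling grid (x ratios, time points in
#'   seconds, or molar concentrations).
#' @param noise_sd Gaussian noise sd (default 0).
#' @param replicates number of replicate series (default 1).
#' @param seed integer seed (required).
#' @return list of class `bret_sim_config`.
#' @export
bret_sim_config <- function(mode = c("saturation", "kinetics",
                                     "dose_response"),
                            params, grid, noise_sd = 0, replicates = 1L,
                            seed) {
  mode <- match.arg(mode)
  need <- switch(mode,
                 saturation = c("BRETmax", "BRET50"),
                 kinetics = c("k_per_s", "plateau"),
                 dose_response = c("EC50_M", "Emax", "baseline"))
  if (!all(need %in% names(params)))
    stop(sprintf("mode '%s' needs params: %s", mode,
                 paste(need, collapse = ", ")), call. = FALSE)
  for (p in need) .check_scalar(params[[p]], p)
  if (any(unlist(params[need]) < 0))
    stop("true curve parameters must be >= 0", call. = FALSE)
  if (length(grid) < 2L || any(diff(grid) <= 0))
    stop("grid must be strictly increasing with >= 2 points", call. = FALSE)
  .check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  .check_scalar(replicates, "replicates", positive = TRUE, integer = TRUE)
  structure(list(mode = mode, params = params[need],
                 grid = as.numeric(grid),
                 noise_sd = noise_sd, replicates = as.integer(replicates),
                 seed = .check_seed(seed)),
            class = "bret_sim_config")
}

.bret_model_value <- function(mode, params, x) {
  switch(mode,
         saturation = params$BRETmax * x / (params$BRET50 + x),
         kinetics = params$plateau * (1 - exp(-params$k_per_s * x)),
         dose_response = params$baseline +
           (params$Emax - params$baseline) / (1 + params$EC50_M / x))
}

#' Simulate BRET readings
#'
#' @param config a [bret_sim_config()].
#' @return data.frame with columns `series` (the mode), `x` (ratio, time in
#'   s, or molar concentration), `y` (BRET response) and `replicate`.
#' @export
simulate_bret <- function(config) {
  stopifnot(inherits(config, "bret_sim_config"))
  .with_seed(config$seed, {
    mu <- .bret_model_value(config$mode, config$params, config$grid)
    out <- do.call(rbind, lapply(seq_len(config$replicates), function(r) {
      data.frame(series = config$mode, x = config$grid,
                 y = mu + stats::rnorm(length(mu), 0, config$noise_sd),
                 replicate = r)
    }))
    rownames(out) <- NULL
    out
  })
}
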