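# Shared internal helpers: argument checking, seeded RNG scoping, small
# geometry utilities used by both the simulators and the analysis stages.

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE,
                          integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  if (integer && x != round(x))
    stop(sprintf("`%s` must be an integer", name), call. = FALSE)
  invisible(x)
}

.check_seed <- function(seed) {
  .check_scalar(seed, "seed", integer = TRUE)
  as.integer(seed %% .Machine$integer.max)
}

# Run `expr` under a fixed RNG seed without touching global RNG state.
.with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr, .rng_kind = "Mersenne-Twister",
                   .rng_normal_kind = "Inversion",
                   .rng_sample_kind = "Rejection")
}

# Derive a reproducible child seed for a named pipeline stage from the global
# seed.  Documented derivation so a single stage can be re-run in isolation.
stage_seed <- function(seed, stage) {
  .check_seed(seed)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Rotation by `angle` (rad) about the z axis.
rot_z <- function(angle) {
  c_ <- cos(angle); s_ <- sin(angle)
  matrix(c(c_, -s_, 0, s_, c_, 0, 0, 0, 1), nrow = 3, byrow = TRUE)
}

# Rodrigues rotation about an arbitrary unit axis.
rot_axis <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), nrow = 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

.is_rotation <- function(R, tol = 1e-6) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) &&
    max(abs(crossprod(R) - diag(3))) < tol && det(R) > 0
}
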