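#' Derive a reproducible sub-seed
#'
#' All randomness in the package flows from one top-level seed; per-call
#' sub-seeds are derived deterministically from that seed and a short tag so
#' that independent stages draw independent but reproducible streams.
#'
#' @param seed master integer seed.
#' @param tag character tag naming the consumer.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  m <- 2147483647  # 2^31 - 1, keeps derived seeds valid R integers
  h <- 0
  for (code in utf8ToInt(tag)) h <- (h * 131 + code) %% m
  as.integer((abs(seed) %% m * 48271 + h) %% m)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @keywords internal
#' @noRd
assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (x < min || x > max) {
    stop(sprintf("`%s` must be in [%s, %s], got %s", name,
                 format(min), format(max), format(x)), call. = FALSE)
  }
  invisible(x)
}

# log-normal multiplicative noise with a given coefficient of variation:
# E[factor] = 1, CV[factor] = cv.  cv = 0 returns exact ones.
lognormal_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}
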