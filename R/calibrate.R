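#' Fit a log10-linear reference curve
#'
#' Ordinary least-squares fit of `log10(intensity)` on `log10(amount)` over
#' the individual replicate points of a synthetic-peptide dilution series.
#' Sub-threshold (non-positive) intensities are dropped with a warning
#' rather than floored — flooring before the log transform would inject
#' minus infinity.
#'
#' @param data a `reference_curve_data` data.frame (columns `amount_pg`,
#'   `intensity`), e.g. from [generate_reference_curve()].
#' @return an object of class `ref_curve_fit`: `slope`, `intercept`
#'   (log10-A.U.), `adj_r2`, `p_value` (slope t-test), `amount_range`
#'   (calibrated pg range), `n_points`, `analyte`.
#' @examples
#' crv <- generate_reference_curve("EGFR_pY1068", 10^(0:3), slope = 0.9,
#'                                 intercept = -2, noise_sd = 0)
#' fit_reference_curve(crv)
#' @export
fit_reference_curve <- function(data) {
  stopifnot(is.data.frame(data), all(c("amount_pg", "intensity") %in% names(data)))
  if (any(data$amount_pg <= 0)) stop("amounts must be > 0", call. = FALSE)
  usable <- data$intensity > 0 & is.finite(data$intensity)
  if (!all(usable)) {
    warning(sprintf("dropping %d non-positive intensity replicate(s)",
                    sum(!usable)), call. = FALSE)
    data <- data[usable, , drop = FALSE]
  }
  if (nrow(data) == 0) stop("all intensities non-positive; nothing to fit", call. = FALSE)
  if (length(unique(data$amount_pg)) < 2) {
    stop("fewer than 2 distinct usable amounts", call. = FALSE)
  }
  x <- log10(data$amount_pg)
  y <- log10(data$intensity)
  n <- length(y)
  if (stats::var(y) == 0) {
    # flat response: slope 0 by construction, no explainable variance
    adj_r2 <- 1 - (n - 1) / (n - 2)
    fit <- list(slope = 0, intercept = y[1L], adj_r2 = adj_r2, p_value = 1)
  } else {
    m <- stats::lm(y ~ x)
    sm <- suppressWarnings(summary(m))  # zero-residual fits trip summary.lm
    fit <- list(slope = unname(stats::coef(m)[2L]),
                intercept = unname(stats::coef(m)[1L]),
                adj_r2 = sm$adj.r.squared,
                p_value = unname(sm$coefficients[2L, 4L]))
    if (is.nan(fit$p_value)) fit$p_value <- 0  # exact fit, zero residual
  }
  structure(c(fit, list(amount_range = range(data$amount_pg), n_points = n,
                        analyte = attr(data, "analyte"))),
            class = "ref_curve_fit")
}

#' @export
print.ref_curve_fit <- function(x, ...) {
  cat(sprintf("Reference curve%s: log10(A.U.) = %.4f + %.4f * log10(pg)\n",
              if (is.null(x$analyte)) "" else paste0(" [", x$analyte, "]"),
              x$intercept, x$slope))
  cat(sprintf("  adj R2 = %.4f, p = %.3g, calibrated range %.4g-%.4g pg (n = %d)\n",
              x$adj_r2, x$p_value, x$amount_range[1L], x$amount_range[2L],
              x$n_points))
  invisible(x)
}

#' Inverse-predict analyte amount from a reference curve
#'
#' Converts a normalized RPPA intensity into an absolute analyte amount via
#' the inverse of the log10-linear fit,
#' `amount = 10^((log10(intensity) - intercept) / slope)`. Queries mapping
#' outside the calibrated amount range are reported, not suppressed: sample
#' levels falling below the lowest dilution point are flagged
#' `"below_curve"` (detectable but not quantifiable), above the highest
#' `"above_curve"`.
#'
#' @param fit a [fit_reference_curve()] result.
#' @param intensity positive intensity (A.U.); vectorized.
#' @return data.frame with columns `intensity`, `amount_pg`, `status`
#'   (`in_range` / `below_curve` / `above_curve`).
#' @export
predict_amount <- function(fit, intensity) {
  stopifnot(inherits(fit, "ref_curve_fit"))
  if (fit$slope == 0) stop("zero-slope curve is not invertible", call. = FALSE)
  if (any(intensity <= 0 | !is.finite(intensity))) {
    stop("`intensity` must be positive and finite", call. = FALSE)
  }
  amount <- 10^((log10(intensity) - fit$intercept) / fit$slope)
  status <- ifelse(amount < fit$amount_range[1L], "below_curve",
            ifelse(amount > fit$amount_range[2L], "above_curve", "in_range"))
  data.frame(intensity = intensity, amount_pg = amount, status = status,
             stringsAsFactors = FALSE)
}

#' Estimate the limit of detection from a mixture series
#'
#' Formalizes "detectable over the background": a mixture fraction is
#' detected when at least `min_detect_reps` of its replicates exceed
#' `background mean + k * background SD`; the limit of detection is the
#' smallest nonzero detected fraction such that every larger fraction is
#' also detected (no detection gaps). Defaults k = 3, 2-of-3 replicates —
#' the conventional assay LOD definition.
#'
#' @param series a [mixture_series()].
#' @param k background SD multiplier (default 3).
#' @param min_detect_reps replicates that must exceed the threshold
#'   (default 2).
#' @return list with `lod_fraction` (percent, or `NA` when not detectable),
#'   `detected` (named logical per fraction), `threshold`, and
#'   `background_stats`.
#' @export
estimate_lod <- function(series, k = 3, min_detect_reps = 2L) {
  stopifnot(inherits(series, "mixture_series"))
  assert_scalar_number(k, "k", min = 0)
  assert_scalar_number(min_detect_reps, "min_detect_reps", min = 1)
  bg <- series$background_stats
  if (is.null(bg)) {
    stop("no background reference: series needs a 0% fraction or explicit background_stats",
         call. = FALSE)
  }
  threshold <- bg$mean + k * bg$sd
  detected <- apply(series$intensities, 1L,
                    function(v) sum(v > threshold, na.rm = TRUE) >= min_detect_reps)
  names(detected) <- series$fractions
  nz <- series$fractions > 0
  lod <- NA_real_
  if (any(nz)) {
    fr <- series$fractions[nz]
    det <- detected[nz]
    # smallest detected fraction with all larger fractions also detected
    ok <- rev(cumprod(rev(det))) == 1
    if (any(ok)) lod <- min(fr[ok])
  }
  list(lod_fraction = lod, detected = detected, threshold = threshold,
       background_stats = bg)
}

#' Linearity of a mixture dilution series
#'
#' Pearson correlation and least-squares slope of the mean replicate
#' intensity against the positive-source fraction — the check that a
#' marker's RPPA level scales with the proportion of marker-positive EVs.
#'
#' @param series a [mixture_series()] with at least 3 distinct fractions.
#' @return list `pearson_r`, `slope` (A.U. per percent), `p_value`, and
#'   `status` (`"ok"` or `"not_applicable"` for degenerate, e.g. constant,
#'   series).
#' @export
mixture_linearity <- function(series) {
  stopifnot(inherits(series, "mixture_series"))
  if (length(unique(series$fractions)) < 3) {
    stop("at least 3 distinct fractions required", call. = FALSE)
  }
  means <- rowMeans(series$intensities, na.rm = TRUE)
  fr <- series$fractions
  if (stats::sd(means) == 0) {
    return(list(pearson_r = NA_real_, slope = 0, p_value = NA_real_,
                status = "not_applicable"))
  }
  ct <- stats::cor.test(fr, means, method = "pearson")
  slope <- unname(stats::coef(stats::lm(means ~ fr))[2L])
  list(pearson_r = unname(ct$estimate), slope = slope,
       p_value = ct$p.value, status = "ok")
}
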