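# Empirical ROC machinery: tie-aware AUC (rank statistic), Youden-optimal
# cut-off over midpoints between adjacent distinct scores, DeLong variance
# for the 95% CI and the test against AUC = 0.5.

# Mann-Whitney AUC of `scores` for cases vs controls, ties counted 1/2.
auc_rank <- function(scores, is_case) {
  n1 <- sum(is_case)
  n0 <- sum(!is_case)
  r <- rank(scores)  # midranks handle ties
  (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong (1988) variance of the empirical AUC via placement values.
delong_var <- function(scores, is_case) {
  x <- scores[is_case]   # cases
  y <- scores[!is_case]  # controls
  m <- length(x); n <- length(y)
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  v10 <- vapply(x, function(xi) mean(psi(xi, y)), numeric(1))
  v01 <- vapply(y, function(yj) mean(psi(x, yj)), numeric(1))
  s10 <- if (m > 1) stats::var(v10) else 0
  s01 <- if (n > 1) stats::var(v01) else 0
  s10 / m + s01 / n
}

#' ROC analysis of a single marker
#'
#' Empirical (tie-aware) ROC analysis: the AUC equals the rank-sum /
#' pair-counting statistic; the marker direction is chosen so that AUC is
#' at least 0.5 (`"greater"` when cases are enriched at high values,
#' `"less"` otherwise); the optimal cut-off maximizes the Youden index
#' J = sensitivity + specificity - 1 over the midpoints between adjacent
#' distinct scores, breaking exact ties in J toward higher specificity.
#' The 95% confidence interval and the p-value against AUC = 0.5 come from
#' the DeLong variance estimate.
#'
#' @param scores numeric marker values, one per sample.
#' @param labels binary case/control labels (logical, 0/1, or a factor /
#'   character vector with `positive` naming the case level).
#' @param positive the case label when `labels` is not already binary
#'   numeric/logical.
#' @param direction `NULL` (default) chooses the direction that makes
#'   AUC >= 0.5; `"greater"` or `"less"` fixes it, as needed e.g. in
#'   permutation nulls where the auto-flip would bias the AUC upward.
#' @return an object of class `roc_result`: `auc`, `ci_low`, `ci_high`,
#'   `p_value`, `direction`, `cutoff`, `sensitivity`, `specificity`,
#'   `youden`, `n_case`, `n_control`, `degenerate` (TRUE when the scores
#'   are constant and no cut-off exists).
#' @examples
#' roc_analysis(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
#' @export
roc_analysis <- function(scores, labels, positive = NULL, direction = NULL) {
  is_case <- as_case_labels(labels, positive)
  keep <- is.finite(scores) & !is.na(is_case)
  scores <- scores[keep]
  is_case <- is_case[keep]
  n1 <- sum(is_case); n0 <- sum(!is_case)
  if (n1 < 2 || n0 < 2) {
    stop("need >= 2 cases and >= 2 controls with finite scores", call. = FALSE)
  }

  if (is.null(direction)) {
    auc_raw <- auc_rank(scores, is_case)
    direction <- if (auc_raw >= 0.5) "greater" else "less"
  } else {
    direction <- match.arg(direction, c("greater", "less"))
  }
  eff <- if (direction == "greater") scores else -scores
  auc <- auc_rank(eff, is_case)

  se <- sqrt(delong_var(eff, is_case))
  if (se > 0) {
    ci <- auc + c(-1, 1) * stats::qnorm(0.975) * se
    ci <- pmin(pmax(ci, 0), 1)
    p <- 2 * stats::pnorm(-abs(auc - 0.5) / se)
  } else {
    ci <- c(auc, auc)
    p <- if (auc == 0.5) 1 else 0
  }

  uniq <- sort(unique(eff))
  if (length(uniq) < 2) {
    res <- list(auc = 0.5, ci_low = 0.5, ci_high = 0.5, p_value = 1,
                direction = direction, cutoff = NA_real_,
                sensitivity = NA_real_, specificity = NA_real_,
                youden = NA_real_, n_case = n1, n_control = n0,
                degenerate = TRUE)
    return(structure(res, class = "roc_result"))
  }
  cand <- (uniq[-1] + uniq[-length(uniq)]) / 2
  sens <- vapply(cand, function(cut) mean(eff[is_case] >= cut), numeric(1))
  spec <- vapply(cand, function(cut) mean(eff[!is_case] < cut), numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))
  if (length(best) > 1) best <- best[which.max(spec[best])]
  cutoff <- cand[best]
  if (direction == "less") cutoff <- -cutoff

  structure(list(auc = auc, ci_low = ci[1L], ci_high = ci[2L], p_value = p,
                 direction = direction, cutoff = cutoff,
                 sensitivity = sens[best], specificity = spec[best],
                 youden = j[best], n_case = n1, n_control = n0,
                 degenerate = FALSE),
            class = "roc_result")
}

as_case_labels <- function(labels, positive = NULL) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1, NA))) {
      stop("numeric labels must be 0/1", call. = FALSE)
    }
    return(labels == 1)
  }
  labels <- as.character(labels)
  if (is.null(positive)) {
    stop("`positive` must name the case label for character/factor labels",
         call. = FALSE)
  }
  if (!positive %in% labels) {
    stop(sprintf("case label '%s' absent from labels", positive), call. = FALSE)
  }
  labels == positive
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f), p = %.3g [direction: %s]\n",
              x$auc, x$ci_low, x$ci_high, x$p_value, x$direction))
  if (x$degenerate) {
    cat("  constant scores: no informative cut-off\n")
  } else {
    cat(sprintf("  optimal cut-off %.4g: sensitivity %.3f, specificity %.3f (J = %.3f)\n",
                x$cutoff, x$sensitivity, x$specificity, x$youden))
  }
  cat(sprintf("  n = %d cases / %d controls\n", x$n_case, x$n_control))
  invisible(x)
}

# TRUE where a value lies beyond the cut-off in the case-enriched direction
beyond_cutoff <- function(values, cutoff, direction) {
  if (is.na(cutoff)) return(rep(FALSE, length(values)))
  out <- if (direction == "greater") values >= cutoff else values <= cutoff
  out[!is.finite(values)] <- FALSE
  out
}
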