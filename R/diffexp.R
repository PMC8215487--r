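#' Per-endpoint two-group comparison
#'
#' Compares two cohort groups endpoint by endpoint with a two-sided
#' Student's t-test or Wilcoxon rank-sum test, reporting
#' `log2fc = log2(mean_a / mean_b)` from the arithmetic group means of the
#' normalized A.U. values. Raw p-values are primary (significance at
#' `p <= alpha`); Benjamini-Hochberg q-values are reported alongside.
#'
#' @param matrix samples-by-endpoints matrix (e.g. from
#'   [run_normalization()]) with sample ids as row names.
#' @param annotation data.frame with `sample_id` and `group` columns.
#' @param group_a,group_b group labels to compare (log2fc is a over b).
#' @param test `"t"` or `"wilcoxon"`.
#' @param alpha significance threshold on the raw p-value (default 0.05).
#' @return data.frame of class `comparison_result`: one row per endpoint
#'   with `endpoint`, `group_a`, `group_b`, `n_a`, `n_b`, `mean_a`,
#'   `mean_b`, `log2fc`, `p_value`, `q_value`, `significant`, `test`,
#'   `status` (`"ok"` or `"not_testable"`).
#' @export
compare_groups <- function(matrix, annotation, group_a, group_b,
                           test = c("t", "wilcoxon"), alpha = 0.05) {
  test <- match.arg(test)
  assert_scalar_number(alpha, "alpha", min = 0, max = 1)
  stopifnot(all(c("sample_id", "group") %in% names(annotation)))
  for (g in c(group_a, group_b)) {
    if (!g %in% annotation$group) {
      stop(sprintf("unknown group label '%s'", g), call. = FALSE)
    }
  }
  ids_a <- annotation$sample_id[annotation$group == group_a]
  ids_b <- annotation$sample_id[annotation$group == group_b]
  ids_a <- intersect(ids_a, rownames(matrix))
  ids_b <- intersect(ids_b, rownames(matrix))

  res <- lapply(colnames(matrix), function(ep) {
    va <- matrix[ids_a, ep]
    vb <- matrix[ids_b, ep]
    va <- va[is.finite(va)]
    vb <- vb[is.finite(vb)]
    row <- data.frame(endpoint = ep, group_a = group_a, group_b = group_b,
                      n_a = length(va), n_b = length(vb),
                      mean_a = NA_real_, mean_b = NA_real_,
                      log2fc = NA_real_, p_value = NA_real_,
                      test = test, status = "not_testable",
                      stringsAsFactors = FALSE)
    if (length(va) < 2 || length(vb) < 2) return(row)
    row$mean_a <- mean(va)
    row$mean_b <- mean(vb)
    row$log2fc <- if (row$mean_b == 0) {
      warning(sprintf("zero mean in group %s for %s: infinite log2fc",
                      group_b, ep), call. = FALSE)
      if (row$mean_a == 0) 0 else Inf
    } else log2(row$mean_a / row$mean_b)
    row$p_value <- if (test == "t") {
      if (stats::sd(va) == 0 && stats::sd(vb) == 0) {
        if (row$mean_a == row$mean_b) 1 else 0
      } else stats::t.test(va, vb)$p.value
    } else {
      # normal approximation without continuity correction: a fully tied
      # comparison then yields exactly p = 1
      suppressWarnings(stats::wilcox.test(va, vb, exact = FALSE,
                                          correct = FALSE)$p.value)
    }
    row$status <- "ok"
    row
  })
  out <- do.call(rbind, res)
  out$q_value <- NA_real_
  ok <- out$status == "ok"
  out$q_value[ok] <- stats::p.adjust(out$p_value[ok], method = "BH")
  out$significant <- ok & out$p_value <= alpha
  class(out) <- c("comparison_result", "data.frame")
  out
}

#' Exact set intersections of significant-endpoint lists
#'
#' UpSet-style decomposition: for every non-empty combination of comparison
#' sets, the number of endpoints significant in exactly that combination
#' (and no other). Counts over all combinations partition the union of the
#' sets.
#'
#' @param significant_sets named list: comparison label -> character vector
#'   of significant endpoint ids.
#' @return data.frame with one row per combination: `combination`
#'   (labels joined by `&`), `degree`, `count`, `endpoints`
#'   (comma-separated ids).
#' @export
comparison_intersections <- function(significant_sets) {
  stopifnot(is.list(significant_sets), length(significant_sets) >= 2,
            !is.null(names(significant_sets)))
  labels <- names(significant_sets)
  sets <- lapply(significant_sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(labels)),
                        KEEP.OUT.ATTRS = FALSE)
  combos <- combos[rowSums(combos) > 0, , drop = FALSE]
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    mask <- as.logical(combos[i, ])
    inside <- if (length(universe)) {
      apply(membership, 1L, function(m) all(m == mask))
    } else logical(0)
    data.frame(combination = paste(labels[mask], collapse = "&"),
               degree = sum(mask), count = sum(inside),
               endpoints = paste(universe[inside], collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$degree, out$combination), , drop = FALSE]
}

.ptnm_levels <- c("T1a", "T1b", "T1c", "T2a", "T2b", "T2c", "T3a", "T3b", "T4")
.gleason_levels <- c("6", "7(3+4)", "7(4+3)", "8", "9", "10")

#' Ordered clinical category levels
#'
#' The declared orderings of pathological stage (T1a < T1b < T1c < T2a <
#' T2b < T2c < T3a < T3b < T4) and Gleason grade, with 7(3+4) below 7(4+3).
#'
#' @return character vector of levels.
#' @export
ptnm_levels <- function() .ptnm_levels

#' @rdname ptnm_levels
#' @export
gleason_levels <- function() .gleason_levels

#' Stratify prostate-cancer cases into recurrence-risk classes
#'
#' Deterministic stratification on Gleason grade and pathological stage:
#' \itemize{
#'   \item low: Gleason 6 and pTNM at or below T2a;
#'   \item low/intermediate: Gleason at or below 7(3+4) and pTNM T2b-T2c;
#'   \item high: Gleason 7(4+3) with pTNM T2c, and every Gleason grade with
#'     pTNM at or above T3a.
#' }
#' Grade/stage combinations the rule does not cover (for instance Gleason 8
#' with pTNM T2a) return `"unclassified"` — never a silently guessed class.
#'
#' @param gleason character vector drawn from [gleason_levels()].
#' @param ptnm character vector drawn from [ptnm_levels()].
#' @return character vector: `"low"`, `"low_intermediate"`, `"high"` or
#'   `"unclassified"`.
#' @examples
#' classify_risk("6", "T2a")       # low
#' classify_risk("7(4+3)", "T2c")  # high
#' classify_risk("6", "T3a")       # high (stage trumps grade)
#' @export
classify_risk <- function(gleason, ptnm) {
  gi <- match(as.character(gleason), .gleason_levels)
  ti <- match(as.character(ptnm), .ptnm_levels)
  if (anyNA(gi)) {
    stop(sprintf("unknown Gleason value(s): %s",
                 paste(unique(gleason[is.na(gi)]), collapse = ", ")),
         call. = FALSE)
  }
  if (anyNA(ti)) {
    stop(sprintf("unknown pTNM value(s): %s",
                 paste(unique(ptnm[is.na(ti)]), collapse = ", ")),
         call. = FALSE)
  }
  i_t2a <- match("T2a", .ptnm_levels)
  i_t2b <- match("T2b", .ptnm_levels)
  i_t2c <- match("T2c", .ptnm_levels)
  i_t3a <- match("T3a", .ptnm_levels)
  i_g6 <- match("6", .gleason_levels)
  i_g734 <- match("7(3+4)", .gleason_levels)
  i_g743 <- match("7(4+3)", .gleason_levels)

  out <- rep("unclassified", length(gi))
  out[ti >= i_t3a] <- "high"                              # any grade, >= T3a
  out[gi == i_g743 & ti == i_t2c] <- "high"
  out[gi <= i_g734 & ti >= i_t2b & ti <= i_t2c] <- "low_intermediate"
  out[gi == i_g6 & ti <= i_t2a] <- "low"
  out
}

#' PSA gray-zone sample filter
#'
#' Selects the samples whose PSA falls in the diagnostic gray zone where
#' benign hyperplasia and carcinoma overlap (conventionally 4-10 ng/mL,
#' inclusive). Samples with missing PSA are excluded and counted.
#'
#' @param annotation data.frame with `sample_id` and `psa_ng_ml`.
#' @param low,high inclusive PSA bounds in ng/mL (defaults 4 and 10).
#' @return the filtered annotation rows, with attribute `n_missing_psa`.
#' @export
gray_zone_filter <- function(annotation, low = 4, high = 10) {
  stopifnot(all(c("sample_id", "psa_ng_ml") %in% names(annotation)))
  if (low > high) stop("`low` must not exceed `high`", call. = FALSE)
  psa <- annotation$psa_ng_ml
  missing <- !is.finite(psa)
  keep <- !missing & psa >= low & psa <= high
  out <- annotation[keep, , drop = FALSE]
  attr(out, "n_missing_psa") <- sum(missing)
  out
}

#' Flag values above a percentile threshold
#'
#' Marks samples whose endpoint level lies strictly above the given
#' percentile of the observed distribution (linear-interpolation percentile,
#' `stats::quantile` type 7). With all values equal, nothing is flagged.
#'
#' @param values numeric endpoint intensities (>= 2 finite values).
#' @param pct percentile in `[0, 100]` (default 65).
#' @return logical vector of flags (NA values yield NA flags), with
#'   attribute `threshold`.
#' @examples
#' percentile_flag(1:20, 65)  # threshold 13.35 -> values 14..20 flagged
#' @export
percentile_flag <- function(values, pct = 65) {
  assert_scalar_number(pct, "pct", min = 0, max = 100)
  fin <- values[is.finite(values)]
  if (length(fin) < 2) stop("need >= 2 finite values", call. = FALSE)
  thr <- unname(stats::quantile(fin, pct / 100, type = 7))
  structure(values > thr, threshold = thr)
}
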