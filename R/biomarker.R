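#' Define a k-of-n composite signature
#'
#' A panel of endpoints with directional cut-offs and a positivity rule: a
#' sample is signature-positive when at least `k` of the `n` endpoints lie
#' beyond their cut-off in the disease-enriched direction (the prognostic
#' default is 3 of 5).
#'
#' @param endpoints character vector of endpoint ids.
#' @param cutoffs numeric cut-offs in A.U., one per endpoint.
#' @param directions `"greater"` or `"less"` per endpoint (the direction in
#'   which disease is enriched; `"less"` counts low values as exceedance).
#' @param k positivity threshold, `1 <= k <= n` (default 3).
#' @return an object of class `composite_signature`.
#' @export
composite_signature <- function(endpoints, cutoffs, directions, k = 3L) {
  n <- length(endpoints)
  if (length(cutoffs) != n || length(directions) != n) {
    stop("`endpoints`, `cutoffs` and `directions` must have equal length",
         call. = FALSE)
  }
  if (!all(directions %in% c("greater", "less"))) {
    stop("directions must be 'greater' or 'less'", call. = FALSE)
  }
  assert_scalar_number(k, "k", min = 1, max = n)
  structure(list(endpoints = as.character(endpoints),
                 cutoffs = as.numeric(cutoffs),
                 directions = as.character(directions),
                 k = as.integer(k)),
            class = "composite_signature")
}

#' Derive a signature from univariate ROC analyses
#'
#' Runs [roc_analysis()] per endpoint and assembles a
#' [composite_signature()] from the resulting optimal cut-offs and
#' case-enriched directions.
#'
#' @param matrix samples-by-endpoints matrix.
#' @param endpoints endpoint ids to include.
#' @param labels,positive case/control labels as in [roc_analysis()].
#' @param k positivity threshold.
#' @return list with `signature` and `roc` (named list of per-endpoint
#'   `roc_result`s).
#' @export
derive_signature <- function(matrix, endpoints, labels, positive = NULL,
                             k = 3L) {
  missing_ep <- setdiff(endpoints, colnames(matrix))
  if (length(missing_ep)) {
    stop(sprintf("endpoint(s) absent from matrix: %s",
                 paste(missing_ep, collapse = ", ")), call. = FALSE)
  }
  rocs <- lapply(endpoints, function(ep) {
    roc_analysis(matrix[, ep], labels, positive)
  })
  names(rocs) <- endpoints
  sig <- composite_signature(
    endpoints,
    cutoffs = vapply(rocs, `[[`, numeric(1), "cutoff"),
    directions = vapply(rocs, `[[`, character(1), "direction"),
    k = min(k, length(endpoints)))
  list(signature = sig, roc = rocs)
}

#' Score samples against a composite signature
#'
#' Counts, per sample, how many signature endpoints lie beyond their
#' cut-off in the stated direction. Missing endpoint values contribute 0
#' and are tallied in `n_missing`.
#'
#' @param matrix samples-by-endpoints matrix.
#' @param signature a [composite_signature()].
#' @return data.frame: `sample_id`, `score` (integer `0..n`), `positive`
#'   (`score >= k`), `n_missing`.
#' @export
composite_score <- function(matrix, signature) {
  stopifnot(inherits(signature, "composite_signature"))
  missing_ep <- setdiff(signature$endpoints, colnames(matrix))
  if (length(missing_ep)) {
    stop(sprintf("endpoint(s) absent from matrix: %s",
                 paste(missing_ep, collapse = ", ")), call. = FALSE)
  }
  hits <- mapply(function(ep, cut, dir) {
    beyond_cutoff(matrix[, ep], cut, dir)
  }, signature$endpoints, signature$cutoffs, signature$directions)
  hits <- matrix(hits, nrow = nrow(matrix))
  miss <- vapply(signature$endpoints,
                 function(ep) !is.finite(matrix[, ep]),
                 logical(nrow(matrix)))
  miss <- matrix(miss, nrow = nrow(matrix))
  data.frame(sample_id = rownames(matrix) %||% seq_len(nrow(matrix)),
             score = as.integer(rowSums(hits)),
             positive = rowSums(hits) >= signature$k,
             n_missing = as.integer(rowSums(miss)),
             stringsAsFactors = FALSE)
}

#' Combined ROC of several candidate markers
#'
#' Builds a per-sample combined score from a candidate panel and evaluates
#' it with [roc_analysis()]. The default combination is the directional
#' exceedance count: each endpoint contributes 1 when the sample lies
#' beyond that endpoint's univariate optimal cut-off in its case-enriched
#' direction — consistent with the k-of-n composite rule. A logistic
#' combination (fitted linear predictor) is available as a non-canonical
#' alternative.
#'
#' @param matrix samples-by-endpoints matrix.
#' @param endpoints candidate endpoint ids (>= 2).
#' @param labels,positive case/control labels as in [roc_analysis()].
#' @param method `"exceedance"` (default) or `"logistic"`.
#' @return list with `roc` (the combined `roc_result`), `scores` (the
#'   per-sample combined score), `univariate` (per-endpoint `roc_result`s)
#'   and `method`.
#' @export
combine_candidates <- function(matrix, endpoints, labels, positive = NULL,
                               method = c("exceedance", "logistic")) {
  method <- match.arg(method)
  if (length(endpoints) < 2) stop("need >= 2 endpoints", call. = FALSE)
  der <- derive_signature(matrix, endpoints, labels, positive,
                          k = length(endpoints))
  if (method == "exceedance") {
    score <- composite_score(matrix, der$signature)$score
  } else {
    is_case <- as_case_labels(labels, positive)
    df <- data.frame(y = as.integer(is_case), matrix[, endpoints])
    fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
    score <- unname(stats::predict(fit, type = "link"))
  }
  list(roc = roc_analysis(score, labels, positive), scores = score,
       univariate = der$roc, method = method)
}

#' Evaluate a composite signature against outcome labels
#'
#' ROC analysis of the integer composite score plus the 2x2 confusion
#' table, sensitivity and specificity of the k-of-n positivity rule.
#'
#' @param matrix samples-by-endpoints matrix.
#' @param signature a [composite_signature()].
#' @param labels,positive case/control labels as in [roc_analysis()].
#' @param direction optional fixed ROC direction for the integer score (see
#'   [roc_analysis()]); the composite score is constructed so that
#'   `"greater"` is the case-enriched direction.
#' @return list with `roc`, `scores` (the [composite_score()] table),
#'   `confusion` (2x2 matrix), `sensitivity`, `specificity` at the k rule.
#' @export
evaluate_signature <- function(matrix, signature, labels, positive = NULL,
                               direction = NULL) {
  sc <- composite_score(matrix, signature)
  is_case <- as_case_labels(labels, positive)
  roc <- roc_analysis(sc$score, labels, positive, direction = direction)
  confusion <- table(
    predicted = factor(ifelse(sc$positive, "positive", "negative"),
                       levels = c("positive", "negative")),
    truth = factor(ifelse(is_case, "case", "control"),
                   levels = c("case", "control")))
  sens <- confusion["positive", "case"] / sum(confusion[, "case"])
  spec <- confusion["negative", "control"] / sum(confusion[, "control"])
  list(roc = roc, scores = sc, confusion = confusion,
       sensitivity = unname(sens), specificity = unname(spec))
}
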