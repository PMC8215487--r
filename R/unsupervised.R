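#' Z-score standardization of an intensity matrix
#'
#' Standardizes each endpoint (column) to mean 0 and sample SD 1 (n - 1
#' convention). Endpoints with fewer than two finite values or zero SD
#' carry no contrast and are dropped with a warning.
#'
#' @param matrix samples-by-endpoints numeric matrix.
#' @return the standardized matrix; attribute `dropped` lists removed
#'   endpoints.
#' @export
zscore_standardize <- function(matrix) {
  matrix <- as.matrix(matrix)
  sds <- apply(matrix, 2L, stats::sd, na.rm = TRUE)
  nfin <- colSums(is.finite(matrix))
  bad <- !is.finite(sds) | sds == 0 | nfin < 2
  if (any(bad)) {
    warning(sprintf("dropping %d zero-variance/degenerate endpoint(s): %s",
                    sum(bad), paste(colnames(matrix)[bad], collapse = ", ")),
            call. = FALSE)
    matrix <- matrix[, !bad, drop = FALSE]
  }
  out <- scale(matrix, center = TRUE, scale = TRUE)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  structure(out, dropped_endpoints = names(sds)[bad] %||% character(0))
}

#' Two-way hierarchical clustering
#'
#' Agglomerative clustering of samples (rows) and endpoints (columns) with
#' Euclidean distance and Ward's method, on the Z-score-standardized
#' matrix by default — the standard two-way heatmap view.
#'
#' @param matrix samples-by-endpoints matrix; missing cells are rejected
#'   (standardization-dropped endpoints aside) unless `na_action = "omit"`
#'   removes incomplete endpoints first.
#' @param standardize standardize columns with [zscore_standardize()] first
#'   (default TRUE).
#' @param na_action `"fail"` (default) or `"omit"` incomplete endpoints.
#' @return list of class `clustering_result`: `row_tree`, `col_tree`
#'   (`hclust` objects, Ward on Euclidean distance), `row_order`,
#'   `col_order` (dendrogram permutations), `standardized` (the matrix the
#'   trees were built on).
#' @export
hierarchical_cluster <- function(matrix, standardize = TRUE,
                                 na_action = c("fail", "omit")) {
  na_action <- match.arg(na_action)
  matrix <- as.matrix(matrix)
  if (anyNA(matrix)) {
    if (na_action == "fail") {
      stop("matrix contains missing cells; use na_action = 'omit' to drop incomplete endpoints",
           call. = FALSE)
    }
    keep <- colSums(!is.finite(matrix)) == 0
    message(sprintf("dropping %d endpoint(s) with missing values", sum(!keep)))
    matrix <- matrix[, keep, drop = FALSE]
  }
  if (nrow(matrix) < 2 || ncol(matrix) < 2) {
    stop("need >= 2 rows and >= 2 columns", call. = FALSE)
  }
  m <- if (standardize) zscore_standardize(matrix) else matrix
  row_tree <- stats::hclust(stats::dist(m, method = "euclidean"),
                            method = "ward.D2")
  col_tree <- stats::hclust(stats::dist(t(m), method = "euclidean"),
                            method = "ward.D2")
  structure(list(row_tree = row_tree, col_tree = col_tree,
                 row_order = row_tree$order, col_order = col_tree$order,
                 standardized = m),
            class = "clustering_result")
}

#' Export a clustering tree as a Newick string
#'
#' @param tree an `hclust` object (e.g. `row_tree` from
#'   [hierarchical_cluster()]).
#' @return single Newick string with branch lengths in distance units.
#' @export
tree_newick <- function(tree) {
  stopifnot(inherits(tree, "hclust"))
  ape::write.tree(ape::as.phylo(tree))
}

#' Principal component analysis on the covariance matrix
#'
#' PCA of column-centered (not scaled) data — an eigen-decomposition of the
#' endpoint covariance matrix. Components are ordered by decreasing
#' eigenvalue; each loading vector's sign is fixed so that its
#' largest-magnitude entry is positive.
#'
#' @param matrix samples-by-endpoints matrix, no missing cells, >= 2
#'   samples.
#' @return list of class `pca_result`: `scores` (samples x components),
#'   `loadings` (endpoints x components, orthonormal),
#'   `explained_variance` (per-component fraction), `sdev`.
#' @export
pca_covariance <- function(matrix) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) < 2) stop("need >= 2 samples", call. = FALSE)
  if (anyNA(matrix)) stop("matrix contains missing cells", call. = FALSE)
  pc <- stats::prcomp(matrix, center = TRUE, scale. = FALSE)
  flip <- apply(pc$rotation, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  loadings <- sweep(pc$rotation, 2L, flip, `*`)
  scores <- sweep(pc$x, 2L, flip, `*`)
  ev <- pc$sdev^2
  structure(list(scores = scores, loadings = loadings,
                 explained_variance = ev / sum(ev), sdev = pc$sdev * flip^0),
            class = "pca_result")
}
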