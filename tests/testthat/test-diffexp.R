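make_matrix <- function(values_by_group) {
  # values_by_group: named list group -> matrix (samples x endpoints)
  mats <- lapply(names(values_by_group), function(g) {
    m <- values_by_group[[g]]
    rownames(m) <- sprintf("%s_%02d", g, seq_len(nrow(m)))
    m
  })
  mat <- do.call(rbind, mats)
  ann <- data.frame(
    sample_id = rownames(mat),
    group = rep(names(values_by_group),
                vapply(values_by_group, nrow, integer(1))),
    stringsAsFactors = FALSE)
  list(matrix = mat, annotation = ann)
}

test_that("group comparison handles null, fold-change and error contracts", {
  same <- matrix(rep(c(1, 2, 3, 4), 2), ncol = 2,
                 dimnames = list(NULL, c("E1", "E2")))
  d <- make_matrix(list(A = same, B = same))
  res <- compare_groups(d$matrix, d$annotation, "A", "B", test = "t")
  expect_equal(res$log2fc, c(0, 0))
  expect_equal(res$p_value, c(1, 1), tolerance = 1e-12)
  resw <- compare_groups(d$matrix, d$annotation, "A", "B", test = "wilcoxon")
  expect_true(all(resw$p_value >= 0.99))

  d2 <- make_matrix(list(A = matrix(c(4, 4, 4), ncol = 1,
                                    dimnames = list(NULL, "E1")),
                         B = matrix(c(1, 1, 1), ncol = 1,
                                    dimnames = list(NULL, "E1"))))
  res2 <- compare_groups(d2$matrix, d2$annotation, "A", "B", test = "t")
  expect_equal(res2$log2fc, 2)

  expect_error(compare_groups(d$matrix, d$annotation, "A", "Z"), "unknown")

  d3 <- d
  d3$matrix[d3$annotation$group == "A", "E1"] <- NA
  res3 <- compare_groups(d3$matrix, d3$annotation, "A", "B")
  expect_equal(res3$status, c("not_testable", "ok"))
})

test_that("swapping the groups negates log2fc and preserves p", {
  set.seed(71)
  d <- make_matrix(list(A = matrix(rlnorm(40), 10), B = matrix(rlnorm(48), 12)))
  colnames(d$matrix) <- sprintf("E%d", 1:4)
  for (tst in c("t", "wilcoxon")) {
    ab <- compare_groups(d$matrix, d$annotation, "A", "B", test = tst)
    ba <- compare_groups(d$matrix, d$annotation, "B", "A", test = tst)
    expect_equal(ab$log2fc, -ba$log2fc, tolerance = 1e-12)
    expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
  }
})

test_that("type-I error of the null comparison sits near alpha", {
  set.seed(2024)
  n <- 20
  p_t <- p_w <- numeric(500)
  for (i in seq_len(500)) {
    d <- make_matrix(list(A = matrix(rlnorm(n, 0, 0.4), n),
                          B = matrix(rlnorm(n, 0, 0.4), n)))
    colnames(d$matrix) <- "E1"
    p_t[i] <- compare_groups(d$matrix, d$annotation, "A", "B", "t")$p_value
    p_w[i] <- compare_groups(d$matrix, d$annotation, "A", "B", "wilcoxon")$p_value
  }
  expect_gt(mean(p_t <= 0.05), 0.02)
  expect_lt(mean(p_t <= 0.05), 0.09)
  expect_gt(mean(p_w <= 0.05), 0.02)
  expect_lt(mean(p_w <= 0.05), 0.09)
})

test_that("intersection counts follow exact UpSet semantics and partition the union", {
  sets <- list(first = c("A", "B"), second = c("B", "C"), third = "B")
  tab <- comparison_intersections(sets)
  get <- function(comb) tab$count[tab$combination == comb]
  expect_equal(get("first&second&third"), 1)  # B everywhere
  expect_equal(get("first"), 1)               # A unique to first
  expect_equal(get("second"), 1)              # C unique to second
  expect_equal(sum(tab$count), 3)

  disj <- comparison_intersections(list(x = c("A", "B"), y = c("C")))
  expect_equal(disj$count[disj$combination == "x&y"], 0)
  expect_equal(sum(disj$count), 3)

  ident <- comparison_intersections(list(x = c("A", "B"), y = c("A", "B")))
  expect_equal(ident$count[ident$combination == "x&y"], 2)
  expect_equal(sum(ident$count), 2)

  # randomized property: counts always partition the union, and every
  # combination count matches a power-set oracle
  set.seed(5)
  for (rep in 1:25) {
    k <- sample(2:4, 1)
    sets <- lapply(seq_len(k), function(i) {
      sample(LETTERS[1:8], sample(0:6, 1))
    })
    names(sets) <- paste0("S", seq_len(k))
    tab <- comparison_intersections(sets)
    expect_equal(sum(tab$count), length(unique(unlist(sets))))
    oracle <- intersections_oracle(sets)
    for (key in names(oracle)) {
      expect_equal(tab$count[tab$combination == key],
                   length(oracle[[key]]))
    }
  }
})

test_that("risk classification reproduces the stratification rule over the full grid", {
  expect_equal(classify_risk("6", "T2a"), "low")
  expect_equal(classify_risk("7(4+3)", "T2c"), "high")
  expect_equal(classify_risk("6", "T3a"), "high")

  grid <- expand.grid(gleason = gleason_levels(), ptnm = ptnm_levels(),
                      stringsAsFactors = FALSE)
  got <- classify_risk(grid$gleason, grid$ptnm)

  t_rank <- match(grid$ptnm, ptnm_levels())
  g_rank <- match(grid$gleason, gleason_levels())
  want <- rep("unclassified", nrow(grid))
  want[t_rank >= match("T3a", ptnm_levels())] <- "high"
  want[grid$gleason == "7(4+3)" & grid$ptnm == "T2c"] <- "high"
  lowint <- g_rank <= match("7(3+4)", gleason_levels()) &
    grid$ptnm %in% c("T2b", "T2c") & want == "unclassified"
  want[lowint] <- "low_intermediate"
  want[grid$gleason == "6" &
         t_rank <= match("T2a", ptnm_levels())] <- "low"
  expect_equal(got, want)

  # spot checks of documented gaps
  expect_equal(classify_risk("8", "T2a"), "unclassified")
  expect_equal(classify_risk("7(4+3)", "T2b"), "unclassified")
  expect_equal(classify_risk("6", "T2b"), "low_intermediate")
  expect_error(classify_risk("5", "T2a"), "Gleason")
  expect_error(classify_risk("6", "T5"), "pTNM")
})

test_that("the PSA gray-zone filter keeps the inclusive 4-10 ng/mL window", {
  ann <- data.frame(sample_id = sprintf("S%d", 1:4),
                    psa_ng_ml = c(2, 5, 9, 11))
  kept <- gray_zone_filter(ann)
  expect_equal(kept$sample_id, c("S2", "S3"))
  expect_equal(attr(kept, "n_missing_psa"), 0)

  expect_equal(nrow(gray_zone_filter(ann[0, ])), 0)
  ann$psa_ng_ml <- NA_real_
  all_missing <- gray_zone_filter(ann)
  expect_equal(nrow(all_missing), 0)
  expect_equal(attr(all_missing, "n_missing_psa"), 4)
  expect_error(gray_zone_filter(ann, 10, 4), "exceed")
  # inclusive bounds
  ann2 <- data.frame(sample_id = c("a", "b"), psa_ng_ml = c(4, 10))
  expect_equal(nrow(gray_zone_filter(ann2)), 2)
})

test_that("percentile flags use linear interpolation and strict exceedance", {
  fl <- percentile_flag(1:20, 65)
  expect_equal(attr(fl, "threshold"), 13.35)
  expect_equal(which(fl), 14:20)

  expect_false(any(percentile_flag(rep(5, 10), 65)))
  fl0 <- percentile_flag(c(1, 1, 2, 3), 0)
  expect_equal(as.logical(fl0), c(FALSE, FALSE, TRUE, TRUE))
  expect_error(percentile_flag(1:10, 101), "pct")
  expect_error(percentile_flag(5, 50), "finite")
})
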