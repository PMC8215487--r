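test_that("roc_analysis handles perfect, uninformative and tied markers", {
  r <- roc_analysis(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(r$auc, 1.0)
  expect_gt(r$cutoff, 0.2)
  expect_lt(r$cutoff, 0.8)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)

  const <- roc_analysis(rep(3, 8), rep(c(0, 1), 4))
  expect_equal(const$auc, 0.5)
  expect_true(const$degenerate)
  expect_true(is.na(const$cutoff))

  r2 <- roc_analysis(c(1, 2, 3, 4), c(0, 1, 0, 1))
  expect_equal(r2$auc, 0.75)  # 3 of 4 case/control pairs concordant

  expect_error(roc_analysis(1:4, c(1, 1, 1, 1)), ">= 2")
})

test_that("AUC equals pair counting and the cutoff attains the scan maximum", {
  # exhaustive over label sign patterns on fixed score sets
  for (n in c(5, 8)) {
    set.seed(n)
    scores_sets <- list(seq_len(n), round(rnorm(n), 1),
                        sample(c(1, 2, 2, 3), n, replace = TRUE))
    for (scores in scores_sets) {
      for (code in 0:(2^n - 1)) {
        is_case <- as.logical(bitwAnd(bitwShiftR(code, 0:(n - 1)), 1L))
        if (sum(is_case) < 2 || sum(!is_case) < 2) next
        r <- roc_analysis(scores, is_case)
        want <- auc_pair_oracle(scores, is_case)
        want <- max(want, 1 - want)  # direction auto-flip
        expect_equal(r$auc, want, tolerance = 1e-12)
        if (!r$degenerate) {
          eff <- if (r$direction == "greater") scores else -scores
          expect_equal(r$youden, youden_scan_oracle(eff, is_case),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("AUC and DeLong inference agree with pROC on random instances", {
  skip_if_not_installed("pROC")
  set.seed(17)
  for (i in 1:25) {
    n <- sample(8:30, 1)
    labels <- c(rep(0, 4), rep(1, 4), rbinom(n - 8, 1, 0.5))
    scores <- round(rnorm(n) + labels, 2)
    r <- roc_analysis(scores, labels)
    pr <- pROC::roc(labels, scores, direction = "<", quiet = TRUE)
    want_auc <- max(as.numeric(pROC::auc(pr)), 1 - as.numeric(pROC::auc(pr)))
    expect_equal(r$auc, want_auc, tolerance = 1e-12)
    if (r$direction == "greater" && r$auc > 0.5 && r$auc < 1) {
      ci <- suppressWarnings(pROC::ci.auc(pr, method = "delong"))
      expect_equal(c(r$ci_low, r$ci_high), as.numeric(ci)[c(1, 3)],
                   tolerance = 1e-9)
    }
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(9)
  for (i in 1:20) {
    scores <- rnorm(20)
    labels <- rbinom(20, 1, 0.5)
    if (sum(labels) < 2 || sum(1 - labels) < 2) next
    r1 <- roc_analysis(scores, labels)
    r2 <- roc_analysis(exp(scores) + 5, labels)
    expect_equal(r1$auc, r2$auc, tolerance = 1e-12)
    expect_equal(r1$direction, r2$direction)
  }
})

test_that("composite scoring implements the k-of-n rule with missingness", {
  sig <- composite_signature(paste0("E", 1:5), cutoffs = rep(10, 5),
                             directions = c(rep("greater", 4), "less"),
                             k = 3)
  mat <- rbind(
    all5  = c(20, 20, 20, 20, 1),
    none  = c(1, 1, 1, 1, 20),
    three = c(20, 20, 20, 1, 20),
    miss  = c(20, 20, NA, 1, 20))
  colnames(mat) <- paste0("E", 1:5)
  sc <- composite_score(mat, sig)
  expect_equal(sc$score, c(5L, 0L, 3L, 2L))
  expect_equal(sc$positive, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(sc$n_missing, c(0L, 0L, 0L, 1L))

  expect_error(composite_score(mat[, 1:4], sig), "absent")
  expect_error(composite_signature("E1", 1, "greater", k = 2), "k")
})

test_that("moving a value further beyond its cutoff never lowers the score", {
  sig <- composite_signature(c("E1", "E2"), c(5, 5), c("greater", "less"),
                             k = 1)
  set.seed(4)
  for (i in 1:20) {
    mat <- matrix(runif(10, 0, 10), 5, 2,
                  dimnames = list(NULL, c("E1", "E2")))
    s0 <- composite_score(mat, sig)$score
    mat2 <- mat
    mat2[, "E1"] <- mat2[, "E1"] + 3   # further in the "greater" direction
    mat2[, "E2"] <- mat2[, "E2"] - 3   # further in the "less" direction
    expect_true(all(composite_score(mat2, sig)$score >= s0))
  }
})

test_that("candidate combination preserves perfection and ignores dead markers", {
  set.seed(2)
  labels <- rep(c(0, 1), each = 6)
  perfect1 <- c(rnorm(6, 0, 0.1), rnorm(6, 5, 0.1))
  perfect2 <- c(rnorm(6, 10, 0.1), rnorm(6, 2, 0.1))  # separates downward
  mat <- cbind(M1 = perfect1, M2 = perfect2, FLAT = rep(1, 12))
  comb <- combine_candidates(mat, c("M1", "M2"), labels)
  expect_equal(comb$roc$auc, 1.0)

  # informative + constant: combined equals the informative exceedance AUC
  comb2 <- combine_candidates(mat, c("M1", "FLAT"), labels)
  ex1 <- as.integer(evrppa:::beyond_cutoff(mat[, "M1"],
                                  comb2$univariate$M1$cutoff,
                                  comb2$univariate$M1$direction))
  expect_equal(comb2$roc$auc, roc_analysis(ex1, labels)$auc)

  # duplicated marker: combined equals univariate exceedance AUC
  mat3 <- cbind(A = perfect1, B = perfect1)
  comb3 <- combine_candidates(mat3, c("A", "B"), labels)
  exA <- as.integer(evrppa:::beyond_cutoff(mat3[, "A"], comb3$univariate$A$cutoff,
                                  comb3$univariate$A$direction))
  expect_equal(comb3$roc$auc, roc_analysis(exA, labels)$auc)

  expect_error(combine_candidates(mat, c("M1", "NOPE"), labels), "absent")
})

test_that("signature evaluation reports ROC and the k-rule confusion table", {
  set.seed(12)
  labels <- rep(c(0, 1), each = 8)
  mat <- sapply(1:5, function(i) c(rnorm(8, 0), rnorm(8, 4)))
  colnames(mat) <- paste0("E", 1:5)
  der <- derive_signature(mat, colnames(mat), labels, k = 3)
  ev <- evaluate_signature(mat, der$signature, labels)
  expect_equal(ev$roc$auc, 1.0)
  expect_equal(ev$sensitivity, 1.0)
  expect_equal(ev$specificity, 1.0)
  expect_equal(sum(ev$confusion), 16)

  # k = n with no sample reaching n: sensitivity 0
  sig_hard <- composite_signature(paste0("E", 1:5), cutoffs = rep(1e6, 5),
                                  directions = rep("greater", 5), k = 5)
  ev2 <- evaluate_signature(mat, sig_hard, labels)
  expect_equal(ev2$sensitivity, 0)
})

test_that("permuted labels drive the signature AUC to chance", {
  set.seed(33)
  labels <- rep(c(0, 1), each = 10)
  mat <- sapply(1:5, function(i) c(rnorm(10, 0), rnorm(10, 1.5)))
  colnames(mat) <- paste0("E", 1:5)
  der <- derive_signature(mat, colnames(mat), labels, k = 3)
  aucs <- replicate(200, {
    evaluate_signature(mat, der$signature, sample(labels),
                       direction = "greater")$roc$auc
  })
  expect_gt(mean(aucs), 0.45)
  expect_lt(mean(aucs), 0.55)
})
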