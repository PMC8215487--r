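# Independent oracles used across the suite. These deliberately use naive
# (quadratic / exhaustive) formulations so they stay independent of the
# package's implementations.

# AUC by explicit pair counting: (concordant + 0.5 * tied) / (n1 * n0)
auc_pair_oracle <- function(scores, is_case) {
  x <- scores[as.logical(is_case)]
  y <- scores[!as.logical(is_case)]
  tot <- 0
  for (xi in x) tot <- tot + sum(xi > y) + 0.5 * sum(xi == y)
  tot / (length(x) * length(y))
}

# Maximum Youden J over the exhaustive midpoint scan (direction "greater")
youden_scan_oracle <- function(scores, is_case) {
  u <- sort(unique(scores))
  if (length(u) < 2) return(NA_real_)
  cand <- (u[-1] + u[-length(u)]) / 2
  best <- -Inf
  for (cut in cand) {
    sens <- mean(scores[as.logical(is_case)] >= cut)
    spec <- mean(scores[!as.logical(is_case)] < cut)
    best <- max(best, sens + spec - 1)
  }
  best
}

# Naive quadratic-time Ward (ward.D2) agglomeration: returns the sorted
# sequence of merge heights from the Lance-Williams update on Euclidean
# distances.
ward_heights_oracle <- function(X) {
  d <- as.matrix(dist(X))
  n <- nrow(d)
  active <- seq_len(n)
  size <- rep(1, n)
  heights <- numeric(0)
  while (length(active) > 1) {
    sub <- d[active, active, drop = FALSE]
    diag(sub) <- Inf
    ij <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    i <- active[ij[1]]; j <- active[ij[2]]
    h <- d[i, j]
    heights <- c(heights, h)
    ni <- size[i]; nj <- size[j]
    for (k in setdiff(active, c(i, j))) {
      nk <- size[k]
      dk <- sqrt(((ni + nk) * d[i, k]^2 + (nj + nk) * d[j, k]^2 -
                    nk * h^2) / (ni + nj + nk))
      d[i, k] <- d[k, i] <- dk
    }
    size[i] <- ni + nj
    active <- setdiff(active, j)
  }
  sort(heights)
}

# Brute-force LOD: apply the mean + k*SD rule fraction by fraction and scan
# for the smallest nonzero detected fraction with no detection gap above it.
lod_scan_oracle <- function(fractions, intensities, bg_mean, bg_sd, k,
                            min_reps) {
  thr <- bg_mean + k * bg_sd
  det <- apply(intensities, 1, function(v) sum(v > thr) >= min_reps)
  lod <- NA_real_
  nz <- which(fractions > 0)
  for (idx in rev(nz)) {
    if (det[idx]) lod <- fractions[idx] else break
  }
  lod
}

# Exact intersection counts by scanning every element of the union against
# the full power set of memberships.
intersections_oracle <- function(sets) {
  universe <- unique(unlist(sets))
  out <- list()
  for (el in universe) {
    mask <- vapply(sets, function(s) el %in% s, logical(1))
    key <- paste(names(sets)[mask], collapse = "&")
    out[[key]] <- c(out[[key]], el)
  }
  out
}

# small randomized spot table fixtures -----------------------------------

random_cohort <- function(seed, groups = c(HD = 3, PCa = 3), noise_cv = 0.15,
                          ...) {
  cohort_spec(groups, noise_cv = noise_cv, seed = seed, ...)
}

random_slide <- function(seed, n_endpoints = 3, n_per_group = 3, ...) {
  coh <- random_cohort(seed, groups = c(HD = n_per_group, PCa = n_per_group),
                       ...)
  lay <- assay_layout(sprintf("AB%d", seq_len(n_endpoints)),
                      cohort_samples(coh)$sample_id)
  generate_slide(lay, coh)
}
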