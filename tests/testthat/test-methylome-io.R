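test_that("coverage files parse, validate and round-trip exactly", {
  f <- tempfile(fileext = ".cov")
  writeLines(c("chr1\t100\t100\t50.0\t5\t5",
               "chr1\t200\t200\t0\t0\t0",
               "chr2\t50\t50\t100.0\t12\t0"), f)
  ds <- read_coverage_file(f, "sampleA", age_days = 61)
  expect_equal(nrow(ds), 3)
  expect_equal(unname(meth_counts(ds)["chr1:100:+", 1]), 5L)
  expect_equal(unname(percent_methylation(ds)["chr1:100:+", 1]), 50)
  # zero-coverage row recorded as missing
  expect_true(is.na(meth_counts(ds)["chr1:200:+", 1]))
  expect_true(is.na(percent_methylation(ds)["chr1:200:+", 1]))

  f2 <- tempfile(fileext = ".cov")
  write_coverage_file(ds, "sampleA", f2)
  ds2 <- read_coverage_file(f2, "sampleA", age_days = 61)
  obs <- !is.na(meth_counts(ds))
  expect_identical(meth_counts(ds)[obs], meth_counts(ds2)[!is.na(meth_counts(ds2))])

  bad <- tempfile()
  writeLines(c("chr1\t100\t100\t50.0\t5\t5", "chr1\t200\t200"), bad)
  expect_error(read_coverage_file(bad, "x"), "line 2")
  neg <- tempfile()
  writeLines("chr1\t100\t100\t50.0\t-5\t5", neg)
  expect_error(read_coverage_file(neg, "x"), "negative")
})

test_that("opposite-strand cytosines at the same position stay distinct", {
  sites <- data.frame(chrom = "chr1", pos = c(100L, 100L),
                      strand = c("+", "-"))
  ds <- methylation_dataset(matrix(c(5L, 8L), 2), matrix(c(5L, 2L), 2),
                            sites, data.frame(sample_id = "s1"))
  expect_equal(nrow(ds), 2)
  expect_setequal(site_keys(ds), c("chr1:100:+", "chr1:100:-"))
})

test_that("coverage filter is inclusive at 5 and 100 and drops empty sites", {
  tot <- c(4L, 5L, 50L, 100L, 101L)
  meth <- matrix(tot %/% 2L, 5)
  ds <- ds_from_counts(meth, matrix(tot, 5) - meth)
  out <- filter_by_coverage(ds)
  kept <- !is.na(meth_counts(out)[, 1])
  # site order follows position; sites 2..4 survive, 1 and 5 are dropped
  expect_equal(nrow(out), 3)
  expect_true(all(kept))
  expect_setequal(site_table(out)$pos, c(2000L, 3000L, 4000L))
  # unchanged when everything is mid-window
  ds50 <- ds_from_counts(matrix(25L, 4, 3), matrix(25L, 4, 3))
  expect_identical(meth_counts(filter_by_coverage(ds50)), meth_counts(ds50))
  expect_error(filter_by_coverage(ds, min_cov = 10, max_cov = 5), "min_cov")
})

test_that("coverage normalisation equalises medians and preserves fractions", {
  set.seed(42)
  n <- 200
  m1 <- rbinom(n, 10, 0.3); m2 <- rbinom(n, 40, 0.7)
  ds <- ds_from_counts(cbind(m1, m2), cbind(10L - m1, 40L - m2))
  out <- normalize_coverage(ds)
  tot <- total_coverage(out)
  meds <- apply(tot, 2, median)
  # reference = median of per-sample medians {10, 40} = 25
  expect_true(all(abs(meds - 25) <= 1))
  # fraction preserved within 1/(2 * coverage) after rounding
  frac_in <- m1 / 10
  frac_out <- meth_counts(out)[, 1] / tot[, 1]
  expect_true(all(abs(frac_in - frac_out) <= 1 / (2 * tot[, 1]) + 1e-12))
  # identical coverage distributions are untouched
  ds_same <- ds_from_counts(cbind(m1, m1), cbind(10L - m1, 10L - m1))
  expect_identical(meth_counts(normalize_coverage(ds_same)),
                   meth_counts(ds_same))
  zed <- ds_from_counts(cbind(m1, rep(0L, n)), cbind(10L - m1, rep(0L, n)))
  expect_error(normalize_coverage(zed), "zero median")
})

test_that("uniting keeps sites covered in >= min_per_group samples everywhere", {
  # two groups of 7; site1 in 5/7 of both, site2 in 4/7 of group B
  P <- matrix(50, 2, 14)
  P[1, c(6, 7, 13, 14)] <- NA
  P[2, c(11, 12, 13)] <- NA
  meth <- round(P); unmeth <- 100 - meth
  meth[is.na(P)] <- NA; unmeth[is.na(P)] <- NA
  storage.mode(meth) <- "integer"; storage.mode(unmeth) <- "integer"
  ds <- ds_from_counts(meth, unmeth, group = rep(c("A", "B"), each = 7))
  out <- unite_sites(ds, min_per_group = 5)
  expect_equal(nrow(out), 1)
  expect_equal(site_table(out)$pos, 1000L)
  expect_error(unite_sites(ds, min_per_group = 8), "unsatisfiable")
})

test_that("KNN imputation matches a brute-force nearest-neighbour oracle", {
  set.seed(7)
  n <- 30; s <- 8
  P <- matrix(runif(n * s, 0, 100), n, s)
  miss <- cbind(c(3, 11, 25), c(2, 5, 7))
  P[miss] <- NA
  ds <- ds_from_percent(P)
  k <- 4
  out <- impute_knn(ds, k = k)
  filled <- percent_methylation(out)
  # oracle: exhaustive pairwise RMS distance over shared samples
  for (r in seq_len(nrow(miss))) {
    i <- miss[r, 1]; sm <- miss[r, 2]
    d <- sapply(seq_len(n), function(j) {
      if (j == i) return(Inf)
      sh <- which(!is.na(P[i, ]) & !is.na(P[j, ]))
      if (length(sh) == 0) return(Inf)
      sqrt(mean((P[i, sh] - P[j, sh])^2))
    })
    cand <- order(d, seq_len(n))
    cand <- cand[!is.na(P[cand, sm])][1:k]
    expect_equal(unname(filled[i, sm]), mean(P[cand, sm]))
  }
  # remaining values untouched; no-missing dataset returned unchanged
  expect_equal(filled[!is.na(P)], P[!is.na(P)])
  full <- ds_from_percent(matrix(runif(50), 10, 5))
  expect_equal(percent_methylation(impute_knn(full)),
               percent_methylation(full))
})

test_that("four equal nearest neighbours impute their common value", {
  # site 1 identical to sites 2-5 on observed samples; all carry 50 at s4
  P <- rbind(c(10, 20, 30, NA),
             matrix(rep(c(10, 20, 30, 50), 4), 4, byrow = TRUE),
             c(90, 90, 90, 70))
  ds <- ds_from_percent(P)
  out <- impute_knn(ds, k = 4)
  expect_equal(unname(percent_methylation(out)[1, 4]), 50)
})

test_that("near-zero-variance rule applies strict ratio and unique cuts", {
  n_samp <- 40
  constant <- rep(50, n_samp)
  ratio19 <- c(rep(50, 38), 60, 60)            # ratio exactly 19 -> kept
  ratio38 <- c(rep(50, 38), 60, 70)            # wait: ratio 38 vs 1
  varied <- seq(1, 80, length.out = n_samp)    # all distinct -> kept
  P <- rbind(constant, ratio19, ratio38, varied)
  ds <- ds_from_percent(P)
  out <- suppressMessages(drop_near_zero_variance(ds))
  kept_pos <- site_table(out)$pos
  pos <- site_table(ds)$pos
  expect_true(pos[2] %in% kept_pos)   # ratio == 19: strict inequality
  expect_true(pos[4] %in% kept_pos)   # many distinct values
  expect_false(pos[1] %in% kept_pos)  # constant
  expect_false(pos[3] %in% kept_pos)  # 38/1 > 19 and 3/40 distinct
})

test_that("near-zero-variance agrees with the caret reference", {
  skip_if_not_installed("caret")
  set.seed(11)
  P <- matrix(sample(c(0, 25, 50, 100), 30 * 20, replace = TRUE,
                     prob = c(0.7, 0.1, 0.1, 0.1)), 30, 20)
  ds <- ds_from_percent(P)
  out <- suppressMessages(drop_near_zero_variance(ds))
  nzv <- caret::nearZeroVar(t(P), freqCut = 19, uniqueCut = 10)
  expect_setequal(site_table(out)$pos, site_table(ds)$pos[-nzv])
})

test_that("preprocessing steps are idempotent from the second application", {
  cfg <- sim_config(seed = 5, n_sites = 400)
  sim <- simulate_aging_cohort(cfg)
  ds <- filter_by_coverage(sim$dataset)
  expect_identical(meth_counts(filter_by_coverage(ds)), meth_counts(ds))
  un <- unite_sites(ds, 5)
  expect_identical(site_keys(unite_sites(un, 5)), site_keys(un))
  im <- impute_knn(un)
  expect_equal(percent_methylation(impute_knn(im)), percent_methylation(im))
  nz <- suppressMessages(drop_near_zero_variance(im))
  expect_identical(site_keys(suppressMessages(drop_near_zero_variance(nz))),
                   site_keys(nz))
})
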