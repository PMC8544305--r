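test_that("monotone methylation gives Spearman rho of +/- 1", {
  ages <- c(61, 122, 183, 244)
  P <- rbind(c(10, 20, 30, 40), c(40, 30, 20, 10))
  ds <- ds_from_percent(P, age_days = ages)
  assoc <- site_age_correlation(ds)
  expect_equal(assoc$rho, c(1, -1))
  expect_true(all(assoc$age_associated))
  expect_equal(as.character(assoc$bin), c("0.5 to 1", "-1 to -0.5"))
})

test_that("tied values use midranks: matches a rank-then-Pearson oracle", {
  ages <- c(61, 122, 183, 244)
  x <- c(10, 10, 30, 40)
  ds <- ds_from_percent(rbind(x, c(1, 2, 3, 4)), age_days = ages)
  assoc <- site_age_correlation(ds)
  oracle <- cor(rank(x, ties.method = "average"),
                rank(ages, ties.method = "average"))
  expect_equal(assoc$rho[1], oracle, tolerance = 1e-12)
})

test_that("small-sample p-values come from the exact permutation null", {
  ages <- c(61, 122, 183, 244, 305)
  x <- c(10, 25, 30, 42, 55)  # perfectly monotone
  ds <- ds_from_percent(rbind(x, c(5, 1, 9, 2, 7)), age_days = ages)
  assoc <- site_age_correlation(ds)
  # P(|rho| = 1) under random permutation of 5 distinct values = 2/120
  expect_equal(assoc$p[1], 2 / 120, tolerance = 1e-12)
})

test_that("constant sites are flagged with rho 0 and p 1", {
  ages <- seq(61, 426, length.out = 12)
  P <- rbind(rep(42, 12), seq(5, 60, length.out = 12))
  ds <- ds_from_percent(P, age_days = ages)
  assoc <- site_age_correlation(ds)
  expect_true(assoc$constant[1])
  expect_equal(assoc$rho[1], 0)
  expect_equal(assoc$p[1], 1)
  expect_false(assoc$age_associated[1])
})

test_that("BH q-values are monotone in p rank and bound below by p", {
  cfg <- sim_config(seed = 31, n_sites = 800, missing_rate = 0,
                    coverage_mean = 50, coverage_dispersion = 20)
  sim <- simulate_aging_cohort(cfg)
  assoc <- site_age_correlation(sim$dataset)
  expect_true(all(assoc$q >= assoc$p))
  o <- order(assoc$p)
  expect_true(all(diff(assoc$q[o]) >= -1e-15))
})

test_that("null simulations keep false positives near nominal rates", {
  cfg <- sim_config(seed = 37, n_sites = 3000, frac_age_sites = 0,
                    missing_rate = 0, coverage_mean = 50,
                    coverage_dispersion = 20)
  sim <- simulate_aging_cohort(cfg)
  assoc <- site_age_correlation(sim$dataset)
  mc_err <- sqrt(0.05 * 0.95 / 3000)
  expect_lte(mean(assoc$q < 0.05), 0.05 + 3 * mc_err)
  # |rho| > 0.5 under the n = 47 permutation null (Monte-Carlo oracle)
  set.seed(1)
  y <- rank(sample_meta(sim$dataset)$age_days)
  null_frac <- mean(replicate(20000, abs(cor(sample(y), y)) > 0.5))
  obs <- mean(assoc$age_associated)
  tol <- 3 * sqrt(max(null_frac, 1 / 3000) / 3000) + 3 / 3000
  expect_lte(abs(obs - null_frac), tol)
})

test_that("correlation bins partition sites with boundary-out assignment", {
  rho <- c(-1, -0.7, -0.5, -0.4, -0.25, -0.1, 0, 0.1, 0.25, 0.3, 0.5, 0.9, 1)
  b <- correlation_bin(rho)
  expect_equal(as.character(b[rho == 0.3]), "0.25 to 0.5")
  expect_equal(as.character(b[rho == 0.5]), "0.5 to 1")
  expect_equal(as.character(b[rho == -0.5]), "-1 to -0.5")
  expect_equal(as.character(b[rho == 0.25]), "0.25 to 0.5")
  expect_equal(as.character(b[rho == -0.25]), "-0.5 to -0.25")
  expect_equal(as.character(b[rho == 0]), "0")
  expect_false(any(is.na(b)))
  occ <- classify_and_bin(data.frame(site = as.character(seq_along(rho)),
                                     rho = rho))$occupancy
  expect_equal(sum(occ), length(rho))
})

test_that("DMC calling applies both the difference and q thresholds", {
  meth <- cbind(c(90L, 50L, 40L), c(10L, 50L, 60L))
  tot <- matrix(100L, 3, 2)
  tot[3, ] <- 10000L
  meth[3, ] <- c(4000L, 6000L)
  ds <- ds_from_counts(meth, tot - meth, group = c("A", "B"))
  tab <- call_dmcs(ds, "A", "B")
  expect_equal(tab$meth_diff[1], -80)
  expect_lt(tab$p[1], 1e-10)
  expect_true(tab$is_dmc[1])
  expect_equal(tab$meth_diff[2], 0)
  expect_false(tab$is_dmc[2])
  # 20% difference with a tiny p still fails the 25% rule
  expect_lt(tab$p[3], 1e-12)
  expect_false(tab$is_dmc[3])
  expect_equal(tab$direction[1], "hypo")
  # Fisher route agrees to order of magnitude on the strong site
  fish <- call_dmcs(ds, "A", "B", test = "fisher")
  expect_lt(fish$p[1], 1e-10)
})

test_that("DMC calling is antisymmetric under group swap", {
  set.seed(5)
  meth <- matrix(rbinom(40, 60, 0.4), 20, 2)
  ds <- ds_from_counts(meth, 60L - meth, group = c("A", "B"))
  ab <- call_dmcs(ds, "A", "B")
  ba <- call_dmcs(ds, "B", "A")
  expect_equal(ab$meth_diff, -ba$meth_diff)
  expect_equal(ab$p, ba$p)
})

test_that("the pooled LRT matches a binomial logistic-regression oracle", {
  set.seed(9)
  m <- matrix(rbinom(30, 80, runif(30, 0.1, 0.9)), 15, 2)
  ds <- ds_from_counts(m, 80L - m, group = c("A", "B"))
  tab <- call_dmcs(ds, "A", "B")
  for (i in seq_len(15)) {
    g <- factor(c("A", "B"))
    fit1 <- glm(cbind(m[i, ], 80 - m[i, ]) ~ g, family = binomial)
    fit0 <- glm(cbind(m[i, ], 80 - m[i, ]) ~ 1, family = binomial)
    p_glm <- anova(fit0, fit1, test = "LRT")$`Pr(>Chi)`[2]
    expect_equal(tab$p[i], p_glm, tolerance = 1e-8)
  }
})

test_that("early/late rates use metadata days and the paired t formula", {
  ages <- rep(c(61, 122, 183, 274, 426), each = 2)
  groups <- paste0("g", ages)
  set.seed(2)
  P <- matrix(runif(8 * 10, 10, 90), 8, 10)
  # deterministic site: 10% at 61 d, 28.4% at 183 d
  P[1, ages == 61] <- 10
  P[1, ages == 183] <- 28.4
  ds <- ds_from_percent(P, age_days = ages, group = groups)
  res <- early_late_rates(ds, site_keys(ds),
                          early = c("g61", "g183"), late = c("g274", "g426"))
  expect_equal(res$rates$abs_change_early[1], 18.4, tolerance = 1e-9)
  expect_equal(res$rates$rate_early_pct_day[1], 18.4 / 122, tolerance = 1e-9)
  # closed-form paired t oracle
  d <- res$rates$rate_early_pct_day - res$rates$rate_late_pct_day
  t_oracle <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(res$t, t_oracle, tolerance = 1e-10)
  expect_equal(res$df, length(d) - 1)
  # identical rates in both intervals: t = 0, p = 1
  Q <- P
  Q[, ages == 274] <- Q[, ages == 61]
  Q[, ages == 426] <- Q[, ages == 61] + (Q[, ages == 183] - Q[, ages == 61]) *
    (426 - 274) / 122
  ds2 <- ds_from_percent(Q, age_days = ages, group = groups)
  res2 <- early_late_rates(ds2, site_keys(ds2),
                           early = c("g61", "g183"), late = c("g274", "g426"))
  expect_equal(res2$t, 0)
  expect_equal(res2$p, 1)
})
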