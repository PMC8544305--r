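make_study_ds <- function(seed = 1, n_sites = 60, noise = 2) {
  set.seed(seed)
  ages <- rep(study_ages, study_ns)
  n <- n_sites
  P <- matrix(runif(n * length(ages), 10, 90), n, length(ages))
  # first 20 sites track age linearly (percent spans ~36 points)
  for (i in 1:20)
    P[i, ] <- 10 + (ages - 61) / 365 * 36 + rnorm(length(ages), 0, noise)
  ds_from_percent(clamp_mat(P), age_days = ages,
                  group = paste0("age_", ages, "d"))
}

clamp_mat <- function(P) pmin(pmax(P, 0), 100)

test_that("stratified split is a deterministic partition of the cohort", {
  ds <- make_study_ds()
  sp <- split_train_test(ds, n_test = 10, seed = 4)
  expect_equal(length(sp$train), 37)
  expect_equal(length(sp$test), 10)
  expect_setequal(c(sp$train, sp$test), sample_meta(ds)$sample_id)
  expect_length(intersect(sp$train, sp$test), 0)
  # 1-2 test samples per group
  grp <- sample_meta(ds)$group[match(sp$test, sample_meta(ds)$sample_id)]
  expect_true(all(table(grp) %in% 1:2))
  expect_identical(sp, split_train_test(ds, n_test = 10, seed = 4))
  expect_error(split_train_test(ds, n_test = 20, seed = 1), "infeasible")
})

test_that("top-k selection enforces the 100 bp spacing rule", {
  ages <- rep(study_ages, study_ns)
  a <- (ages - 61) / 4
  P <- rbind(a,                       # chr1:100, r = 1
             a + rnorm(47, 0, 0.8),   # chr1:150, slightly weaker
             a + rnorm(47, 0, 2))     # chr2:5000, weaker still
  set.seed(3)
  ds <- ds_from_percent(clamp_mat(P + 20), age_days = ages,
                        group = paste0("g", ages),
                        chrom = c("chr1", "chr1", "chr2"),
                        pos = c(100L, 150L, 5000L))
  model <- fit_linear_topk(ds, k = 2)
  expect_setequal(model$sites, c("chr1:100:+", "chr2:5000:+"))
  expect_error(fit_linear_topk(ds, k = 3), "spacing")
})

test_that("noiseless linear aging is recovered exactly by OLS", {
  ages <- rep(study_ages, study_ns)
  x <- (ages - 10) / 2          # age = 2 * x + 10
  P <- rbind(x, matrix(runif(5 * 47, 40, 60), 5, 47))
  set.seed(6)
  ds <- ds_from_percent(P, age_days = ages, group = paste0("g", ages))
  model <- fit_linear_topk(ds, k = 1)
  expect_equal(model$weights, 2, tolerance = 1e-8)
  expect_equal(model$intercept, 10, tolerance = 1e-8)
  pred <- predict_age(model, ds)
  expect_equal(pred$predicted_age_days, ages, tolerance = 1e-8)
})

test_that("elastic net collapses to the mean at large lambda and to OLS at 0", {
  set.seed(12)
  ages <- rep(study_ages, study_ns)
  n <- length(ages)
  P <- matrix(runif(5 * n, 10, 90), 5, n)
  P[1, ] <- 10 + (ages / 426) * 70 + rnorm(n, 0, 2)
  ds <- ds_from_percent(clamp_mat(P), age_days = ages, group = paste0("g", ages))
  # lambda -> infinity: all weights zero, prediction = mean of log10 ages
  m_inf <- fit_elastic_net(ds, lambda = c(1e6, 1e5))
  expect_length(m_inf$sites, 0)
  pred <- predict_age(m_inf, ds)$predicted_age_days
  expect_equal(pred, rep(10^mean(log10(ages)), n), tolerance = 1e-6)
  # lambda = 0 with p < n matches closed-form OLS
  m0 <- fit_elastic_net(ds, lambda = c(1, 0.1, 0.01, 0.001, 0))
  X <- t(percent_methylation(ds))
  ols <- coef(lm(log10(ages) ~ X))
  expect_equal(m0$intercept, unname(ols[1]), tolerance = 1e-6)
  w_full <- setNames(rep(0, 5), site_keys(ds))
  w_full[m0$sites] <- m0$weights
  expect_equal(unname(w_full[site_keys(ds)]), unname(ols[-1]),
               tolerance = 1e-6)
  # predictions are back-transformed to days: 10^(b0 + Xw)
  manual <- 10^(m0$intercept + as.vector(X[, match(m0$sites, site_keys(ds))] %*%
                                         m0$weights))
  expect_equal(predict_age(m0, ds)$predicted_age_days, manual,
               tolerance = 1e-12)
})

test_that("PCA clock: perfect age signal gives PC1 explaining everything", {
  ages <- rep(study_ages, study_ns)
  P <- rbind(ages / 5, ages / 6, ages / 7)
  ds <- ds_from_percent(P, age_days = ages, group = paste0("g", ages))
  model <- fit_pca_clock(ds)
  expect_equal(model$var_explained_pct, 100, tolerance = 1e-8)
  pred <- predict_age(model, ds)$predicted_age_days
  expect_equal(pred, ages, tolerance = 1e-6)
})

test_that("PC1 variance explained matches an eigendecomposition oracle", {
  set.seed(8)
  ages <- rep(study_ages, study_ns)
  P <- matrix(runif(6 * 47, 10, 90), 6, 47)
  for (i in 1:4) P[i, ] <- clamp_mat(10 + ages / 6 + rnorm(47, 0, 8))
  ds <- ds_from_percent(P, age_days = ages, group = paste0("g", ages))
  model <- fit_pca_clock(ds, rho_threshold = 0.3)
  sel <- match(model$sites, site_keys(ds))
  Z <- scale(t(P[sel, ]))
  ev <- eigen(cov(Z))$values
  expect_equal(model$var_explained_pct, 100 * ev[1] / sum(ev),
               tolerance = 1e-6)
})

test_that("prediction degrades linearly and gracefully with missing sites", {
  ages <- rep(study_ages, study_ns)
  set.seed(10)
  P <- rbind((ages - 10) / 2, matrix(runif(4 * 47, 30, 70), 4, 47))
  ds <- ds_from_percent(P, age_days = ages, group = paste0("g", ages))
  model <- fit_linear_topk(ds, k = 2)
  # dataset lacking every model site: prediction = intercept
  other <- ds_from_percent(matrix(50, 3, 5), pos = c(9L, 99L, 999L) * 100000L)
  expect_equal(predict_age(model, other)$predicted_age_days,
               rep(model$intercept, 5), tolerance = 1e-10)
  # removing one site with weight w and value v shifts prediction by -w*v
  keep1 <- ds[site_keys(ds) == model$sites[1], ]
  p_full <- predict_age(model, ds)$predicted_age_days
  p_miss <- predict_age(model, keep1)$predicted_age_days
  v2 <- percent_methylation(ds)[match(model$sites[2], site_keys(ds)), ]
  expect_equal(p_full - p_miss, unname(model$weights[2] * v2),
               tolerance = 1e-8)
})

test_that("serialised clocks reload and predict bit-identically", {
  ds <- make_study_ds(seed = 14)
  for (fit in list(fit_linear_topk(ds, k = 4),
                   fit_elastic_net(ds),
                   fit_pca_clock(ds, rho_threshold = 0.4))) {
    f <- tempfile(fileext = ".json")
    write_clock(fit, f)
    back <- read_clock(f)
    expect_identical(predict_age(fit, ds)$predicted_age_days,
                     predict_age(back, ds)$predicted_age_days)
  }
})

test_that("evaluation metrics and the overfit comparison behave", {
  ev <- evaluate_clock(c(100, 200), c(110, 190))
  expect_equal(ev$mae, 10)
  perfect <- evaluate_clock(c(61, 122, 183), c(61, 122, 183))
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$r2, 1)
  tr <- evaluate_clock(c(100, 105, 98, 101), c(100, 100, 100, 100), "train")
  te <- evaluate_clock(c(140, 60, 150), c(100, 100, 100), "test")
  ov <- compare_overfit(tr, te)
  expect_lt(ov$p, 0.05)
  expect_lt(ov$mae_train, ov$mae_test)
})

test_that("group ANOVA is calibrated on null predictions", {
  set.seed(20)
  reject <- mean(replicate(400, {
    pred <- data.frame(predicted_age_days = rnorm(24, 230, 20))
    compare_groups(pred, rep(c("0", "5", "50", "500"), each = 6))$p < 0.05
  }))
  expect_gt(reject, 0.02)
  expect_lt(reject, 0.09)
  expect_error(compare_groups(data.frame(predicted_age_days = 1:3),
                              rep("a", 3)), "2 groups")
})
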