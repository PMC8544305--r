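#' Stratified train/test split by age group
#'
#' Draws one sample per age group, then tops up to the requested test size
#' with a second sample from randomly chosen groups (so each group
#' contributes one or two test samples). Deterministic under `seed`.
#'
#' @param ds dataset whose samples carry `group`.
#' @param n_test total test-set size (default 10).
#' @param seed integer seed.
#' @return list with `train` and `test` sample-id vectors (a partition of
#'   all samples).
#' @export
split_train_test <- function(ds, n_test = 10, seed = 1L) {
  meta <- sample_meta(ds)
  groups <- split(meta$sample_id, meta$group)
  if (any(lengths(groups) < 3)) stop2("every group needs >= 3 samples")
  ng <- length(groups)
  if (n_test < ng || n_test > 2 * ng)
    stop2("requested test size infeasible: need between ", ng, " and ", 2 * ng)
  set.seed(substream_seed(seed, "split"))
  per_group <- setNames(rep(1L, ng), names(groups))
  extra <- n_test - ng
  if (extra > 0) {
    up <- sample(names(groups), extra)
    per_group[up] <- 2L
  }
  test <- unlist(lapply(names(groups), function(g)
    sample(groups[[g]], per_group[[g]])), use.names = FALSE)
  list(train = setdiff(meta$sample_id, test), test = test)
}

clock_model <- function(family, sites, weights, intercept, age_transform,
                        extra = list(), training_meta = list()) {
  structure(c(list(family = family, sites = sites, weights = weights,
                   intercept = intercept, age_transform = age_transform,
                   training_meta = training_meta), extra),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat("Epigenetic clock (", x$family, "): ", length(x$sites),
      " sites, age transform ", x$age_transform, "\n", sep = "")
  invisible(x)
}

transform_age <- function(age, transform) {
  switch(transform, identity = age, log10 = log10(age))
}

untransform_age <- function(y, transform) {
  switch(transform, identity = y, log10 = 10^y)
}

clock_matrix <- function(model, ds) {
  # model sites absent from ds contribute predictor value 0 (the documented
  # degradation path for datasets that do not cover every clock site)
  P <- percent_methylation(ds)
  idx <- match(model$sites, site_keys(ds))
  X <- matrix(0, ncol(ds), length(model$sites),
              dimnames = list(sample_meta(ds)$sample_id, model$sites))
  present <- !is.na(idx)
  X[, present] <- t(P[idx[present], , drop = FALSE])
  X[is.na(X)] <- 0
  X
}

#' Fit the top-k linear clock
#'
#' Ranks sites by the magnitude of the Pearson correlation between percent
#' methylation and untransformed age on the training samples, greedily
#' takes the top `k` while skipping any site within `min_spacing_bp` of an
#' already-chosen site on the same chromosome (ties in |r| break by
#' (chrom, pos) order), and fits ordinary least squares of age in days on
#' the k percent-methylation predictors.
#'
#' @param ds preprocessed dataset restricted to training samples.
#' @param k number of clock sites (default 10).
#' @param min_spacing_bp spacing rule in bp (default 100).
#' @return a `clock_model`.
#' @export
fit_linear_topk <- function(ds, k = 10, min_spacing_bp = 100) {
  P <- percent_methylation(ds)
  age <- sample_meta(ds)$age_days
  r <- rowwise_pearson(P, age)
  r[is.na(r)] <- 0
  st <- site_table(ds)
  ord <- order(-abs(r), st$chrom, st$pos)
  chosen <- integer(0)
  for (i in ord) {
    if (length(chosen) >= k) break
    close_by <- length(chosen) > 0 &&
      any(st$chrom[chosen] == st$chrom[i] &
          abs(st$pos[chosen] - st$pos[i]) <= min_spacing_bp)
    if (!close_by) chosen <- c(chosen, i)
  }
  if (length(chosen) < k)
    stop2("fewer than k sites remain after the spacing filter")
  X <- t(P[chosen, , drop = FALSE])
  fit <- lm(age ~ X)
  cf <- coef(fit)
  cf[is.na(cf)] <- 0
  clock_model("linear_topk",
              sites = site_keys(ds)[chosen],
              weights = unname(cf[-1]),
              intercept = unname(cf[1]),
              age_transform = "identity",
              training_meta = list(n_train = ncol(ds), k = k,
                                   min_spacing_bp = min_spacing_bp,
                                   train_r = unname(r[chosen])))
}

#' Fit the elastic-net clock
#'
#' Penalised gaussian regression of log10(age in days) on standardised
#' percent-methylation predictors (glmnet, alpha = 0.5 by default). Lambda
#' is selected as the grid value minimising leave-one-out cross-validated
#' mean squared error over 100 log-spaced values spanning four decades
#' below the smallest lambda that zeroes all coefficients; the path is
#' deterministic given the data. Only sites with nonzero weights are
#' stored.
#'
#' @param ds preprocessed training dataset.
#' @param alpha elastic-net mixing parameter (default 0.5).
#' @param lambda optional fixed lambda vector overriding the grid (the
#'   smallest value is used for coefficients, without cross-validation).
#' @param nlambda,lambda_min_ratio grid size and span.
#' @return a `clock_model` with `age_transform = "log10"`.
#' @export
fit_elastic_net <- function(ds, alpha = 0.5, lambda = NULL, nlambda = 100,
                            lambda_min_ratio = 1e-4) {
  P <- percent_methylation(ds)
  age <- sample_meta(ds)$age_days
  y <- log10(age)
  if (sd(y) == 0) stop2("degenerate (constant) response")
  X <- t(P)
  n <- nrow(X)
  if (is.null(lambda)) {
    Xs <- scale(X)
    Xs[, attr(Xs, "scaled:scale") == 0] <- 0
    lmax <- max(abs(crossprod(Xs, y - mean(y)))) / (n * max(alpha, 1e-3))
    grid <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                    length.out = nlambda))
    cv <- glmnet::cv.glmnet(X, y, alpha = alpha, lambda = grid,
                            foldid = seq_len(n), grouped = FALSE,
                            standardize = TRUE, family = "gaussian")
    lambda_min <- cv$lambda.min
    fit <- cv$glmnet.fit
    cvm <- cv$cvm
  } else {
    fit <- glmnet::glmnet(X, y, alpha = alpha,
                          lambda = sort(lambda, decreasing = TRUE),
                          standardize = TRUE, family = "gaussian",
                          thresh = 1e-14, maxit = 1e6)
    lambda_min <- min(lambda)
    cvm <- NULL
  }
  cf <- as.matrix(coef(fit, s = lambda_min, exact = FALSE))
  w <- cf[-1, 1]
  nz <- which(w != 0)
  clock_model("elastic_net",
              sites = site_keys(ds)[nz],
              weights = unname(w[nz]),
              intercept = unname(cf[1, 1]),
              age_transform = "log10",
              training_meta = list(n_train = n, alpha = alpha,
                                   lambda = lambda_min,
                                   cv_mse = if (!is.null(cvm)) min(cvm)))
}

#' Fit the PCA clock
#'
#' Selects training-set age-associated sites (|Spearman rho| > threshold),
#' centres and (by default) scales them to unit variance, computes the
#' first principal component, orients it so its correlation with age is
#' positive, and regresses age in days on PC1.
#'
#' @param ds preprocessed training dataset.
#' @param rho_threshold Spearman magnitude threshold for site selection
#'   (default 0.5, strict).
#' @param scale. scale sites to unit variance before PCA (default TRUE).
#' @return a `clock_model` storing loadings, centring/scaling constants,
#'   the PC1-to-age regression and the percent variance explained by PC1.
#' @export
fit_pca_clock <- function(ds, rho_threshold = 0.5, scale. = TRUE) {
  P <- percent_methylation(ds)
  age <- sample_meta(ds)$age_days
  R <- rowwise_midranks(P)
  rho <- rowwise_pearson(R, rank(age))
  rho[is.na(rho)] <- 0
  sel <- which(abs(rho) > rho_threshold)
  if (length(sel) < 2) stop2("fewer than 2 age-associated sites in training")
  X <- t(P[sel, , drop = FALSE])
  ctr <- colMeans(X)
  scl <- if (scale.) apply(X, 2, sd) else rep(1, ncol(X))
  scl[scl == 0] <- 1
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  sv <- svd(Z)
  loadings <- sv$v[, 1]
  pc1 <- as.vector(Z %*% loadings)
  if (cor(pc1, age) < 0) { loadings <- -loadings; pc1 <- -pc1 }
  fit <- lm(age ~ pc1)
  var_explained <- 100 * sv$d[1]^2 / sum(sv$d^2)
  clock_model("pca",
              sites = site_keys(ds)[sel],
              weights = loadings,
              intercept = unname(coef(fit)[1]),
              age_transform = "identity",
              extra = list(centers = unname(ctr), scales = unname(scl),
                           pc1_slope = unname(coef(fit)[2]),
                           pc1_intercept = unname(coef(fit)[1]),
                           var_explained_pct = var_explained),
              training_meta = list(n_train = ncol(ds),
                                   rho_threshold = rho_threshold,
                                   n_selected = length(sel)))
}

#' Predict age from a clock model
#'
#' Clock sites absent from the dataset contribute a predictor value of 0
#' (and sites with missing percent values likewise), which is the
#' documented degradation path when applying a clock to a dataset that
#' covers only part of its sites. Predictions are back-transformed to days.
#'
#' @param model a `clock_model`.
#' @param ds dataset to predict on (any samples).
#' @return data.frame sample_id, predicted_age_days.
#' @export
predict_age <- function(model, ds) {
  X <- clock_matrix(model, ds)
  pred <- if (model$family == "pca") {
    Z <- sweep(sweep(X, 2, model$centers), 2, model$scales, "/")
    pc1 <- as.vector(Z %*% model$weights)
    model$pc1_intercept + model$pc1_slope * pc1
  } else {
    untransform_age(model$intercept + as.vector(X %*% model$weights),
                    model$age_transform)
  }
  data.frame(sample_id = rownames(X), predicted_age_days = unname(pred),
             stringsAsFactors = FALSE)
}

#' Evaluate predictions against chronological age
#'
#' MAE in days and the coefficient of determination R^2 = 1 - SSres/SStot,
#' both on the day scale.
#'
#' @param predicted,truth aligned numeric vectors (days).
#' @param split optional label ("train"/"test").
#' @return list with mae, r2, n, split and the per-sample table.
#' @export
evaluate_clock <- function(predicted, truth, split = NA_character_) {
  stopifnot(length(predicted) == length(truth), length(truth) > 0)
  res <- truth - predicted
  list(mae = mean(abs(res)),
       r2 = 1 - sum(res^2) / sum((truth - mean(truth))^2),
       n = length(truth), split = split,
       table = data.frame(predicted = predicted, truth = truth,
                          abs_error = abs(res)))
}

#' Compare training and test absolute errors (overfit check)
#'
#' Two-sample t-test on the absolute errors of the two splits.
#'
#' @param train_eval,test_eval results of [evaluate_clock()].
#' @return list with t, df, p and the two MAEs.
#' @export
compare_overfit <- function(train_eval, test_eval) {
  tt <- t.test(train_eval$table$abs_error, test_eval$table$abs_error)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mae_train = train_eval$mae, mae_test = test_eval$mae)
}

#' Compare predicted ages across exposure groups
#'
#' One-way ANOVA of predicted age on group label.
#'
#' @param predictions data.frame from [predict_age()].
#' @param groups group label per prediction row.
#' @return list with F, df, p.
#' @export
compare_groups <- function(predictions, groups) {
  stopifnot(nrow(predictions) == length(groups))
  if (length(unique(groups)) < 2) stop2("need >= 2 groups for ANOVA")
  fit <- aov(predictions$predicted_age_days ~ factor(groups))
  s <- summary(fit)[[1]]
  list(F = s$`F value`[1], df = s$Df[1:2], p = s$`Pr(>F)`[1])
}

#' Serialise and restore clock models
#'
#' JSON schema: family, sites as "chrom:pos:strand", weights, intercept,
#' age transform, per-family extras and training metadata. Numbers are
#' written with 17 significant digits so reloaded models reproduce
#' predictions bit-identically.
#'
#' @param model a `clock_model`.
#' @param path JSON file path.
#' @return `read_clock()` returns the restored `clock_model`.
#' @export
write_clock <- function(model, path) {
  obj <- unclass(model)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_clock
#' @export
read_clock <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$sites <- as.character(obj$sites)
  obj$weights <- as.numeric(obj$weights)
  for (f in c("centers", "scales"))
    if (!is.null(obj[[f]])) obj[[f]] <- as.numeric(obj[[f]])
  structure(obj, class = "clock_model")
}
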