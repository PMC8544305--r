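#' Mask cells outside the coverage window
#'
#' Cells with total coverage below `min_cov` or above `max_cov` are set to
#' missing (both bounds inclusive on the retained side: coverage 5 and 100
#' survive the default window). Sites left with no observed cell are
#' dropped. Surviving count values are never altered.
#'
#' @param ds methylation dataset.
#' @param min_cov,max_cov inclusive coverage bounds (defaults 5 and 100).
#' @return filtered dataset.
#' @export
filter_by_coverage <- function(ds, min_cov = 5, max_cov = 100) {
  if (min_cov > max_cov) stop2("min_cov > max_cov")
  m <- meth_counts(ds); u <- unmeth_counts(ds)
  tot <- m + u
  drop <- !is.na(tot) & (tot < min_cov | tot > max_cov)
  m[drop] <- NA_integer_; u[drop] <- NA_integer_
  SummarizedExperiment::assay(ds, "meth") <- m
  SummarizedExperiment::assay(ds, "unmeth") <- u
  keep <- rowSums(!is.na(m)) > 0
  ds[keep, ]
}

#' Scale sample coverage to a common median
#'
#' Each sample's counts are scaled by (reference median coverage / sample
#' median coverage), where the reference is the median of the per-sample
#' median coverages. The scaled total is rounded to the nearest integer and
#' the methylated count recomputed from the pre-rounding methylation
#' fraction, so each cell's fraction is preserved within rounding.
#'
#' @param ds multi-sample methylation dataset.
#' @return dataset with normalised counts.
#' @export
normalize_coverage <- function(ds) {
  if (ncol(ds) < 2) stop2("normalize_coverage needs >= 2 samples")
  m <- meth_counts(ds); u <- unmeth_counts(ds)
  tot <- m + u
  med <- apply(tot, 2, median, na.rm = TRUE)
  if (any(!is.finite(med)) || any(med == 0))
    stop2("sample with zero median coverage")
  ref <- median(med)
  f <- ref / med
  for (j in seq_len(ncol(ds))) {
    obs <- !is.na(tot[, j])
    new_tot <- as.integer(round(tot[obs, j] * f[j]))
    frac <- m[obs, j] / tot[obs, j]
    new_m <- as.integer(round(new_tot * frac))
    m[obs, j] <- new_m
    u[obs, j] <- new_tot - new_m
  }
  SummarizedExperiment::assay(ds, "meth") <- m
  SummarizedExperiment::assay(ds, "unmeth") <- u
  ds
}

#' Unite sites across samples by per-group coverage
#'
#' Keeps sites observed (after coverage filtering) in at least
#' `min_per_group` samples of every group. Unobserved cells of surviving
#' sites remain missing.
#'
#' @param ds multi-sample dataset whose samples carry a `group` label, or a
#'   list of single-sample datasets (combined first).
#' @param min_per_group minimum observed samples per group (default 5).
#' @return united dataset.
#' @export
unite_sites <- function(ds, min_per_group = 5) {
  if (is.list(ds) && !is(ds, "SummarizedExperiment"))
    ds <- combine_samples(ds)
  meta <- sample_meta(ds)
  if (any(is.na(meta$group))) stop2("every sample needs a group label")
  grp_sizes <- table(meta$group)
  if (any(grp_sizes < min_per_group))
    stop2("group smaller than min_per_group: criterion unsatisfiable")
  obs <- !is.na(meth_counts(ds))
  keep <- rep(TRUE, nrow(ds))
  for (g in names(grp_sizes)) {
    cols <- meta$group == g
    keep <- keep & rowSums(obs[, cols, drop = FALSE]) >= min_per_group
  }
  ds[keep, ]
}

#' K-nearest-neighbour imputation of percent methylation
#'
#' Fills each missing percent value with the mean percent of the `k`
#' nearest sites at that sample, where site-site distance is the root mean
#' squared difference of percent values over samples where both sites are
#' observed, and only sites observed at the target sample are candidate
#' neighbours. Ties in distance break by site order. Counts stay missing:
#' stages downstream of imputation operate on the `percent` assay this
#' function adds.
#'
#' @param ds united dataset.
#' @param k number of neighbours (default 4).
#' @return dataset with a complete `percent` assay.
#' @export
impute_knn <- function(ds, k = 4) {
  p <- percent_methylation(ds)
  if (nrow(p) < k + 1) stop2("need at least k + 1 sites")
  if (any(rowSums(!is.na(p)) == 0))
    stop2("site missing in all samples; drop it before imputation")
  obs <- !is.na(p)
  if (all(obs)) {
    SummarizedExperiment::assay(ds, "percent", withDimnames = FALSE) <- p
    return(ds)
  }
  X0 <- p; X0[!obs] <- 0
  M <- obs * 1
  X2 <- X0^2
  need <- which(rowSums(!obs) > 0)
  filled <- p
  block <- 512L
  n <- nrow(p)
  for (bs in split(need, ceiling(seq_along(need) / block))) {
    D2 <- X2[bs, , drop = FALSE] %*% t(M) +
      M[bs, , drop = FALSE] %*% t(X2) -
      2 * X0[bs, , drop = FALSE] %*% t(X0)
    nshared <- M[bs, , drop = FALSE] %*% t(M)
    D <- sqrt(pmax(D2, 0) / pmax(nshared, 1))
    D[nshared == 0] <- Inf
    for (ii in seq_along(bs)) {
      i <- bs[ii]
      d <- D[ii, ]
      d[i] <- Inf
      ord <- order(d, seq_len(n))
      for (s in which(!obs[i, ])) {
        cand <- ord[obs[ord, s]]
        nb <- cand[seq_len(min(k, length(cand)))]
        filled[i, s] <- mean(p[nb, s])
      }
    }
  }
  SummarizedExperiment::assay(ds, "percent", withDimnames = FALSE) <- filled
  ds
}

#' Remove near-zero-variance sites
#'
#' Drops sites whose percent values are (near-)invariable across samples:
#' a site is dropped when the ratio of the most common value's count to the
#' second most common value's count exceeds `freq_cut` (strictly) AND the
#' fraction of distinct values over samples is at most `unique_cut`.
#' Constant sites (no second value) are always dropped.
#'
#' @param ds imputed dataset (complete `percent` assay).
#' @param freq_cut frequency-ratio threshold (default 19, i.e. 95/5).
#' @param unique_cut distinct-value fraction threshold (default 0.10).
#' @return dataset with invariable sites removed; the number retained is
#'   reported as a message.
#' @export
drop_near_zero_variance <- function(ds, freq_cut = 19, unique_cut = 0.10) {
  p <- percent_methylation(ds)
  keep <- vapply(seq_len(nrow(p)), function(i) {
    v <- p[i, ]
    v <- v[!is.na(v)]
    tab <- sort(table(v), decreasing = TRUE)
    if (length(tab) == 1) return(FALSE)
    ratio <- tab[1] / tab[2]
    pct_unique <- length(tab) / length(v)
    !(ratio > freq_cut && pct_unique <= unique_cut)
  }, logical(1))
  message(sum(keep), " of ", nrow(p), " sites retained after ",
          "near-zero-variance removal")
  ds[keep, ]
}

#' Run the full preprocessing chain
#'
#' Order-fixed: coverage filter, coverage normalisation, uniting across
#' samples, KNN imputation, near-zero-variance removal.
#'
#' @param ds multi-sample dataset (or list of single-sample datasets).
#' @param min_cov,max_cov coverage window (default 5-100).
#' @param min_per_group uniting threshold (default 5).
#' @param knn_k imputation neighbours (default 4).
#' @return preprocessed dataset with a complete `percent` assay.
#' @export
preprocess <- function(ds, min_cov = 5, max_cov = 100, min_per_group = 5,
                       knn_k = 4) {
  if (is.list(ds) && !is(ds, "SummarizedExperiment"))
    ds <- combine_samples(ds)
  ds <- filter_by_coverage(ds, min_cov, max_cov)
  ds <- normalize_coverage(ds)
  ds <- unite_sites(ds, min_per_group)
  ds <- impute_knn(ds, knn_k)
  drop_near_zero_variance(ds)
}
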