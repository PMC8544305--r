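CORR_BIN_LEVELS <- c("-1 to -0.5", "-0.5 to -0.25", "-0.25 to 0", "0",
                     "0 to 0.25", "0.25 to 0.5", "0.5 to 1")

#' Assign Spearman coefficients to correlation bins
#'
#' Seven bins along the age-correlation continuum. A coefficient of exactly
#' zero gets its own "0" bin; boundary values (0.25, 0.5 and their
#' negatives) are assigned to the bin farther from zero, so rho = 0.5 falls
#' in "0.5 to 1" and rho = -0.25 in "-0.5 to -0.25".
#'
#' @param rho numeric vector of correlation coefficients in [-1, 1].
#' @return factor with levels `"-1 to -0.5"`, ..., `"0.5 to 1"`.
#' @export
correlation_bin <- function(rho) {
  lab <- character(length(rho))
  lab[rho == 0] <- "0"
  lab[rho > 0 & rho < 0.25] <- "0 to 0.25"
  lab[rho >= 0.25 & rho < 0.5] <- "0.25 to 0.5"
  lab[rho >= 0.5] <- "0.5 to 1"
  lab[rho < 0 & rho > -0.25] <- "-0.25 to 0"
  lab[rho <= -0.25 & rho > -0.5] <- "-0.5 to -0.25"
  lab[rho <= -0.5] <- "-1 to -0.5"
  lab[is.na(rho)] <- NA
  factor(lab, levels = CORR_BIN_LEVELS)
}

bin_midpoint <- function(bin) {
  mid <- c("-1 to -0.5" = -0.75, "-0.5 to -0.25" = -0.375,
           "-0.25 to 0" = -0.125, "0" = 0, "0 to 0.25" = 0.125,
           "0.25 to 0.5" = 0.375, "0.5 to 1" = 0.75)
  unname(mid[as.character(bin)])
}

rowwise_pearson <- function(X, y) {
  # correlation of each row of X with y, NA-free input
  Xc <- X - rowMeans(X)
  yc <- y - mean(y)
  num <- as.vector(Xc %*% yc)
  den <- sqrt(rowSums(Xc^2) * sum(yc^2))
  r <- ifelse(den > 0, num / den, NA_real_)
  clamp(r, -1, 1)
}

rowwise_midranks <- function(X) {
  t(apply(X, 1, rank, ties.method = "average"))
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

spearman_exact_p <- function(x, y) {
  # exact permutation two-sided p for the Spearman coefficient, small n
  n <- length(x)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  obs <- abs(cor(rx, ry))
  perms <- permutations_of(n)
  stat <- apply(perms, 1, function(pm) abs(cor(rx[pm], ry)))
  mean(stat >= obs - 1e-12)
}

#' Per-site correlation of percent methylation with age
#'
#' Spearman (midranks for ties) and Pearson coefficients are both computed
#' for every site; p-values come from the coefficient selected by `method`
#' (t approximation for n >= 10, exact permutation below), q-values by
#' Benjamini-Hochberg across all tested sites. Sites with constant
#' methylation get rho = 0, p = 1 and a `constant` flag. A site is flagged
#' age-associated when its Spearman coefficient exceeds 0.5 in magnitude
#' (strictly).
#'
#' @param ds preprocessed dataset (complete percent matrix) whose samples
#'   carry `age_days`.
#' @param method "spearman" (default) or "pearson" for the p-value.
#' @param age_transform "identity" (default) or "log10" applied to age
#'   before correlating.
#' @return data.frame with site, rho, r, p, q, bin, age_associated,
#'   constant; one row per site.
#' @export
site_age_correlation <- function(ds, method = c("spearman", "pearson"),
                                 age_transform = c("identity", "log10")) {
  method <- match.arg(method)
  age_transform <- match.arg(age_transform)
  P <- percent_methylation(ds)
  if (any(is.na(P))) stop2("percent matrix has missing values; impute first")
  age <- sample_meta(ds)$age_days
  if (length(unique(age)) < 3) stop2("need >= 3 samples with distinct ages")
  y <- if (age_transform == "log10") log10(age) else age
  n <- ncol(P)

  r <- rowwise_pearson(P, y)
  R <- rowwise_midranks(P)
  rho <- rowwise_pearson(R, rank(y, ties.method = "average"))
  const <- is.na(rho) | is.na(r)
  rho[is.na(rho)] <- 0
  r[is.na(r)] <- 0

  stat <- if (method == "spearman") rho else r
  if (n >= 10) {
    tt <- stat * sqrt((n - 2) / pmax(1 - stat^2, .Machine$double.eps))
    p <- pmin(2 * pt(abs(tt), df = n - 2, lower.tail = FALSE), 1)
  } else {
    p <- vapply(seq_len(nrow(P)), function(i) {
      if (const[i]) return(1)
      if (method == "spearman") spearman_exact_p(P[i, ], y)
      else {
        perms <- permutations_of(n)
        obs <- abs(cor(P[i, ], y))
        mean(apply(perms, 1, function(pm) abs(cor(P[i, pm], y))) >= obs - 1e-12)
      }
    }, numeric(1))
  }
  p[const] <- 1
  data.frame(site = site_keys(ds),
             rho = rho, r = r, p = p,
             q = p.adjust(p, method = "BH"),
             bin = correlation_bin(rho),
             age_associated = rho > 0.5 | rho < -0.5,
             constant = const,
             stringsAsFactors = FALSE)
}

#' Bin occupancy along the age-correlation continuum
#'
#' @param records output of [site_age_correlation()].
#' @return list with `records` (bin column refreshed) and `occupancy`
#'   (count per bin; sums to the number of sites).
#' @export
classify_and_bin <- function(records) {
  records$bin <- correlation_bin(records$rho)
  occ <- table(records$bin)
  list(records = records, occupancy = occ)
}

# closed-form 2x2 binomial likelihood-ratio (G) statistic; identical to the
# deviance of a logistic regression of methylation state on group
lrt_two_proportions <- function(m1, t1, m2, t2) {
  term <- function(o, e) ifelse(o > 0, o * log(o / e), 0)
  p0 <- (m1 + m2) / (t1 + t2)
  g <- 2 * (term(m1, t1 * p0) + term(t1 - m1, t1 * (1 - p0)) +
            term(m2, t2 * p0) + term(t2 - m2, t2 * (1 - p0)))
  pchisq(pmax(g, 0), df = 1, lower.tail = FALSE)
}

#' Call differentially methylated cytosines between two groups
#'
#' Methylated and total counts are pooled within each group per site; the
#' p-value is a two-proportion binomial likelihood-ratio test (equivalent
#' to a logistic regression of methylation state on group with no
#' covariates), q-values are Benjamini-Hochberg across tested sites, and
#' the methylation difference is the pooled percent difference (group B
#' minus group A). A site is a DMC when |difference| >= `diff_threshold`
#' and q <= `q_threshold`. Fisher's exact test is available via `test`.
#'
#' @param ds dataset with counts (pre-imputation) and group labels.
#' @param group_a,group_b group labels to compare.
#' @param diff_threshold percent-difference threshold (default 25).
#' @param q_threshold FDR threshold (default 0.01).
#' @param test "lrt" (default) or "fisher".
#' @return data.frame site, group_a, group_b, meth_diff, p, q, is_dmc,
#'   direction ("hyper"/"hypo" by the sign of meth_diff). Sites with zero
#'   pooled coverage in either group are skipped (reported via a message).
#' @export
call_dmcs <- function(ds, group_a, group_b, diff_threshold = 25,
                      q_threshold = 0.01, test = c("lrt", "fisher")) {
  test <- match.arg(test)
  meta <- sample_meta(ds)
  stopifnot(group_a %in% meta$group, group_b %in% meta$group)
  m <- meth_counts(ds); tot <- m + unmeth_counts(ds)
  ca <- meta$group == group_a; cb <- meta$group == group_b
  m1 <- rowSums(m[, ca, drop = FALSE], na.rm = TRUE)
  t1 <- rowSums(tot[, ca, drop = FALSE], na.rm = TRUE)
  m2 <- rowSums(m[, cb, drop = FALSE], na.rm = TRUE)
  t2 <- rowSums(tot[, cb, drop = FALSE], na.rm = TRUE)
  ok <- t1 > 0 & t2 > 0
  if (any(!ok))
    message(sum(!ok), " sites skipped (zero pooled coverage in a group)")
  keys <- site_keys(ds)[ok]
  m1 <- m1[ok]; t1 <- t1[ok]; m2 <- m2[ok]; t2 <- t2[ok]
  meth_diff <- 100 * (m2 / t2 - m1 / t1)
  p <- if (test == "lrt") {
    lrt_two_proportions(m1, t1, m2, t2)
  } else {
    vapply(seq_along(m1), function(i)
      fisher.test(matrix(c(m1[i], t1[i] - m1[i], m2[i], t2[i] - m2[i]), 2))$p.value,
      numeric(1))
  }
  q <- p.adjust(p, method = "BH")
  data.frame(site = keys, group_a = group_a, group_b = group_b,
             meth_diff = meth_diff, p = p, q = q,
             is_dmc = abs(meth_diff) >= diff_threshold & q <= q_threshold,
             direction = ifelse(meth_diff >= 0, "hyper", "hypo"),
             stringsAsFactors = FALSE)
}

#' Early- versus late-life rate of methylation change
#'
#' For each supplied site, the absolute change in group-mean percent
#' methylation across the early interval (first to second group) and the
#' late interval (third to fourth group) is divided by the actual days
#' elapsed between the group mean ages, giving per-day rates that are
#' compared with a paired t-test.
#'
#' @param ds preprocessed dataset (complete percent matrix).
#' @param sites character vector of site keys (typically the
#'   age-associated set).
#' @param early,late length-2 character vectors of group labels bounding
#'   each interval.
#' @return list with `rates` (per-site absolute change and per-day rate for
#'   each interval), `t` , `df`, `p` (paired t-test of early vs late
#'   per-day rates) and the interval lengths in days.
#' @export
early_late_rates <- function(ds, sites, early, late) {
  stopifnot(length(early) == 2, length(late) == 2, length(sites) > 0)
  P <- percent_methylation(ds)
  meta <- sample_meta(ds)
  idx <- match(sites, site_keys(ds))
  if (any(is.na(idx))) stop2("unknown site keys")
  gmean <- function(g) rowMeans(P[idx, meta$group == g, drop = FALSE])
  gage <- function(g) mean(meta$age_days[meta$group == g])
  d_early <- gage(early[2]) - gage(early[1])
  d_late <- gage(late[2]) - gage(late[1])
  if (d_early <= 0 || d_late <= 0) stop2("zero or negative days elapsed")
  abs_early <- abs(gmean(early[2]) - gmean(early[1]))
  abs_late <- abs(gmean(late[2]) - gmean(late[1]))
  rate_early <- abs_early / d_early
  rate_late <- abs_late / d_late
  diffs <- rate_early - rate_late
  if (all(abs(diffs - diffs[1]) < 1e-12) && abs(mean(diffs)) < 1e-12) {
    tt <- list(statistic = c(t = 0), parameter = c(df = length(diffs) - 1),
               p.value = 1)
  } else {
    tt <- t.test(rate_early, rate_late, paired = TRUE)
  }
  list(rates = data.frame(site = sites,
                          abs_change_early = abs_early,
                          abs_change_late = abs_late,
                          rate_early_pct_day = rate_early,
                          rate_late_pct_day = rate_late,
                          stringsAsFactors = FALSE),
       days_early = d_early, days_late = d_late,
       mean_rate_early = mean(rate_early),
       mean_rate_late = mean(rate_late),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}
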