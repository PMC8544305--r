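#' Classify a read's within-read methylation pattern
#'
#' Reads with fewer than two CpG calls are ineligible. Otherwise the
#' within-read percent methylation m = 100 * mean(calls) (exact fraction,
#' no rounding) classifies the read as concordant (m <= 9 or m >= 91) or
#' discordant (10 <= m <= 90). Order of calls is irrelevant.
#'
#' @param calls binary vector (1 = methylated) or binary string ("1101").
#' @return "concordant", "discordant" or "ineligible".
#' @export
classify_read <- function(calls) {
  if (is.character(calls) && length(calls) == 1)
    calls <- as.integer(strsplit(calls, "")[[1]])
  if (any(!calls %in% c(0, 1))) stop2("non-binary call values")
  if (length(calls) < 2) return("ineligible")
  m <- 100 * mean(calls)
  if (m <= 9 || m >= 91) "concordant" else "discordant"
}

#' Percent of discordant reads for one sample
#'
#' PDR = 100 * (discordant reads) / (reads with >= 2 CpGs).
#'
#' @param patterns read-pattern table (columns sample_id, calls) as
#'   produced by [simulate_read_patterns()] or [read_pattern_file()].
#' @param sample sample id.
#' @return list sample_id, n_eligible, n_discordant, pdr (NA with a
#'   warning when no read is eligible).
#' @export
compute_pdr <- function(patterns, sample) {
  calls <- patterns$calls[patterns$sample_id == sample]
  ncpg <- nchar(calls)
  eligible <- ncpg >= 2
  if (!any(eligible)) {
    warning("no eligible reads (>= 2 CpGs) for sample ", sample)
    return(list(sample_id = sample, n_eligible = 0L, n_discordant = 0L,
                pdr = NA_real_))
  }
  nmeth <- vapply(strsplit(calls[eligible], ""), function(x) sum(x == "1"), 1)
  m <- 100 * nmeth / ncpg[eligible]
  disc <- m >= 10 & m <= 90
  list(sample_id = sample, n_eligible = sum(eligible),
       n_discordant = sum(disc),
       pdr = 100 * sum(disc) / sum(eligible))
}

#' PDR for every sample in a pattern set
#'
#' @param patterns read-pattern table.
#' @return data.frame sample_id, n_eligible, n_discordant, pdr.
#' @export
compute_pdr_all <- function(patterns) {
  do.call(rbind, lapply(unique(patterns$sample_id), function(s)
    as.data.frame(compute_pdr(patterns, s))))
}

#' Trend of PDR with log age, with a batch random effect
#'
#' Fits PDR ~ beta * log(age_days) with a random intercept per library
#' batch (lme4, REML). The p-value for beta uses a t statistic with
#' residual degrees of freedom (n - 2). With a single batch the model
#' reduces to ordinary least squares, with a warning.
#'
#' @param pdr data.frame from [compute_pdr_all()].
#' @param metadata sample metadata (sample_id, age_days, batch).
#' @param log_base base of the age log-transform (default e).
#' @return list beta, se, t, df, p, batch_sd, model.
#' @export
pdr_age_trend <- function(pdr, metadata, log_base = exp(1)) {
  d <- merge(pdr, metadata[, c("sample_id", "age_days", "batch")],
             by = "sample_id")
  if (any(d$age_days <= 0)) stop2("non-positive ages")
  d <- d[!is.na(d$pdr), ]
  d$log_age <- log(d$age_days, base = log_base)
  n <- nrow(d)
  if (length(unique(d$batch)) < 2) {
    warning("single batch: falling back to ordinary least squares")
    fit <- lm(pdr ~ log_age, data = d)
    sm <- summary(fit)$coefficients
    return(list(beta = sm["log_age", 1], se = sm["log_age", 2],
                t = sm["log_age", 3], df = n - 2,
                p = 2 * pt(abs(sm["log_age", 3]), n - 2, lower.tail = FALSE),
                batch_sd = 0, model = fit))
  }
  fit <- lme4::lmer(pdr ~ log_age + (1 | batch), data = d, REML = TRUE)
  sm <- summary(fit)$coefficients
  beta <- sm["log_age", "Estimate"]
  se <- sm["log_age", "Std. Error"]
  tval <- beta / se
  df <- n - 2
  vc <- as.data.frame(lme4::VarCorr(fit))
  list(beta = beta, se = se, t = tval, df = df,
       p = 2 * pt(abs(tval), df, lower.tail = FALSE),
       batch_sd = vc$sdcor[vc$grp == "batch"], model = fit)
}

#' Read and write read-pattern tables
#'
#' Tab-separated columns sample_id, chrom, start, calls (binary string).
#'
#' @param patterns read-pattern data.frame.
#' @param path file path.
#' @return `read_pattern_file()` returns the pattern data.frame.
#' @export
write_pattern_file <- function(patterns, path) {
  utils::write.table(patterns[, c("sample_id", "chrom", "start", "calls")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_pattern_file
#' @export
read_pattern_file <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("character", "character", "integer",
                                   "character"))
}
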