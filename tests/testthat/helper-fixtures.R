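# Small in-code fixture builders shared across test files.

# Dataset whose percent matrix equals P exactly: meth = P reads of 100.
# P may contain NA (missing cells).
ds_from_percent <- function(P, age_days = NULL, group = NULL, batch = "b1",
                            chrom = NULL, pos = NULL, strand = NULL) {
  n <- nrow(P); s <- ncol(P)
  meth <- pmax(round(P), 0)
  storage.mode(meth) <- "integer"
  unmeth <- pmax(100L - meth, 0L)
  sites <- data.frame(
    chrom = chrom %||% rep("chr1", n),
    pos = pos %||% seq(1000L, by = 1000L, length.out = n),
    strand = strand %||% rep("+", n))
  samples <- data.frame(
    sample_id = paste0("s", seq_len(s)),
    age_days = age_days %||% rep(NA, s),
    batch = rep(batch, length.out = s),
    group = group %||% rep("g", s))
  ds <- methylation_dataset(meth, unmeth, sites, samples)
  SummarizedExperiment::assay(ds, "percent", withDimnames = FALSE) <-
    matrix(as.numeric(P), n, s)
  ds
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Dataset built directly from count matrices.
ds_from_counts <- function(meth, unmeth, age_days = NULL, group = NULL,
                           batch = "b1", pos = NULL) {
  n <- nrow(meth); s <- ncol(meth)
  sites <- data.frame(chrom = "chr1",
                      pos = pos %||% seq(1000L, by = 1000L, length.out = n),
                      strand = "+")
  samples <- data.frame(sample_id = paste0("s", seq_len(s)),
                        age_days = age_days %||% rep(NA, s),
                        batch = rep(batch, length.out = s),
                        group = group %||% rep("g", s))
  methylation_dataset(meth, unmeth, sites, samples)
}

# The seven-group aging design used by the study-shaped simulations.
study_ages <- c(61L, 122L, 152L, 183L, 274L, 365L, 426L)
study_ns <- c(7L, 6L, 6L, 8L, 6L, 8L, 6L)

# Random read-pattern table for PDR tests.
random_patterns <- function(n_reads, sample_id = "s1", max_cpg = 8) {
  k <- sample(1:max_cpg, n_reads, replace = TRUE)
  calls <- vapply(k, function(kk)
    paste(sample(0:1, kk, replace = TRUE), collapse = ""), "")
  data.frame(sample_id = sample_id, chrom = "chr1",
             start = seq_len(n_reads), calls = calls,
             stringsAsFactors = FALSE)
}
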