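#' Construct a methylation dataset
#'
#' The central container is a [SummarizedExperiment::RangedSummarizedExperiment]
#' with integer assays `meth` and `unmeth` (per-cytosine methylated /
#' unmethylated read counts; `NA` marks an unobserved cell), row ranges
#' holding the cytosine coordinates (1-based, stranded; opposite-strand
#' cytosines are never merged) and column data holding the sample metadata.
#' After KNN imputation a third assay `percent` carries the working
#' percent-methylation matrix.
#'
#' @param meth,unmeth integer site-by-sample count matrices (same dimensions).
#' @param sites data.frame with columns `chrom`, `pos`, `strand`, one row per
#'   site, or a `GRanges` of width-1 ranges.
#' @param samples data.frame of sample metadata; must contain `sample_id`,
#'   and may contain `age_days`, `batch`, `dose_mGy_day`, `group`.
#' @return a `RangedSummarizedExperiment` sorted by (chrom, pos).
#' @export
methylation_dataset <- function(meth, unmeth, sites, samples) {
  meth <- as.matrix(meth); unmeth <- as.matrix(unmeth)
  stopifnot(identical(dim(meth), dim(unmeth)))
  if (any(meth < 0, na.rm = TRUE) || any(unmeth < 0, na.rm = TRUE))
    stop2("negative methylation counts")
  if (is.data.frame(sites)) {
    gr <- GenomicRanges::GRanges(
      seqnames = as.character(sites$chrom),
      ranges = IRanges::IRanges(start = sites$pos, width = 1L),
      strand = if (!is.null(sites$strand)) sites$strand else "+")
  } else gr <- sites
  stopifnot(length(gr) == nrow(meth))
  samples <- as.data.frame(samples)
  stopifnot("sample_id" %in% names(samples), nrow(samples) == ncol(meth))
  for (col in c("age_days", "batch", "dose_mGy_day", "group"))
    if (is.null(samples[[col]])) samples[[col]] <- NA
  rownames(meth) <- rownames(unmeth) <- site_key_from_granges(gr)
  colnames(meth) <- colnames(unmeth) <- samples$sample_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(meth = meth, unmeth = unmeth),
    rowRanges = gr,
    colData = S4Vectors::DataFrame(samples, row.names = samples$sample_id))
  sort_sites(se)
}

site_key_from_granges <- function(gr) {
  paste(as.character(GenomicRanges::seqnames(gr)),
        GenomicRanges::start(gr),
        as.character(GenomicRanges::strand(gr)), sep = ":")
}

sort_sites <- function(ds) {
  gr <- SummarizedExperiment::rowRanges(ds)
  o <- order(as.character(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr),
             as.character(GenomicRanges::strand(gr)))
  ds[o, ]
}

#' Accessors for methylation datasets
#'
#' @param ds a methylation dataset.
#' @return `meth_counts()` / `unmeth_counts()` return the count matrices;
#'   `total_coverage()` their sum; `percent_methylation()` the percent
#'   matrix (the `percent` assay if present, otherwise recomputed from
#'   counts, `NA` where a cell is missing or has zero coverage);
#'   `sample_meta()` the column metadata as a data.frame; `site_keys()` the
#'   "chrom:pos:strand" identifiers; `site_table()` the coordinates as a
#'   data.frame.
#' @name dataset-accessors
NULL

#' @rdname dataset-accessors
#' @export
meth_counts <- function(ds) SummarizedExperiment::assay(ds, "meth")

#' @rdname dataset-accessors
#' @export
unmeth_counts <- function(ds) SummarizedExperiment::assay(ds, "unmeth")

#' @rdname dataset-accessors
#' @export
total_coverage <- function(ds) meth_counts(ds) + unmeth_counts(ds)

#' @rdname dataset-accessors
#' @export
percent_methylation <- function(ds) {
  if ("percent" %in% SummarizedExperiment::assayNames(ds))
    return(SummarizedExperiment::assay(ds, "percent"))
  m <- meth_counts(ds); tot <- m + unmeth_counts(ds)
  p <- 100 * m / tot
  p[!is.na(tot) & tot == 0] <- NA_real_
  p
}

#' @rdname dataset-accessors
#' @export
sample_meta <- function(ds) as.data.frame(SummarizedExperiment::colData(ds))

#' @rdname dataset-accessors
#' @export
site_keys <- function(ds) site_key_from_granges(SummarizedExperiment::rowRanges(ds))

#' @rdname dataset-accessors
#' @export
site_table <- function(ds) {
  gr <- SummarizedExperiment::rowRanges(ds)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             pos = GenomicRanges::start(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Read a Bismark-style coverage file as a single-sample dataset
#'
#' Expects the six tab-separated columns chrom, start, end, percent
#' methylation, count methylated, count unmethylated (1-based inclusive
#' coordinates; start == end for CpG rows). Counts are authoritative: the
#' percent column is only checked for consistency (within 0.1) and then
#' recomputed. Cells with zero total coverage are recorded as missing.
#' An optional seventh column carries the strand; "+" is assumed otherwise.
#'
#' @param path coverage file path.
#' @param sample_id sample identifier.
#' @param age_days,batch,dose_mGy_day,group optional sample metadata.
#' @return a single-sample methylation dataset.
#' @export
read_coverage_file <- function(path, sample_id, age_days = NA, batch = NA,
                               dose_mGy_day = NA, group = NA) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 6L | nf > 7L)
  if (length(bad))
    stop2("malformed coverage row at line ", bad[1], " of ", path)
  tab <- do.call(rbind, lapply(fields, `[`, 1:7))
  chrom <- tab[, 1]
  pos <- suppressWarnings(as.integer(tab[, 2]))
  endp <- suppressWarnings(as.integer(tab[, 3]))
  pct <- suppressWarnings(as.numeric(tab[, 4]))
  m <- suppressWarnings(as.integer(tab[, 5]))
  u <- suppressWarnings(as.integer(tab[, 6]))
  strand <- ifelse(is.na(tab[, 7]), "+", tab[, 7])
  bad <- which(is.na(pos) | is.na(endp) | is.na(pct) | is.na(m) | is.na(u))
  if (length(bad))
    stop2("malformed coverage row at line ", bad[1], " of ", path)
  if (any(m < 0 | u < 0))
    stop2("negative counts at line ", which(m < 0 | u < 0)[1], " of ", path)
  tot <- m + u
  stated_ok <- tot == 0 | abs(pct - 100 * m / pmax(tot, 1)) <= 0.1
  if (!all(stated_ok))
    warning("stated %methylation differs from counts by > 0.1 at ",
            sum(!stated_ok), " rows of ", path, "; counts used")
  mm <- matrix(m, ncol = 1); uu <- matrix(u, ncol = 1)
  mm[tot == 0] <- NA_integer_; uu[tot == 0] <- NA_integer_
  methylation_dataset(
    mm, uu,
    sites = data.frame(chrom = chrom, pos = pos, strand = strand),
    samples = data.frame(sample_id = sample_id, age_days = age_days,
                         batch = batch, dose_mGy_day = dose_mGy_day,
                         group = group))
}

#' Write one sample of a dataset as a Bismark-style coverage file
#'
#' Missing cells are omitted. A seventh strand column is written so that
#' write-then-read round-trips counts exactly (readers of the 6-column
#' dialect can ignore it).
#'
#' @param ds methylation dataset.
#' @param sample_id which sample to write.
#' @param path destination.
#' @export
write_coverage_file <- function(ds, sample_id, path) {
  stopifnot(sample_id %in% sample_meta(ds)$sample_id)
  st <- site_table(ds)
  m <- meth_counts(ds)[, sample_id]
  u <- unmeth_counts(ds)[, sample_id]
  keep <- !is.na(m) & !is.na(u)
  tot <- m[keep] + u[keep]
  pct <- ifelse(tot > 0, 100 * m[keep] / tot, 0)
  out <- paste(st$chrom[keep], st$pos[keep], st$pos[keep],
               formatC(pct, digits = 6, format = "g"),
               m[keep], u[keep], st$strand[keep], sep = "\t")
  writeLines(out, path)
}

#' Combine single-sample datasets over the union of their sites
#'
#' Cells for sites unobserved in a sample stay missing. Sample order is
#' preserved; sites are sorted by (chrom, pos, strand).
#'
#' @param ds_list list of methylation datasets (typically single-sample).
#' @return one multi-sample dataset.
#' @export
combine_samples <- function(ds_list) {
  stopifnot(length(ds_list) >= 1)
  keys <- lapply(ds_list, site_keys)
  all_keys <- unique(unlist(keys))
  n <- length(all_keys)
  ids <- unlist(lapply(ds_list, function(d) sample_meta(d)$sample_id))
  if (anyDuplicated(ids)) stop2("duplicate sample ids across datasets")
  nc <- sum(vapply(ds_list, ncol, 1L))
  M <- matrix(NA_integer_, n, nc, dimnames = list(all_keys, ids))
  U <- M
  j <- 0L
  meta <- list()
  for (d in ds_list) {
    idx <- match(site_keys(d), all_keys)
    cols <- j + seq_len(ncol(d))
    M[idx, cols] <- meth_counts(d)
    U[idx, cols] <- unmeth_counts(d)
    meta[[length(meta) + 1L]] <- sample_meta(d)
    j <- j + ncol(d)
  }
  parts <- strsplit(all_keys, ":", fixed = TRUE)
  sites <- data.frame(chrom = vapply(parts, `[`, "", 1),
                      pos = as.integer(vapply(parts, `[`, "", 2)),
                      strand = vapply(parts, `[`, "", 3))
  methylation_dataset(M, U, sites, do.call(rbind, meta))
}

#' Read and write sample-metadata tables
#'
#' Tab-separated with header columns sample_id, age_days, batch,
#' dose_mGy_day, group.
#'
#' @param meta data.frame of sample metadata.
#' @param path file path.
#' @return `read_sample_metadata()` returns a data.frame.
#' @export
write_sample_metadata <- function(meta, path) {
  cols <- c("sample_id", "age_days", "batch", "dose_mGy_day", "group")
  for (col in cols) if (is.null(meta[[col]])) meta[[col]] <- NA
  utils::write.table(meta[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' @rdname write_sample_metadata
#' @export
read_sample_metadata <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
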