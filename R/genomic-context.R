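#' Detect CpG islands with a sliding window
#'
#' Slides a 100 bp window by 1 bp; a window passes when its G+C content is
#' at least 50 percent and its observed/expected CpG ratio is at least 0.6,
#' where observed = count of CG dinucleotides in the window and expected =
#' count(C) * count(G) / window length. Overlapping passing windows are
#' merged and merged runs of at least `min_length` bp are reported with the
#' average GC and observed/expected of their contributing windows.
#' Windows containing N never pass. Coordinates are 1-based inclusive.
#'
#' @param sequence a DNA string (character or [Biostrings::DNAString]) over
#'   A/C/G/T/N.
#' @param chrom chromosome name attached to results (default "chr1").
#' @param window window size in bp (default 100).
#' @param min_gc,min_obs_exp window thresholds (defaults 50 and 0.6).
#' @param min_length minimum merged-island length (default 200).
#' @return data.frame chrom, start, end (1-based inclusive), length,
#'   gc (percent), obs_exp; zero rows when nothing passes or the sequence
#'   is shorter than the window.
#' @export
detect_cgi <- function(sequence, chrom = "chr1", window = 100,
                       min_gc = 50, min_obs_exp = 0.6, min_length = 200) {
  s <- toupper(as.character(sequence))
  len <- nchar(s)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), length = integer(),
                      gc = numeric(), obs_exp = numeric())
  if (len < window) return(empty)
  chars <- strsplit(s, "")[[1]]
  isC <- chars == "C"; isG <- chars == "G"; isN <- !chars %in% c("A", "C", "G", "T")
  isCG <- c(isC[-len] & isG[-1], FALSE)
  win_sum <- function(x, w) {
    cs <- cumsum(c(0, x))
    cs[(w + 1):(len + 1)] - cs[1:(len - w + 1)]
  }
  nC <- win_sum(isC, window)
  nG <- win_sum(isG, window)
  nN <- win_sum(isN, window)
  # CG dinucleotides fully inside the window [i, i+window-1]: starts in
  # [i, i+window-2], i.e. a sliding sum of width window-1 truncated to the
  # same number of windows
  nCG <- win_sum(isCG, window - 1)[seq_len(len - window + 1)]
  gc <- 100 * (nC + nG) / window
  expected <- nC * nG / window
  obs_exp <- ifelse(expected > 0, nCG / expected, 0)
  pass <- nN == 0 & gc >= min_gc & obs_exp >= min_obs_exp
  if (!any(pass)) return(empty)
  starts <- which(pass)
  wins <- IRanges::IRanges(start = starts, width = window)
  merged <- IRanges::reduce(wins)
  keep <- IRanges::width(merged) >= min_length
  merged <- merged[keep]
  if (length(merged) == 0) return(empty)
  ov <- IRanges::findOverlaps(wins, merged, type = "within")
  grp <- factor(S4Vectors::subjectHits(ov), levels = seq_along(merged))
  avg <- function(x) tapply(x[S4Vectors::queryHits(ov)], grp, mean)
  data.frame(chrom = chrom,
             start = IRanges::start(merged),
             end = IRanges::end(merged),
             length = IRanges::width(merged),
             gc = as.numeric(avg(gc[starts])),
             obs_exp = as.numeric(avg(obs_exp[starts])),
             row.names = NULL)
}

#' Classify sites by CpG-island context
#'
#' Distance is the bp gap from the site to the nearest island on the same
#' chromosome (0 inside an island). Labels: island (distance 0), shore
#' (distance in (0, 2000]), shelf ((2000, 4000]), open_sea (> 4000, or no
#' island on the chromosome).
#'
#' @param sites data.frame chrom, pos (1-based).
#' @param islands data.frame chrom, start, end (1-based inclusive), e.g.
#'   from [detect_cgi()].
#' @return character vector of labels, one per site.
#' @export
assign_cgi_context <- function(sites, islands) {
  out <- rep("open_sea", nrow(sites))
  for (ch in unique(sites$chrom)) {
    si <- which(sites$chrom == ch)
    isl <- islands[islands$chrom == ch, , drop = FALSE]
    if (nrow(isl) == 0) next
    d <- vapply(sites$pos[si], function(p) {
      gaps <- pmax(isl$start - p, p - isl$end, 0)
      min(gaps)
    }, numeric(1))
    out[si][d == 0] <- "island"
    out[si][d > 0 & d <= 2000] <- "shore"
    out[si][d > 2000 & d <= 4000] <- "shelf"
  }
  out
}

genes_to_granges <- function(genes) {
  span <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start, genes$end))
  exon_list <- lapply(seq_len(nrow(genes)), function(i) {
    st <- as.integer(strsplit(genes$exon_starts[i], ",")[[1]])
    sz <- as.integer(strsplit(genes$exon_sizes[i], ",")[[1]])
    if (any(st < genes$start[i] | st + sz - 1 > genes$end[i]))
      stop2("malformed gene model: exon outside gene span (",
            genes$name[i], ")")
    GenomicRanges::GRanges(genes$chrom[i], IRanges::IRanges(st, width = sz))
  })
  exons <- do.call(c, exon_list)
  list(span = span, exons = exons)
}

#' Classify sites by genic context
#'
#' Exon if the site lies inside any exon block; otherwise intron if inside
#' a gene span; otherwise intergenic. Exon takes precedence over intron for
#' overlapping gene models.
#'
#' @param sites data.frame chrom, pos.
#' @param genes gene models: data.frame with chrom, start, end, name and
#'   comma-separated `exon_starts` / `exon_sizes` (1-based inclusive), as
#'   produced by [simulate_genome()] or read from BED12.
#' @return character vector "exon"/"intron"/"intergenic" per site.
#' @export
assign_genic_context <- function(sites, genes) {
  gr <- genes_to_granges(genes)
  pts <- GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(sites$pos, width = 1))
  in_exon <- IRanges::overlapsAny(pts, gr$exons)
  in_gene <- IRanges::overlapsAny(pts, gr$span)
  ifelse(in_exon, "exon", ifelse(in_gene, "intron", "intergenic"))
}

#' Binomial enrichment of a focal site set against background
#'
#' For each category, tests the focal hit count against the background
#' proportion with a two-sided exact binomial test (minimum-likelihood
#' two-sidedness, as implemented by [stats::binom.test]).
#'
#' @param focal_labels category label per focal site.
#' @param background_labels category label per background site.
#' @param categories categories to test (default: those present in the
#'   background).
#' @return data.frame category, focal_hits, focal_n, background_hits,
#'   background_n, p0, p, direction ("enriched"/"depleted").
#' @export
enrichment_test <- function(focal_labels, background_labels,
                            categories = NULL) {
  if (length(background_labels) == 0) stop2("empty background")
  if (length(focal_labels) == 0) stop2("empty focal set")
  if (is.null(categories))
    categories <- sort(unique(as.character(background_labels)))
  focal_n <- length(focal_labels)
  background_n <- length(background_labels)
  rows <- lapply(categories, function(cat) {
    fh <- sum(focal_labels == cat)
    bh <- sum(background_labels == cat)
    p0 <- bh / background_n
    p <- if (p0 <= 0 || p0 >= 1) {
      if (fh == round(focal_n * p0)) 1 else 0
    } else binom.test(fh, focal_n, p0)$p.value
    data.frame(category = cat, focal_hits = fh, focal_n = focal_n,
               background_hits = bh, background_n = background_n,
               p0 = p0, p = p,
               direction = ifelse(fh / focal_n >= p0, "enriched", "depleted"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
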