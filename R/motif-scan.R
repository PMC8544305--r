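MOTIF_BASES <- c("A", "C", "G", "T")

#' Read a JASPAR-style position frequency matrix
#'
#' Accepts the bracketed JASPAR text layout, e.g.
#' `>MA0000.1 NAME` followed by `A [ 1 2 3 ]` lines, or four bare
#' whitespace-separated count rows in A/C/G/T order.
#'
#' @param path PFM text file.
#' @return named list of 4-by-L count matrices (rows A, C, G, T).
#' @export
read_jaspar_pfm <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  out <- list()
  cur_name <- NULL; cur_rows <- list()
  flush <- function() {
    if (length(cur_rows) == 0) return()
    m <- do.call(rbind, cur_rows)
    rownames(m) <- MOTIF_BASES
    out[[cur_name %||% paste0("motif", length(out) + 1)]] <<- m
    cur_rows <<- list()
  }
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      flush()
      cur_name <- sub("^>\\s*", "", ln)
      cur_name <- strsplit(cur_name, "\\s+")[[1]][1]
    } else {
      nums <- gsub("^[ACGTacgt]\\s*\\[|\\]$", "", ln)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(nums), "\\s+")[[1]]))
      if (any(is.na(vals))) stop2("unparseable PFM row: ", ln)
      cur_rows[[length(cur_rows) + 1]] <- vals
    }
  }
  flush()
  out
}

#' Convert a position frequency matrix to a log-odds score matrix
#'
#' Each column of counts is normalised to probabilities (PPM); zero entries
#' are floored at `epsilon` before taking logs; the score matrix (PSSM) is
#' log2(PPM / 0.25), i.e. log-odds in bits against a uniform background.
#'
#' @param counts 4-by-L nonnegative matrix (rows A, C, G, T).
#' @param epsilon floor for zero probabilities (default 1e-6).
#' @param name optional motif name.
#' @return list of class `motif_matrix` with `counts`, `probs`, `scores`.
#' @export
pfm_to_pssm <- function(counts, epsilon = 1e-6, name = "motif") {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 4, all(counts >= 0))
  totals <- colSums(counts)
  if (any(totals == 0)) stop2("all-zero PFM column")
  probs <- sweep(counts, 2, totals, "/")
  scores <- log2(pmax(probs, epsilon) / 0.25)
  rownames(probs) <- rownames(scores) <- MOTIF_BASES
  structure(list(name = name, counts = counts, probs = probs,
                 scores = scores), class = "motif_matrix")
}

#' Exact distribution of the motif score under a uniform background
#'
#' Positionwise convolution of the per-column score distributions of an
#' i.i.d. uniform-base sequence, on a discretised score grid (bin width
#' `binwidth` bits). Returns the support, probabilities, and a survival
#' function P(score >= s) queryable at arbitrary s.
#'
#' @param pssm a `motif_matrix` (or bare 4-by-L score matrix).
#' @param binwidth discretisation in bits (default 1e-3).
#' @return list with `scores`, `probs`, `sf(s)` and
#'   `threshold(p)` (smallest score with survival < p).
#' @export
score_distribution <- function(pssm, binwidth = 1e-3) {
  S <- if (is(pssm, "motif_matrix")) pssm$scores else as.matrix(pssm)
  L <- ncol(S)
  K <- round(S / binwidth)
  offset_min <- sum(apply(K, 2, min))
  width <- sum(apply(K, 2, max)) - offset_min + 1
  probs <- rep(0, width)
  probs[1] <- 1
  cur_min <- 0
  for (j in seq_len(L)) {
    newp <- rep(0, width)
    for (b in 1:4) {
      k <- K[b, j] - min(K[, j])
      idx <- seq_len(width - k)
      newp[idx + k] <- newp[idx + k] + 0.25 * probs[idx]
    }
    probs <- newp
  }
  support <- (offset_min + seq_len(width) - 1) * binwidth
  keep <- probs > 0
  support <- support[keep]; probs <- probs[keep]
  surv <- rev(cumsum(rev(probs)))
  sf <- function(s) {
    i <- findInterval(s - binwidth / 2, support) + 1
    ifelse(i > length(support), 0, surv[pmax(i, 1)])
  }
  threshold <- function(p) {
    ok <- which(surv < p)
    if (length(ok) == 0) Inf else support[min(ok)]
  }
  list(scores = support, probs = probs, sf = sf, threshold = threshold)
}

revcomp_chars <- function(chars) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rev(unname(comp[chars]))
}

scan_one_strand <- function(base_idx, S, L) {
  n <- length(base_idx)
  nw <- n - L + 1
  if (nw < 1) return(numeric(0))
  sc <- rep(0, nw)
  valid <- rep(TRUE, nw)
  for (j in seq_len(L)) {
    b <- base_idx[j:(j + nw - 1)]
    ok <- !is.na(b)
    valid <- valid & ok
    sc[ok] <- sc[ok] + S[cbind(b[ok], j)]
  }
  sc[!valid] <- -Inf
  sc
}

#' Scan a sequence for motif hits with exact p-values
#'
#' Scores every length-L window on both strands against the PSSM and
#' reports windows whose uniform-background p-value (from
#' [score_distribution()]) is below `p_threshold`. Windows containing N
#' are skipped. Coordinates are 1-based inclusive on the forward strand.
#'
#' @param sequence character or [Biostrings::DNAString].
#' @param pssm a `motif_matrix`.
#' @param p_threshold significance threshold (default 1e-4, strict).
#' @param chrom chromosome name for the output (default "chr1").
#' @param both_strands scan the reverse complement too (default TRUE).
#' @return data.frame chrom, start, end, strand, score (bits), p.
#' @export
scan_sequence <- function(sequence, pssm, p_threshold = 1e-4,
                          chrom = "chr1", both_strands = TRUE) {
  S <- pssm$scores
  L <- ncol(S)
  dist <- score_distribution(pssm)
  smin <- dist$threshold(p_threshold)
  chars <- strsplit(toupper(as.character(sequence)), "")[[1]]
  idx_fwd <- match(chars, MOTIF_BASES)
  hits <- list()
  collect <- function(scores, strand) {
    hit <- which(scores >= smin & is.finite(scores))
    if (length(hit) == 0) return(NULL)
    if (strand == "+") {
      start <- hit
    } else {
      n <- length(chars)
      start <- n - (hit + L - 1) + 1
    }
    data.frame(chrom = chrom, start = start, end = start + L - 1,
               strand = strand, score = scores[hit], p = dist$sf(scores[hit]),
               stringsAsFactors = FALSE)
  }
  hits[["+"]] <- collect(scan_one_strand(idx_fwd, S, L), "+")
  if (both_strands) {
    idx_rev <- match(revcomp_chars(chars), MOTIF_BASES)
    hits[["-"]] <- collect(scan_one_strand(idx_rev, S, L), "-")
  }
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      score = numeric(), p = numeric())
  out <- out[order(out$start, out$strand), ]
  rownames(out) <- NULL
  out
}

#' Enrichment of motif hits near focal sites
#'
#' A site overlaps a motif when the 2 kb window centred on it (1 kb
#' upstream, 1 kb downstream) intersects any hit interval. Overlap
#' fractions of the focal set are tested against the background with the
#' same two-sided exact binomial machinery as genomic-context enrichment.
#'
#' @param focal_sites,background_sites data.frames chrom, pos.
#' @param hits motif hits from [scan_sequence()].
#' @param window full window width in bp (default 2000).
#' @return one-row data.frame in the [enrichment_test()] layout for the
#'   "overlapping" category, plus the focal/background overlap fractions.
#' @export
hre_overlap_enrichment <- function(focal_sites, background_sites, hits,
                                   window = 2000) {
  half <- window / 2
  overlaps <- function(sites) {
    if (nrow(hits) == 0) return(rep(FALSE, nrow(sites)))
    out <- rep(FALSE, nrow(sites))
    for (ch in unique(sites$chrom)) {
      si <- which(sites$chrom == ch)
      h <- hits[hits$chrom == ch, , drop = FALSE]
      if (nrow(h) == 0) next
      win <- IRanges::IRanges(sites$pos[si] - half, sites$pos[si] + half)
      hr <- IRanges::IRanges(h$start, h$end)
      out[si] <- IRanges::overlapsAny(win, hr)
    }
    out
  }
  fo <- overlaps(focal_sites)
  bo <- overlaps(background_sites)
  if (nrow(hits) == 0 || sum(bo) == 0) {
    return(data.frame(category = "overlapping",
                      focal_hits = sum(fo), focal_n = length(fo),
                      background_hits = sum(bo), background_n = length(bo),
                      p0 = 0, p = 1, direction = "enriched",
                      stringsAsFactors = FALSE))
  }
  enrichment_test(ifelse(fo, "overlapping", "non_overlapping"),
                  ifelse(bo, "overlapping", "non_overlapping"),
                  categories = "overlapping")
}
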