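#' Simulation configuration for a synthetic RRBS aging study
#'
#' Defaults emulate the structure of the study the package targets: seven
#' all-male age groups between 2 and 14 months (47 fish total, ages in days
#' derived as round(months * 365.25 / 12)), two library batches, 5-100x
#' coverage, a small minority of cytosines genuinely tracking age with
#' faster early-life change, and a four-arm chronic ionizing-radiation
#' cohort (0/5/50/500 mGy/day, six fish per arm) sampled at a single age.
#'
#' @param seed master integer seed; all stage substreams derive from it.
#' @param n_sites number of simulated cytosines.
#' @param age_groups data.frame with columns `age_days`, `n`; default the
#'   seven-group design above.
#' @param frac_age_sites fraction of sites with a true age trend.
#' @param frac_hyper fraction of true age sites gaining methylation.
#' @param effect_scale maximum percent-methylation change across the
#'   lifespan at a true age site.
#' @param early_late_rate_ratio ratio of early to late per-day rate of
#'   change (piecewise-linear latent trajectory, breakpoint at
#'   `maturity_age_days`).
#' @param maturity_age_days trajectory breakpoint (default 183 d, 6 months).
#' @param baseline_beta_params shape parameters (a, b) of the Beta baseline
#'   methylation fraction at null sites.
#' @param coverage_mean,coverage_dispersion negative-binomial coverage model
#'   (mean and size), independent of methylation.
#' @param n_batches,batch_sd library batches and the SD (percent units) of
#'   the per-site-by-batch shift.
#' @param noise_sd SD of the logit-scale site-by-sample jitter applied
#'   before binomial sampling (0 disables noise).
#' @param missing_rate fraction of site-by-sample cells masked as
#'   unobserved (on top of coverage-driven missingness).
#' @param ir_doses exposure arms in mGy/day (first entry is the control).
#' @param ir_n_per_arm fish per exposure arm.
#' @param ir_age_days age of the exposure cohort at sampling (default 232 d:
#'   6 months plus a 7-week exposure).
#' @param ir_effect_size planted percent-methylation shift at IR-affected
#'   sites (applied at every nonzero dose).
#' @param ir_frac_affected fraction of candidate sites that receive an IR
#'   effect; when bins are targeted the planted sites are allocated across
#'   the target bins proportionally to the square root of bin occupancy
#'   (capped by occupancy), so each targeted bin is overrepresented.
#' @param ir_target_bins correlation-bin labels preferentially hit by IR
#'   (see [classify_and_bin()] for labels); `NULL` targets all sites.
#' @param ir_relation direction of the IR shift relative to the site's age
#'   direction: "opposite", "same" or "random".
#' @param pdr_intercept,pdr_slope per-sample expected percent of discordant
#'   reads: intercept + slope * ln(age_days).
#' @param pdr_batch_sd SD (percent units) of the per-batch PDR shift.
#' @param pdr_reads_per_sample reads simulated per sample.
#' @param pdr_cpg_lambda Poisson rate of CpGs per read (truncated at >= 1).
#' @param genome_length,genome_gc simulated chromosome length and background
#'   GC fraction.
#' @param cpg_depletion fraction of background CpG dinucleotides mutated
#'   away (emulates genome-wide CpG depletion outside islands).
#' @param n_cgi,cgi_length planted CpG-island count and length (bp).
#' @param n_genes,exons_per_gene gene models planted on the genome.
#' @param n_motif_instances exact motif instances planted per motif.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(seed = 1L,
                       n_sites = 20000L,
                       age_groups = data.frame(
                         age_days = c(61L, 122L, 152L, 183L, 274L, 365L, 426L),
                         n = c(7L, 6L, 6L, 8L, 6L, 8L, 6L)),
                       frac_age_sites = 0.005,
                       frac_hyper = 0.8,
                       effect_scale = 40,
                       early_late_rate_ratio = 2.27,
                       maturity_age_days = 183,
                       baseline_beta_params = c(0.4, 0.4),
                       coverage_mean = 30,
                       coverage_dispersion = 3,
                       n_batches = 2L,
                       batch_sd = 2,
                       noise_sd = 0.4,
                       missing_rate = 0.03,
                       ir_doses = c(0, 5, 50, 500),
                       ir_n_per_arm = 6L,
                       ir_age_days = 232,
                       ir_effect_size = 30,
                       ir_frac_affected = 0.25,
                       ir_target_bins = c("0.25 to 0.5", "-0.5 to -0.25"),
                       ir_relation = c("opposite", "same", "random"),
                       pdr_intercept = 5,
                       pdr_slope = 3.01,
                       pdr_batch_sd = 1,
                       pdr_reads_per_sample = 2000L,
                       pdr_cpg_lambda = 4,
                       genome_length = 200000L,
                       genome_gc = 0.40,
                       cpg_depletion = 0.75,
                       n_cgi = 20L,
                       cgi_length = 400L,
                       n_genes = 20L,
                       exons_per_gene = 4L,
                       n_motif_instances = 30L) {
  cfg <- as.list(environment())
  cfg$ir_relation <- match.arg(ir_relation)
  with(cfg, {
    stopifnot(frac_age_sites >= 0, frac_age_sites <= 1,
              frac_hyper >= 0, frac_hyper <= 1,
              missing_rate >= 0, missing_rate <= 1,
              effect_scale >= 0, effect_scale <= 100,
              early_late_rate_ratio > 0,
              all(age_groups$n >= 1), n_sites >= 1)
  })
  if (any(cfg$age_groups$n < 1)) stop2("zero samples in a declared age group")
  structure(cfg, class = "sim_config")
}

age_group_label <- function(age_days) paste0("age_", age_days, "d")

sim_sample_sheet <- function(config) {
  ag <- config$age_groups
  age <- rep(ag$age_days, ag$n)
  grp <- age_group_label(age)
  # two library batches split by age group, alternating as in an RRBS study
  # where groups are libraried in two preparation rounds
  batch_of_group <- rep(paste0("batch", seq_len(config$n_batches)),
                        length.out = nrow(ag))
  batch <- rep(batch_of_group, ag$n)
  data.frame(
    sample_id = paste0("s", seq_along(age), "_", age, "d"),
    age_days = age, batch = batch, dose_mGy_day = NA_real_, group = grp,
    stringsAsFactors = FALSE)
}

# Piecewise-linear latent trajectory shared by the aging and IR simulators.
# Slopes (fraction/day) are set so the total change across [a_min, a_max]
# equals effect_scale and early:late per-day rates have the configured ratio.
latent_slopes <- function(config) {
  a_min <- min(config$age_groups$age_days)
  a_max <- max(config$age_groups$age_days)
  brk <- clamp(config$maturity_age_days, a_min, a_max)
  r <- config$early_late_rate_ratio
  s_late <- (config$effect_scale / 100) / (r * (brk - a_min) + (a_max - brk))
  list(a_min = a_min, a_max = a_max, brk = brk,
       s_early = r * s_late, s_late = s_late)
}

latent_at_age <- function(baseline, direction, slopes, age) {
  d_early <- pmin(age, slopes$brk) - slopes$a_min
  d_late <- pmax(age - slopes$brk, 0)
  clamp(baseline + direction * (slopes$s_early * d_early +
                                slopes$s_late * d_late), 0, 1)
}

sim_sites <- function(config) {
  pos <- sort(sample.int(config$n_sites * 50L, config$n_sites))
  data.frame(chrom = "chr1", pos = pos,
             strand = sample(c("+", "-"), config$n_sites, replace = TRUE,
                             prob = c(0.7, 0.3)),
             stringsAsFactors = FALSE)
}

#' Simulate the aging cohort
#'
#' Draws per-site latent methylation trajectories (null sites constant at a
#' Beta baseline; age sites follow a piecewise-linear-in-age trajectory
#' whose early per-day change exceeds the late one by the configured
#' ratio), adds a per-site-by-batch shift and logit-normal site-by-sample
#' jitter, then samples negative-binomial coverage and binomial methylated
#' counts. A fraction of cells is masked as missing. The latent percent
#' matrix is stashed in `metadata(ds)$latent_percent` for validation.
#'
#' @param config a [sim_config()].
#' @return list with `dataset` (methylation dataset) and `truth`
#'   (per-site data.frame: direction in \{-1, 0, +1\}, baseline percent and
#'   true early/late per-day slopes in percent/day).
#' @export
simulate_aging_cohort <- function(config) {
  set.seed(substream_seed(config$seed, "aging"))
  samples <- sim_sample_sheet(config)
  sites <- sim_sites(config)
  n <- config$n_sites
  ns <- nrow(samples)

  n_age <- round(config$frac_age_sites * n)
  is_age <- rep(FALSE, n)
  if (n_age > 0) is_age[sample.int(n, n_age)] <- TRUE
  direction <- integer(n)
  direction[is_age] <- ifelse(runif(n_age) < config$frac_hyper, 1L, -1L)

  a <- config$baseline_beta_params[1]; b <- config$baseline_beta_params[2]
  baseline <- rbeta(n, a, b)
  eff <- config$effect_scale / 100
  # leave room for the planted trajectory so clamping does not erase it
  idx_hyper <- which(direction == 1L)
  idx_hypo <- which(direction == -1L)
  baseline[idx_hyper] <- runif(length(idx_hyper), 0.02, max(0.98 - eff, 0.02))
  baseline[idx_hypo] <- runif(length(idx_hypo), min(0.02 + eff, 0.98), 0.98)

  slopes <- latent_slopes(config)
  ages <- samples$age_days
  latent <- matrix(baseline, n, ns)
  if (any(is_age)) {
    for (j in seq_len(ns))
      latent[is_age, j] <- latent_at_age(baseline[is_age], direction[is_age],
                                         slopes, ages[j])
  }

  batches <- unique(samples$batch)
  batch_shift <- matrix(rnorm(n * length(batches), 0, config$batch_sd / 100),
                        n, length(batches))
  shift <- batch_shift[, match(samples$batch, batches), drop = FALSE]
  p <- clamp(latent + shift, 0, 1)
  if (config$noise_sd > 0) {
    eps <- 1e-4
    p <- plogis(qlogis(clamp(p, eps, 1 - eps)) +
                matrix(rnorm(n * ns, 0, config$noise_sd), n, ns))
  }

  cov <- matrix(rnbinom(n * ns, size = config$coverage_dispersion,
                        mu = config$coverage_mean), n, ns)
  meth <- matrix(rbinom(n * ns, as.vector(cov), as.vector(p)), n, ns)
  unmeth <- cov - meth
  miss <- matrix(runif(n * ns) < config$missing_rate, n, ns) | cov == 0
  meth[miss] <- NA_integer_; unmeth[miss] <- NA_integer_

  ds <- methylation_dataset(meth, unmeth, sites, samples)
  S4Vectors::metadata(ds)$latent_percent <-
    100 * latent[match(site_keys(ds),
                       paste(sites$chrom, sites$pos, sites$strand, sep = ":")), ]
  key <- paste(sites$chrom, sites$pos, sites$strand, sep = ":")
  truth <- data.frame(
    site = key,
    chrom = sites$chrom, pos = sites$pos, strand = sites$strand,
    direction = direction,
    baseline_pct = 100 * baseline,
    slope_early_pct_day = 100 * direction * slopes$s_early,
    slope_late_pct_day = 100 * direction * slopes$s_late,
    stringsAsFactors = FALSE)
  truth <- truth[match(site_keys(ds), truth$site), ]
  rownames(truth) <- NULL
  list(dataset = ds, truth = truth)
}

#' Simulate the ionizing-radiation exposure cohort
#'
#' Reuses the aging truth table so exposure effects can be planted at sites
#' in configured age-correlation bins: all arms share the latent methylation
#' of the aging trajectory evaluated at `ir_age_days`; IR-affected sites are
#' shifted by `ir_effect_size` percent in every nonzero-dose arm, in a
#' direction set by `ir_relation` relative to the site's age direction
#' (observed bin sign when `site_bins` is supplied, true direction
#' otherwise). With `ir_effect_size = 0` all arms are identically
#' distributed.
#'
#' @param config a [sim_config()].
#' @param truth aging truth table from [simulate_aging_cohort()].
#' @param site_bins optional named character vector of correlation-bin
#'   labels (names = site keys), typically from [classify_and_bin()] on the
#'   aging analysis; used to select target sites.
#' @return list with `dataset` and `ir_truth` (per-site affected flag and
#'   planted per-dose direction).
#' @export
simulate_ir_cohort <- function(config, truth, site_bins = NULL) {
  set.seed(substream_seed(config$seed, "ir"))
  if (config$ir_effect_size > 0 && length(config$ir_target_bins) == 0)
    stop2("ir_target_bins empty while ir_effect_size > 0")
  doses <- config$ir_doses
  nper <- config$ir_n_per_arm
  samples <- data.frame(
    sample_id = paste0("ir", seq_len(length(doses) * nper), "_",
                       rep(doses, each = nper), "mGy"),
    age_days = config$ir_age_days,
    batch = "ir_batch1",
    dose_mGy_day = rep(doses, each = nper),
    group = paste0("dose_", rep(doses, each = nper)),
    stringsAsFactors = FALSE)
  n <- nrow(truth); ns <- nrow(samples)
  slopes <- latent_slopes(config)
  base <- latent_at_age(truth$baseline_pct / 100,
                        truth$direction, slopes, config$ir_age_days)

  affected <- rep(FALSE, n)
  ir_dir <- integer(n)
  if (config$ir_effect_size > 0) {
    if (!is.null(site_bins)) {
      bins <- site_bins[truth$site]
      candidates <- which(bins %in% config$ir_target_bins)
      bin_sign <- sign(bin_midpoint(bins))
      # allocate planted effects across the targeted bins proportionally to
      # the square root of bin occupancy: every targeted bin ends up
      # overrepresented relative to background, whether dense or sparse
      k <- round(config$ir_frac_affected * length(candidates))
      occ <- vapply(config$ir_target_bins, function(b) sum(bins == b,
                                                           na.rm = TRUE), 1)
      w <- sqrt(occ) / sum(sqrt(occ))
      hit <- unlist(lapply(seq_along(config$ir_target_bins), function(i) {
        cand_b <- which(bins == config$ir_target_bins[i])
        sample(cand_b, min(ceiling(k * w[i]), length(cand_b)))
      }))
    } else {
      candidates <- seq_len(n)
      bin_sign <- truth$direction
      k <- round(config$ir_frac_affected * length(candidates))
      hit <- sample(candidates, min(k, length(candidates)))
    }
    affected[hit] <- TRUE
    rel <- config$ir_relation
    s <- bin_sign[hit]
    s[s == 0] <- sample(c(-1L, 1L), sum(s == 0), replace = TRUE)
    ir_dir[hit] <- switch(rel,
      opposite = -s,
      same = s,
      random = sample(c(-1L, 1L), length(hit), replace = TRUE))
  }

  eff <- config$ir_effect_size / 100
  p <- matrix(base, n, ns)
  exposed <- samples$dose_mGy_day > 0
  p[affected, exposed] <- clamp(p[affected, exposed] +
                                ir_dir[affected] * eff, 0, 1)
  if (config$noise_sd > 0) {
    eps <- 1e-4
    p <- plogis(qlogis(clamp(p, eps, 1 - eps)) +
                matrix(rnorm(n * ns, 0, config$noise_sd), n, ns))
  }
  cov <- matrix(rnbinom(n * ns, size = config$coverage_dispersion,
                        mu = config$coverage_mean), n, ns)
  meth <- matrix(rbinom(n * ns, as.vector(cov), as.vector(p)), n, ns)
  unmeth <- cov - meth
  miss <- matrix(runif(n * ns) < config$missing_rate, n, ns) | cov == 0
  meth[miss] <- NA_integer_; unmeth[miss] <- NA_integer_

  sites <- truth[, c("chrom", "pos", "strand")]
  ds <- methylation_dataset(meth, unmeth, sites, samples)
  ir_truth <- data.frame(site = truth$site, affected = affected,
                         stringsAsFactors = FALSE)
  for (d in doses[doses > 0])
    ir_truth[[paste0("dir_dose_", d)]] <- ifelse(affected, ir_dir, 0L)
  ir_truth <- ir_truth[match(site_keys(ds), ir_truth$site), ]
  rownames(ir_truth) <- NULL
  list(dataset = ds, ir_truth = ir_truth)
}

#' Simulate per-read CpG methylation patterns
#'
#' Generates reads for every sample of the aging design. CpG counts per
#' read are truncated-Poisson (>= 1). Reads with >= 2 CpGs are made
#' discordant (within-read methylation strictly between 10 and 90 percent)
#' with per-sample probability `pdr_intercept + pdr_slope * ln(age_days)`
#' (percent, plus a per-batch shift, clamped to [0, 100]); otherwise they
#' are fully methylated or fully unmethylated.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns sample_id, chrom, start, calls (binary
#'   string, e.g. "1101"); class `read_pattern_set`.
#' @export
simulate_read_patterns <- function(config) {
  set.seed(substream_seed(config$seed, "pdr"))
  samples <- sim_sample_sheet(config)
  expected <- config$pdr_intercept + config$pdr_slope * log(samples$age_days)
  if (any(expected < 0 | expected > 100))
    stop2("expected PDR outside [0, 100] for a configured age")
  batches <- unique(samples$batch)
  bshift <- setNames(rnorm(length(batches), 0, config$pdr_batch_sd), batches)
  expected <- clamp(expected + bshift[samples$batch], 0, 100)

  out <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    nr <- config$pdr_reads_per_sample
    k <- rpois(nr, config$pdr_cpg_lambda)
    k[k < 1] <- 1L
    p_disc <- expected[i] / 100
    calls <- character(nr)
    for (j in seq_len(nr)) {
      kj <- k[j]
      if (kj == 1L) {
        calls[j] <- as.character(rbinom(1, 1, 0.5))
      } else if (runif(1) < p_disc) {
        ok <- which(100 * seq_len(kj - 1) / kj >= 10 &
                    100 * seq_len(kj - 1) / kj <= 90)
        if (length(ok) == 0) ok <- floor(kj / 2)
        nm <- if (length(ok) == 1) ok else sample(ok, 1)
        calls[j] <- paste(sample(c(rep(1L, nm), rep(0L, kj - nm))),
                          collapse = "")
      } else {
        calls[j] <- paste(rep(rbinom(1, 1, 0.5), kj), collapse = "")
      }
    }
    out[[i]] <- data.frame(sample_id = samples$sample_id[i],
                           chrom = "chr1",
                           start = sample.int(1e6, nr),
                           calls = calls, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  class(res) <- c("read_pattern_set", class(res))
  res
}

#' Simulate a genome with planted CpG islands, genes and motif instances
#'
#' The background is i.i.d. at the configured GC with most CpG dinucleotides
#' mutated away (CpG depletion, so observed/expected CpG is low outside
#' islands). Planted islands are GC-rich (70 percent) segments with no
#' depletion. Gene models receive evenly spaced exon blocks. Exact motif
#' consensus instances are written at recorded positions.
#'
#' @param config a [sim_config()].
#' @param motifs optional named character vector of motif consensus
#'   sequences to plant.
#' @return list with `genome` (named [Biostrings::DNAStringSet]),
#'   `cgi_truth` (data.frame of planted island intervals, 1-based
#'   inclusive), `genes` (gene models: data.frame with chrom, start, end,
#'   name, strand and comma-separated exon block starts/sizes), and
#'   `motif_truth` (planted motif positions).
#' @export
simulate_genome <- function(config, motifs = NULL) {
  set.seed(substream_seed(config$seed, "genome"))
  len <- config$genome_length
  gc <- config$genome_gc
  base_probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seq_chars <- sample(names(base_probs), len, replace = TRUE, prob = base_probs)
  # CpG depletion: mutate the G of most CG dinucleotides to A
  cg <- which(seq_chars[-len] == "C" & seq_chars[-1] == "G")
  kill <- cg[runif(length(cg)) < config$cpg_depletion]
  seq_chars[kill + 1L] <- "A"

  # plant islands on an even grid, keeping them apart by > 8 kb so shore /
  # shelf / open-sea annotation has unambiguous truth
  n_cgi <- config$n_cgi
  island_len <- config$cgi_length
  gap <- floor(len / (n_cgi + 1))
  if (gap <= island_len + 100) stop2("requested features overlap beyond chromosome length")
  starts <- gap * seq_len(n_cgi) - floor(island_len / 2)
  for (s in starts) {
    isl <- sample(c("A", "C", "G", "T"), island_len, replace = TRUE,
                  prob = c(0.15, 0.35, 0.35, 0.15))
    seq_chars[s:(s + island_len - 1)] <- isl
  }
  cgi_truth <- data.frame(chrom = "chr1", start = starts,
                          end = starts + island_len - 1L)

  motif_truth <- NULL
  if (!is.null(motifs)) {
    used <- IRanges::IRanges()
    rows <- list()
    for (m in names(motifs)) {
      cons <- strsplit(motifs[[m]], "")[[1]]
      L <- length(cons)
      placed <- 0L
      while (placed < config$n_motif_instances) {
        p <- sample.int(len - L, 1)
        cand <- IRanges::IRanges(p, p + L - 1L)
        if (length(IRanges::findOverlaps(cand, used)) == 0) {
          seq_chars[p:(p + L - 1)] <- cons
          used <- c(used, cand)
          rows[[length(rows) + 1L]] <-
            data.frame(motif = m, chrom = "chr1", start = p,
                       end = p + L - 1L, strand = "+")
          placed <- placed + 1L
        }
      }
    }
    motif_truth <- do.call(rbind, rows)
  }

  genome <- Biostrings::DNAStringSet(paste(seq_chars, collapse = ""))
  names(genome) <- "chr1"

  # gene models between islands: span with evenly spaced exon blocks
  genes <- list()
  for (g in seq_len(config$n_genes)) {
    gstart <- sample.int(len - 6000L, 1)
    gend <- gstart + sample(2000:5000, 1)
    gend <- min(gend, len)
    ne <- config$exons_per_gene
    span <- gend - gstart + 1L
    esize <- max(50L, floor(span / (2 * ne)))
    estarts <- gstart + floor((span - esize) * (seq_len(ne) - 1) / max(ne - 1, 1))
    genes[[g]] <- data.frame(
      chrom = "chr1", start = gstart, end = gend,
      name = sprintf("gene%02d", g), strand = "+",
      exon_starts = paste(estarts, collapse = ","),
      exon_sizes = paste(rep(esize, ne), collapse = ","),
      stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, genes)
  list(genome = genome, cgi_truth = cgi_truth, genes = genes,
       motif_truth = motif_truth)
}

#' Sample cytosine coordinates from the CG dinucleotides of a genome
#'
#' Used by the pipeline to place methylation sites on the simulated genome
#' so genomic-context labels are real rather than synthetic.
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @param n number of sites to draw.
#' @param seed integer seed.
#' @return data.frame chrom, pos, strand.
#' @export
sample_cpg_sites <- function(genome, n, seed = 1L) {
  set.seed(substream_seed(seed, "cpg_sites"))
  hits <- lapply(seq_along(genome), function(i) {
    m <- Biostrings::matchPattern("CG", genome[[i]])
    data.frame(chrom = names(genome)[i], pos = IRanges::start(m))
  })
  all <- do.call(rbind, hits)
  if (nrow(all) < n) n <- nrow(all)
  take <- all[sort(sample.int(nrow(all), n)), ]
  take$strand <- sample(c("+", "-"), n, replace = TRUE)
  rownames(take) <- NULL
  take
}
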