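#' Re-place simulated methylation sites onto genome CpG coordinates
#'
#' Replaces the synthetic site coordinates of a simulated cohort with CpG
#' dinucleotide positions sampled from a simulated genome, so that
#' genomic-context and motif-overlap stages operate on real coordinates.
#'
#' @param sim result of [simulate_aging_cohort()].
#' @param coords data.frame chrom, pos, strand with as many rows as the
#'   dataset has sites (e.g. from [sample_cpg_sites()]).
#' @return the `sim` list with dataset and truth re-keyed.
#' @export
place_on_genome <- function(sim, coords) {
  ds <- sim$dataset
  stopifnot(nrow(coords) == nrow(ds))
  coords <- coords[order(coords$chrom, coords$pos, coords$strand), ]
  latent <- S4Vectors::metadata(ds)$latent_percent
  new_ds <- methylation_dataset(meth_counts(ds), unmeth_counts(ds),
                                coords, sample_meta(ds))
  S4Vectors::metadata(new_ds)$latent_percent <- latent
  truth <- sim$truth
  truth$chrom <- coords$chrom; truth$pos <- coords$pos
  truth$strand <- coords$strand
  truth$site <- paste(coords$chrom, coords$pos, coords$strand, sep = ":")
  list(dataset = new_ds, truth = truth)
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full synthetic-study analysis pipeline
#'
#' Orchestrates simulate, preprocess, age association, differential
#' methylation, early/late rates, the three clocks, genomic context, motif
#' overlap, PDR and the exposure-by-aging interaction from one
#' configuration, writing stage outputs and a manifest (file, md5, stage)
#' under `output_dir` and returning a report of headline numbers.
#'
#' @param config named list (or path to a YAML file) with optional blocks
#'   `simulate` (arguments to [sim_config()]) and `thresholds`
#'   (min_cov, max_cov, min_per_group, knn_k, diff_threshold, q_threshold,
#'   rho_threshold, n_test, clock_families); missing entries use the
#'   package defaults.
#' @param output_dir directory for stage outputs.
#' @param seed master seed (overrides the one in `config`).
#' @return report list (invisibly also written as report.json).
#' @export
run_pipeline <- function(config = list(), output_dir = tempfile("methylaging_"),
                         seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  sim_args <- config$simulate %||% list()
  if (!is.null(seed)) sim_args$seed <- seed
  th <- utils::modifyList(
    list(min_cov = 5, max_cov = 100, min_per_group = 5, knn_k = 4,
         diff_threshold = 25, q_threshold = 0.01, rho_threshold = 0.5,
         n_test = 10,
         clock_families = c("linear_topk", "elastic_net", "pca")),
    config$thresholds %||% list())
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  stage_log <- list()
  tick <- function(stage, files) {
    outputs <<- c(outputs, files)
    stage_log[[stage]] <<- files
  }
  sim_args$n_sites <- sim_args$n_sites %||% 4000L
  sim_args$genome_length <- sim_args$genome_length %||% 500000L
  cfg <- do.call(sim_config, sim_args)

  # --- simulate ---
  genome_sim <- simulate_genome(cfg, motifs = c(
    hre_like = "AGGTCACAGTGACCT"))
  aging <- simulate_aging_cohort(cfg)
  coords <- sample_cpg_sites(genome_sim$genome, nrow(aging$dataset),
                             seed = cfg$seed)
  if (nrow(coords) == nrow(aging$dataset))
    aging <- place_on_genome(aging, coords)
  meta_path <- write_tsv(sample_meta(aging$dataset),
                         file.path(output_dir, "sample_metadata.tsv"))
  truth_path <- file.path(output_dir, "truth_aging.json")
  jsonlite::write_json(aging$truth, truth_path, digits = I(10))
  tick("simulate", c(meta_path, truth_path))

  # --- preprocess ---
  ds <- preprocess(aging$dataset, th$min_cov, th$max_cov, th$min_per_group,
                   th$knn_k)
  tick("preprocess", character(0))

  # --- age association ---
  assoc <- site_age_correlation(ds)
  cb <- classify_and_bin(assoc)
  assoc_path <- write_tsv(assoc, file.path(output_dir, "age_association.tsv"))
  tick("age_assoc", assoc_path)
  aa_sites <- assoc$site[assoc$age_associated]
  n_hyper <- sum(assoc$age_associated & assoc$rho > 0)
  n_hypo <- sum(assoc$age_associated & assoc$rho < 0)

  # --- DMCs between age groups (2 vs 6, 9 vs 14, 2 vs 14 month analogue) ---
  groups <- unique(sample_meta(ds)$group)
  ages <- sort(unique(sample_meta(ds)$age_days))
  glab <- function(a) age_group_label(a)
  dmc_pairs <- list(c(glab(ages[1]), glab(ages[4])),
                    c(glab(ages[5]), glab(ages[length(ages)])),
                    c(glab(ages[1]), glab(ages[length(ages)])))
  dmc_files <- character(0)
  dmc_counts <- list()
  for (pr in dmc_pairs) {
    if (!all(pr %in% groups)) next
    tab <- call_dmcs(ds, pr[1], pr[2], th$diff_threshold, th$q_threshold)
    f <- write_tsv(tab, file.path(output_dir,
                                  paste0("dmc_", pr[1], "_vs_", pr[2], ".tsv")))
    dmc_files <- c(dmc_files, f)
    dmc_counts[[paste(pr, collapse = "_vs_")]] <-
      c(hyper = sum(tab$is_dmc & tab$direction == "hyper"),
        hypo = sum(tab$is_dmc & tab$direction == "hypo"))
  }
  tick("dmc", dmc_files)

  # --- early vs late rates on the age-associated set ---
  rates <- NULL
  if (length(aa_sites) >= 2 && length(ages) >= 6) {
    rates <- early_late_rates(ds, aa_sites,
                              early = c(glab(ages[1]), glab(ages[4])),
                              late = c(glab(ages[5]), glab(ages[length(ages)])))
    tick("rates", write_tsv(rates$rates, file.path(output_dir, "rates.tsv")))
  }

  # --- clocks ---
  split <- split_train_test(ds, n_test = th$n_test, seed = cfg$seed)
  train <- ds[, split$train]; test <- ds[, split$test]
  clock_metrics <- list()
  clock_files <- character(0)
  fitters <- list(linear_topk = function() fit_linear_topk(train),
                  elastic_net = function() fit_elastic_net(train),
                  pca = function() fit_pca_clock(train, th$rho_threshold))
  models <- list()
  for (fam in th$clock_families) {
    model <- fitters[[fam]]()
    models[[fam]] <- model
    f <- file.path(output_dir, paste0("clock_", fam, ".json"))
    write_clock(model, f)
    clock_files <- c(clock_files, f)
    ev_tr <- evaluate_clock(predict_age(model, train)$predicted_age_days,
                            sample_meta(train)$age_days, "train")
    ev_te <- evaluate_clock(predict_age(model, test)$predicted_age_days,
                            sample_meta(test)$age_days, "test")
    ov <- compare_overfit(ev_tr, ev_te)
    clock_metrics[[fam]] <- list(mae_train = ev_tr$mae, r2_train = ev_tr$r2,
                                 mae_test = ev_te$mae, r2_test = ev_te$r2,
                                 overfit_p = ov$p)
  }
  tick("clocks", clock_files)

  # --- genomic context + motif overlap ---
  islands <- do.call(rbind, lapply(seq_along(genome_sim$genome), function(i)
    detect_cgi(genome_sim$genome[[i]], chrom = names(genome_sim$genome)[i])))
  st <- site_table(ds)
  bg_cgi <- assign_cgi_context(st, islands)
  bg_genic <- assign_genic_context(st, genome_sim$genes)
  focal_idx <- match(aa_sites, site_keys(ds))
  ctx_files <- character(0)
  if (length(focal_idx) > 0) {
    enr_cgi <- enrichment_test(bg_cgi[focal_idx], bg_cgi)
    enr_genic <- enrichment_test(bg_genic[focal_idx], bg_genic)
    ctx_files <- c(
      write_tsv(rbind(enr_cgi, enr_genic),
                file.path(output_dir, "context_enrichment.tsv")))
  }
  pssm <- pfm_to_pssm(consensus_pfm("AGGTCACAGTGACCT", strength = 50),
                      name = "hre_like")
  hits <- do.call(rbind, lapply(seq_along(genome_sim$genome), function(i)
    scan_sequence(genome_sim$genome[[i]], pssm,
                  chrom = names(genome_sim$genome)[i])))
  hre <- if (length(focal_idx) > 0)
    hre_overlap_enrichment(st[focal_idx, ], st, hits) else NULL
  if (!is.null(hre))
    ctx_files <- c(ctx_files, write_tsv(hre, file.path(output_dir,
                                                       "hre_enrichment.tsv")))
  tick("context", ctx_files)

  # --- PDR ---
  patterns <- simulate_read_patterns(cfg)
  pdr <- compute_pdr_all(patterns)
  trend <- pdr_age_trend(pdr, sample_meta(aging$dataset))
  pdr_path <- write_tsv(pdr, file.path(output_dir, "pdr.tsv"))
  tick("pdr", pdr_path)

  # --- IR interaction ---
  bins <- setNames(as.character(assoc$bin), assoc$site)
  ir <- simulate_ir_cohort(cfg, aging$truth, site_bins = bins)
  ir_ds <- filter_by_coverage(ir$dataset, th$min_cov, th$max_cov)
  ir_dmcs <- call_ir_dmcs(ir_ds, th$diff_threshold, th$q_threshold)
  ov <- overlap_and_bin_enrichment(ir_dmcs, assoc, site_keys(ir_ds))
  ir_files <- write_tsv(ov$enrichment,
                        file.path(output_dir, "ir_bin_enrichment.tsv"))
  dirn <- if (length(ov$dmc_shared) > 0)
    classify_directionality(ir_dmcs, assoc) else NULL
  if (!is.null(dirn))
    ir_files <- c(ir_files, write_tsv(dirn$per_bin,
                                      file.path(output_dir,
                                                "ir_directionality_bins.tsv")))
  tick("ir_interaction", ir_files)

  report <- list(
    seed = cfg$seed,
    n_sites_simulated = cfg$n_sites,
    n_sites_after_preprocess = nrow(ds),
    n_age_associated = length(aa_sites),
    n_age_associated_hyper = n_hyper,
    n_age_associated_hypo = n_hypo,
    bin_occupancy = as.list(cb$occupancy),
    dmc_counts = dmc_counts,
    rates = if (!is.null(rates))
      list(mean_rate_early = rates$mean_rate_early,
           mean_rate_late = rates$mean_rate_late,
           t = rates$t, p = rates$p),
    clocks = clock_metrics,
    pdr_trend = list(beta = trend$beta, se = trend$se, p = trend$p),
    ir_summary = ov$summary,
    ir_directionality = if (!is.null(dirn)) dirn$per_bin)
  report_path <- file.path(output_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = I(10),
                       null = "null")
  outputs <- c(outputs, report_path)
  manifest <- data.frame(
    file = basename(outputs),
    md5 = unname(tools::md5sum(outputs)),
    stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(output_dir, "manifest.tsv"))
  report$manifest <- manifest
  report$output_dir <- output_dir
  report
}

#' Build a sharply peaked PFM from a consensus sequence
#'
#' Utility for tests and the pipeline: the consensus base of each column
#' receives `strength` counts and the other bases one count each.
#'
#' @param consensus character consensus (A/C/G/T).
#' @param strength consensus count per column (default 50).
#' @return 4-by-L count matrix.
#' @export
consensus_pfm <- function(consensus, strength = 50) {
  chars <- strsplit(toupper(consensus), "")[[1]]
  stopifnot(all(chars %in% MOTIF_BASES))
  m <- matrix(1, 4, length(chars), dimnames = list(MOTIF_BASES, NULL))
  for (j in seq_along(chars)) m[chars[j], j] <- strength
  m
}
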