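#' Call IR differentially methylated cytosines per dose
#'
#' Runs [call_dmcs()] for control versus each nonzero dose and unions the
#' significant sites across comparisons ("significantly affected by at
#' least one dose").
#'
#' @param ir_ds exposure-cohort dataset whose samples carry group labels
#'   `dose_<d>` and numeric `dose_mGy_day`.
#' @param diff_threshold,q_threshold DMC thresholds (defaults 25, 0.01).
#' @return list with `per_dose` (named list of DMC tables) and `union`
#'   (character site keys significant in >= 1 comparison).
#' @export
call_ir_dmcs <- function(ir_ds, diff_threshold = 25, q_threshold = 0.01) {
  meta <- sample_meta(ir_ds)
  doses <- sort(unique(meta$dose_mGy_day))
  if (!0 %in% doses) stop2("no control (dose 0) arm")
  control <- "dose_0"
  per_dose <- list()
  for (d in doses[doses > 0]) {
    tab <- call_dmcs(ir_ds, control, paste0("dose_", d),
                     diff_threshold = diff_threshold,
                     q_threshold = q_threshold)
    per_dose[[paste0("dose_", d)]] <- tab
  }
  union_sites <- unique(unlist(lapply(per_dose, function(t)
    t$site[t$is_dmc])))
  list(per_dose = per_dose, union = union_sites %||% character(0))
}

#' Overlap of IR DMCs with the aging analysis and per-bin enrichment
#'
#' The background is the set of sites shared by the aging and exposure
#' analyses, labelled by their age-correlation bin; the focal set is the
#' shared IR DMCs. Each bin is tested with the two-sided exact binomial
#' enrichment machinery. Summary percentages are reported to one decimal.
#'
#' @param ir_dmcs result of [call_ir_dmcs()].
#' @param age_table result of [site_age_correlation()].
#' @param ir_covered_sites site keys covered in the exposure dataset.
#' @param background "shared" (default: the intersection) or "aging" (the
#'   full aging analysis set).
#' @return list with `summary` (counts and one-decimal percentages) and
#'   `enrichment` (per-bin table).
#' @export
overlap_and_bin_enrichment <- function(ir_dmcs, age_table, ir_covered_sites,
                                       background = c("shared", "aging")) {
  background <- match.arg(background)
  aging_sites <- age_table$site
  shared <- intersect(aging_sites, ir_covered_sites)
  if (length(shared) == 0) stop2("no shared sites")
  dmc_union <- ir_dmcs$union
  dmc_shared <- intersect(dmc_union, shared)
  bins <- setNames(as.character(age_table$bin), age_table$site)
  bg_sites <- if (background == "shared") shared else aging_sites
  focal_labels <- bins[dmc_shared]
  bg_labels <- bins[bg_sites]
  enr <- if (length(dmc_shared) > 0) {
    enrichment_test(focal_labels, bg_labels, categories = CORR_BIN_LEVELS)
  } else NULL
  summary <- list(
    n_aging = length(aging_sites),
    n_ir_covered = length(ir_covered_sites),
    n_shared = length(shared),
    n_ir_dmc = length(dmc_union),
    n_ir_dmc_shared = length(dmc_shared),
    pct_shared_of_aging = percent_of(length(shared), length(aging_sites)),
    pct_dmc_shared_of_dmc = if (length(dmc_union) > 0)
      percent_of(length(dmc_shared), length(dmc_union)) else NA_real_)
  list(summary = summary, enrichment = enr, shared = shared,
       dmc_shared = dmc_shared)
}

#' Directionality of IR effects relative to normal aging
#'
#' For each shared IR DMC, compares the sign of its age association
#' (Spearman rho) with the signs of its significant per-dose methylation
#' differences (exposed minus control): `dose_dependent` when two or more
#' significant doses disagree in sign, else `same` when all significant
#' signs equal the age direction, else `opposite`. Sites with rho exactly
#' zero are excluded from directionality and counted separately. The
#' same/opposite split per bin is tested against 50:50 with a two-sided
#' exact binomial test.
#'
#' @param ir_dmcs result of [call_ir_dmcs()].
#' @param age_table result of [site_age_correlation()].
#' @return list with `records` (per-site relation), `per_bin` (counts,
#'   percent same/opposite and binomial p per bin), `per_dose` (percent
#'   same/opposite per dose) and `n_zero_rho`.
#' @export
classify_directionality <- function(ir_dmcs, age_table) {
  rho <- setNames(age_table$rho, age_table$site)
  bins <- setNames(as.character(age_table$bin), age_table$site)
  per_dose_tabs <- ir_dmcs$per_dose
  sites <- intersect(ir_dmcs$union, age_table$site)
  if (length(sites) == 0) stop2("no shared IR DMCs")
  age_dir <- sign(rho[sites])
  zero <- age_dir == 0
  rows <- lapply(sites[!zero], function(s) {
    sig_signs <- integer(0)
    sig_doses <- character(0)
    for (d in names(per_dose_tabs)) {
      t <- per_dose_tabs[[d]]
      i <- match(s, t$site)
      if (!is.na(i) && t$is_dmc[i]) {
        sig_signs <- c(sig_signs, sign(t$meth_diff[i]))
        sig_doses <- c(sig_doses, d)
      }
    }
    relation <- if (length(unique(sig_signs)) > 1) "dose_dependent"
    else if (all(sig_signs == sign(rho[s]))) "same"
    else "opposite"
    data.frame(site = s, age_direction = sign(rho[s]), bin = bins[s],
               n_sig_doses = length(sig_doses),
               ir_sign = if (length(unique(sig_signs)) == 1) sig_signs[1]
                         else NA_integer_,
               relation = relation, stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, rows)
  rownames(records) <- NULL

  per_bin <- do.call(rbind, lapply(CORR_BIN_LEVELS, function(b) {
    rb <- records[records$bin == b & records$relation != "dose_dependent", ]
    ns <- sum(rb$relation == "same"); no <- sum(rb$relation == "opposite")
    p <- if (ns + no > 0) binom.test(no, ns + no, 0.5)$p.value else NA_real_
    data.frame(bin = b, n = nrow(records[records$bin == b, ]),
               n_same = ns, n_opposite = no,
               pct_same = if (ns + no > 0) percent_of(ns, ns + no) else NA_real_,
               pct_opposite = if (ns + no > 0) percent_of(no, ns + no) else NA_real_,
               p_vs_5050 = p, stringsAsFactors = FALSE)
  }))

  per_dose <- do.call(rbind, lapply(names(per_dose_tabs), function(d) {
    t <- per_dose_tabs[[d]]
    sig <- t$site[t$is_dmc]
    sig <- intersect(sig, records$site)
    if (length(sig) == 0)
      return(data.frame(dose = d, n = 0L, pct_same = NA_real_,
                        pct_opposite = NA_real_))
    sg <- sign(t$meth_diff[match(sig, t$site)])
    ad <- records$age_direction[match(sig, records$site)]
    same <- sum(sg == ad); opp <- sum(sg == -ad)
    data.frame(dose = d, n = length(sig),
               pct_same = percent_of(same, same + opp),
               pct_opposite = percent_of(opp, same + opp),
               stringsAsFactors = FALSE)
  }))
  list(records = records, per_bin = per_bin, per_dose = per_dose,
       n_zero_rho = sum(zero))
}
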