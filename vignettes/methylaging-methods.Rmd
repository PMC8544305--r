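---
title: "Methods: aging-methylome analysis and epigenetic clocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aging-methylome analysis and epigenetic clocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical procedures implemented by
`methylaging`, the assumptions behind them, the defaults and why they were
chosen, and the design decisions taken where the methodology left genuine
latitude. The package targets RRBS-style per-cytosine count data from a
cross-sectional aging cohort of a short-lived fish, plus a chronic
ionizing-radiation (IR) exposure cohort, but nothing in the implementation
is species-specific.

## Data model and preprocessing

A dataset is a `RangedSummarizedExperiment` with integer assays `meth` and
`unmeth` (missing cells are `NA`), stranded single-base row ranges (sites
on opposite strands are never merged), and per-sample metadata (age in
days, library batch, dose in mGy/day, group). Coordinates are 1-based
inclusive, matching the Bismark coverage dialect; BED interchange converts
to 0-based half-open at the boundary.

The preprocessing chain is order-fixed:

1. **Coverage filter** — cells with total coverage `< 5` or `> 100` are
   masked (both retained bounds inclusive: coverage 5 and 100 survive).
   The lower bound controls sampling noise in percent methylation; the
   upper bound removes PCR-duplicated or collapsed-repeat signal.
2. **Coverage normalisation** — each sample is scaled by
   (reference median coverage / sample median coverage). The reference is
   the *median of the per-sample median coverages*; the tool family this
   mirrors offers median scaling but leaves the reference unspecified, so
   the package fixes this symmetric choice. The scaled total is rounded
   and the methylated count recomputed from the pre-rounding fraction, so
   every cell's methylation fraction is preserved within `1/(2·coverage)`.
3. **Uniting** — a site is kept when observed in at least `min_per_group`
   (default 5) samples of *every* group. With 6–8 samples per group this
   is roughly a 75% completeness requirement per group.
4. **KNN imputation** (`k = 4`) — each missing percent value is replaced
   by the mean percent of the k nearest sites at that sample. Distance is
   the root-mean-square difference of percent values over samples where
   both sites are observed (the mean, not the sum, so sites sharing more
   samples are not penalised); only sites observed at the target sample
   are candidate neighbours; ties in distance break by site order.
   Counts are not imputed — every stage downstream of imputation operates
   on the percent matrix.
5. **Near-zero-variance removal** — a site is dropped when the ratio of
   the most to the second-most frequent value exceeds 19 (strictly;
   19 = 95/5) *and* at most 10% of values are distinct. The thresholds are
   the defaults of the variance filter convention this reproduces; they
   are restated explicitly so behaviour is reproducible without that tool.

Whether normalisation should precede or follow the coverage filter is not
dictated by the data model; the package fixes filter-first, so the
normalisation medians are computed on the retained coverage window.

## Age-association screening

Spearman ρ (midranks for ties) captures monotone age trends; Pearson r is
computed alongside because the linear clock selects by r. Ages enter
untransformed (ρ is invariant to monotone transforms anyway). P-values use
the t approximation `t = ρ√((n−2)/(1−ρ²))` for n ≥ 10 and the exact
permutation null below that; q-values are Benjamini–Hochberg. BH is used
everywhere a false-discovery rate is needed — the differential-methylation
tool this follows defaults to a different FDR approximation (SLIM), and BH
is the standard, documented substitution. A site is *age-associated* when
|ρ| > 0.5 (strict). Sites with constant methylation are reported with
ρ = 0, p = 1 and a `constant` flag rather than `NA`, so downstream joins
stay total.

Correlation bins partition the continuum into seven intervals. A
coefficient of exactly 0 has its own bin; boundary values ±0.25 and ±0.5
are assigned to the bin *farther from zero* (so ρ = 0.5 sits in
"0.5 to 1"). The exactly-zero bin is a deliberate reading of the binning
scheme; with continuous data it is almost always empty.

Differential methylation pools methylated/total counts within each group
and applies the two-proportion binomial likelihood-ratio (G) test —
algebraically identical to the deviance test of a logistic regression of
methylation state on group, which is what the reference tooling fits with
no covariates — vectorised in closed form for speed and cross-checked
against `glm(..., family = binomial)` in the test suite. Fisher's exact
test is available behind a flag. A DMC requires both |Δ| ≥ 25 percentage
points and q ≤ 0.01; effect size and significance are deliberately
separate gates.

Early- versus late-life rates divide the absolute change in group-mean
percent methylation by the days elapsed *as recorded in the metadata* —
not by nominal month arithmetic, which would be internally inconsistent —
and compare per-day rates with a paired t-test. When the paired
differences are identically zero the test degenerates to t = 0, p = 1
rather than erroring.

## The three clocks

All clocks share one contract: an ordered site list, per-site weights, an
intercept, and an age transform; serialisation to JSON uses 17 significant
digits so reloaded models predict bit-identically. Sites absent from a
prediction dataset contribute a predictor value of zero — the documented
degradation path for cohorts that only partially cover the clock sites.

* **Top-k linear** (k = 10): sites ranked by |Pearson r| on training
  samples versus untransformed age; any site within 100 bp of an already
  chosen site on the same chromosome is skipped (replaced by the next
  best), preventing a locally co-methylated cluster from occupying the
  whole model; ties in |r| break by (chrom, pos). Ranking uses the
  magnitude with no direction constraint — any hyper/hypo imbalance in the
  selected sites is a property of the data, not the selector. OLS of age
  (days) on the k percent values.
* **Elastic net** (α = 0.5, gaussian, response log10(age in days)):
  λ is the grid value minimising leave-one-out CV mean squared error; the
  grid has 100 log-spaced values spanning four decades below λ_max (the
  smallest λ zeroing all coefficients), a standard construction.
  With `foldid = 1:n` the CV curve is fully deterministic. Predictions
  are back-transformed (`10^ŷ`) before any error metric.
* **PCA clock**: training-set age-associated sites (|ρ| > 0.5) are
  centred and scaled to unit variance (scaling is on by default — whether
  the convention this mirrors scaled is unstated, and unit variance stops
  high-variance sites from dominating PC1), PC1 is oriented so its
  correlation with age is positive (sign-flip invariance), and age is
  regressed on PC1.

R² is reported as the coefficient of determination on the day scale
(1 − SSres/SStot), not a squared correlation; the two differ whenever
predictions are biased, and the choice is stated because conventions vary.
The train/test split is stratified: one sample per age group, topped up to
the requested test size (default 10 of 47) with a second sample from
randomly chosen groups.

## Genomic context and motif scanning

CpG islands: a 100 bp window sliding by 1 bp passes when GC ≥ 50% and
observed/expected CpG ≥ 0.6 with expected = count(C)·count(G)/window;
passing windows are merged (overlapping or adjacent) and merged runs of
≥ 200 bp are reported with the mean statistics of their contributing
windows. The merge rule is the package's documented choice — the
cpgplot-style convention leaves it unspecified. Windows containing N never
pass, which makes detection invariant to flanking N-padding. Context
labels use the bp gap to the nearest island: 0 = island, (0, 2000] =
shore, (2000, 4000] = shelf, > 4000 = open sea (closed on the right).
Genic context gives exons precedence over introns for overlapping models.
Enrichment of a focal set against background is the two-sided exact
binomial test with minimum-likelihood two-sidedness (`binom.test`), with
the background proportion as the null.

Motif matrices follow PFM → PPM (column-normalised) → PSSM
(log2(PPM/0.25), bits against a uniform background). Zero probabilities
are floored at ε = 1e-6 *instead of adding pseudocounts*: the
transformation is kept literal and impossible bases stay effectively
impossible while logs remain finite. The score distribution under an
i.i.d. uniform background is computed exactly by positionwise convolution
on a discretised grid (default bin 1e-3 bits; the test suite verifies
agreement with exhaustive enumeration at bin 1e-6); a hit is any window on
either strand with P(score ≥ observed) < 1e-4. Site-motif overlap uses a
2 kb window centred on the cytosine (1 kb each side).

## Read-level discordance

A read with ≥ 2 CpG calls is *discordant* when its within-read methylation
m = 100·mean(calls) satisfies 10 ≤ m ≤ 90, *concordant* when m ≤ 9 or
m ≥ 91 (exact fractions, no rounding; the narrow gaps (9, 10) and
(90, 91) — reachable only with ≥ 11 CpGs per read — are resolved to
discordant). PDR is the percent of discordant reads among eligible reads;
it is invariant to call order and to duplicating the read set. The age
trend is the linear mixed model `PDR ~ β·ln(age) + (1 | batch)` fitted by
REML; natural log is the package's choice where only "log-transformed" is
conventional, and the base is configurable. The p-value for β uses a t
statistic with residual degrees of freedom (n − 2): with two batches any
finer degrees-of-freedom correction (Satterthwaite/Kenward–Roger) is
unstable, so the simple approximation is used and documented. With a
single batch the model falls back to OLS with a warning.

## IR × aging interaction

An *IR DMC* is a site significant in at least one control-versus-dose
comparison (union over doses). Bin enrichment uses as background the
sites shared by the aging and exposure analyses, labelled by their
age-correlation bin — the intersection reading of an ambiguous convention;
the full aging set is available behind a flag. Directionality compares the
sign of ρ with the signs of the significant per-dose differences:
`dose_dependent` when two or more significant doses disagree, else `same`
when all agree with the age direction, else `opposite`; ρ = 0 sites are
excluded and counted separately. The same/opposite split per bin is tested
against a 50:50 binomial null — the null is an explicit assumption, stated
because no convention fixes it. Summary percentages are reported to one
decimal.

## The synthetic-data generator

`sim_config()` encodes the study conditions: seven male age groups at
61/122/152/183/274/365/426 days (n = 7, 6, 6, 8, 6, 8, 6; 47 total; days
derived as round(months·365.25/12)), two library batches interleaved
across age groups, and a four-arm exposure cohort (0/5/50/500 mGy/day,
6 per arm) at 232 days (six months plus a seven-week exposure).

Latent trajectories are piecewise-linear in age with a breakpoint at the
maturity age (183 days): two interpretable slopes whose per-day ratio is
the configured `early_late_rate_ratio` (default 2.27, the ratio of the
printed early and late per-day rates) and whose total change across the
lifespan is `effect_scale` (default 40 percentage points). Planted age
sites are 80% hypermethylating by default, the observed direction split.
Baselines at null sites are Beta(0.4, 0.4) — the bimodal shape typical of
CpG methylation; planted sites draw baselines leaving room for the
trajectory so clamping cannot erase the signal. Noise is logit-normal
site-by-sample jitter (SD 0.4 logit units, roughly a 10-point SD at 50%
methylation) applied *before* binomial sampling, keeping fractions in
(0, 1) without truncation artifacts; batch effects are additive per
site-by-batch shifts (SD 2 points). Coverage is negative binomial
(mean 30, size 3 — spanning the 5–100x window) independent of
methylation; 3% of cells are masked on top of coverage-driven
missingness, a level under which the ≥ 5-per-group uniting rule retains
most sites. IR effects (default 30 points, above the 25-point calling
threshold so planted effects are detectable) are planted at all nonzero
doses; when the aging analysis' bin labels are supplied, affected sites
are drawn from the configured target bins proportionally to the *square
root* of bin occupancy — so both dense and sparse targeted bins end up
overrepresented relative to background, which is the point of bin
targeting. Read patterns draw CpG counts per read from a truncated
Poisson (≥ 1, rate 4); eligible reads are discordant with per-sample
probability `(intercept + slope·ln(age) + batch shift)/100`
(defaults 5 + 3.01·ln(age), the published slope used as a simulation
setting, batch SD 1).

The simulated genome is i.i.d. at 40% GC with 75% of background CpG
dinucleotides mutated away (emulating genome-wide CpG depletion, so
observed/expected is genuinely low outside islands), GC-rich (70%)
planted islands on an even grid ≥ 8 kb apart (keeping shore/shelf truth
unambiguous), gene models with evenly spaced exon blocks, and exact motif
consensus instances at recorded positions.

All randomness flows from one integer seed through deterministic
per-stage substreams, so outputs are byte-identical across runs.

**What the generator does not emulate:** linkage disequilibrium of
methylation between neighbouring sites (sites are independent given the
design), realistic per-site effect-size distributions (no published
distribution exists; defaults are calibrated only to the headline
fractions — ~0.3–0.5% age-associated sites and a ~2× early/late ratio),
sequence-driven coverage bias, bisulfite conversion error, or cell-type
mixture. Passing tests therefore demonstrate correctness of the
*procedures* under a faithful study geometry, not performance guarantees
on real RRBS data.

## Validation scale and numerical choices

The test suite validates at these problem sizes, chosen to exercise the
study geometry fully while keeping the default run at desk scale: clock
recovery on one 47-sample, 20,000-site cohort with 100 planted sites
(held-out MAE threshold 15% of the age range); enrichment calibration over
1,000 null focal draws of 100 sites against a 10,000-site background;
PDR against a brute-force reimplementation on 10,000 random reads and
slope recovery over 10 seeds; island detection against a per-window
brute-force oracle on 50 random 10 kb sequences; exact PSSM p-values by
enumeration up to motif length 8; and IR bin-targeting power over 20
replicates of a 3,000-site cohort. The elastic-net path uses glmnet with
`thresh = 1e-14` when an explicit λ sequence is supplied, which brings the
λ = 0 solution within 1e-6 of closed-form OLS; KNN imputation processes
sites in blocks of 512 through BLAS cross-products; degenerate inputs
(constant sites, empty focal sets, zero pooled coverage, single batches,
all-zero PFM columns) error or flag explicitly rather than propagating
`NaN`.

## Known limitations

Correlation-based screening with 47 samples has limited power for weak
trends, and the |ρ| > 0.5 rule is a hard threshold — sites near the
boundary flip between runs of a noisy simulation. The pooled-count DMC
test ignores within-group overdispersion and so is anticonservative for
biological replicates; this mirrors the default behaviour of the tooling
convention it follows. The PCA clock extrapolates linearly in PC1 and can
predict negative ages far outside the training range. Mixed-model
inference with two batches is effectively a fixed-effect correction; the
random-intercept formulation is kept for continuity with larger designs.
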