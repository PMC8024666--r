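---
title: "Detecting noncoding mutation hotspots with a covariate-corrected background model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting noncoding mutation hotspots with a covariate-corrected background model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nchotspot)
```

## The problem

Most somatic mutations in a cancer genome fall outside protein-coding
sequence, and a small number of noncoding sites — the *TERT* promoter being
the canonical example — recur across independent tumors far beyond what the
local background mutation rate explains. Because protein factors typically
contact 6–10 bp of DNA, a functional regulatory hotspot is expected to be
*clustered*: several donors mutated within a window of roughly a dozen base
pairs, often near a transcription start site.

Finding such windows requires two things done carefully:

1. an accurate **background mutation probability** for every (donor, site)
   pair, because regional mutation rates vary by orders of magnitude with
   chromatin state, replication timing, and sequence context, and donors
   differ widely in total burden; and
2. an **exact recurrence test** that respects donor heterogeneity: the number
   of donors mutated in a window is a sum of independent, *unequal* Bernoulli
   trials — a Poisson-binomial count, not a binomial one.

`nchotspot` implements this pipeline end to end, together with a synthetic
cohort generator so that every stage can be exercised and validated without
any external data.

## The model

### Background mutation probability

For donor $j$ and genome site $i$ the probability of a somatic SNV is

$$ q_{ij} = \sigma\!\left(\alpha_j + \beta^\top x_i\right), $$

where $\sigma$ is the logistic function, $x_i$ is the site's feature vector
and $\alpha_j$ a donor-specific intercept. The features are:

* continuous tracks (replication timing, GC content, conservation,
  mappability, …), z-scored with the normalization stored in the model;
* binary tracks (TFBS clusters, DNase peaks, histone-mark peaks such as
  H3K9me3/H3K27me3, CpG islands) as 0/1 indicators;
* trinucleotide context as indicators over the 32 pyrimidine-collapsed
  categories (a purine-centred trinucleotide is reverse-complemented;
  one category serves as baseline).

"Sample-specific" is realized as the per-donor intercept with shared
covariate slopes. Per-donor slopes would be unidentifiable at realistic
burdens (a few thousand SNVs per donor against millions of sites); the
intercept captures the dominant sample effect, the overall burden.

Fitting the full design — donors × genome sites — is prohibitive and
unnecessary. `fit_background()` uses a case-control design: every mutated
(donor, site) pair is a positive, and `n_background_sites` uniformly sampled
unmutated pairs are negatives. The classical case-control result for
logistic regression says the subsampling shifts only the intercept, by the
log of the control sampling fraction $f_0$; fitting with a fixed offset
$\log(1/f_0)$ in the linear predictor therefore returns coefficients
calibrated to the whole genome. Two testable consequences (both in the test
suite): mean predicted probability matches the cohort's empirical mutation
frequency, and halving the background budget moves fitted probabilities by
well under 2%.

The fit is plain maximum likelihood (IRLS); a non-converged fit is refused,
and complete separation raises an error suggesting the optional ridge
penalty (`l2 > 0`). Donors present in the cohort list but with zero
mutations cannot be estimated and receive a floor intercept
($\sigma^{-1}(10^{-12})$), flagged in the model. Predicted probabilities are
clamped to $[10^{-12}, 1-10^{-12}]$ so the window survival product below
never degenerates.

### The window recurrence test

Candidate windows of odd width $w$ (default 11 bp — a central site plus
10 bp of surrounding DNA, matching protein-binding footprints; a 7–21 bp
sweep is supported) are centred on *recurrently mutated sites*: exact
positions carried by at least `min_donors` (default 2) distinct donors.

For each window the probability that donor $j$ is mutated at least once is

$$ p_j \;=\; 1-\prod_{i \in \text{window}} (1-q_{ij}), $$

accumulated in `log1p` space. The observed recurrence $k$ is the number of
distinct donors with ≥1 SNV inside the window (a donor counts once however
many SNVs it carries there). The p-value is the exact upper tail
$P(K \ge k)$ of the Poisson-binomial distribution of
$K=\sum_j \mathrm{Bernoulli}(p_j)$, computed by the $O(n^2)$
dynamic-programming convolution over donors — no normal or Poisson
approximation. The implementation is validated against exhaustive $2^n$
enumeration (to $10^{-12}$ for $n\le 12$) and against the closed-form
binomial tail for equal probabilities (to $10^{-10}$ up to $n=5000$).

### Multiple testing, and a caveat about seeding

Windows tested at one width are Bonferroni-adjusted. Two choices of the
denominator $m$ are offered:

* `m_mode = "tested"` (default): $m$ = the number of windows actually
  tested at that width. This matches the convention of ranking only seeded
  windows, and is what the ranked reports use.
* `m_mode = "genome"`: $m$ = every possible window position.

The distinction matters. Seeding windows at recurrent sites is a
*data-dependent selection*: a window is only tested because it already
contains a coincidence, so the unconditional p-value of a tested window is
not uniform under the null, and with $m$ = tested windows the family-wise
error is not controlled — at desk-scale simulations the majority of null
cohorts produce a "significant" window. Counting every window position in
$m$ accounts for the selection (every position was implicitly eligible), and
restores strict family-wise control; `scan_all_windows()` makes the same
point directly by evaluating the exact test at *every* center, where the
per-window validity $P(p \le \alpha) \le \alpha$ holds unconditionally (with
slack, because the count statistic is discrete). The null-calibration checks
in the test suite use this unconditional view. For ranking candidates — the
primary use — the choice of $m$ is immaterial since it is a monotone
transformation of the p-values.

### Element annotation

Tested windows are classified by genomic element with the precedence
promoter > 5′-UTR > 3′-UTR > intron > intergenic. "Promoter" means any
window base within 5 kb of a transcription start site; the region is
symmetric around the TSS (the source analysis states "within 5 kb" without a
direction), with strand affecting only the sign of the reported distance
(negative = upstream). Windows overlapping coding exons are flagged and
dropped from the noncoding report by default. Gene models load from BED12
or GFF3; introns are derived as exon gaps and UTRs as exon bases outside the
CDS, so both encodings of a gene yield the same model.

### Megabase correlation module

`build_bins()` / `bin_mutation_rate()` / `correlate_features()` reproduce
the regional analysis that motivates the covariates: per-bin mutation rate
(mutations per bp per donor, optionally restricted to a coding or noncoding
mask) against per-bin mean covariate values. Spearman is the default
(regional rates are strongly skewed); Pearson is available. In cohorts
simulated with a positive heterochromatin-mark coefficient the mark's
bin-level correlation is strongly positive while a zero-coefficient track
stays near zero, and because the generative model is mask-independent, the
coding and noncoding correlation profiles agree within sampling error.

## The synthetic cohort generator

`cohort_spec()` + `simulate_cohort()` generate, deterministically under one
seed:

* a random nucleotide sequence (default 1 Mb, one chromosome);
* covariate tracks with spatial autocorrelation — smoothed Gaussian fields,
  sigmoid-mapped to $[0,1]$ for continuous tracks, thresholded at a target
  coverage for binary tracks (correlation lengths: 50 kb replication
  timing, 10 kb GC, 20 kb heterochromatin mark at 30% coverage, 1 kb TFBS
  at 5% coverage);
* donor mutation sets drawn from the same logistic model the fitter
  assumes, with donor intercepts normal on the logit scale around
  $\sigma^{-1}(10^{-3})$ (sd 0.5, i.e. several-fold burden heterogeneity
  across 50 donors, echoing the wide burden spread seen in real pan-cancer
  cohorts at a per-bp rate that keeps desk-scale runs informative);
* default covariate effects (logit scale): heterochromatin mark $+0.5$,
  TFBS $+0.3$, replication timing $-0.5$ — elevated rates in closed
  chromatin and bound regions;
* optional injected clustered hotspots: exactly `n_recurrent_donors`
  distinct donors forced to carry ≥1 SNV in an odd window (injection is
  idempotent and deterministic);
* non-overlapping three-exon gene models providing TSSs, UTRs, introns and
  CDS for the annotation stage.

`write_fixture()` emits the whole cohort as standard files (FASTA, ICGC-style
TSV, VCF 4.2, bedGraph, BED, BED12, plus a JSON truth file with the
generative parameters and per-site linear predictor), so the pipeline can be
driven purely from disk.

What the generator deliberately does **not** emulate: mutational signatures
(the 96-channel substitution spectrum), indels, multi-chromosome genomes,
copy-number or purity effects, and real chromatin track structure. Passing
tests therefore demonstrate the *statistical machinery* — calibration,
exactness, error control, power — under the stated generative model, not
performance on real ICGC data.

## Numerical and design choices

* Coordinates: mutation records are 1-based inclusive (MAF/VCF convention);
  all intervals are 0-based half-open (BED convention); converters are
  single-sourced.
* Chromosome names are stored without the `chr` prefix; both dialects are
  accepted on input.
* Hypermutators: excluded when a donor's SNV count exceeds
  `min(absolute_cap, fold_over_median × cohort median)` — defaults 100,000
  and 10×. The fold rule adapts to per-cancer-type burden; the cap guards
  small cohorts (for a single-donor cohort the fold rule is vacuous by
  construction).
* Common-SNP removal is allele-aware by default (position-only available):
  removing by position alone discards genuine somatic events at
  polymorphic sites.
* Mappability filtering defaults to requiring a perfect (1.0) uniqueness
  score; positions outside the supplied track are treated as score 0 and
  removed, with a warning.
* Continuous-track gaps return a declared fill value (default 0) rather
  than silently interpolating.
* p-values are floored at $10^{-300}$ only for the $-\log_{10}$ column;
  the stored p-value is untouched.
* Ties in the ranked report: p ascending, then recurrence $k$ descending,
  then coordinates; gene assignment ties go to the smallest |distance to
  TSS|, then lexicographic gene name.

### Problem sizes used in the validation suite

The test suite and the acceptance script run entirely on simulated cohorts
(sizes chosen to keep the full run in the minutes range while leaving the
statistical checks well-powered): parameter recovery on the 1 Mb / 50-donor
default cohort across background budgets of 10k/50k/200k sites; null
calibration on fifty 0.5 Mb / 30-donor cohorts with the true model supplied;
the power curve at injected recurrence 4/8/16 of 50 donors (five replicates
each); and the correlation module on a 2 Mb cohort binned into 1,000 bins.

## Limitations

* The per-donor intercept absorbs burden but not per-donor *signature*
  differences; a donor whose mutations concentrate in an unusual context is
  only partially corrected by the shared context coefficients.
* The exact test assumes donors are independent given the model; shared
  artifacts (mapping errors, germline leakage) violate this, which is why
  the mappability and common-SNP filters run first.
* With `m_mode = "tested"` the Bonferroni-adjusted values are best read as
  a ranking, not as calibrated family-wise error rates (see the seeding
  caveat above).
* Windows are tested per width without merging overlapping candidates; a
  hotspot spread over more than one seed site appears as several
  overlapping, individually tested windows.

## A worked example

```{r example, eval = FALSE}
library(nchotspot)

# a 1 Mb, 50-donor cohort with a hotspot injected 1 kb downstream of a TSS
base <- cohort_spec(seed = 301)
tss  <- simulate_genome(base)$genes$genes$tss[5]
spec <- cohort_spec(seed = 301, hotspots = list(
  hotspot_spec(center = tss + 1000L, n_recurrent_donors = 8)))
paths <- write_fixture(spec, "fixture")

cfg <- run_config(
  mutations = paths[["tsv"]], format = "icgc_tsv",
  tracks = list(
    replication_timing = list(path = paths[["replication_timing"]],
                              kind = "continuous"),
    gc_content = list(path = paths[["gc_content"]], kind = "continuous"),
    H3K9me3 = list(path = paths[["H3K9me3"]], kind = "binary"),
    TFBS = list(path = paths[["TFBS"]], kind = "binary")),
  fasta = paths[["fasta"]], genes = paths[["genes"]],
  widths = c(7, 11, 21), restrict = "promoter", seed = 5)
res <- run_pipeline(cfg, "out")

head(res$report[["11"]])      # ranked promoter hotspots
plot(res$scan, width = 11)    # -log10 adjusted p vs recurrence k
```
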