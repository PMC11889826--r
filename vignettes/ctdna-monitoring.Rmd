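---
title: "Tumor-agnostic ctDNA quantification and monitoring from shallow WGS"
author: "ctfrag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumor-agnostic ctDNA quantification and monitoring from shallow WGS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctfrag)
```

## The problem

Low-coverage whole-genome sequencing (lcWGS, roughly 0.8-6x) of plasma
cell-free DNA (cfDNA) carries two largely independent classes of tumor
signal: read-depth deviations caused by somatic copy-number variation
(CNVs), and fragmentation changes -- tumor-derived cfDNA is shorter, uses
different fragment end positions and end motifs, and reflects the altered
methylation of the tumor genome. Because none of these signals requires
sequencing the patient's tumor tissue, they permit *tumor-agnostic*
quantification of circulating tumor DNA (ctDNA), which is attractive when
biopsies are unavailable and during therapy monitoring, e.g. under
anti-PD-(L)1 immunotherapy in non-small-cell lung cancer (NSCLC).

ctfrag implements this analysis end to end: seven per-sample markers, an
empirical healthy-cohort calibration at fixed specificity, marker
combination rules, longitudinal response classification, and survival
analysis of the marker-defined strata -- together with a synthetic cfDNA
cohort generator so the whole chain is testable without controlled-access
patient data.

## Markers

All fragmentomic markers are computed on the mononucleosomal peak
(fragments <= 250 bp, boundary inclusive); copy-number profiling uses all
fragment lengths. The per-fragment unit is a 0-based half-open interval
with the 5' trinucleotide of each end (`motif5_right` stored as the
reverse complement of the reference at the right end, so both motifs are
5'-oriented).

**CPA (copy-number abnormality).** Fragments are counted in fixed-width
genome bins by midpoint, scaled to library size, GC-corrected by median
ratio per GC decile, divided by the expectation of a panel of normals,
log2-transformed and median-recentred per sample. A least-squares
changepoint segmentation (dynamic programming, SIC-style penalty
`2*sigma^2*log(n)` with `sigma` from robust first differences) yields
segments with mean ratios `r_s`, and

$$\mathrm{CPA} = \frac{\sum_s L_s\,|r_s|}{\sum_s L_s},$$

the length-weighted mean absolute segment log2 ratio -- a genome-wide
chromosomal-instability summary. The published score this reconstructs is
defined only up to its citation chain; any strictly monotone variant is
equivalent here because the score is used solely relative to its own
healthy-derived threshold.

**ctCPA (ctDNA-informed CPA).** For a patient with a CNV-detectable
baseline, the baseline's aberrant segments (standardised deviation
`sqrt(n_bins)*|mean z| >= 3`, at least 3 bins) form an *informative set*
with recorded directions. A follow-up profile is then projected onto that
set:

$$\mathrm{ctCPA} = \frac{\sum_s L_s\,\mathrm{sign}(r_s^{\,\mathrm{base}})\,
\bar r_s^{\,\mathrm{fu}}}{\sum_s L_s}.$$

The signed projection does not fold noise the way `|.|` does, so its null
is centred at zero and low-burden deviations in the baseline direction
become detectable -- the tumor-informed gain. Whether the published score
uses bin- or segment-level follow-up ratios, or an absolute value, is not
derivable from the main text; the signed, bin-averaged projection above is
this package's documented choice.

**P126-135 and D126-135.** The proportion of fragments of 126-135 bp
(inclusive; denominator = all mononucleosomal fragments) and its absolute
deviation from the healthy-cohort median. The deviation captures shifts in
*either* direction, since copy-neutral tumors can show reduced
short-fragment proportions.

**MDS.** Normalized Shannon entropy of the 64 end-trinucleotide
frequencies over both fragment ends, `-sum f log f / log 64`, in [0, 1].

**Alu CGN/NCG ratio.** Among end motifs of ends falling inside Alu
elements, `(#CGN + 0.5) / (#NCG + 0.5)`, where CGN means the motif starts
with CG and NCG that it ends with CG (disjoint patterns for 3-mers).
Unmethylated Alu CpGs are preferentially cut immediately before the CpG,
so hypomethylated tumor DNA raises the ratio. Both fragment ends are
evaluated (left end at `start`, right end at `end - 1`).

**iwFAF.** A reference of recurrent healthy end positions is built from
the healthy cohort (a position qualifies when used by at least
`ceiling(n/4)` distinct healthy samples); each reference position carries
its pooled usage frequency. A fragment is *aberrant* when neither end
falls within `w` bp (default 0) of a reference position; its weight is the
self-information `-log p` of its less frequent end (pseudocounted for
unseen positions), and iwFAF is the weighted aberrant share in [0, 1]. The
exact published weighting is not restated in its source; the
self-information form preserves the name's semantics and is declared as a
reconstruction.

## Detection, combination, and longitudinal rules

Thresholds are calibrated per marker on healthy samples at a target
specificity (default 95%): the least extreme healthy value `t` such that
the fraction of healthy values strictly beyond `t` is at most
`1 - specificity`. This order-statistic rule uses no interpolation,
guarantees the specificity exactly on the calibration cohort, and calls
ties negative. At calibration size `n`, the held-out exceedance
probability of such a threshold is `Beta(a, n+1-a)` with
`a = floor((1-spec)*n) + 1`; its mean `a/(n+1)` is slightly above the
nominal `1-spec` (7.3% at `n = 40`, 5.2% at `n = 57`), which matters when
several markers are combined by union -- an inherent property of empirical
thresholds that users should keep in mind.

One subtlety the packaged validation experiments respect: healthy samples
used to *build* the panel of normals and the end-position reference are
not exchangeable with future samples normalized against them (panel
members see their own mean, and reference members contributed their own
end positions), so their CPA/ctCPA/iwFAF nulls run slightly cold. The
experiments therefore build the panel and end reference from a separate
healthy reference cohort and calibrate thresholds on an independent
healthy cohort; `run_pipeline()` itself keeps the conventional
single-healthy-cohort design, whose thresholds are correspondingly a
little conservative-looking on the calibration cohort yet slightly
anti-conservative on new samples.

ctCPA has no single global null: its scale depends on the informative set.
Thresholds are therefore per subject, obtained by projecting the entire
healthy cohort through that subject's informative set and applying the
same order-statistic rule.

Combination rules: `cnv_detect = CPA+ or ctCPA+`; `ctdna_any` = any of the
seven markers positive; `residual_ctdna = cnv_detect or iwFAF+` (the
residual-disease call after four therapy cycles). Markers that cannot be
evaluated (e.g. ctCPA without an informative set, as happens for baselines
with CPA marginally above threshold but no usable segments) count as
negative and are flagged, so combinations never silently drop samples.

Longitudinal categories on the residual basis: negative/negative =
`double_negative`, positive/negative = `clearance`, any cycle-4 positive =
`residual_positive`. Risk groups: Group A = PD-L1 TPS >= 1% *and* baseline
D126-135 undetectable *and* no residual ctDNA after cycle 4; everything
else (or TPS < 1%) is Group B. Survival endpoints are compared by
two-sided log-rank tests and Cox proportional-hazards models
(`survival::survdiff` / `survival::coxph` behind `km_logrank()` /
`cox_fit()`, with broom-style `tidy()`/`glance()`); durable vs short
clinical response splits PFS at 12 months (exactly 12.0 with an event is
short; subjects censored at or before the cut are not evaluable, a case
the rule's source does not address).

## The synthetic cohort generator

The generator emulates the statistical structure each marker assumes,
without claiming any empirical plasma distribution:

* **Lengths**: mixtures of discretised Gaussians; healthy plasma has a
  166 bp mononucleosomal core (sd 9), 10-bp sawtooth sub-peaks below
  160 bp with geometrically decaying weights, and a small dinucleosomal
  tail; tumor fragments shift to a 145 bp mode with sub-peaks at 134,
  124, ... bp, concentrating extra mass in the 126-135 bp window
  (analytic window masses: `length_window_mass()`).
* **Copy number**: a fragment's position is drawn proportionally to
  `(1-tf)*2 + tf*CN`; the default clone has high-level gains (CN 4) over
  80% of chr1 and deep/hemizygous losses (CN 0-1) over 80% of chr2.
  Gains and losses are balanced genome-wide so per-sample median
  recentring leaves the copy-neutral level at zero, and each chromosome
  is aberrant in one direction so chromosome-scale signal does not
  self-cancel -- both properties matter at very low tumor fractions,
  where segmentation cannot resolve individual segments and the signal
  lives in chromosome-level means.
* **End positions**: a fixed genome-wide grid of preferred end sites
  (spacing 20,411 bp, deliberately incommensurate with the Alu spacing so
  site residues cover all positions relative to Alu elements); healthy
  fragments snap one end to the nearest site with probability 0.8, tumor
  fragments with probability `0.8*(1-0.6)`, so the sample-level
  aberrant-end rate grows linearly in tumor fraction.
* **End motifs**: healthy ends follow a fixed non-uniform 64-simplex;
  tumor ends mix it with the uniform distribution (weight 0.6), raising
  motif diversity.
* **Alu CpG ends**: regularly spaced 300 bp Alu elements every 5 kb; ends
  inside an Alu emit CGN with probability 0.05 (healthy) vs 0.14 (tumor)
  and NCG with 0.05 vs 0.04.
* **Outcomes**: exponential PFS (median 12 months for residual-negative
  subjects) with hazard multiplied by 4 for subjects whose cycle-4 tumor
  fraction is positive; independent exponential censoring (rate
  0.025/month, about 20% censored) truncated at 60 months; OS adds an
  exponential post-progression time and shares the censoring time.

All sampling is inverse-CDF over a per-fragment matrix of uniforms that
depends only on `(seed, fragment index)`. Two consequences: byte-identical
reproducibility, and *coupled dilution series* -- running the generator at
increasing tumor fraction under one seed yields (near-)nested
tumor-fragment sets, the computational analogue of serially diluting a
single specimen, which removes most between-level Monte-Carlo noise in
dose-response experiments.

What the generator does **not** emulate: sequencing error, GC bias (bins
carry a synthetic GC track so the correction code is exercised, but
counts are unbiased), mappability gaps, subclonal structure, batch
effects, or the empirical shape of real cfDNA length/motif distributions.
Passing tests therefore demonstrate that the estimators recover the
signals they are designed for at realistic signal-to-noise, not that any
specific clinical performance transfers to real plasma.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open throughout; BAM positions are
  converted on read; a bin-boundary midpoint belongs to the right-hand
  bin.
* A fragment is the outer span of a proper pair; discordant and singleton
  reads are excluded; defaults `min_mapq = 30`, duplicates dropped,
  autosomes only, minimum length 50 bp (all configurable and recorded in
  the result's provenance).
* The length pmf integrates each Gaussian over unit bins and renormalises
  over the truncated support.
* Segmentation minimises within-segment RSS with penalty
  `max(2*sigma^2*log(n), 1e-12)`; chromosomes with fewer than two usable
  bins give one trivial segment; zero-count bins are unusable (no
  pseudocounts in the log ratio).
* Log2 profiles are median-recentred per sample; without this, the
  depth-dependent Jensen offset of log ratios (about `-1/(2 ln 2 * m)`
  at `m` fragments per bin) makes small gains move segment means *toward*
  zero and deflates CPA at low tumor fraction.
* Thresholding is strictly-greater (ties negative); quantile splits use
  the default continuous empirical quantile (type 7).
* Rank tests delegate to `stats::wilcox.test` (exact where available);
  degenerate inputs (all values equal, or all paired differences zero)
  return p = 1 with a flag rather than erroring.
* Minimum-data guards (1,000 fragments for P126-135; 200 Alu ends; 10
  healthy samples per threshold; 5 for the end reference and panel) exist
  because synthetic and downsampled data can be far sparser than the
  multi-million-fragment real samples the markers were designed for.

## Study-scale choices in the test suite

The packaged experiments run at desk scale: a 2 x 50 Mb toy genome with
500 kb bins (200 bins), 20,000 fragments per sample (10,000 in the
dose-response experiment), healthy cohorts of 20-100 samples (57 in the
hazard-recovery experiment, matching a typical donor panel), 50-subject
patient cohorts and 20 seeded replicates. These sizes were chosen so each
property is measurable with comfortable signal-to-noise on a single CPU;
they are package design choices, not estimates of any study's scale. At
10,000 fragments the genome-wide depth noise floor is
`sqrt(1/N)/ln 2 ~ 0.014` in log2 units, which is why tumor fractions of
1% sit at the edge of CPA detectability in the dilution experiments --
consistent with the general rule that read-depth CNV detection at tf
~1% requires tens of millions of fragments.

## Known limitations

* The CPA/ctCPA formulas reconstruct scores whose exact published forms
  sit behind citations and supplementary material; both are declared
  reconstructions, calibrated only against their own healthy nulls.
* The union of several markers thresholded at 95% specificity has a
  union-level false-positive rate near `1 - 0.95^k`; the package reports
  per-marker and combined calls separately so users can see this.
* Empirical thresholds from small healthy cohorts are noisy
  (Beta-distributed exceedance); the reported achieved specificity refers
  to the calibration cohort.
* No absolute tumor-fraction estimation, no allele-specific or subclonal
  copy-number inference, no DELFI-style windowed fragmentation profiles,
  and no multiple-testing correction (single-marker p-values are reported
  unadjusted at alpha = 0.05, as is conventional for this analysis).

## A worked mini-run

```{r, eval = FALSE}
cfg <- sim_config(n_fragments = 5000,
                  cohort_model = default_cohort_model(n_healthy = 10,
                                                      n_subjects = 6))
run <- run_pipeline(cfg)
run$thresholds
dplyr::count(run$longitudinal, category)
tidy(run$survival_fits$pfs_residual_cox)
```
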