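---
title: "Quantifying hemispheric lateralization dynamics in songbird auditory recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hemispheric lateralization dynamics in songbird auditory recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(neurolat)
library(dplyr)
```

## The analysis problem

In songbirds, the higher-order auditory forebrain (the caudomedial
nidopallium, NCM) responds to complex vocalizations in a lateralized way, and
that lateral bias is labile: prolonged passive exposure to a novel acoustic
environment can transiently reverse the typical right-hemisphere bias before
it returns. Tracking this requires a chain of quantitative steps that this
package implements as a reusable, tested pipeline:

1. **Response magnitudes.** From trial-aligned voltage traces, the absolute
   response magnitude (ARM) of a stimulus presentation is the RMS of the
   stimulus-on window (stimulus duration plus 100 ms) minus the RMS of the
   500 ms pre-stimulus control window. For multi-unit activity (MUA) this is
   computed per trial (`compute_arm()`); for event-related potentials (ERPs)
   the waveforms of the first 25 presentations of a stimulus are averaged
   first and the same window arithmetic is applied to the averaged waveform
   (`compute_earm()`), because single-trial ERPs are noise-dominated.
2. **Stimulus-specific adaptation.** NCM responses to a repeated novel
   stimulus decline across repetitions. The adaptation rate (AdR) is the OLS
   slope of ARM against presentation index over trials 6–25, normalized by
   the mean ARM of those trials (`compute_adr()`), giving the fractional
   response drop per repetition. Sites whose aggregated AdR is not below
   −0.05 lack the NCM adaptation signature (they behave like the adjacent
   primary area, Field L) and are excluded (`filter_sites()`).
3. **Lateralization.** Per hemisphere, response magnitudes are averaged
   (stimuli within channel first, then channels), and the lateralization
   index is `LI = (R − L) / ((R + L)/2)` — signed, unitless, bounded by
   [−2, 2], positive for right bias. Each bird's exposure trajectory is
   referenced to its own pre-exposure sessions by subtracting its mean
   baseline LI (`baseline_correct()`), and sessions are grouped into 3-day
   exposure bins labelled `0-2` … `18-20` (`bin_days()`).
4. **Behavior.** Go/NoGo operant logs are scored in consecutive 50-trial
   blocks; the discrimination criterion is at least 80% correct in 2
   consecutive complete blocks within 21 training days
   (`detect_criterion()`).
5. **Statistics.** Factorial ANOVA (Type III, sum-to-zero coding) over
   condition × time-bin, Bonferroni-corrected two-sided pairwise t tests,
   repeated-measures ANCOVA with a depth covariate for site-level MUA
   measures, and Kruskal–Wallis for baseline-RMS comparisons.

On the sign convention: the LI is sometimes described via an "absolute
difference", but the analysis throughout depends on left-biased indices
being negative, so the signed numerator `R − L` is the only coherent
reading and is what `lateralization_index()` computes.

## The synthetic-data generator

No public recordings accompany this kind of experiment, so the package
treats the generator as a first-class module: every downstream stage is
exercised against simulated sessions whose ground truth is known exactly.

`generate_session()` emulates acute bilateral MUA recordings: i.i.d.
Gaussian background noise of configurable RMS; per presentation *t* of a
stimulus, one evoked waveform (a unit-RMS Gaussian draw shared across
channels) added to the stimulus-on window and scaled to RMS
`A · h(c) · (1 − k)^(t−1)`, where `h(c)` is the hemispheric gain ratio `g`
for right channels and 1 for left, and `k` is the per-repetition adaptation
fraction. Two consequences matter for testing:

* Sharing the evoked waveform across channels makes the between-hemisphere
  evoked-RMS ratio *exactly* `g` in every trial, so noiseless LI recovery is
  exact: `LI = 2(g − 1)/(g + 1)`, e.g. 0.4 for `g = 1.5`.
* Geometric decay with small `k` yields an almost-linear ARM decline over
  trials 6–25, so the linear-regression AdR estimator recovers `−k` closely
  (within 1% at `k = 0.05`, noiselessly); this is why the generator uses a
  geometric rather than a linear decrement.

`generate_erp_session()` emulates chronic epidural ERP sessions: a
deterministic damped-sinusoid template (energy confined to the stimulus
window, unit RMS there) scaled per channel, plus independent noise per
trial; 3 call stimuli × 100 presentations over 8 electrodes in four
quadrants, with rostral electrodes at 0.4× the caudal evoked gain because
the caudal pins overlie the auditory lobule. The template shape itself is
arbitrary by design — the analysis must not depend on it, only on where its
energy lies.

`lateralization_profile()` encodes the exposure-condition ground truth as a
step function of day: `Con-Env` holds `g = g_high` (default 1.5, i.e. a
right-bias LI of 0.4) for the whole exposure; `Het-Env` is unbiased on days
0–5, reversed (`g = 1/g_high`) on days 6–14, and returns to `g_high` on days
15–20; `Silence` is `g = 1` throughout; baseline days are always `g = 1`.
The reversal window matches the period in which left-biased activity is
expected, and the step form is deliberately simple: it is simulation ground
truth, never an analysis assumption.

`generate_behavior_log()` draws per-trial correctness from a saturating
exponential learning curve
`p(d) = asymptote − (asymptote − p0) · exp(−rate · (d − 1))`. The fast-learner
defaults (`p0 = 0.5`, asymptote 0.95, rate 0.12/day) put criterion
attainment near training day 10–11, the regime reported for birds with
prolonged heterospecific exposure; chance performers use a flat curve at
0.5. Go/NoGo assignment is exactly balanced 25/25 within each 50-trial
block (an i.i.d. mode is available behind `balanced_blocks = FALSE`); exact
balance is how a "50/50 probability per 50-trial block" design is most
naturally read, and it makes block performance well-defined in tests.

What the generator does *not* emulate: spike waveforms and sorting,
non-Gaussian or correlated noise, amplitude drift, movement artifacts,
stimulus acoustics, or response-latency structure. Tests passing on this
generator therefore certify the *analysis arithmetic and its contracts*
— window placement, regression and filter logic, aggregation order, sign
conventions, statistical calibration — not robustness to every pathology of
real recordings.

## Numerical and design choices

* **Window discretization.** Time windows are half-open in samples,
  `[floor(start·fs), floor(end·fs))`, so the baseline and stimulus windows
  meeting at stimulus onset never share a sample; a 1 ns epsilon guards
  `floor()` against floating-point products landing one ulp low. A 500 ms
  baseline at 1 kHz is exactly 500 samples.
* **No rectification.** RMS is computed on stored traces as-is; recordings
  are assumed band-passed at acquisition. (Whether MUA should be rectified
  first is a lab-convention question; the default here is no, and the
  windows are the only preprocessing.)
* **AdR edge cases.** Groups missing any of trials 6–25 are flagged, never
  imputed; a non-positive mean ARM leaves AdR undefined (non-responsive
  site) and the site is excluded with a reason code. The inclusion
  comparison is strict (`adr < −0.05`).
* **Site filter aggregation.** AdR is defined per (site, stimulus); the
  filter is per site. The default aggregates by the mean of defined AdRs
  across stimuli, with `median` and `any` rules selectable — the choice is
  genuinely open, and the default is the least outlier-sensitive symmetric
  option.
* **Averaging order for LI.** Per-stimulus magnitudes are averaged within
  channel before hemisphere averaging, weighting stimuli equally regardless
  of trial counts. ERP LIs use all 4 pins per hemisphere by default;
  `channels = "caudal_only"` restricts to the pins over the auditory
  lobule.
* **Binning.** Exposure onset is day 0; baseline days are negative and
  labelled `baseline`; bins are `[3⌊d/3⌋, 3⌊d/3⌋+2]`, which makes the
  printed bin names (`0-2` … `18-20`) emerge exactly for a 21-day exposure.
* **Blocks across days.** Behavior blocks are defined purely by trial
  count and may span calendar days; the day criterion is the day of the
  qualifying pair's last trial. This is an assumption (the alternative —
  resetting blocks at midnight — would discard partial blocks daily).
* **Post-hoc error term.** `posthoc_pairwise()` defaults to
  independent-samples Student t tests on the two cells' own data. A
  `pooled_error = TRUE` variant uses the full model's residual mean square,
  which reproduces the pooled-df style of report (e.g. *t*(45) with 8 bins
  of modest n); both are exposed because published reports are ambiguous
  about which error term produced their df.
* **Repeated-measures engine.** `rm_ancova()` uses `aov` with
  `Error(unit/within)` strata (Type I within strata). On the balanced
  designs the generator produces this coincides with Type III for the
  tested effects; for badly unbalanced real tables a mixed-model approach
  would be preferable and is out of scope here. Units missing within-factor
  levels are dropped with an explicit report, never silently.
* **Determinism.** One master seed; per-session streams are derived as
  `(seed·10007 + subject_index·131 + day + 512) mod 2147483647`, so any
  session is independently reproducible. `run_pipeline()` writes a manifest
  (package version, seed, full parameters, deterministic parameter hash)
  from which `run_pipeline_from_manifest()` reproduces every output file
  byte-for-byte.

## Scale of the bundled simulations

The demonstration and test configurations are deliberately desk-scale: ERP
sessions at 2 kHz (the generator default is 10 kHz, configurable; MUA-band
acquisition implies ≥10 kHz, but window arithmetic is rate-invariant), 25
presentations per stimulus, cohorts of 4–5 subjects with one session per
3-day bin, and calibration studies of 1000 replicates. These sizes were
chosen so that the full test suite and the reproduction script each complete
in minutes on a single core while keeping every Monte-Carlo interval tight
enough to be informative; all of them are parameters, not constants, and
scale up transparently.

## A worked run

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(seed = 7, n_subjects = 5)
p <- run_pipeline(cfg, quiet = TRUE)

p$li |>
  filter(day >= 0) |>
  group_by(condition, bin_label) |>
  summarise(mean_li = mean(li_corrected), .groups = "drop")

plot_li_timecourse(p$li)
```

The Het-Env cohort's baseline-corrected LI means are negative in bins
`6-8`, `9-11` and `12-14` and positive in `15-17` and `18-20`, while the
Con-Env cohort stays positive in every bin — the reversal-and-return
signature the pipeline is built to detect. `p$behavior_groups` shows the
companion behavioral separation (all fast-learning subjects reach the 80%
criterion; chance performers do not).

## Known limitations

* The generator's hemispheric gain acts multiplicatively and identically on
  all channels of a hemisphere; real lateralization is likely
  heterogeneous across sites.
* The noise-driven positive bias of RMS-difference estimators (the RMS of
  signal-plus-noise exceeds the signal RMS) is inherited from the ARM
  definition itself; eARM's 25-trial averaging suppresses but does not
  eliminate it. Comparisons between hemispheres at matched noise levels are
  unaffected to first order.
* No automated outlier exclusion is provided: dropping a subject is an
  explicit, user-visible decision, not a rule the pipeline applies.
* `rm_ancova()` assumes sphericity (trivially satisfied for two-level
  repeated factors, the intended use) and applies no epsilon correction.
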