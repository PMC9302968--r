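---
title: "Closed-loop ERD-triggered paired-pulse TMS: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop ERD-triggered paired-pulse TMS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erdtms)
```

## Scope

`erdtms` rebuilds, at desk scale, a closed-loop experiment in which
dual-coil transcranial magnetic stimulation is triggered by the
instantaneous bilateral sensorimotor-rhythm ERD, and interhemispheric
inhibition (IHI) is read out from conditioned/unconditioned motor-evoked
potentials (MEPs). Human participants and stimulation hardware are replaced
by a seeded synthetic generator with known ground truth, so every stage —
online estimation, triggering, MEP quantification, connectivity, and the
statistical battery — is testable end to end. Hardware control, scalp
topography rendering, and source-space analyses are out of scope.

## The online ERD estimator

Every 100 ms, the estimator consumes the last 1 s of EEG and emits one
bilateral ERD sample:

1. causal 1–70 Hz second-order Butterworth band-pass, then a 50 Hz notch
   (48–52 Hz second-order band-stop);
2. large Laplacian per hemisphere: C3 (or C4) minus the mean of its six
   surrounding channels;
3. FFT of the exact 1 s buffer with a rectangular window — no taper is used
   on the online path, giving 1 Hz bins;
4. power as the squared magnitude spectrum;
5. band power as the mean over the inclusive integer-Hz bins of the target
   band;
6. smoothing by the mean of up to the last five window powers (500 ms);
7. ERD relative to the trial's resting reference,
   `ERD = (P_ref − P) / P_ref × 100`.

Numerical conventions worth stating explicitly:

* **Warm-up.** Smoothing averages however many windows exist (fewer than
  five) instead of stalling; the earliest trigger at 0.5 s after MI onset
  requires estimates from the first windows on. The first ERD sample of a
  trial appears at t = 1.0 s (one full second of history), so a 12 s trial
  yields 111 samples.
* **Reference.** The reference is the mean *smoothed* band power over the
  windows lying fully inside the trial's 1–5 s resting epoch (ends at
  2.0–5.0 s, 31 windows); numerator and reference are smoothed identically.
  By linearity, the mean ERD over the reference windows themselves is
  exactly zero. A pooled-across-trials reference is available via
  `run_realtime(..., reference = "pooled")` for sensitivity analysis; the
  per-trial reference is the default and the one the trigger path uses.
* **Filter state** is carried across the whole recording rather than reset
  per trial, matching continuous acquisition and avoiding per-trial
  transients. Because the filters are causal and start from zero state,
  streaming and batch execution agree sample for sample — this is asserted
  as a prefix-equivalence property in the tests.
* **Filter order.** Band-pass before notch; nothing downstream depends on
  the order of two linear time-invariant filters applied back to back, so
  the choice is arbitrary and recorded here.

## Calibration and target boxes

A calibration recording (nominally 20 trials of 5 s rest / 1 s ready / 6 s
motor imagery) selects the per-hemisphere target band by scanning the alpha
range with four 3 Hz-wide candidate bins (8–10, 9–11, 10–12, 11–13 Hz; the
"3 Hz bin with 2 Hz overlap" rule read as a 1 Hz step), picking the bin
with maximal mean motor-imagery ERD, ties to the lowest bin. The 100-ms ERD
samples of the rest and MI epochs are pooled across trials into empirical
percentile tables stored at 0.5-percentile resolution; the feedback axis
spans the [5th, 95th] percentile of the MI distribution with the median as
origin.

Session target boxes take the contralateral 37.5–62.5th percentile band
combined with the ipsilateral band that defines the condition: HIGH
75–95th, MID 37.5–62.5th, LOW 5–25th, NoFB 5–95th (all of the MI
distribution); REST uses the 37.5–62.5th band of the *rest* distribution on
both axes, applied in the epoch homologous to MI — the REST timing is not
otherwise constrained, and symmetry was chosen. Box intervals are closed:
boundary equality counts as inside. A single 100-ms sample inside the box
fires the trigger (no dwell requirement); the trigger window is 0.5–5.5 s
from MI onset, at most one trigger per trial, and trials that never reach
the box receive the fallback pulse at a uniformly random time in
5.5–6.0 s. Pulse kinds (CS+TS vs TS-only) are pre-planned per session in an
exactly balanced, seeded order — balanced design serves "approximately
equal numbers" better than per-event coin flips at n = 40 — and fallback
trials keep their planned kind rather than re-randomizing. Waiting times
are logged both from MI onset and from the earliest eligible trigger time
(0.5 s later), since the two offset conventions are both in circulation.

## MEP quantification and IHI

Peak-to-peak amplitude is taken strictly within 20–45 ms after the pulse.
Three rejection rules: a metadata coil-shift flag (>3 mm and/or >3°);
pre-innervation, i.e. RMS of the 250 ms before the pulse above 5% of the
maximal voluntary contraction (MVC); and amplitudes outside mean ± 3 SD of
their session × pulse-kind stratum. The outlier screen runs once (no
re-iteration after removal) and conditioned/unconditioned trials form
separate strata — both points are under-determined by the rule's usual
one-line statement, so the simplest reading was fixed and is noted here.
MVC itself is the RMS of the most stable contiguous 3 s of a ≥5 s
contraction trace, "stable" operationalized as the window minimizing the
variance of its 250-ms chunk RMS values.

IHI is the ratio of means (not the mean of ratios) × 100, making it
scale-invariant and matching the wording "mean conditioned over mean
unconditioned". The manipulation range between HIGH and LOW sessions is the
percentage change `(IHI_LOW − IHI_HIGH) / IHI_LOW × 100`, reported signed
and as a magnitude; session values can also be normalized to the NoFB
baseline. IHI curves over conditioning intensities (100–140% RMT plus
TS-only at 0) are normalized to the TS-only mean; monotonicity is not
enforced.

## Connectivity

Offline analysis re-references to the common average, rejects per trial any
channel exceeding 100 µV, and computes the corrected imaginary coherence
between the seven left-hemisphere channels (C3 + ring) and the seven
right-hemisphere channels (C4 + ring). Epochs are subdivided into 1 s
segments with 90% overlap (a 4 s resting epoch gives exactly 31 segments),
each Hanning-tapered. The complex coherency `C` is formed from cross- and
auto-spectra averaged over segments and over the band's bins — spectra are
band-averaged *before* the ratio; a per-bin variant sits behind
`per_bin = TRUE` — and

```
ciCOH = Im(C) / sqrt(1 − Re(C)^2),  clipped to [−1, 1].
```

Any zero-lag (instantaneously mixed) pair has purely real coherency and
hence ciCOH = 0, which is the volume-conduction robustness that motivates
the measure. The network intensity of a band is the sum of the significant
ciCOH values over the 49 interhemispheric pairs. Control bands are theta
4–7, low-beta 14–20, high-beta 21–30, gamma 31–50 Hz; the alpha band is the
participant-specific calibration band, chosen for consistency with the
online path.

**Significance.** Which ciCOH values count as "significant" is genuinely
open; the package uses seeded surrogate testing (default 200 surrogates,
alpha 0.05): the observed |ciCOH| is compared with the null distribution
obtained by circularly time-shifting the second signal by a random offset
of at least one window and re-segmenting. The shift preserves the signal's
spectrum and autocorrelation — crucially including the dependence between
90%-overlapping segments, which the null must share with the observed
estimator to be calibrated — while destroying its temporal alignment with
the partner. Two alternatives were evaluated and rejected: whole-signal
phase randomization leaves narrowband signals fully coherent (a global
phase change), producing a degenerate, far-too-wide null; independent
per-segment phase randomization ignores the overlap dependence and was
measurably anticonservative (false-positive rate ≈ 0.5 at alpha = 0.05 on
independent pairs). The circular-shift null holds its nominal rate on
independent pairs (≈ 0.07 measured at alpha = 0.05 with 100 surrogates, the
small excess being the usual finite-surrogate quantile effect). Its known
limitation is the mirror image of its strength: for strictly periodic,
noiseless signals every shift stays coherent and nothing can be declared
significant; physiological signals have finite coherence times.

## The statistical battery

* `rm_anova_oneway()` computes the balanced within-subject decomposition
  directly (the sums of squares are exposed and tested for conservation),
  with partial eta squared, Mauchly's test via `stats::mauchly.test`, and a
  Greenhouse–Geisser df correction applied conditionally when Mauchly's
  p < 0.05. The direct decomposition was preferred over parsing `aov`
  error strata so that the SS components are first-class outputs; the F
  statistic is verified against the squared paired-t identity in the
  two-session case.
* `paired_t_bonferroni()` multiplies p by the number of contrasts, capped
  at 1, and reports the paired-difference Cohen's d.
* `cohen_d_pooled()` is the two-group pooled-SD form used in a priori power
  analysis; it is distinct from the paired-difference d above, and the two
  agree only when the between-condition correlation is 0.5.
* `chi2_2x2()` is Pearson's chi-square *without* continuity correction —
  the closed form `n(ad−bc)² / ((a+b)(c+d)(a+c)(b+d))` — plus the
  two-sided Fisher exact p by probability-mass summation (not tail
  doubling).
* `rm_corr()` estimates the common within-participant slope by analysis of
  covariance with participant as a factor; df = N − k − 1, and a single
  participant degenerates to the ordinary Pearson correlation.
* `jackknife_corr()` reports the full-sample r, the mean leave-one-out r,
  and bias = (n − 1) × (mean LOO r − full r), the standard definition.
* `mixed_model_ihi()` is the random-intercept model
  `ihi ~ erd_contra * erd_ipsi + (1 | participant)` via `lmerTest`
  (Satterthwaite p-values); a singular fit falls back, with a warning, to
  participant-centered least squares. The contract is the model formula,
  not the optimizer.
* `sample_size_paired_t()` searches the smallest n whose two-sided paired
  t-test at level alpha/m reaches the target power, by exact noncentral-t
  power evaluation; it matches `power.t.test` on every case tested. The
  number of planned comparisons entering the Bonferroni divisor of a given
  historical power analysis is often unstated, so no particular published
  n is asserted.

## The synthetic generator

`generate_eeg()` emulates exactly the statistical structure the pipeline
assumes, no more:

* background EEG is pink (1/f) noise plus white sensor noise — real EEG
  shows approximately 1/f spectra on which alpha peaks stand out;
* a mu oscillation (default 10 Hz, configurable within 8–13) rides on C3
  and C4, with a fraction (`neighbor_leak`, default 0.2) on each ring
  channel as a crude stand-in for volume conduction;
* during motor imagery the oscillation amplitude scales by
  `sqrt(1 − ERD/100)`, so band power drops by exactly the configured ERD
  depth; transitions use 200 ms raised-cosine ramps to avoid spectral
  splatter (the transition shape is otherwise unconstrained);
* per-trial depths jitter around the session value (Gaussian,
  `erd_sd` = 10 percentage points by default) so the percentile target
  boxes are non-degenerate;
* MEP amplitudes are lognormal (median `mep_test_mean` = 1 mV, CV 0.3 — a
  stand-in choice, as no trial-level distribution is prescribed anywhere;
  the CV is configurable), and conditioned trials scale by true IHI / 100
  with `true IHI = ihi_intercept + ihi_slope × ERD_ipsi + noise`, linear
  with Gaussian noise as the simplest model consistent with a linear
  correlation analysis; draws below `ihi_floor` are clipped and flagged;
* background EMG for pre-innervation QC is 5–1000 Hz band-limited noise at
  a controlled percentage of MVC.

The cohort generator's latent session targets (mean ipsilateral ERD 40% in
HIGH, 15% in MID and NoFB, −10% in LOW; contralateral 20% in all
motor-imagery sessions; 0% at REST) are fixed once as plausible
neurofeedback outcomes: a well-trained participant roughly doubles the
intrinsic ipsilateral ERD in HIGH and pushes into synchronization in LOW,
while the contralateral side stays constant by design. With the default
coupling (intercept 100, slope −0.8, participant SD 8) these produce
session IHI means near 66/85/108% and a manipulation range near 40% —
physiologically sensible magnitudes.

What the generator does *not* emulate: realistic volume-conduction head
geometry, non-stationary artifacts other than muscle pre-innervation
(ocular, electrode pops), line-noise harmonics beyond the 50 Hz component
the notch removes, and measurement noise on IHI beyond the MEP lognormal —
so passing recovery tests demonstrates correctness of the estimators under
the assumed signal model, not robustness to real-world artifacts.

## Problem sizes

The test suite and examples run calibrations of 6–20 trials, sessions of
2–10 trials through the full signal path, latent cohorts of 22 × 5 × 40
trials, and surrogate tests with 100 draws; these sizes were chosen so the
whole suite completes in about a minute while leaving every recovery check
comfortably inside its tolerance. All generators and tests are seeded; the
same seed reproduces byte-identical arrays.

## I/O formats

Recordings travel as a CSV sample matrix plus a JSON sidecar (sampling
rate, montage, neighbor map, session layout); events as CSV; calibration
profiles as JSON with the full percentile tables; run configurations as
YAML with an explicit seed per stochastic stage. Text serialization
quantizes doubles at 15 significant digits; reading back a recording with a
different expected sampling rate is an explicit error, never a silent
resample.
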