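# erdtms

Closed-loop sensorimotor-rhythm (SMR) neurofeedback with brain-state-dependent
paired-pulse TMS, rebuilt as a desk-scale, fully testable R package.

## The problem

During kinesthetic motor imagery of one hand, the sensorimotor cortex on both
sides desynchronizes its mu-band (8–13 Hz) rhythm. Event-related
desynchronization (ERD) is expressed relative to a resting reference,

```
ERD(t) = (P_ref − P(t)) / P_ref × 100  [%]
```

so positive values indicate desynchronization, complete power loss is exactly
100%, and synchronization is unbounded below. A bivariate neurofeedback
display lets a participant steer the *ipsilateral* ERD up or down while
holding the *contralateral* ERD constant; when the instantaneous bilateral
ERD enters a percentile-defined target box, a conditioning stimulus (CS) is
fired over right M1 followed 10 ms later by a test stimulus (TS) over left
M1. Interhemispheric inhibition (IHI) is then quantified from the evoked
EMG responses:

```
IHI = mean conditioned MEP / mean unconditioned MEP × 100  [%]
```

with smaller values meaning stronger inhibition. The package implements the
full loop — causal online ERD estimation, target-box triggering with a
non-triggered fallback, MEP quality control and IHI, corrected imaginary
coherence (ciCOH) connectivity with a network-intensity summary, and the
statistical battery (repeated-measures ANOVA with Greenhouse–Geisser
handling, Bonferroni paired contrasts, repeated-measures correlation,
jackknife correlation, proportion tests, mixed models, paired-t sample-size
search) — driven by a seeded synthetic EEG/EMG generator with known ground
truth in place of human participants and stimulation hardware.

## Worked example

```r
library(erdtms)

## calibrate the online estimator on a 20-trial synthetic recording
cfg     <- sim_config(erd_depth = c(contra = 20, ipsi = 40))
calib   <- generate_eeg(cfg, session_spec("NoFB", n_trials = 20), seed = 1)
profile <- calibrate(calib$recording)
profile
#> <calibration_profile> bands 8-10 (contra) / 8-10 (ipsi) Hz; origin 20.6 / 41.9 %ERD

## run a closed-loop HIGH session on fresh data
high <- generate_eeg(cfg, session_spec("HIGH", n_trials = 10), seed = 2)
ses  <- run_session(high$recording, profile, seed = 3)
ses$log[c("n_triggered", "mean_wait_from_mi_onset_s")]
#> $n_triggered                [1] 3
#> $mean_wait_from_mi_onset_s  [1] 2.97

## cohort-level battery on 22 synthetic participants
cohort <- simulate_cohort(22, sim_config(), n_trials = 40, seed = 4)
tab    <- cohort_ihi(cohort)
round(tapply(tab$ihi, tab$session, mean), 1)
#>  HIGH   LOW   MID  NoFB  REST
#>  65.7 108.5  84.9  87.1  98.6

rm_anova_oneway(data.frame(participant = tab$participant,
                           session = tab$session, value = tab$ihi))
#> rmANOVA: F(4.00, 84.00) = 56.94, p = 3.808e-23, partial eta^2 = 0.73

means <- tapply(tab$ihi, tab$session, mean)
manipulation_range(means[["HIGH"]], means[["LOW"]])$signed
#> [1] 39.5
```

The session means show the intended bidirectional IHI manipulation: stronger
inhibition (smaller IHI) when the ipsilateral ERD is driven up (HIGH),
weaker when it is driven down (LOW), with MID/NoFB in between — and the
manipulation range is the HIGH-vs-LOW percentage change. The waiting time
and success count are the session's two difficulty indices.

A thin command-line wrapper around the same functions lives in
`inst/cli/erdtms.R`:

```sh
Rscript inst/cli/erdtms.R simulate    --seed 1 --kind NoFB --n-trials 20 --out run
Rscript inst/cli/erdtms.R calibrate   --eeg run/eeg --out run
Rscript inst/cli/erdtms.R run-session --eeg run/eeg --profile run/profile.json --kind HIGH --out run
Rscript inst/cli/erdtms.R all         --seed 1 --out run
```

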