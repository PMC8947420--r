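# dcaflow

Dynamic cerebral autoregulation (dCA) modelling and wavelet statistical
complexity for two-channel hemodynamic recordings: arterial blood pressure
(BP, mmHg) and cerebral blood flow velocity (BFV, cm/s, transcranial
Doppler).

## What it does

**Who it is for.** Physiologists and methods researchers analysing
beat-to-beat BP/BFV recordings (e.g. posture or maneuver protocols) who want
a reproducible, fully offline implementation of two complementary analyses:

1. **Autoregulation index (ARI).** Dynamic FIR / NFIR / ARX / NARX models of
   the BP→BFV relationship are fitted by ν-support-vector regression
   (one-step-ahead training on the first half of a recording, free-run
   validation on the second, exhaustive hyperparameter grid search). The
   fitted model is probed with a negative pressure step; its response is
   gated by three physiological-plausibility criteria and matched (least
   mean-squared difference over 0–10 s) against the ten templates of the
   second-order Tiecks model,

   ```
   x2(n) = x2(n-1) + (x1(n-1) - 2 D x2(n-1)) / (f T)
   x1(n) = x1(n-1) + (dP(n) - x2(n-1)) / (f T)
    V(n) = V_base (1 + dP(n) - K x2(n)),   dP = (P - P_ref)/(P_ref - CrCP)
   ```

   whose per-grade constants (T, D, K) span grade 0 (no autoregulation,
   K = 0) to grade 9 (fastest recovery).

2. **Statistical complexity.** The BFV signal's relative wavelet energy
   distribution `p_j` over octave bands gives the Shannon entropy
   `H = -Σ p_j ln p_j`, the disequilibrium `Q` (normalized Euclidean or
   Wootters distance from uniformity) and the López-Ruiz complexity
   `C = H_norm · Q`, the coordinates of the complexity–entropy plane.

Around these sit the standard preprocessing chain (spline gap repair, Hampel
outlier filter, zero-phase 20 Hz Butterworth, beat detection and averaging,
2.5 Hz resampling, min–max normalization to [-1, 1]), cohort statistics
(Shapiro–Wilk, paired t / Wilcoxon with a hemisphere-merging rule,
repeated-measures ANOVA with Tukey HSD, ROC/AUC), and a synthetic cohort
generator (pulsatile BP + Tiecks-model BFV at known grades) so the whole
pipeline is testable without any recorded data.

## Worked example

```r
library(dcaflow)

spec <- synthetic_cohort_spec(n_subjects = 1, postures = "lay",
                              duration_s = 300, ari_grade_per_posture = 5L,
                              noise_sd = 0.02, seed = 11)
rec  <- generate_recording(spec, 1, "lay")      # BP + Tiecks-grade-5 BFV
prep <- preprocess_recording(rec$bp, rec$bfv)
prep
#> <preprocessed_recording> 742 samples @ 2.5 Hz, 301 beats
#>   BP range 71.36..78.52 mmHg | BFV range 54.77..63.03 cm/s

fit <- grid_search(prep$p, prep$v, "narx",
                   p_norm = prep$p_norm, v_norm = prep$v_norm)
fit$model
#> <trained_flow_model> NARX: n_p = 2, n_v = 1, 371 training samples, 187 SVs
round(fit$cc_val, 3)
#> [1] 0.993

estimate_ari(fit$model, require_plausible = FALSE)
#> <ari_estimate> grade = 6 (plausible: FALSE); best MSE 0.103 at template 6

complexity_entropy_point(prep$v_beat)
#> <complexity_point> H = 1.0274 nats, H_norm = 0.5280, Q = 0.3540, C = 0.1869
#>   db4 wavelet, 7 levels, euclidean distance
```

The free-run validation correlation (0.993) says the NARX model reproduces
the unseen half of the flow signal; the step-response match lands one grade
above the generating grade 5 (the template bank is coarse at 2.5 Hz), and
the plausibility verdict flags that this particular model's long-run plateau
drifts past the +10% band — the gate reports model quality separately from
the matched grade. `run_full_pipeline()` does the same per cohort and adds
the group statistics; `inst/scripts/run_pipeline.R` wraps it for the shell.

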