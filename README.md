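# stnbeta

Subthalamic beta-band LFP biomarkers of deep-brain-stimulation efficacy in
Parkinson's disease.

After a DBS lead (four contacts, 2 mm center-to-center) is implanted in the
subthalamic nucleus (STN), resting local field potentials recorded from the
lead carry exaggerated beta-band (13–35 Hz) oscillations — the canonical
electrophysiological marker of parkinsonian motor impairment. This package
implements, as a tested pipeline, the analysis linking those recordings to
stimulation outcome, for clinical neurophysiologists and methods
researchers who want to reproduce, stress-test, or extend it:

- **Preprocessing** — common-average reference, robust (median/MAD)
  artifact-window screening, LOWESS detrending (512-sample span).
- **Spectral features** — Welch PSD (1-s Hann, 50% overlap, 1-Hz bins),
  power normalized to the 5–55 ∪ 65–95 Hz reference total, band powers
  (θ 4–7, α 7–13, low-β 13–20, high-β 20–35, low-γ 40–55 Hz), per-band
  maxima across contacts, 10–35 Hz peak frequencies.
- **Clinical outcomes** — UPDRS-III hemibody subscores and stimulation
  efficacy 100 × (OFF-stim − ON-stim)/OFF-stim under medication withdrawal,
  with contralateral STN↔hemibody pairing and explicit inclusion rules.
- **Lead geometry** — contact labels (C0–C3 left, C8–C11 right) and
  center-to-center distances between the stimulation contact and the
  maximum-power contact.
- **Association statistics** — Spearman and partial (rank) correlation,
  Mann–Whitney U (exact at small n), paired t, and the two-predictor OLS

  improvement = β₀ + β₁·P_high-β + β₂·d + ε,

  with 95% CIs, R², and the overall F(2, n−3).
- **Synthetic cohorts** — a fully seeded generator (1/f^χ background,
  narrowband beta oscillations with Gaussian depth profiles, 60-Hz mains,
  outcome draws from the published model β₁ = 0.425, β₂ = −0.026 with noise
  calibrated to R² = 0.374), so the entire pipeline runs and is validated
  without any patient data.

## Worked example

```r
library(stnbeta)

cfg <- sim_config(seed = 42, duration_s = 30)   # short demo recording
g <- generate_lfp_side(cfg, patient_index = 14, side = "left")
g$recording
#> <lfp_recording> P14/left: 4 channels x 30.0 s @ 2048 Hz [C0, C1, C2, C3]

extract_side_features(g$recording)[, c("power_low_beta", "power_high_beta",
                                       "contact_high_beta", "peak_freq_hz")]
#>   power_low_beta power_high_beta contact_high_beta peak_freq_hz
#> 1          0.217           0.616                 0           24
```

The extracted maximum high-beta fraction (0.616 of reference power, on
contact C0, spectral peak at 24 Hz) recovers this side's analytic ground
truth (0.607, contact 0). A full cohort and the outcome regression:

```r
plan <- cohort_plan(sim_config(seed = 42))      # 26 patients x 2 sides
sum(!plan$poor_quality)
#> [1] 50
fit_outcome_model(plan)
#> OLS fit (n = 50): R^2 = 0.365, F(2, 47) = 13.485, p = 2.35e-05
#>          term estimate    ci_lo     ci_hi       se      t        p
#> 1 (Intercept)  0.20787  0.08752  0.328229 0.059826  3.475 0.001110
#> 2       power  0.56811  0.23465  0.901575 0.165759  3.427 0.001277
#> 3    distance -0.02097 -0.03889 -0.003056 0.008907 -2.355 0.022758
```

One 50-side cohort refit scatters around the generating model (slope 0.425
per unit normalized power, −0.026 per mm, 37.4% explained variance);
averaging refits over 200 seeded cohorts recovers it closely (see below).
The packaged 26-patient characteristics table reproduces its summary
statistics:

```r
s <- cohort_summary(load_table1())
#> age 61.0, duration 14.4, OFF-med UPDRS-III 45.0, 9 women, 7 tremor-dominant
```

`run_pipeline(run_config("out_dir", seed = 1))` executes
simulate → validate → extract → associate → report end to end and writes
the band-by-domain correlation grid, the covariate grid, the regression
JSON, and a markdown report; `inst/scripts/stnbeta-pipeline.R` exposes the
same stages as shell subcommands.

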