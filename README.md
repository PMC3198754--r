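# perovol

Slice-based optoelectronic leg volumetry, its reproducibility, and daytime
bias correction — for clinicians and methodologists who monitor leg edema
with repeated volume measurements and need to know which part of an observed
change is real.

An optoelectronic leg scanner records the front and side silhouette widths
of a standing leg every 4.7 mm, models each slice as an ellipse (area
πab, circumference by Ramanujan's approximation
π[3(a+b) − √((3a+b)(a+3b))]), detects the anatomic landmarks on the
circumference profile — ankle minimum **B**, calf maximum **C**, below-knee
**D**, mid-thigh **F** — and integrates the lower leg (**leg_BD**) and the
whole limb (**limb_BF**).

Repeated measurements disagree for three quantifiable reasons, and the
package estimates all three from two-visit, duplicate-measurement cohorts:

* **CV_A** — analytical (device) noise, from within-visit duplicates:
  s²_A = Σd²/2n;
* the **orthostatic shift** — the second immediate standing replicate reads
  systematically higher (paired *t* test on replicate 1 vs 2);
* **CV_W** and **ICC(1,1)** — between-visit within-subject variability and
  one-way intraclass correlation of the visit means, part of which is a
  **diurnal drift** of roughly 0.29 %/h (lower leg) and 0.26 %/h (limb).

The drift is removable: regressing the between-visit percent change on the
signed clock-time difference Δt gives a correction formula

```
Δ%corr = Δ%meas − c · Δt        c = 0.288 %/h (leg_BD), 0.259 %/h (limb_BF)
```

which the package can apply to single cases, or to whole cohorts (as
V2 / (1 + c·Δt/100)) with the variance components recomputed before and
after. Because no raw data from the underlying study are public, the package
also ships a fully parameterised synthetic cohort generator that reproduces
the study design (63 subjects × 2 legs × 2 visits × 2 replicates, visit
times free in 08:00–18:00) and the reported effect sizes, so every estimator
is validated by parameter recovery.

## Worked example

Single-case correction — a trial participant measured at 3000 ml (09:30) at
baseline and 3020 ml (14:45) three weeks later:

```r
library(perovol)
apply_time_correction(3000, "9:30", 3020, "14:45",
                      published_coefficients()$coeff_legBD)
#>   measured change : +0.67 %
#>   time difference : +5.25 h
#>   coefficient     : 0.288 %/h
#>   corrected change: -0.85 %
```

The apparent +0.67 % volume increase is an artifact of the later measurement
time; corrected for 5.25 h of diurnal swelling the leg actually *shrank* by
0.85 %. (The unrounded measured change is used internally — rounding first
would give −0.84.)

Full cohort analysis on a simulated study:

```r
rec <- simulate_cohort(cohort_config(n_subjects = 63, seed = 20))
fit <- volrep(rec)    # derives coefficients from this cohort's own regression
fit
#> Leg volumetry reproducibility analysis
#>   504 measurements, 63 subjects
#>
#> daytime correction coefficients (derived):
#>   leg_BD : 0.269 %/h
#>   limb_BF: 0.280 %/h
#>   [legBD] n = 126 legs, r^2 = 0.320, 95% CI 0.199 to 0.339, p = 5.2e-12
#>   [limbBF] n = 126 legs, r^2 = 0.340, 95% CI 0.211 to 0.349, p = 7.6e-13
#>
#> Crude vs corrected within-individual CV [%] and ICC:
#>   side volume_type cv_a_pct cv_w_pct_crude icc_crude cv_w_pct_corrected
#>   left       legBD   0.5771          1.522    0.9916              1.292
#>   left      limbBF   0.7407          1.350    0.9924              1.228
#>  right       legBD   0.5653          1.552    0.9919              1.149
#>  right      limbBF   0.8199          1.674    0.9911              1.191
#>  icc_corrected
#>         0.9939
#>         0.9936
#>         0.9955
#>         0.9955
```

Reading the output: device noise is ~0.6–0.8 % (CV_A); visit-to-visit
agreement is ~1.4–1.7 % before and consistently lower after daytime
correction, with ICC rising toward 1 — the correction removes a real,
systematic bias. `summary(fit)` adds the replicate-shift (orthostatic)
table and all regression fits; `coef(fit)` returns the two coefficients;
`plot(fit)` draws the change-versus-Δt scatter.

Geometry on its own:

```r
prof <- generate_leg_profile(leg_shape_params(), slice_thickness = 4.7)
measure_leg(prof)
#> Leg volumes: leg_BD 3123.1 ml, limb_BF 4947.9 ml
#> Leg landmarks (slice index @ height mm from sole):
#>   B (ankle min)        27 @   124.6
#>   C (calf max)         71 @   331.4
#>   D (below knee)      105 @   491.2
#>   F (mid-thigh)       138 @   646.2
```

A file-based pipeline (`run_pipeline()`, YAML-configured) and a thin CLI
(`inst/cli/perovol.R` with `simulate|measure|analyze|correct|pipeline`
subcommands) wrap the same functions for shell use.

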