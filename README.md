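# patlakr

Quantitative dynamic PET analysis in R: Patlak net-influx-rate estimation
with fitted and extrapolated arterial input functions, SUV and
tumor-to-blood ratio (SUR) extraction with uptake-time correction, and
intrascan test–retest repeatability statistics — driven by a synthetic
tracer-kinetics and voxel-phantom generator.

## The problem

In oncologic PET the standardized uptake value (SUV) of a viable tumor
keeps rising after injection, so any mismatch in uptake time between two
scans contaminates the comparison. Three families of metrics address this:

- **K_i**, the Patlak net influx rate. For a tracer trapped irreversibly
  in tissue, the graphical transform
  *x(t) = ∫₀ᵗ C_p dτ / C_p(t)*, *y(t) = C_t(t)/C_p(t)*
  becomes linear once blood and free tissue equilibrate; its slope is
  *K_i = K₁k₃/(k₂+k₃)* (reported here ×100, in mL/min/100 mL), which is
  ideally uptake-time independent but requires dynamic imaging and an
  arterial input function (AIF) C_p(t).
- **cSUV**, the uptake-time-corrected SUV:
  *cSUV = SUV·(T_c/T₀)^(1−b)*, rescaling a measurement at actual uptake
  time T₀ to a reference time T_c (60 min), with a tracer-specific
  exponent *b* (0.313 for FDG; 0.63 for DOTATATE, derived empirically
  from early/late SUV pairs).
- **cSUR**, the corrected tumor-to-blood ratio: *SUR = SUV/SUV_blood*,
  *cSUR = SUR·T_c/T₀* — exact when SUR grows linearly in time, the
  Patlak-like regime.

`patlakr` implements the full chain and the repeatability framework used
to compare these metrics between an early (~35–50 min) and a late
(~75–90 min) acquisition, each built from three 5-min whole-body passes:
test–retest Δ and %Δ (difference over pair mean), |%Δ|, 95% limits of
repeatability (μ ± 2σ), absolute-agreement ICC(A,1), R², and exact
Wilcoxon signed-rank tests. Because no patient scans ship with the
package, a first-class synthetic module generates two-tissue-compartment
lesion kinetics (irreversible FDG-like, k₄ = 0; partially reversible
DOTATATE-like, k₄ > 0), Feng-type input functions measurable only to
50 min (forcing late-window extrapolation, with hematocrit correction
K_i/(1−hct) for DOTATATE), and small 4D voxel phantoms with an aortic
blood-pool tube.

## Worked example

Simulate a 10-subject FDG-like cohort, quantify every lesion on the early
and late windows, and summarize repeatability:

```r
library(patlakr)

cfg <- pipeline_config(cohort = cohort_config(n_subjects = 10), seed = 42)
res <- run_pipeline(cfg)
dplyr::select(res$summary, metric, n, mean_pct_delta,
              median_abs_pct_delta, icc, r_squared)
#> # A tibble: 10 × 6
#>    metric        n mean_pct_delta median_abs_pct_delta   icc r_squared
#>  1 ki_max       26          4.97                  7.01 0.938     0.913
#>  2 ki_peak      26          1.03                  4.70 0.986     0.974
#>  3 suv_max      26         42.3                  41.2  0.469     0.967
#>  4 suv_peak     26         41.8                  40.5  0.595     0.983
#>  5 csuv_max     26         -2.77                  2.69 0.996     0.998
#>  6 csuv_peak    26         -3.26                  2.97 0.998     1.000
#>  7 sur_max      26         63.8                  62.5  0.268     0.942
#>  8 sur_peak     26         63.4                  61.9  0.382     0.969
#>  9 csur_max     26         -0.320                 1.48 0.998     0.997
#> 10 csur_peak    26         -0.801                 1.36 0.999     0.999
```

Reading the table: SUV_max and SUR_max drift up by ~40–60% between the
windows (mean %Δ) and their absolute-agreement ICCs collapse (0.27–0.47)
even though R² stays high — the systematic early-to-late shift, not
scatter, destroys agreement. K_i and the corrected metrics are
uptake-time stable: |mean %Δ| < 5% and ICC ≥ 0.94. Note the small
*positive* residual drift of K_i,max: the late window is analyzed with an
AIF extrapolated from the pre-50-min fit, whose mild underestimation of
late blood activity pushes late K_i up — the same mechanism the
repeatability framework is designed to expose.

A single lesion end to end:

```r
aif <- make_aif("feng_exponential_sum", scale = 0.5)
kp  <- kinetic_params(K1 = 0.1, k2 = 0.3, k3 = 0.15)   # true Ki = 3.33
tac <- simulate_tissue_tac(kp, aif, make_schedule())
fit <- fit_patlak(patlak_points(tac, aif), window = c(75, 90))
glance(fit)
#> # A tibble: 1 × 4
#>      ki intercept r_squared n_points
#> 1  3.33     0.150     1.000        3
```

`autoplot(fit)` draws the Patlak plot; `plot_bland_altman()` and
`plot_pct_delta_box()` visualize the report tables from `run_report()`.

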