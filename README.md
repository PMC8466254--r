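# guidedev

Accuracy analysis for static computer-assisted implant surgery (sCAIS).

In guided implant surgery, an implant is planned on a fusion of a digital
dental cast with the patient's CBCT scan and placed through a
stereolithographic drill guide. Accuracy studies then compare the planned
and the actually placed fixture. `guidedev` provides the complete analysis
chain for such studies, for clinical researchers and for methodologists
simulating the error budget:

* **Registration** — point-based rigid best-fit (`rigid_point_register()`)
  of cast-space landmarks to CBCT-space landmarks, the superimposition used
  both for dental-surface points and for fiducial markers. Closed-form
  Kabsch/SVD solution of `min Σ ||R s_i + t − t_i||²` with reflection
  correction, fiducial registration error (FRE) reporting, and
  target-registration-error (TRE) diagnostics for simulation studies.
* **Deviation metrics** — `measure_deviations()` computes the six standard
  outcomes between planned and placed implants: global deviation
  `||p' − p||` at platform and apex, lateral deviation (component of the
  center displacement perpendicular to the planned axis), signed depth
  deviation (along the planned axis, positive = deeper), and angular
  deviation between the axes. The decomposition satisfies
  `global² = lateral² + depth²` exactly. `safety_flags()` screens records
  against a 2-mm planning margin and the 1.2 mm / 0.5 mm
  horizontal/vertical expected system error.
* **Synthetic cohorts** — `generate_cohort()` simulates seeded study
  cohorts: a parabolic dental arch with surface landmarks and template
  fiducials, a true cast-to-CBCT transform, isotropic marker noise versus
  buccal-lingually inflated surface noise (a metal-streak artifact
  surrogate), guide mechanical error, and a 56-implant factor design
  (registration method 21/35, jaw 23/33, guide support 28/20/8).
* **Statistics** — `two_sample_t()` (pooled/Welch, raw samples or published
  `mean ± SD, n` summaries), `one_way_anova()` with `tukey_kramer()`
  multiple comparisons, Type III unbalanced `factorial_anova()`,
  `pooled_mean()` table-consistency arithmetic, and
  `sample_size_two_group_t()`.

Everything is data-frame-first and pipe-friendly; fitted objects support
`tidy()`/`glance()`, and `plot_deviation_box()` / `autoplot()` give the
standard figures.

## Worked example

Simulate a 56-implant cohort, summarise it by registration method, and test
the group contrast:

```r
library(guidedev)

coh <- generate_cohort(seed = 42)

summarise_deviations(coh, by = "registration_method", depth = "absolute")
#> # A tibble: 12 × 5
#>   registration_method metric                  n  mean    sd
#>   <chr>               <chr>               <int> <dbl> <dbl>
#> 1 dental_surface      global_platform_mm     21 0.757 0.402
#> 2 fiducial_marker     global_platform_mm     35 0.545 0.265
#> 3 dental_surface      lateral_platform_mm    21 0.561 0.343
#> 4 fiducial_marker     lateral_platform_mm    35 0.410 0.229
#> # … 8 more rows

gs <- split(coh$lateral_apex_mm, coh$registration_method)
two_sample_t(gs$dental_surface, gs$fiducial_marker)
#> # A tibble: 1 × 9
#>   method                estimate statistic    df p_value mean1 mean2    n1    n2
#> 1 two-sample t (pooled)   0.0962      1.27    54   0.211 0.562 0.466    21    35
```

The dental-surface group shows the larger mean lateral deviation at the
implant apex (0.56 vs 0.47 mm here), driven by the simulated buccal-lingual
artifact noise; at the default noise levels a single 21/35 cohort is usually
underpowered for that contrast (p = 0.21), which is itself informative.
Adjusting for the other design factors:

```r
tidy(factorial_anova(coh, "lateral_apex_mm",
                     c("registration_method", "jaw", "guide_support"),
                     include_interactions = FALSE))
#> # A tibble: 4 × 5
#>   term                  sumsq    df statistic p_value
#> 1 registration_method 0.00449     1    0.0643  0.801
#> 2 jaw                 0.0150      1    0.216   0.644
#> 3 guide_support       0.503       2    3.61    0.0343
#> 4 Residuals           3.56       51   NA      NA
```

Published summary tables can be analysed directly from their printed
numbers:

```r
two_sample_t(list(mean = 1.24, sd = 0.68, n = 21),
             list(mean = 0.92, sd = 0.49, n = 35))$p_value
#> [1] 0.04608515

round(pooled_mean(c(0.97, 1.84), c(56, 18)), 2)  # marginal of 56+18 implants
#> [1] 1.18
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/guidedev.R`
(`guidedev simulate|register|measure|analyze`); see `?cmd_simulate` and
friends. The methods vignette
(`vignettes/guided-implant-accuracy.Rmd`) documents the model, its
parameters and its limitations.

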