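# thrombospectra

Characterisation of aspirated coronary thrombus from hyperspectral
reflectance images, for interventional-cardiology research groups studying
microvascular injury after ST-elevation acute coronary syndrome.

Thrombus retrieved by manual thrombectomy during primary PCI is imaged
frozen on its collection filter; each pixel carries a 150-band reflectance
spectrum (470–900 nm) that distinguishes red-cell-rich thrombus,
plasma/platelet-rich thrombus, contaminating blood, water ice and bare
filter. The package implements the full analysis pipeline plus a
synthetic-data generator with known ground truth, so every stage is
verifiable without patient data (which are not publicly available for this
application).

## What it computes

1. **Two-pass k-means classification.** Pixels pooled across samples are
   clustered into K = 11 groups (k-means++ seeding, multi-restart Lloyd's
   algorithm, deterministic given a seed); thrombus clusters are selected
   automatically by spectral similarity to RBC/plasma mixtures or set
   explicitly. A second K2 = 7 pass on thrombus pixels only yields each
   sample's compositional *k-fraction* profile `f_1..f_7` (non-negative,
   summing to 1) and the thrombus **area fraction** used to audit
   thrombectomy adequacy (score 4–5 and area ≥ 0.22).
2. **Per-pixel spectral unmixing.** Each spectrum is decomposed as
   `S(λ) = c0 + c_plasma S_plasma + c_rbc S_rbc + c_filter S_filter + c_ice S_ice`
   by non-negative (or ordinary) least squares, with χ² goodness-of-fit
   and coefficient maps.
3. **Regression of injury indices on k-fractions.** IMR
   (`hyperaemic Pd × mean transit time`, dichotomised at 40 U) and MVO
   (dichotomised at 1.55% of LV mass) are fitted with four families —
   linear, power, `y = c0 exp(−Σ ck fk)`, and `y = c0 (1 − exp(−Σ ck fk))`
   — ranked by R² (R² > 0.2 flagged notable) with permutation p-values.

See `vignettes/thrombus-spectral-pipeline.Rmd` for the model details,
identifiability gauge, generator design and limitations.

## Worked example

The `analysis/` scripts run the whole study on simulated data
(`Rscript analysis/01_simulate.R` … `04_cohort_models.R`). In miniature:

```r
library(thrombospectra)

basis <- make_basis_spectra(seed = 1)                  # plasma/rbc/filter/ice
scene <- demo_scene(64, 64, noise_sd = 0.02, seed = 5) # known ground truth
sim   <- make_cube(scene, basis, sample_id = "P001")

model <- fit_kmeans(sim$cube, K = 11, seed = 0, n_restarts = 10)
labels <- assign_pixels(model, sim$cube)
ids   <- identify_thrombus_clusters(model, basis)
mask  <- mask_thrombus(labels, ids)
thrombus_area_fraction(mask)
#> [1] 0.2192383          # truth: 0.1879883 (blood patch shares the RBC
#>                        # signature; pass override ids to exclude it)
kfractions(sim$cube, mask, K2 = 7, seed = 0)
#> <kfraction_profile> P001: 898 thrombus pixels (area 0.219)
#>   f: 0.182 0.188 0.117 0.143 0.163 0.094 0.115

cohort <- make_cohort(cohort_spec(40, noise_sd = 6, seed = 21,
                                  score_levels = 3:5))
kept <- filter_successful(cohort)$records              # score 4-5, area >= 0.22
compare_models(dichotomize(kept), "imr", seed = 1, n_perm = 199)
#>     model        r2 p_value  n converged notable
#> 1     exp 0.8570344   0.005 21      TRUE    TRUE
#> 2  linear 0.8455158   0.005 21      TRUE    TRUE
#> 3 sat_exp 0.8450461   0.005 21     FALSE    TRUE
#> 4   power 0.7208869   0.015 21      TRUE    TRUE
```

The ranking table reads: on this simulated cohort (generated from the
exponential model) the exponential family fits best, all families clear
the 0.2 notability bar, and the strongest associations are significant at
the permutation resolution (p = 1/(B+1) = 0.005).

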