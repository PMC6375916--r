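# liverFFQ

Combined morphological and functional liver-MRI analysis in R: spin-lock
**T1ρ relaxometry**, hepatobiliary-phase **relative enhancement (RE)**, and
their quotient, the **fibrosis function quotient (FFQ)**, with the full
diagnostic evaluation that separates cirrhotic from noncirrhotic livers.
It is aimed at quantitative-MRI researchers who want a reproducible,
testable implementation of this biomarker pipeline, exercisable end to end
on synthetic phantoms and cohorts with known ground truth.

## The model

T1ρ-weighted signal decays mono-exponentially with the spin-lock time
T<sub>SL</sub>:

```
ln( S(T_SL) / S0 ) = − T_SL / T1ρ + C
```

`t1rho_fit()` solves this per pixel by ordinary least squares over the
acquisition's spin-lock times (0, 10, 20, 30, 40, 50 ms), yielding a T1ρ
map with a validity mask. The map is aggregated two ways: **T1ρ-cROI**
(mean of up to six small circular right-lobe ROIs) and **T1ρ-wl** (one
whole-liver ROI per slice), both avoiding vessels, lesions and a ~1 cm
edge margin. From pre- and 20-min post-contrast images,

```
RE  = (SI_20min − SI_pre) / SI_pre          (whole-liver ROI means)
FFQ = T1ρ-cROI / RE                          [ms]
```

T1ρ rises with fibrosis, RE falls with lost hepatocyte function, so FFQ
rises on both fronts. `evaluate_biomarkers()` scores all four markers with
empirical ROC curves, trapezoidal AUC (provably equal to the Mann–Whitney
statistic), Youden-index cutoffs, sensitivity/specificity and likelihood
ratios.

## Worked example

```r
library(liverFFQ)

# a noisy phantom with one bright, slowly decaying vessel
sp  <- phantom_spec(grid_shape = c(64, 64), background_t1rho = 50,
                    vessels = list(list(center = c(40, 40), radius = 4)),
                    noise_sigma = 10, seed = 2)
map <- t1rho_fit(simulate_decay_series(sp))
map
#> T1rho map 64 x 64 px: 4096 valid pixels (100.0% of mask)
#>   T1rho: mean 52.41 ms, sd 21.96 ms, range [46.03, 266.39]
#>   fitted on T_SL = {0, 10, 20, 30, 40, 50} ms

rois <- phantom_rois(sp)               # ROI sets excluding the vessel
croi <- aggregate_croi(map, rois$croi) # 49.99 ms  (truth: 50)
pair <- simulate_contrast_pair(sp, 0.70)
re   <- compute_re(pair$pre, pair$post, rois$wl)   # 0.700 (truth: 0.70)
compute_ffq(croi, re)                  # 71.44 ms
```

The raw map mean (52.4 ms) is pulled up by the vessel; the ROI protocol
with vessel exclusion recovers the true 50 ms. A synthetic cohort at the
published group parameters (47 cirrhotic / 166 noncirrhotic) then yields:

```r
co <- generate_cohort(cohort_spec(seed = 1))
evaluate_biomarkers(co)
#> Diagnostic performance (cirrhosis vs none)
#>   biomarker        orientation  auc cutoff sensitivity specificity  plr  nlr
#>  t1rho_croi higher_is_positive 0.74  47.85        0.89        0.54 1.93 0.20
#>    t1rho_wl higher_is_positive 0.59  48.29        0.87        0.48 1.66 0.27
#>          re  lower_is_positive 0.79   0.67        0.87        0.59 2.13 0.22
#>         ffq higher_is_positive 0.83  75.71        0.85        0.69 2.77 0.21
```

One simulated cohort is noisy; averaged over many seeds the AUCs settle
near 0.74 (cROI), 0.60 (wl), 0.74 (RE) and 0.77 (FFQ), with FFQ the
strongest single marker — the composite outperforms either ingredient.
`run_pipeline(pipeline_config(seed = 1))` chains all stages (phantom →
NIfTI → map → biomarkers → cohort → report) with byte-identical reruns
under a fixed seed.

See `vignettes/liverffq-methods.Rmd` for the model assumptions, parameter
choices and limitations.

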