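---
title: "Methods: T1rho relaxometry, relative enhancement and the FFQ"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: T1rho relaxometry, relative enhancement and the FFQ}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liverFFQ)
```

## The problem

Liver cirrhosis is usually staged invasively. Two MRI-derived quantities
offer a noninvasive alternative that this package combines:

* **T1rho** (spin-lattice relaxation in the rotating frame), measured during
  a continuous spin-lock radio-frequency pulse. It is sensitive to slow
  macromolecular motion and therefore rises with fibrotic remodelling of the
  parenchyma — a *morphological* marker.
* **Relative enhancement (RE)** of a hepatocyte-specific contrast agent
  (Gd-EOB-DTPA) in the hepatobiliary phase (~20 min after injection).
  Functioning hepatocytes take the agent up, so RE *falls* as liver function
  deteriorates — a *functional* marker.

Their quotient, the **fibrosis function quotient**

$$\mathrm{FFQ} = \frac{T_{1\rho}\text{-cROI}}{RE} \quad [\mathrm{ms}],$$

rises with disease on both fronts at once and is the composite biomarker of
interest.

## T1rho mapping

The signal of a spin-lock series decays mono-exponentially with the
spin-lock time $T_{SL}$:

$$\ln\!\frac{S(T_{SL})}{S_0} = -\frac{T_{SL}}{T_{1\rho}} + C.$$

`t1rho_fit()` performs, at every pixel, an unweighted ordinary least-squares
regression of $\ln S$ on $T_{SL}$ and reports $T_{1\rho} = -1/\text{slope}$,
the intercept $C$, the implied amplitude, and a per-pixel $R^2$. The
acquisition modelled here uses $T_{SL} \in \{0, 10, 20, 30, 40, 50\}$ ms on
two slices (3 cm cranial and caudal of the hilus), 128 × 128 pixels over a
30 cm field of view (≈ 2.34 mm/px).

Numerical choices:

* **All six images are used by default.** Acquisition protocols of this
  type acquire six images but promise only that "at least five" enter the
  fit; `tsl_subset` selects any subset. On noiseless data every ≥ 5-point
  subset returns the identical $T_{1\rho}$ (tested), so the choice only
  matters under noise.
* **$S_0$ is the measured signal at the smallest used $T_{SL}$.** Dividing
  by $S_0$ only shifts the intercept, never the slope, so the estimate is
  invariant to global signal scaling (tested). When $T_{SL}=0$ is excluded,
  the amplitude is simply absorbed into $C$.
* **Nonpositive signals are dropped sample-wise** (their logarithm is
  undefined); a pixel with fewer than `min_samples = 5` usable samples, or
  with a non-negative fitted slope (no decay), is flagged invalid rather
  than raising an error — flat vessels and background behave this way by
  design.
* **No variance reweighting, no spatial smoothing, no inter-frame
  registration.** The log-domain fit is kept deliberately plain; a
  nonlinear signal-domain fit exists in the test suite purely as an
  independent oracle, and the two agree to a fraction of a millisecond at
  clinically realistic SNR.

## ROI protocols and biomarkers

Two aggregation protocols are implemented, mirroring manual reading:

* **cROI** — up to three circular ROIs (2–3 cm diameter) per slice on the
  right liver lobe, up to two slices, six ROIs total.
  `aggregate_croi()` returns the *unweighted mean of per-ROI means*,
  treating each ROI as one observation as the protocol literature does; a
  pooled-pixel alternative is available by flag, and the two coincide
  exactly only when all ROIs have equal pixel counts (tested both ways).
* **wl** — one ROI covering the whole liver per slice;
  `aggregate_wl()` averages the per-slice means with equal weights.

Exclusions: vessels, tumor/ablation areas and a ~1 cm edge margin.
The margin is implemented as an exact Euclidean-disc erosion of the liver
mask (`erode_mask()`), with the physical distance converted through the
pixel spacing (default 10 mm ≈ 4.3 px at 2.34 mm/px). Whether published SI
averages weight slices by area or equally is unstated; equal-slice
weighting was chosen and is flagged here.

`compute_re()` forms $RE = (SI_{20\min} - SI_{\text{pre}})/SI_{\text{pre}}$
from whole-liver ROI means averaged across slices; it is invariant to
global multiplicative rescaling of both images (tested). `compute_ffq()` is
the plain quotient and requires $RE > 0$.

A deliberate arithmetic point: FFQ summary statistics are subject-level
means of ratios, **not** ratios of group means — with the published group
means, $51.11/0.59 = 86.63$, which differs from the published group-mean
FFQ of 89.53. The cohort generator therefore computes FFQ per subject.

## The synthetic-data module

No patient images are publicly available, so validation runs on synthetic
data with known ground truth at the published study conditions.

**Phantoms** (`phantom_spec()`, `simulate_decay_series()`,
`simulate_contrast_pair()`) are circles-on-background: parenchyma with
constant $T_{1\rho}$ (default 50 ms, the order of magnitude of liver),
optional lesion discs with their own $T_{1\rho}$, and vessel discs that are
bright (2 × S0) and decay slowly (default apparent $T_{1\rho}$ of 250 ms,
qualitatively blood-like). The slow — rather than perfectly flat — vessel
decay is a design choice: a flat profile is rejected by the fit as invalid
and could never bias an ROI mean, whereas a bright, slowly decaying vessel
demonstrates measurably how whole-liver ROIs that fail to exclude vessels
overestimate $T_{1\rho}$ (tested directionally). Noise is additive
Gaussian on the magnitude image by default — it keeps the log-linear fit
unbiased at high SNR — with Rician noise (magnitude of a complex Gaussian
perturbation) available, which exhibits the expected low-signal magnitude
floor (tested).

**Cohorts** (`cohort_spec()`, `generate_cohort()`) draw, per group,
`(t1rho_croi, re)` from a bivariate normal and `t1rho_wl` from its own
normal at the published group parameters
(`reference_group_params()`): cROI 51.11 ± 3.45 vs 47.56 ± 4.17 ms, wl
50.44 ± 3.16 vs 49.14 ± 4.21 ms, RE 0.59 ± 0.11 vs 0.70 ± 0.13, with group
sizes 47 (cirrhosis) and 166 (none). Choices made where the study reports
nothing:

* **Within-group correlation between T1rho and RE defaults to 0** — no
  joint distribution is published. The observed pooled negative correlation
  then emerges purely from the group-mean separation; the closed-form
  mixture covariance predicts $r \approx -0.12$, close to the published
  $-0.14$, which is reassuring evidence that little or no within-group
  correlation is needed to explain the data. The parameter is exposed for
  sensitivity analyses.
* **RE positivity by truncation-with-redraw**, not clipping, so the FFQ
  distribution acquires no atoms; an impossible configuration fails loudly
  after a bounded number of redraw rounds.
* **FFQ is the per-subject ratio by default.** For diagnostic-performance
  simulations the generator can instead draw FFQ from its published group
  Gaussians (89.53 ± 19.84 vs 70.83 ± 15.56) via
  `reference_group_params(include_ffq = TRUE)`; this matches the binormal
  reasoning used to verify the simulated AUCs. The two modes give similar
  FFQ moments — the ratio mode's means are ≈ 89.6 and ≈ 70.3 by the
  delta-method inflation of a ratio of independent normals.
* **Prior-intervention labels** are assigned at the overall study rate
  (150/213) in both groups, as a label only; no biomarker shift is
  attached to it.

What the generator does *not* emulate: spin-lock pulse-sequence physics,
B0/B1 inhomogeneity, breathing or pulsation artifacts, anatomical shape,
within-subject measurement error of the reading process, or any
non-Gaussian tails in the biomarker distributions. Passing simulation
checks therefore validates the *analysis*, not the acquisition: they show
that the pipeline recovers known inputs and that Gaussian groups at the
published parameters reproduce the published discrimination, which is
evidence of internal consistency of those published values, not of
real-data performance.

## Diagnostic evaluation

A positive is the presence of cirrhosis. For each biomarker,
`roc_curve()` builds the empirical curve over all observed thresholds;
T1rho-cROI, T1rho-wl and FFQ rise with disease, RE falls and is ranked on
the negated score — for strictly positive scores this is the same ordering
as the reciprocal transform (tested), so the choice between the two is
immaterial. Cutoffs are always reported on the original scale, with the
rule "positive if ≥ cutoff" for rising markers and "positive if ≤ cutoff"
for RE.

* `roc_auc()` integrates by the trapezoid rule, which on every dataset
  equals the Mann–Whitney pair-counting statistic with ties counted ½
  (tested exactly on 100 random cohorts).
* `youden_cutoff()` maximises $J = \text{sens} + \text{spec} - 1$;
  ties are broken toward the most sensitive threshold, a deterministic and
  documented convention.
* `likelihood_ratios()` is the exact algebraic identity
  $PLR = \text{sens}/(1-\text{spec})$, $NLR = (1-\text{sens})/\text{spec}$,
  with flagged infinities at the boundaries. Applied to operating points
  reconstructed from subject counts, it recovers the published PLR/NLR for
  the cROI, wl and FFQ columns; the published RE PLR (1.84) is not
  consistent with its own published sensitivity/specificity (the identity
  gives 1.74), so the package reports the identity-consistent value and
  this discrepancy is simply documented rather than second-guessed.
* `compare_groups()` uses the pooled-variance Student's t-test (Welch by
  flag), two-sided; `pearson_r()` the standard correlation test. No
  multiple-testing correction and no AUC confidence intervals are applied,
  matching the original analysis plan.

The simulated cutoffs are *reported but never asserted*: the Gaussian
surrogate shifts the Youden optimum (the binormal crossing for cROI lies
near 50.3 ms, not at the published 48.34 ms), so only AUCs, group moments
and the pooled correlation are reproduction targets.

## Pipeline and reproducibility

`run_pipeline()` chains phantom generation, NIfTI export (RNifti, with the
spin-lock times in a JSON sidecar and the pixel spacing in the header),
map fitting, ROI measurement, cohort generation and diagnostic reporting.
One global seed is expanded into per-stage child seeds so stages can be
rerun in isolation; reruns under the same configuration are byte-identical
(tested), and every output directory carries a provenance JSON with a
fingerprint of the full configuration, seed included.

## Problem sizes used in the tests

The suite runs phantoms of 16–48 px squares and six spin-lock times, which
is ample for exact closed-form checks; Monte-Carlo checks use 150–1000
replicates; cohort-moment checks use 10^5 subjects per group; and the
simulation reproductions use 200 cohorts of 47/166 subjects, the study's
own group sizes. These sizes keep every check well inside a laptop-scale
run while leaving Monte-Carlo error far below the assertion tolerances.

## Known limitations

* Circles-on-background phantoms have no anatomical realism; vessel and
  lesion geometry is schematic.
* ROI placement is an input, not a computed segmentation; there is no
  vessel detection or registration.
* The Gaussian cohort surrogate cannot reproduce cutoffs, only
  distribution-level quantities (AUC, moments, pooled correlation).
* Rician noise is available but the acceptance-level simulations use the
  Gaussian model; at the SNR of the modelled acquisition the difference is
  negligible except near signal nulls.
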