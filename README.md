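# bsiquant

Semi-automatic **bone scan index (BSI)** quantification for planar
whole-body bone scintigraphy, together with the survival machinery used to
evaluate BSI as a prognostic factor in metastatic castration-resistant
prostate cancer (mCRPC).

On a ^99m^Tc-diphosphonate bone scan, the BSI expresses the skeletal
metastatic burden as a single percentage: the area of "ill" skeleton
relative to the imaged area of the patient. The package implements the
semi-automatic reading scheme in which the operator picks **one pixel** of
diseased skeleton and the software

1. selects every pixel with intensity ≥ the seed's intensity (inclusive
   global threshold),
2. clusters the selection into 8-connected ROIs by border following and
   measures each contour's area with the discrete Green's-theorem
   (shoelace) integral,
3. lets the operator exclude ROIs that are not metastatic (bladder,
   fractures) and adjust contrast in a limited multiplicative range
   `[0.5, 2]`, and
4. reports `BSI = 100 · |ill pixels| / |body ∪ ill pixels|` per view and
   combined across the anterior/posterior pair, with the body silhouette
   estimated by Otsu thresholding of log-counts.

Because no patient scans or outcome data are distributable, the package
also ships two calibrated generators that make every stage testable:

* `generate_phantom()` — synthetic planar scan pairs (procedural skeleton
  silhouette, Poisson counting noise, focal lesions, bladder hotspot) with
  pixel-level ground truth;
* `simulate_cohort()` — six-centre mCRPC-like cohorts whose covariate
  marginals, Weibull proportional-hazards survival (median OS 13 months,
  event fraction 326/370) and per-unit hazard ratios are calibrated to a
  published 370-patient multicentre population.

The prognostic pipeline mirrors the published analysis: Kaplan-Meier
product-limit estimation with log-log CIs (`km_estimate()`),
centre-adjusted Cox regression (stratified baseline, Efron ties,
centre-clustered sandwich SEs; `cox_fit()`), and forward stepwise model
selection by AIC (`stepwise_aic()`).

## Worked example

```r
library(bsiquant)

# a phantom with 3 % of the skeleton involved
ph <- generate_phantom(phantom_config(lesion_fraction = 0.03, rng_seed = 7))
ph$truth$true_bsi_percent
#> [1] 3.586104

res <- quantify_views(
  list(ph$ant, ph$post),
  seeds = list(seed_from_truth(ph$ant,  ph$truth$lesion_mask),
               seed_from_truth(ph$post, ph$truth$lesion_mask_post)),
  exclude_mask = list(ph$truth$bladder_mask, ph$truth$bladder_mask_post))
res
#>   ANTERIOR  ill    263 / body   8033 px  BSI  3.274%
#>   POSTERIOR ill    260 / body   8033 px  BSI  3.237%
#>   combined BSI 3.255%  (2 ROI(s) excluded)
```

The per-view lines show the ill-pixel numerator, the silhouette-union
denominator and the resulting percentage; the two excluded ROIs are the
bladder hotspot in each view. The recovered 3.255 % sits a few percent
below the 3.586 % truth because the automated seed (the 10th-percentile
lesion pixel) deliberately captures ~90 % of the lesion area — see the
methods vignette.

```r
# a cohort at the study's size, and the univariate prognostic fit for BSI
d  <- simulate_cohort(cohort_config(n = 370, rng_seed = 1))
km_estimate(d)
#> <km_result> n=370, events=323, median 14.7664 months (95% CI 12.47702-16.48662)
cox_fit(d, "bsi")
#>   covariate       coef       hr  robust_se   ci_low  ci_high            p   n n_events
#> 1       bsi 0.09764818 1.102575 0.02463809 1.050596 1.157125 7.392011e-05 370      323
```

At n = 370 the hazard ratio per BSI percentage point (1.10, 95 % CI
1.05–1.16) scatters around the generator's true univariate effect; at
n = 20,000 it converges to it.

A command-line front end is installed at `inst/exec/bsi`
(`bsi quantify`, `bsi phantom`, `bsi cohort-sim`, `bsi survival`).

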