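# asymtopo

Topological analysis of hemispheric brain asymmetry, and its association
with behavior.

## The problem

Deformation-based asymmetry imaging produces, per participant, a 3D volume
in which each voxel holds the difference between a brain's local volume and
that of its mirrored homologue: bright voxels mark structures larger on that
side. Two long-standing hypotheses link such asymmetries to reading-related
skill:

* **Cerebral lateralization** — more asymmetry, better performance: a linear
  association between asymmetry magnitude and a standardized behavioral
  score (phonological decoding, mean 100, sd 15).
* **Canalization** — asymmetry constrains performance toward the average:
  the *upper envelope* of asymmetry over the behavior axis is an inverted U
  ("sandpile"), so the most asymmetric individuals score near 100 while
  extreme scorers show little asymmetry.

`asymtopo` implements the full measurement and inference chain for both
hypotheses, for neuroimaging researchers who want to apply it, audit it, or
benchmark it on simulated data:

1. **Asymmetry images** — `flip_subtract()` builds exactly antisymmetric
   volumes from (optionally Gaussian-smoothed) Jacobian volumes.
2. **Topological measurement** — `sublevel_2cycles()` computes the 2-cycle
   (cavity) persistence pairs of the sublevel-set cubical filtration: each
   bright structure enclosed by darker tissue is one pair, its *birth* the
   enclosing boundary level and its *death* the peak asymmetry value. Pairs
   are assigned to atlas regions by their peak voxel (`assign_pairs()`).
3. **Landscapes** — the first persistence landscape
   `lambda(t) = max over pairs (b,d) of max(0, min(t - b, d - t))`,
   sampled at 15 grid positions spanning the pooled sample range
   (`make_grid()`, `landscape_first()`); the 13 interior positions enter
   statistics (`build_matrix()`).
4. **Association models** — per position: linear regression of residualized
   decoding on the landscape value (`fit_linear()`, with
   `d = 2t/sqrt(df)` effect sizes), or 99th-percentile quadratic quantile
   regression of the landscape value on decoding
   (`fit_quantile_sandpile()`), where a negative quadratic term is the
   canalization signature.
5. **Uncertainty and correction** — chained-equations imputation with
   predictive-mean matching (`chained_imputation()`), participant bootstrap
   (`bootstrap_pool()`), pooling over all imputations x draws
   (`pool_over_imputations()`), sign-split `alpha < 0.05` thresholding
   (`threshold_mask()`), permutation run-length extent correction
   (`extent_null()`, `apply_extent()`), and a two-sample replication gate
   (`replication_gate()`).
6. **Synthetic cohorts** — `simulate_cohort()` generates asymmetry volumes,
   parcellations and behavioral tables under null, linear, or canalized
   coupling with known ground truth, so every stage above is testable
   without any imaging data.

`run_pipeline()` executes the whole chain on two cohorts. A thin command
line (`inst/cli/asymtopo.R`) exposes `simulate`, `persist`, `landscape`,
`analyze` and `correct` subcommands.

## Worked example

Two simulated cohorts of 400 participants with a linear
asymmetry-performance coupling of r = 0.3, analyzed end to end:

```r
library(asymtopo)

spec_a <- cohort_spec(n = 400, coupling = "linear", target_r = 0.3, seed = 1)
spec_b <- cohort_spec(n = 400, coupling = "linear", target_r = 0.3, seed = 2)
fit <- run_pipeline(simulate_cohort(spec_a), simulate_cohort(spec_b),
                    analysis_config(B = 200, m = 2, n_perm = 2000, seed = 42))

subset(fit$results_a, scope == "hemisphere_left",
       c(position, estimate_linear, t, p_pooled_t, cohen_d))
#>  position estimate_linear       t p_pooled_t  cohen_d
#>         2          -76.61 -2.2895   2.26e-02 -0.22952
#>         3          -76.47 -2.2863   2.28e-02 -0.22920
#>         4          -76.48 -2.2866   2.27e-02 -0.22923
#>         5           -2.95 -0.0914   9.27e-01 -0.00916
#>         6           36.11  5.1439   4.23e-07  0.51568
#>         7           23.60  6.8777   2.37e-11  0.68949
#>         8           17.95  7.0562   7.65e-12  0.70739
#>         9           18.50  7.0141   1.00e-11  0.70317
#>        10           20.68  6.8136   3.53e-11  0.68307
#>        11           24.69  6.4230   3.81e-10  0.64392
#>        12           31.44  5.6827   2.57e-08  0.56969
#>        13           41.57  4.2751   2.39e-05  0.42858
#>        14           85.97  3.1112   2.00e-03  0.31190

fit$report$hemisphere_left$positive$intersection
#> [1]  6  7  8  9 10 11 12 13 14
fit$headline
#> [1] TRUE
```

Each row is one landscape position: `estimate_linear` is the change in
residualized decoding score per unit of landscape value (the magnitude of
the most asymmetric left-hemisphere structure whose span covers that
boundary level), `t` and `p_pooled_t` are pooled over 2 imputations x 200
bootstrap draws, and `cohen_d = 2t/sqrt(df)`. Mid-to-high positions carry
the structure-magnitude signal, so that is where the planted coupling
appears (d up to 0.71 here); the replication report lists the positions
whose extent-corrected effects appear in *both* cohorts with the same sign,
and the headline flag fires only when that intersection is nonempty. The
right hemisphere, where the simulated structures are uncoupled from
behavior, shows no replicated effect.

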