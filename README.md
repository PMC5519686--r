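# morphpair

Matched-pair voxel-based morphometry for multi-site case-control studies
of brain structure, with permutation inference.

## The problem

Mass-univariate morphometry on Jacobian-determinant images (the local
volume change needed to register a brain to a template) is easily
confounded in retrospective multi-site samples: total brain size covaries
strongly with every voxel, research sites differ in scanners and
sampling, and both are correlated with case status. morphpair implements
the matched case-control workflow for this setting:

- **Profile classification** — deterministic expert rules on the
  percentile scale (Poor Decoder / Poor Comprehender / Generally Poor
  Reader / Control), validated by a random forest (500 trees, mtry = 2)
  under leave-one-out cross-validation, with classical multidimensional
  scaling of the class probabilities.
- **Matching** — coarsened stratification by research site and
  smaller/larger brain size, logistic propensity scores, greedy
  nearest-neighbor pairing of unique cases and controls within strata,
  and balance diagnostics (paired t, Yates chi-square for sex, propensity
  t/ANOVA).
- **Voxelwise inference** — propensity residualization, case-minus-control
  difference images, one-sample sign-flip and two-sample label-permutation
  tests with threshold-free cluster enhancement
  (TFCE(p) = Σ<sub>h</sub> e<sub>h</sub>(p)<sup>E</sup> h<sup>H</sup> dh,
  defaults H = 2, E = 0.5, 26-connectivity) and familywise error
  correction by the permutation distribution of the image-wide maximum;
  Cohen's d maps, cluster tables, ROI summaries, covariate control
  (Freedman–Lane), correlations.
- **Bootstrap** — repeated well-matched versus randomly matched
  re-pairings of the same subjects, quantifying how matching quality
  shapes the voxel-level t distributions.
- **Bias simulation** — demonstrates that residualizing a nuisance highly
  collinear with case status, without matching first, inflates type-I
  error (monotonically in the collinearity), while matching-first
  analysis stays nominal.
- **Synthetic data** — a seeded generator emulating the multi-site
  structure (8 sites, 134 children, case status confounded with brain
  size and site, focal case effects in ellipsoidal regions), so the whole
  pipeline is testable without restricted imaging data.

## Worked example

```r
library(morphpair)

cfg <- run_config(output_dir = "run1",
                  cohort = cohort_config(seed = 2),
                  n_perm = 500, n_boot = 50, seed = 9)
bundle <- run_all(cfg)
make_report(bundle)
```

```
subjects: 134  pairs: 44  unmatched: 46
cluster 1: 115 voxels, peak (22, 14, 2) mm, peak t=10.67, min p=0.0020
cluster 2: 93 voxels, peak (-14, -26, 18) mm, peak t=8.29, min p=0.0020
...
  cluster 1 / PoorDecoder (n=25 pairs): t(24)=15.23, p=0.0000
  cluster 2 / PoorComprehender (n=13 pairs): t(12)=7.67, p=0.0000
...
bootstrap mean pooled t: well=4.96 random=3.11
```

The synthetic cohort injected case expansions in two ellipsoids centered
near (−22, −18, 16) and (18, 8, 4) mm; the matched-pair analysis recovers
both as FWE-significant clusters whose peaks sit inside the injected
regions, reuses them for per-profile subgroup t-tests (every profile
contributes, as in a common-effect design), and the bootstrap shows the
well-matched design yielding consistently higher pooled t than random
cross-site pairing of the same subjects. The classifier side of the run:
LOOCV ensemble accuracy 1.00 on the rule-consistent synthetic profiles
and a two-dimensional embedding with goodness of fit 0.88.

Balance for the matched pairs (same run):

```
    variable        test  statistic df      p
         age    paired_t      0.232 43  0.817
   gm_volume    paired_t     -1.561 43  0.126
   wm_volume    paired_t      0.290 43  0.773
  brain_size    paired_t     -2.329 43  0.025
         sex chisq_yates      0.000  1  1.000
  propensity  unpaired_t      0.601 86  0.549
```

(Synthetic cases are built 40 cm³ smaller on average; residual size
imbalance in a given seed is exactly the kind of thing the balance report
is for.)

Lower-level entry points: `generate_cohort()`, `generate_volumes()`,
`classify_expert_rules()`, `classify_ensemble_loocv()`, `classical_mds()`,
`stratify()`, `fit_propensity()`, `pair_nearest()`,
`balance_diagnostics()`, `residualize()`, `permutation_fwe()`, `tfce()`,
`extract_clusters()`, `run_bootstrap()`, `simulate_bias()`. A thin CLI
lives at `inst/cli/morphpair` (`run-all`, `bias-sim`; JSON config).

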