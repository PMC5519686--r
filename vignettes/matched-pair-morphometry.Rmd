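---
title: "Matched-pair morphometry: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matched-pair morphometry: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphpair)
```

## The problem

Voxel-based and tensor-based morphometry compares brain structure between
groups on registered images. In retrospective multi-site samples of
children, two nuisance sources can dominate the focal group effects of
interest: total brain size (which covaries strongly with local
Jacobian-determinant values, because a smaller brain must expand more to
fit a common template) and research site (scanner, protocol and sampling
differences). Both are typically confounded with case status — children
with reading disabilities tend to have smaller brains, and case
prevalence varies across contributing sites. morphpair implements a
matched case-control workflow for this setting: behavioral profile
classification, coarsened stratification with propensity-score
nearest-neighbor pairing, voxelwise residualization, paired permutation
inference with threshold-free cluster enhancement (TFCE), bootstrap
assessment of matching quality, and a simulation of the bias introduced
when a collinear nuisance is residualized without matching.

## Statistical machinery

**Propensity and residualization.** Case status is modeled by logistic
regression on research site (factor) and total brain size; voxel
intensities are residualized on the resulting score by per-voxel ordinary
least squares, with the voxel grand mean restored so adjusted images stay
on the Jacobian scale. Because a scalar score cannot encode eight site
offsets exactly, and the voxel-score relation inherits the logit
nonlinearity, residualization removes nuisance variance only
approximately — which is precisely why matching is done first.

**Stratification and pairing.** Within each site, subjects are split at
the site-wise median brain size ("smaller"/"larger"); site-by-bin cells
lacking either a case or a control are dropped. Within each retained
stratum, cases (processed by descending distance of their score from the
stratum mean, ties by id) greedily take the unused control minimizing the
equal-weighted sum of standardized propensity and brain-size gaps. The
weights, the coarsening quantile, and an optimal-assignment mode are
configurable; the defaults are deliberately simple because the original
weighting is not recoverable.

**Inference.** One-sample designs (case-minus-control difference images)
use sign-flipping; two-sample designs permute labels. Every permutation
recomputes the t map, enhances it with TFCE
(\(\mathrm{TFCE}(p) = \sum_h e_h(p)^E\, h^H\, \mathrm{d}h\), defaults
\(H=2\), \(E=0.5\), \(\mathrm{d}h = h_{\max}/100\), 26-connectivity — the
canonical parameters of the method), and records the image-wide maximum;
corrected p-values come from that maximum distribution, identity
permutation included, so \(p \ge 1/(P+1)\). With 12 or fewer pairs the
sign-flip null is enumerated exactly (\(p = k/2^n\)). Thresholds run over
\(h = \mathrm{d}h, 2\mathrm{d}h, \dots\) and a voxel participates at
\(h\) when its value is \(\ge h\); a lone suprathreshold voxel of height
1 with \(\mathrm{d}h = 0.1\) therefore scores
\(\sum h^2 \cdot 0.1 = 0.385\). The implementation processes thresholds
descending with an incremental union-find whose nodes carry offsets, so
components keep what they accumulated before merging; a brute-force
per-threshold recomputation backs it in the test suite.

**Covariate control.** Pair differences can be tested while controlling
for a per-pair covariate (for example the case-control gap on a
behavioral embedding dimension), via `diff ~ b0 + b1·covariate`. The
slope is tested by Freedman–Lane permutation of reduced-model residuals;
the intercept by sign-flipping them. The covariate enters uncentered by
default, so the intercept is the brain effect at *zero* behavioral
difference; centering is available when the adjusted-mean reading is
wanted.

## Profile classification

Expert rules are applied on the percentile scale (standard scores, mean
100 and SD 15, converted by the normal CDF; the 25th percentile is 89.88,
the 16th is 85.08). "Typically" clauses in the published rules encode
rater latitude that no program can reproduce; they are implemented as
strict thresholds, and the consistency of Word Identification and Passage
Comprehension with Word Attack is read as "within 10 standard-score
points, or at or below the 25th percentile" (configurable). The rule
engine is total and deterministic; boundary-zone subjects are the known
source of disagreement with human raters.

The ensemble validator is a random forest — 500 bagged CART trees with 2
candidate features per split, the published tuning — over the five
behavioral scores plus age, evaluated by leave-one-out cross-validation;
out-of-fold vote fractions form the probability matrix that classical
multidimensional scaling embeds in two dimensions (double-centered
squared distances, eigendecomposition; goodness of fit is the retained
eigenvalue share; axis signs are fixed by making each dimension correlate
positively with its highest-loading input column). No random-forest
package ships with the target environment, so the forest is implemented
in C++ within the package, including out-of-bag permutation importance
(mean accuracy drop per shuffled feature, in percentage points).

## The synthetic world

The generator states one cohort model and the tests do not move it:

| parameter | default | rationale |
|---|---|---|
| sites × n | 8 sites, 134 children (24,22,20,18,16,14,12,8) | study scale; per-site sizes unpublished, chosen unequal as in multi-site consortia |
| profile mix | Control 67, Poor Decoder 33, Poor Comprehender 22, Generally Poor Reader 12 (/134) | the published matched-sample composition |
| age | normal(9.61, 1.57) in [6, 14]; Poor Comprehenders > 8.3 | published demographics; the profile's age rule |
| sex | 43% female | published |
| tissue volumes | gm normal(740, 60), wm normal(460, 50) cm³ | typical for children of this age |
| case deficit | 40 cm³ smaller total volume | "low brain size is characteristic"; ~0.5 SD |
| site prevalence | case share × spread 0.7–1.3 | case status confounded with site |
| site offsets | ±0.06 additive Jacobian | scanner/protocol differences |
| brain-size coupling | −0.07 per SD | volume-ratio scale: the Jacobian tracks template/subject volume, one SD ≈ 82/1200 ≈ 0.07; makes between-subject variance dominate focal effects, as in the real data |
| noise | SD 0.04 after 8 mm FWHM Gaussian smoothing | spatially correlated registration noise |
| grid | 24³ voxels at 4 mm | desk scale; all algorithms are resolution-agnostic |

Scores are truncated normals inside the percentile windows each profile's
rules imply (margins keep subjects off decision boundaries), so the rule
engine recovers every generated label — a fixture guarantee, not a claim
about clinical data. Case volumes add a fixed amplitude inside
ellipsoidal effect regions; the two defaults stand in for the kind of
parietal and deep white-matter loci such studies report and carry no
anatomical claim.

What the generator does *not* emulate: real registration fields
(smoothness varies anatomically), non-Gaussian site effects, rater
disagreement, longitudinal structure. A green suite therefore establishes
that the machinery is correct and that the design phenomena (pairing
beating unpaired analysis under confounding, bias amplification from
naive residualization) emerge in a world with the stated structure — not
that the published anatomical findings are reproduced; those depend on
consortium images that are not deposited.

## Acceptance-world choices worth knowing

*Effect recovery* (Dice of significant voxels against the injected
region) is evaluated in the noise-limited world — site offsets on,
brain-size coupling and case deficit off — because its premise
"amplitude preset for paired d = 1" is exact only when pair differences
carry noise alone: with coupling, residual within-pair size mismatch both
attenuates d and, with a case deficit, adds a small systematic global
shift that TFCE smears into mask-wide significance. Confound robustness
is what the calibration, sensitivity-ordering, bootstrap and bias
criteria test.

*Bootstrap matching-quality comparison* resamples the members of the
baseline matched pair set in both conditions (within-stratum shuffling
versus cross-site random bijection), so pair counts are identical and
only matching quality differs. Under no confounding the *average* pooled
t shows no systematic ordering, but the two pooled-t distributions are
not literally indistinguishable: the within-stratum pairing space is much
smaller, so its resampling distribution is tighter. The package treats
the run-level ordering of average t as the matching-quality signal and
documents the dispersion difference as inherent to the design.

*Bias simulation.* A pooled residualize-then-test pipeline is actually
conservative under the null; the variant that inflates — and the one the
study's language ("covarying or residualizing") points to — estimates the
nuisance coefficient with case status in the model and then treats the
residuals as raw data, ignoring the coefficient's sampling noise, which
collinearity amplifies by the variance-inflation factor. Its type-I error
grows monotonically with the nuisance-case correlation while
matching-first analysis stays nominal; both the scalar and the voxelwise
variants are exposed.

## Numerical conventions and degenerate inputs

Zero-variance voxels score t = 0 when the mean is zero and a flagged
large finite value otherwise. A constant propensity reduces
residualization to a warning no-op. Perfect separation in the propensity
fit falls back to a small-ridge IRLS fit and is flagged. Exact linear
fits in covariate control are detected (relative tolerance on the
coefficient standard error) and score zero rather than numerical noise.
Near-zero MDS eigenvalues yield zero coordinates; genuinely negative ones
inside the requested dimension error. All randomness is seed-addressed;
exhaustive enumerations are seed-invariant.

## Known limitations

Greedy pairing is order-dependent by design (the deterministic order is
part of the contract); an optimal-assignment mode exists for comparison
but is exponential in stratum size. With only two size bins per site and
no match-quality cutoff (calipers are deliberately out of scope), every
stratum keeps its min(cases, controls) pairs, including poor ones: when
cases genuinely run ~0.5 SD smaller, within-pair size gaps average
30–40 cm³ with a systematic sign, and the paired brain-size balance test
will flag many cohorts. That is a property of coarse stratification
without exclusions, and the balance report exists precisely to surface
it; studies that report clean balance have typically discarded
hard-to-match subjects. The NIfTI codec handles the float32
single-frame images this package writes, not the full standard. TFCE
spatial specificity is limited near strong effects — significant sets
bleed beyond sharp effect boundaries, which is a property of the method,
not of this implementation.
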