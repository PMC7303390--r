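---
title: "Connectome fingerprinting and brain-behavior prediction with connfp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome fingerprinting and brain-behavior prediction with connfp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connfp)
```

## What the package computes

`connfp` implements a connectome-fingerprinting analysis pipeline for
two-session neuroimaging cohorts:

1. **Connectivity matrices.** Functional connectivity (FC) as the Fisher
   z-transformed Pearson correlation of parcel-mean BOLD time series
   (`fcMatrix()`), and structural connectivity (SC) from tractography
   streamlines as three edge weightings (`scMatrices()`): streamline count
   (NS), mean connecting streamline length (ML), and mean quantitative
   anisotropy along the connecting streamlines (QA).
2. **Subject identification.** Cross-session similarity of vectorized
   connectome profiles (`similarityScores()`), argmax identification in
   both session directions (`identifySubjects()`), and a permutation null
   for the pooled accuracy (`permutationTestIdentification()`).
3. **Brain-behavior models.** Connectome-based predictive modeling (CPM):
   per-edge correlation with a behavioral trait, signed edge selection at
   a p threshold, network-strength summation, linear prediction under
   leave-one-out cross-validation (`loocvPredict()`), and
   Benjamini-Hochberg FDR over the full family of trait-by-subnetwork
   models (`runMatrixOfModels()`).
4. **Synthetic cohorts.** A generator with planted ground truth
   (`generateFcCohort()`, `generateStreamlines()`, `generateTraits()`)
   so every stage can be validated without access to restricted data.

## The generative model behind the synthetic cohorts

Edge vectors live in the canonical ordering produced by
`edgeIndexMap()`: upper triangle, row major, `(1,2), (1,3), ..., (2,3),
...`. For a cohort of $N$ subjects and $P$ parcels, the session-$s$ edge
vector of subject $i$ is

$$ x_{i,s} = \mu + f_i + \varepsilon_{i,s}, $$

with a cohort baseline $\mu_e \sim \mathcal N(\mu_0, \sigma_\mu^2)$ drawn
once per cohort per edge, a persistent subject fingerprint
$f_{i,e} \sim \mathcal N(0, \sigma_f^2)$, and session noise
$\varepsilon_{i,s,e} \sim \mathcal N(0, \sigma_s^2)$, all independent.
Traits follow a linear model on the session-averaged weights of planted
effect edges:

$$ y_i = \beta \Big( \sum_{e \in E^+} \bar x_{i,e} -
  \sum_{e \in E^-} \bar x_{i,e} \Big) + \eta_i, \qquad
  \eta_i \sim \mathcal N(0, \sigma_t^2). $$

Defaults (`cohortConfig()`) mirror a two-session resting-state cohort:
144 subjects, 268 parcels, 2 sessions, $\mu_0 = 0.25$, $\sigma_\mu =
0.25$ (a plausible spread of Fisher-z edge weights), and $\sigma_f =
\sigma_s = 0.1$. These values were chosen once for testability: across-
subject fingerprint variance equal to session noise makes identification
succeed at realistic dimensionality while leaving the chance-level and
noise-free limiting cases non-trivial. The variance of the summed effect
signal across subjects is $k(\sigma_f^2 + \sigma_s^2 / S)$ for $k$
planted edges and $S$ sessions; `snrTraitSigma()` returns the
$\sigma_t$ that yields a requested signal-to-noise variance ratio, and at
SNR 1 the population correlation between trait and noiseless signal is
$\sqrt{1/2} \approx 0.707$.

What the generator deliberately does **not** emulate: autocorrelated BOLD
time series (FC matrices are drawn directly in edge space), realistic
white-matter geometry (synthetic streamlines are sinusoidal detours
between cubic parcels), spatially structured session effects, head
motion, or heavy-tailed trait distributions. Passing tests therefore
demonstrate algorithmic correctness and statistical calibration under the
stated model, not robustness to the artifacts of real acquisitions.

Reproducibility contract: every generator draws from its own local
Mersenne-Twister stream seeded from the config (`seed` for the cohort,
`seed + 1` for trait noise) and restores the caller's RNG state, so an
identical config reproduces an identical cohort bit for bit and no global
RNG state leaks.

## Numerical and design choices

* **Fisher z clipping.** Correlations are clipped to $\pm(1 - 10^{-7})$
  before `atanh`, so perfectly correlated parcels give a large finite z
  instead of infinity. Constant time-series columns are an error naming
  the parcel.
* **Edge order.** One canonical edge indexing (upper triangle, row-major)
  is used everywhere; file outputs label edges 1-based. `edgeCount()`
  exposes both the standard unordered pair count ($P(P-1)/2$; 1,326 for a
  52-parcel language network) and the ordered-halved convention
  ($P^2/2$; 1,352) that some reports quote.
* **SC soft weights.** With smooth parcel boundaries a streamline
  contributes mass $w_i(\text{start})\,w_j(\text{end}) +
  w_j(\text{start})\,w_i(\text{end})$ to edge $(i,j)$; products (rather
  than min or max) conserve total mass and reduce to the hard-label tally
  for one-hot weights. Self-connections are excluded; edges with zero
  mass are zero in all three matrices. ML is the mass-weighted mean
  connecting length; with `normalized = TRUE`, NS is divided by the total
  streamline count and ML by the whole-set mean length (the
  normalization is otherwise unspecified in common usage, so both forms
  are recorded in the output metadata). QA per streamline is the mean of
  its per-point values.
* **Bundle assignment.** A streamline belongs to a bundle template when
  at least a fraction `tau` of its points have membership weight above
  0.5; membership is a set, so a streamline crossing two overlapping
  bundles counts toward their bundle pair.
* **Identification ties.** Argmax ties in the similarity matrix are
  broken toward the lowest index with a warning; with real-valued scores
  they have probability zero. Both session directions are computed and
  the pooled accuracy is their mean. The permutation p uses the add-one
  estimator $(1 + \#\{\text{null} \ge \text{obs}\})/(B+1)$ so it is never
  zero; explicit permutation sets can replace sampling for exhaustive
  enumeration at small $N$.
* **CPM conventions.** Default edge-selection threshold $p < 0.01$
  (two-sided per-edge t test); positive and negative networks are modeled
  separately (a combined model is not fitted by default); network
  strength is the unweighted sum over selected edges; missing trait
  values are dropped pairwise per trait, never imputed. Folds whose edge
  set is empty predict the training-fold mean and are flagged; a model
  in which every fold is empty is reported as "no model" rather than a
  number.
* **Subnetwork restriction.** A grouping scheme restricts models to the
  edges with both endpoints in a group (`groupMode = "within"`;
  `"incident"` is available), plus an ungrouped whole-brain row. The FDR
  family is all traits x groups x signs x weight kinds of one run.

## Significance of LOOCV predictions

The predicted-vs-observed correlation $r_{pred}$ from LOOCV-CPM has a
null distribution that is far from the textbook Pearson null, for two
reasons the package had to confront directly:

* Folds with empty edge sets predict leave-one-out training means, which
  are *negatively* correlated with the held-out observation, skewing the
  null of $r_{pred}$ left (null simulations at $n = 200$ show a mean near
  $-0.2$).
* An edge that is significant by chance in the full sample is re-selected
  in nearly every fold, so cross-validation reproduces rather than
  attenuates its chance correlation ("selection leakage"), fattening the
  *positive* tail.

A two-sided t-approximation p is therefore anti-conservative, and even a
one-sided (upper-tail) t p — reported as `p_param` — remains optimistic
in the positive tail. `runMatrixOfModels()` consequently defaults to a
subject-level permutation p (`pMethod = "permutation"`): the trait is
shuffled and the entire LOOCV pipeline, including per-fold edge
selection, is rerun `nPerm` times. In null-cohort simulations (100
replicates, $n = 200$) the permutation route flags FDR-significant rows
in 3% of replicates at $q = 0.05$, versus 14% for the one-sided t route.
The t p remains available (`pMethod = "tapprox"`) as a fast screen. To
make the permutation default affordable, `loocvPredict()` computes
per-fold edge-trait correlations by downdating full-sample sufficient
statistics ($O(nE)$ per model rather than $O(n^2E)$); a test verifies
equivalence with a literal per-fold reference implementation.

## Worked example

```{r example, eval = FALSE}
# a small cohort with a planted positive effect on five edges
cfg <- cohortConfig(
  nSubjects = 120, nParcels = 10,
  effectEdgesPos = c(3, 11, 19, 27, 35), beta = 1, sigmaTrait = 1,
  seed = 7
)
cfg$sigmaTrait <- snrTraitSigma(cfg, snr = 1)
cohort <- generateFcCohort(cfg)

# identification across the two sessions
scores <- similarityScores(
  sessionEdgeMatrix(cohort, 1),
  sessionEdgeMatrix(cohort, 2)
)
permutationTestIdentification(scores, nPerm = 1000, seed = 7)

# CPM with permutation-calibrated FDR
edges <- cohortEdgeMatrix(cohort)
runMatrixOfModels(list(FCz = edges), cohort@traits,
                  pThreshold = 0.01, q = 0.05, seed = 7)
```

## Problem sizes used in the shipped simulations

The package's own validation suite runs: oracle-equivalence checks on
thousands of small random instances; 1,000 fingerprint-free cohorts of
20 subjects for the chance-level identification check; 5 planted-effect
cohorts of 200 subjects against a frozen 500-replicate Monte-Carlo band
for $r_{pred}$ (mean 0.678, SD 0.054 around the $\approx 0.707$
population value); and 30-50 null cohorts of 200 subjects for FDR
calibration. These sizes keep the full suite within a few minutes while
leaving Monte-Carlo error well inside the asserted tolerances.

## Known limitations

* The t-approximation p for $r_{pred}$ is descriptive only; inference
  should use the permutation route (the default).
* The synthetic cohorts draw FC edges directly; nothing is asserted
  about time-series-level preprocessing (filtering, motion regression),
  which is assumed done upstream.
* Streamline handling assumes endpoints are meaningful (no resampling,
  no endpoint dilation); bundle assignment samples every stored point of
  a polyline.
* Identification supports exactly two sessions (reference and target);
  multi-session generalizations are out of scope.
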