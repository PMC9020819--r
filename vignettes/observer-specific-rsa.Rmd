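---
title: "Methods: observer-specific RSA of perceived visual similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: observer-specific RSA of perceived visual similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(idiorsa)
```

This vignette documents the statistical conventions the package
implements, the generative model behind its synthetic-study simulator, and
the design decisions taken where more than one reasonable convention
exists. It states no empirical result beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## The analysis model

### Behaviour RDMs and dissimilarity percentiles

An observer arranges the 4 exemplars of each of 10 categories in a
unit-radius circular arena; perceived dissimilarity is read off as the 6
pairwise Euclidean distances per category. Raw distances have arbitrary,
observer-specific units, so they are converted to **dissimilarity
percentiles**

$$p_i = \frac{\operatorname{rank}(d_i) - 1}{n - 1} \in [0, 1],$$

with averaged ranks for ties, pooled over the observer's $6 \times 10 =
60$ within-category pairs. Pooling scope is a genuine choice: pooling per
category would quantize every category to the same 6 values and destroy
cross-category comparisons, while pooling across observers would leak one
observer's geometry into another's RDM. Per-observer pooling over the 60
within-category pairs keeps RDMs comparable across observers and
modalities while preserving cross-category rank information; it is also
why the simulator applies one arena scale per observer rather than
rescaling each category's arrangement to fill the arena (per-arena
rescaling would erase exactly the cross-category ordinal structure the
pooling relies on — a deliberate simplification relative to real arena
behaviour, noted under limitations).

Percentile conversion is invariant to any strictly monotone transform of
its input; the test suite checks this property directly and against an
$O(n^2)$ pairwise-comparison rank oracle.

### Similarity levels

Per category the 6 percentiles are rank-ordered and split 2-2-2 into
high / medium / low perceived similarity (high = smallest
dissimilarities). To keep levels non-overlapping, whenever the gap across
a level boundary is below `min_gap = 0.1` percentile units, **both**
straddling entries are marked excluded — the rule operates on values, not
categories, and removes the value from each adjacent level, the stricter
of the two readings of an exclusion rule stated only loosely. Ties in the
ranking are broken by canonical pair order, recorded in the output.

### Neural RDMs

Exemplar patterns are the mean over no-response trials (catch trials never
enter pattern analyses); dissimilarity is $1 - r$ (Pearson across
voxels), percentile-converted with the same pooled convention as
behaviour. Conversion happens before any restriction to levels; the
alternative order (restrict, then convert) would make a pair's percentile
depend on which subset is being analysed. Run-wise means exist separately
for decoding folds and split-half stability; the stability partition is
odd vs even runs (the natural unstated default).

### Group inference

All t-tests operate on Fisher-z transformed correlations — uniformly,
rather than only where a transform is strictly required, so that every
family of tests is comparable. Directional hypotheses (r > 0, slope > 0,
accuracy > 0.5, i > 0) use one-sided tests; region contrasts are
two-sided paired t-tests. Bonferroni correction is over regions for
whole-range families and regions × levels for level families. Degenerate
inputs (zero variance across observers) are reported at the machine floor
rather than erroring.

### The i-index and its permutation null

For observer $o$ with brain RDM $B_o$ and behaviour RDM $R_o$,

$$i_o = \operatorname{corr}(B_o, R_o) -
        \frac{1}{n-1}\sum_{p \neq o} \operatorname{corr}(B_o, R_p),$$

and the group statistic is $\bar i$. The null randomizes the observer
labels of the behaviour RDMs: a uniformly random permutation $\pi$ (fixed
points allowed) replaces each within-correlation by
$\operatorname{corr}(B_o, R_{\pi(o)})$ while each observer's mean
correlation over all behaviour RDMs is unchanged, so the whole test needs
only the $n \times n$ cross-correlation matrix and each permutation draw
is $O(n)$ — `n_perm = 10000` is the default. The p-value uses the add-one
convention (never exactly 0); the reported SEM is the standard deviation
of the null distribution, the plainest reading of an
"SEM estimated by randomization". For level subsets, correlations against
observer $p$'s behaviour RDM are restricted by **p's** partition — the
rating owner defines which pairs count, matching the own-vs-other logic of
the behavioural analysis.

### Decoding

Decoding is pairwise (two-class) per exemplar pair, which maps one-to-one
onto the RDM's pair support and aggregates naturally by similarity level;
a multiclass variant would not respect the level structure. The
classifier is a linear SVM with cost fixed at 1 (no tuning), features are
standardized with training-fold statistics only, and folds are runs
(leave-one-run-out), so no trial ever appears on both sides. Degenerate
training data yields chance (0.5) with a warning rather than an error.

## The synthetic study

The generator's defaults are the study conditions for every test: 23
observers, 10 categories × 4 exemplars, 8 runs in which every exemplar
appears 3× as a no-response trial and once as a catch trial (160
trials/run, 75% no-response, 24 no-response presentations per exemplar).

### Latent similarity structure

Each category owns a planar exemplar configuration embedded in a
category-specific 2-D plane of an 8-D latent space. Planarity is a
deliberate choice: a 2-D arena can express a planar 4-point configuration
without distortion, so noiseless arrangements recover the true distance
ranks exactly — making "recovery under vanishing noise" a meaningful
invariant. Generic 8-D 4-point configurations would make classical
scaling to 2-D lossy and the invariant unattainable. The planes differ
across categories, so the exemplar set as a whole still spans the space.

Exemplars come in close **twins** around two well-separated subcluster
centres (centre spread 1.1, minimum separation 1.2, twin jitter drawn per
category from 0.15–0.4), so each category's 6 distances span a wide range
and the three similarity levels are non-degenerate — the high-similarity
level is populated by genuinely hard, fine-grained pairs.

Observer idiosyncrasy has two scales. Cluster-level offsets
(`sigma_observer = 1.8`) move whole twin clusters, constrained orthogonal
to the centre axis so that an observer's cross-cluster distances reshuffle
in rank but never undercut the twin distances; exemplar-level offsets
(`sigma_observer_fine = sigma_observer / 3`) perturb individual exemplars
and carry the fine-grained idiosyncrasy. A graded-similarity guarantee
caps every twin separation at 0.8× the smallest cross-cluster distance in
each observer's geometry (successively smaller caps avoid exact ties), so
"most similar" means the same *kind* of pair for every observer even
though its identity and spacing differ — as in stimulus sets built around
graded similarity. With `sigma_observer = 0` all observers share one
structure, the null condition for the own-vs-other analyses.

### Regions

A simulated ROI mixes four signal channels into its voxel patterns
through a fixed random read-out: fine shared geometry (`w_shared`),
**coarse** shared geometry in which twins are indistinguishable
(`w_coarse`), the observer's own fine geometry (`w_observer`), and
intermediate feature vectors (`w_intermediate`); plus per-trial Gaussian
noise. The defaults operationalize a representational hierarchy:

| region | w_shared | w_coarse | w_observer | w_intermediate | sigma_noise |
| --- | --- | --- | --- | --- | --- |
| EVC-like | 0 | 0.3 | 0 | 1.0 | 3 |
| LOC-like | 0 | 1.0 | 0 | 0.5 | 3 |
| PrC-like | 0.3 | 0 | 1.0 | 0 | 1.2 |
| noise | 0 | 0 | 0 | 0 | 1 |

Posterior regions resolve coarse distinctions only — their inability to
separate twins is structural, not a noise accident — while the PrC-like
region carries fine-grained, observer-specific structure. This is what
produces the qualitative dissociation the acceptance suite checks:
whole-range brain–behaviour correlation wherever there is signal,
high-similarity correlation, positive i-index and above-chance
fine-grained decoding only in the PrC-like region.

Every trial pattern additionally rides on a fixed baseline activation map
(`sigma_baseline = 2`, per observer × region), representing the common
stimulus-evoked topography of an ROI. This matters numerically: $1 - r$
between raw low-dimensional patterns is an angular distance whose
fine-pair ranks are scrambled by differences in pattern norms across
categories; around a common baseline the correlation distance becomes
locally monotone in the underlying Euclidean distances, and the noiseless
recovery invariant (Spearman ≈ 1 against ground truth) holds.

Intermediate feature vectors follow the **coarse** geometry
(`alpha_intermediate = 0.1` of the centre coordinates, the rest
feature noise at centre level, plus a whisper of exemplar jitter): they
distinguish dissimilar objects but carry almost no fine-grained
information, the way intermediate-feature models separate object kinds
but not highly similar exemplars.

### Behaviour

On same-category catch trials the probability of an (incorrect)
same-exemplar response follows a logistic curve in the observer's own
perceived similarity of the repeated pair (base rate 0.15 at
mid-similarity, slope 3 logit units per unit similarity), and RTs grow
linearly with similarity (0.18 s per unit, Gaussian noise 0.15 s) — so
errors and RTs increase across low → medium → high similarity, more
steeply under the observer's own partition than under others'. Misses
(4%), same-exemplar errors on exact repeats (4%) and false alarms on
no-response trials (2%, a free parameter no real-data value constrains)
keep the logs realistic without dominating scoring.

### Trial sequences

Sequences are built constructively: the 120 no-response tokens are ordered
greedily so that consecutive tokens never share a category (with a
majority-category forcing rule to avoid dead ends), then each catch token
is attached directly after a compatible host presentation — the same
exemplar for exact repeats, a same-category different exemplar otherwise.
Restarts are bounded; an infeasible design fails with the violated
constraint named. Catch trials can therefore never open a run, and the
75% / 24-presentation arithmetic holds by construction for any feasible
configuration.

## What the simulator does and does not emulate

It emulates: the factorial design and trial arithmetic; arena behaviour
with placement noise (`sigma_place = 0.02` arena units); graded
within-category similarity with shared and observer-specific components
at two spatial scales; a posterior-to-medial-temporal fidelity gradient;
similarity-coupled 1-back performance; and feature-model coupling.

It does not emulate: haemodynamics or GLM estimation (patterns are taken
as estimated); per-arena rescaling of arrangements (see above); the
scale-dependence of real intermediate-feature models (the simulated
EVC-like region can retain some fine-grained feature signal real EVC may
lack); or realistic effect sizes — simulated within-subject correlations
are far stronger than single-subject fMRI values, so passing tests
demonstrate that the machinery detects structure that is present and stays
silent when it is absent, not that real data would yield effects of this
size. Two consequences are visible in the reported numbers: leave-one-out
intersubject agreement of simulated cohorts runs somewhat above typical
real cohorts because the twin/cross skeleton is shared by construction,
and the average-rating vs model-RDM correlation is inflated for the same
reason.

## Numerical choices and degenerate inputs

* All-equal dissimilarities: percentiles are 0.5 with a warning.
* Zero-variance patterns make $1 - r$ undefined: a data error naming the
  exemplar, not a silent NA.
* Constant correlations across observers: t statistics reported as ±Inf
  with the p-value at the machine floor.
* Identical classes in a decoding fold: accuracy 0.5 with a warning.
* Flat image windows in S1: response 0 (the centred-norm denominator is
  thresholded at 1e-6, which also absorbs FFT round-off).
* Every random draw flows from named seeds; stage seeds derive
  deterministically from the study seed, observer index and stage tag, so
  identical seeds reproduce every artifact bit-for-bit and region names
  act as independent streams.

## Problem sizes used by tests and the acceptance script

Module tests run on 4–8 observer cohorts with 2–4 runs and 12–40 voxels.
The end-to-end dissociation check uses the full default design (23
observers, 8 runs, 60 voxels, three regions, 1 000 label permutations,
high-level decoding). Statistical calibration uses 200 null cohorts of 10
observers with 30-voxel regions, two runs' worth of exemplar
presentations and 199 permutations per test — enough replicates for a
binomial 95% interval around the nominal 5% level. The own-vs-other null
check runs three independent shared-structure cohorts and requires the
majority to be non-significant, testing the property rather than a single
5%-risk draw. The HMAX model checks use 32–48 px procedural textures, a
4-orientation × 4-size bank and 12–20 patch dictionaries; these sizes
exercise every layer of the hierarchy against naive oracles without
large-image cost.

## Known limitations

* Arena placement noise and the common per-observer scale are stylized;
  real arrangement sessions involve multiple partial arrangements and
  evidence-weighted averaging that the package does not model.
* The i-index SEM convention (null-distribution SD) is one reasonable
  reading; bootstrap SEMs over observers would be an alternative.
* Decoding is pairwise only; no multivariate noise normalization or
  hyperparameter search is provided, by design.
* The C2 model is a compact reimplementation with standard parameter
  schedules; numerical equality with any particular external HMAX
  implementation is not a goal, and its dictionary is sampled from the
  analysed images rather than a universal natural-image set.
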