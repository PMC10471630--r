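---
title: "Eigen-microstate analysis of spontaneous activity: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eigen-microstate analysis of spontaneous activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(basicmodes)
```

## The model

Spontaneous brain activity recorded over $N$ nodes and $M$ time points can be
viewed as a sequence of *microstates*: each column $A_t$ of the node-by-time
matrix is the whole-system activity pattern at one instant. After each node's
time course is standardised (zero mean, unit sample variance over time) and
the per-subject matrices are concatenated, the ensemble matrix $A$ is divided
by the root-sum-square of its elements — a dataset-dependent constant $S$ —
so that the total variance equals one.

The economy-size singular value decomposition $A = U \Sigma V^\top$ then
yields the *basic modes* (eigen-microstates)

$$E_i = A v_i = \sigma_i u_i ,$$

each a fixed spatial pattern whose contribution to the instantaneous activity
at time $t$ is the temporal coefficient $v_{ti}$. The weight
$w_i = E_i^\top E_i = \sigma_i^2$ is the fraction of ensemble variance
carried by mode $i$; the normalisation guarantees $\sum_i \sigma_i^2 = 1$.
Unlike plain PCA, which summarises relations between variables (nodes), the
eigen-microstate view is organised around the spatial similarity between
*time points*, and the modes read directly as typical activity patterns.

Because the SVD leaves the sign of each singular vector free, the package
applies a deterministic convention — each mode is flipped so its
largest-magnitude element is positive, ties broken by the lowest node index —
so repeated runs and cross-condition comparisons are stable.

## Selecting the leading modes

A mode is *leading* when it passes three criteria:

1. **Scree elbow.** The rank lies strictly before the elbow of the weight
   curve, located by the Kneedle algorithm (convex/decreasing branch,
   evaluated on the raw weight points; sensitivity 1 by default). The search
   covers the first `n_top = 30` ranks by default.
2. **Mean-weight threshold.** The weight exceeds $1/N$, the average over all
   $N$ possible modes.
3. **Permutation significance.** The weight exceeds its rank-matched null at
   level $\alpha = 0.05$. The null shuffles the node labels within every
   time column — destroying spatial organisation while preserving each
   microstate's value multiset — and recomputes the weight pipeline.

The leading set is the longest prefix of the weight ordering passing all
three. We additionally report a p-value for the *summed* weight of that
prefix against the same null; this aggregate test is an interpretation layered
on top of the three per-mode criteria, and is labelled as such in the output.

Two numerical points deserve mention. First, the permutation null
re-standardises the shuffled node time courses within each concatenated
segment before renormalising (`rezscore = TRUE`). Shuffling the standardised
values alone leaves the observed ensemble with exactly unit row variances
while the shuffled instances have slightly inflated weight spreads, and the
test becomes markedly conservative (measured rejection rate below 1% at
nominal 5% on pure noise); recomputing the standardisation restores
approximate calibration (measured ≈ 3.5% at nominal 5% over 200 pure-noise
replicates at $N = 50$, $M = 500$, 200 permutations). Second, p-values use
the add-one estimator $(1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{perm})$
with ties counted against the observed value, so they are never zero.

## Functional connectivity as a superposition of coactivations

On standardised time courses the functional connectivity is exactly the
Pearson correlation,
$\mathrm{FC}_{ij} = \tfrac{1}{M-1}\sum_t A_{it} A_{jt}$ (sample scaling —
the reason the package z-scores with $M - 1$). Substituting the SVD gives

$$\mathrm{FC}_{ij} = \frac{S^2}{M-1} \sum_{k} E_{ik} E_{jk} ,$$

so each mode contributes a rank-one *coactivation pattern*
$\tfrac{S^2}{M-1} E_k E_k^\top$, and truncating the sum at $k$ modes yields a
low-rank FC reconstruction; at full rank the identity is exact (to machine
precision, asserted in the tests). The $S^2$ factor undoes the ensemble
normalisation. Reconstructed diagonals are reported as computed rather than
forced to one: their approach to unity is a useful convergence diagnostic.
Similarity between FC matrices is Pearson correlation over the strictly
lower triangle; the diagonal is excluded because original-FC diagonals are
constant and would contribute no variance.

## Fingerprinting

Given per-subject FC matrices from two runs, the similarity table entry
$(i, j)$ correlates subject $i$'s run-1 FC with subject $j$'s run-2 FC.
Identification is correct when the row-wise argmax is the diagonal; exact
ties are counted incorrect (they indicate a degenerate configuration) and
reported with a warning. Because the query direction is not symmetric, both
directions are computed and their mean reported alongside. Differential
identifiability is $I_{diff} = (I_{self} - I_{others}) \times 100$ with
$I_{self}$ the mean diagonal and $I_{others}$ the mean off-diagonal
similarity.

## Two-state comparison

Modes are compared across conditions by correlating every pair of patterns
and solving the one-to-one assignment that maximises the summed absolute
correlation (Hungarian method), keeping the sign of each matched
correlation, so rank inversions and sign flips between conditions are
explicit rather than silent.

Node-level amplitude differences of a chosen mode are tested with a paired
permutation scheme: the observed statistic is the difference between the
two states' group-mode patterns (each computed from the per-state
concatenated ensemble), and the null flips each subject's state labels
independently and recomputes both group modes. Every recomputed mode is
re-matched and sign-aligned to the fixed state-A reference before
differencing — without this step the SVD's sign and order indeterminacy
corrupts the null. P-values are two-sided with the add-one estimator;
Benjamini–Hochberg FDR is applied across nodes (and, for the system-level
test, across the 28 within/between system pairs, within-system averages
excluding the diagonal). Inside the permutation loop group modes are
obtained by eigen-decomposing the summed per-subject session
cross-products, which is mathematically identical to re-running the SVD
pipeline and keeps 500-permutation tests in seconds. The test operates on
the $\sigma$-scaled patterns $E_i$ (not the unit-norm $u_i$): amplitude
changes of a mode are part of its effect, not a nuisance.

## Spatial-autocorrelation-preserving surrogates

Map-to-map similarity inherits the spatial smoothness of both maps, so naive
permutation tests overstate significance. The surrogate generator randomises
a map while preserving its binned variogram (25 equal-width distance bins
over the node-pair distances): each surrogate is a random permutation of the
map values, smoothed through squared-exponential distance kernels on a
log-spaced grid of length scales, and the surrogate is the *mixture* of
these smoothed versions (plus the raw permutation) whose variogram best
matches the original map's, fitted by count-weighted relative least squares
(BFGS with analytic gradients). A single scale plus affine rescaling cannot
track a given realisation's variogram across all bins; the mixture does,
except in the extreme-distance bins that contain only a handful of node
pairs, where any single map's empirical variogram is dominated by sampling
noise. An optional rank-remapping replaces surrogate values by the original
values in rank order, preserving the exact value multiset. Distances are
straight-line Euclidean, not geodesic — a documented simplification. The
resulting test (two-sided on $|r|$) is calibrated: on independent targets
the rejection rate at $\alpha = 0.05$ sits inside the binomial confidence
band (asserted in the test suite).

## What the synthetic cohorts emulate — and what they do not

The generator plants $K$ orthonormal spatial modes over $N$ nodes. Each raw
pattern mixes a system-block component (one random level per functional
system; seven canonical cortical systems by default) with a spatially smooth
component (white noise averaged through a squared-exponential kernel on the
node coordinates), making patterns system-dependent and spatially
autocorrelated like empirical mode maps. Sessions superpose the modes with
geometric strengths (`default_mode_spectrum`: variance ratio 0.55 between
successive modes, leading variance 2) on band-limited temporal loadings
(moving-average-smoothed white noise, window ≈ 5 samples, standing in for
the 0.01–0.08 Hz band of BOLD recordings), orthogonalised in-sample, plus
i.i.d. Gaussian noise (sd 0.2 by default). Subjects receive a fixed random
tangent perturbation of every mode (scale 0.3 by default), reused across
runs, which creates the stable signatures fingerprinting needs; the second
state of a paired design flattens mode 1 toward its global mean level,
folding the lost contrast into the state-B spectrum so that mode-1 activity
genuinely weakens — the planted analogue of reduced spatial inhomogeneity
after sleep deprivation, which also reproduces the expected downstream
signatures (amplitude changes opposite in sign to the original amplitudes;
anti-correlated system pairs moving toward zero).

Two design choices matter for interpretation:

* **Variance balancing.** After orthonormalisation the basis is iterated
  toward constant spectrum-weighted row norms, so the planted signal
  variance is spatially homogeneous. The pipeline's first step standardises
  each node; with heterogeneous planted variance that standardisation warps
  the planted geometry and caps mode recovery around $|r| \approx 0.93$
  regardless of noise level. Balancing makes recovery well-posed
  ($|r| > 0.95$ per mode at the default noise) while leaving the patterns'
  system structure intact.
* **Spectrum spacing.** With temporal loadings that are only approximately
  orthogonal *in population*, closely spaced mode strengths mix neighbouring
  modes. The default geometric spacing keeps adjacent weights separated;
  loadings are additionally orthogonalised in-sample.

The generator does **not** emulate hemodynamics, scanner drift, motion
artefacts, non-Gaussian noise, or geodesic cortical geometry. Passing tests
therefore demonstrate the correctness and statistical behaviour of the
*method* under a known low-rank model, not its performance on real fMRI
data. Choices with no stated empirical anchor (spectrum, smoothness 15 on a
100-unit cube, subject-effect 0.3, flattening 0.6) were fixed once at values
a practitioner would call realistic for a strong low-dimensional resting
cohort, and the cohort manifest records them.

## Problem sizes and degenerate inputs

The test-suite and acceptance configurations use $N = 40$–$100$ nodes,
4–20 subjects, $M = 80$–$500$ time points, and 99–500 permutations or
surrogates (10 000 would be typical at study scale; all counts are
arguments). These sizes were chosen so the planted effects are comfortably
detectable and the whole suite runs in minutes on one core.

Degenerate inputs are rejected with classed errors: zero-variance node time
courses (`bm_zero_variance_error`), non-z-scored sessions entering the
ensemble (`bm_contract_error`), mismatched node sets (`bm_alignment_error`),
out-of-range mode indices (`bm_index_error`), constant maps in similarity
tests (`bm_undefined_similarity`), fewer than three nodes for triangle
similarity, flat weight curves (no elbow; criterion (i) fails for all), and
empty permutation nulls. Full retained rank defaults to $\min(N, M)$;
weights are always reported for the full retained rank.

## Known limitations

* The permutation weight test remains slightly conservative (≈ 3.5% at
  nominal 5%) even with re-standardisation; exact calibration would require
  permuting the raw, pre-standardisation data, which the ensemble no longer
  carries.
* The leading-mode count inherits Kneedle's sensitivity parameter; very flat
  or very steep weight curves can move the elbow by one rank.
* Surrogate variograms are matched in distribution, not realisation-wise, in
  the sparse extreme-distance bins.
* Population-level and individual-level analyses share one implementation
  (an individual analysis is a single-session ensemble); no streaming SVD is
  provided, so very long concatenations are memory-bound.
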