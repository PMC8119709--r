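---
title: "Classifying carnivore tooth pits from 3D landmarks: models, choices and limits"
author: "pitmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying carnivore tooth pits from 3D landmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When a carnivore feeds on a carcass its tooth cusps leave pits on the bone
surface. Different species leave pits of different size, depth and outline,
but the differences are subtle and overlapping — the classic equifinality
problem of taphonomy. `pitmorph` implements a complete, testable pipeline
for asking *which* carnivore made a pit, given a 3D landmark model of the
pit: geometric morphometrics to place all pits in a common space, robust
statistics to describe group differences honestly, anomaly filtering to
remove digitisation and preservation artefacts, data augmentation so that
classifiers have enough balanced training material, and maximum-margin
classifiers evaluated only on real (non-synthetic) specimens.

Because the reference scan data are not bundled, the package ships a
synthetic tooth-pit generator whose statistical structure mirrors the
real study design (eight taxa, 620 pits, class-specific size/depth/
elongation structure, heavy-tailed classes, allometry, planted anomalies).
Every stage of the pipeline is unit-tested against that generator and
against independent brute-force oracles.

## The landmark model

Each pit is 30 landmarks in mm: LM1/LM2 span the maximal length (LM1 the
extremity farther from the width axis), LM3/LM4 the perpendicular maximal
width, LM5 the deepest point, and LM6–LM30 a 5×5 semilandmark patch over
the pit interior in row-major order. The bone surface sits near $z = 0$
and the pit interior at $z < 0$, so "LM5 is deepest" is a directly
testable invariant. `validate_configuration()` reports violations and
never auto-corrects them — silent reorientation could mask digitisation
errors. Semilandmarks are treated as fixed points; sliding (e.g. by
minimum bending energy) is deliberately not implemented.

Centroid size is the standard measure
$CS = \sqrt{\sum_i \lVert x_i - \bar{x}\rVert^2}$.

## Superimposition and allometry

`gpa_align()` performs iterative Generalized Procrustes Analysis:
centring, optional rescaling to unit centroid size, rotation of every
configuration to the running consensus by orthogonal Procrustes, and
re-estimation of the consensus until it moves less than `tol` (default
1e-10). Reflections are never fitted: pits are physical impressions and
chirality is meaningful. In shape space the aligned coordinates are then
orthogonally projected into the tangent space at the consensus. In *form*
space (`scale = FALSE`) the scaling step is skipped entirely — centroid
sizes are preserved exactly and log CS is carried for allometric
regression; the tangent projection is not applied there because it is
only defined about a unit-norm consensus on the pre-shape sphere.

`allometry_test()` regresses **shape** on log centroid size: each
form-space configuration is rescaled to unit size before the regression.
Regressing raw form coordinates would detect size itself (they scale with
CS by construction) and would reject under a true null slope essentially
always. Significance comes from permuting log CS (add-one convention,
`p = (1 + \#\{F_{perm} \ge F_{obs}\})/(n_{perm}+1)`, so 999 permutations
bottom out at p = 0.001); the effect size is the observed F standardized
against the raw permutation distribution (a documented choice — log-F
standardization is a plausible alternative the source text does not
distinguish).

`pca_reduce()` is covariance PCA of the flattened coordinates.
`optimal_pcs()` retains the contiguous leading block of PCs whose observed
variance fraction exceeds the 95th percentile of variance fractions from
50 column-permuted re-analyses. On pure noise it retains 0 PCs about 95%
of the time — the 5% false-positive rate at each rank is inherent to the
percentile rule. The pipeline exposes `retained_pcs` as an override
because the reference analysis fixed 5 PCs on its own data.

`phylogenetic_signal()` implements a multivariate K statistic: the ratio
of star-phylogeny to phylogenetically corrected mean squared error, scaled
by its Brownian-motion expectation on the tree, with significance from
permuting tip assignments. The bundled `fixture_phylogeny()` is an
ultrametric stand-in with family-consistent clades (canids and felids
monophyletic, the hyaena on the feliform side) and arbitrary positive
branch lengths; it is a testing fixture, not a published phylogeny.

## Robust statistics and Bayes Factor Bounds

All hypothesis tests are reported with the Bayes Factor Bound
$BFB = 1/(-e\,p\,\ln p)$, the upper bound on the Bayes factor in favour of
the alternative implied by a p-value. For $p \ge 1/e$ the same formula
value is reported with the direction flipped ("against $H_a$"), matching
how such values are conventionally printed. The significance convention
is 3σ: p ≤ 0.005 is "significant", 0.005 < p ≤ 0.05 only "suggestive".

Univariate group tests are gated by Shapiro–Wilk normality (threshold
0.05, a conventional choice): ANOVA when every group passes, tie-corrected
Kruskal–Wallis otherwise. Multivariate tests use the Hotelling–Lawley
trace (parametric branch) or Wilks' Λ (robust branch), both computed from
the eigenvalues of $E^{-1}H$ with the standard F approximations, and are
unit-tested to 1e-10 against `stats::manova`. Pairwise comparisons report
raw p-values with BFBs by default; Benjamini–Hochberg adjustment is an
option, not the default, to match the reporting convention the pipeline
mirrors.

Robust scale is the Lax/Tukey biweight midvariance (9-MAD tuning).
`robust_equivalence()` declares two samples equivalent via TOST on 20%
trimmed means, with the margin expressed in pooled robust-sd units
(default 0.1). The absolute difference `|d|` is the difference of medians
on the same standardized scale. Two caveats are worth stating plainly:
the exact test behind the reference analysis's equivalence p-values is
not documented (TOST is our choice), and a TOST with margin 0.2 sd is
mathematically undecidable below roughly n = 1000 per sample — the margin
must exceed ~2.6 standard errors before p ≤ 0.005 is reachable at all.
The augmentation stage validates with thousands of synthetic rows, where
the margin is ~8 standard errors.

## Anomaly filtering

`isolation_scores()` is a from-scratch isolation forest: random trees
splitting uniformly chosen features at uniform cuts, score
$s(x) = 2^{-E[h(x)]/c(\psi)}$ with the usual average-path normalizer. It
was validated against a mature reference implementation on identical data
(background score distributions agree to ~0.005). The cleaning stage
scores **each class against itself** (`isolation_scores_by_class()`):
pooled scoring lets between-class size and depth differences mask
within-class anomalies, and risks flagging unusually variable species
wholesale — precisely the over-classification concern that motivates a
generous threshold band. The default threshold is 0.65, the midpoint of
the 0.625–0.700 operating band; `filter_anomalies()` warns when any
single class loses more than 20% of its members.

## Augmentation

Classes are topped up to a target size (default 100; the family-level
grouping balances to its largest class) with synthetic rows used **only**
for training — every reported metric is computed on original specimens,
enforced through the provenance flag that accompanies every row.

The default backend is per-PC random-walk Metropolis from robustly
defined targets: location = median, scale = √biweight-midvariance,
Gaussian by default, skew-normal (method-of-moments shape on 10%-trimmed
data) as an alternative that tends to exaggerate skew. Per-PC independent
targets are a deliberate choice — PCs are decorrelated by construction
and equivalency is validated per PC — with a joint-Gaussian switch
(`build_target(..., joint = TRUE)`) for users who want residual
dependence. The proposal step adapts toward 30–45% acceptance during
burn-in only (default burn-in 1000, thinning 10), so the retained chain
is a fixed-kernel sampler; chain count, burn-in and thinning are
documented defaults, not reconstructions of the original analysis.

The WGAN-GP backend trains a small generator/critic pair (two 32-unit
ReLU hidden layers) with the Wasserstein objective and gradient penalty
λ = 10, five critic steps per generator step. Backpropagation — including
the double backprop through the gradient penalty, which has a closed form
for ReLU critics — is implemented analytically and verified against
finite differences to 1e-11. At desk scale (a thousand generator updates,
full-batch) it reliably matches 1-D targets; in 5-D its marginals remain
visibly rougher than MCMC's at the same time budget, which is consistent
with adversarial training being orders of magnitude more expensive per
unit of synthetic-data quality. MCMC is the recommended backend.

## Classification

`train_svm()` solves the soft-margin SVM in the primal with a squared
hinge (smooth, convex, deterministic; BFGS), with either the Gaussian
radial kernel or a Laplacian random-Fourier-feature map (frequencies from
the Laplacian kernel's Cauchy spectral measure, then a linear SVM).
Multiclass is one-vs-one with Platt-scaled pairwise probabilities coupled
into per-class estimates; probabilities feed AUC and the MSE loss.
`train_nsvm()` replaces the kernel with a trained feature extractor: a
small tanh MLP feeding a linear squared-hinge margin layer, trained
jointly by full-batch Adam. Probability calibration is considered part of
training, so a 0-epoch NSVM predicts at chance. `bayesian_optimize()`
provides Gaussian-process expected-improvement search over log-scaled
hyperparameter bounds.

Two evaluation protocols mirror the augmented-vs-raw comparison:
`evaluate_on_originals()` (train on augmented, report on originals only)
and `raw_split_protocol()` (stratified 70/30 on originals, no
augmentation). Reports carry per-class and overall accuracy, sensitivity,
specificity, precision, recall (= sensitivity), AUC (rank formulation
with tie correction; macro average), F-measure, Cohen's κ and the MSE
loss on probability vectors. Overall accuracy is micro (trace/total);
overall sensitivity/specificity are macro averages, a documented reading
of single-row summary tables.

## What the generator does and does not emulate

`default_study_spec()` reproduces the design constants of the reference
sample — eight taxa, per-class counts 69/86/80/89/53/77/84/82, 620 pits —
and a qualitative reading of its descriptive findings: lions largest and
deep, foxes smallest but deep for their size, wolves superficial and
round, felids elongated, lions and wolves heavy-tailed (noise-scale
mixture: ×2 with probability 0.1). Within-class noise acts in *shape
space* (`within_sd` is the mm noise at the class's geometric-mean size),
which makes shape exactly independent of size when the allometric slope
is zero — this is what makes the null calibration of the allometry test
exact. Planted anomalies displace the whole semilandmark patch coherently
along the depth axis by 10 within-class sd; depth is where natural pit
variation concentrates, so planted anomalies remain visible after
dimensionality reduction. The heavy-tail weight (2) was calibrated so the
default study sits in the documented anomaly-removal regime (total
removals ≈ 2%, at most ~2.3%).

The generator does **not** emulate: real per-class shape covariances
(unpublished; defaults are qualitative and user-overridable), mesh- or
scan-level artefacts, correlated digitisation error, or inter-analyst
variation. A green test therefore establishes that the pipeline recovers
known structure of this stated world — not that it would reach any
particular accuracy on real scan data.

## Numerical choices and degenerate inputs

* GPA convergence 1e-10 on the consensus; degenerate (all-coincident)
  configurations are an error, non-convergence a warning with
  `converged = FALSE`.
* Permutation p-values use the add-one convention throughout.
* p-values numerically equal to 0 or 1 are clamped into the open interval
  only for the BFB evaluation.
* `biweight_midvariance()` returns 0 with a warning when the MAD is 0.
* Isolation-forest subsampling clamps to n with a warning; duplicated
  rows receive identical scores.
* MCMC warns (naming the step size) when post-adaptation acceptance
  leaves [0.05, 0.95]; WGAN-GP errors on non-finite loss and suggests a
  lower learning rate.
* One global pipeline seed derives every stage seed
  (`seed * 101 + stage offset`, kept below 2^31), so partial reruns match
  full runs and rerunning a config is byte-identical.

## Known limitations

* Semilandmark sliding is not implemented (documented switch left out).
* The WGAN-GP backend is desk-scale; its 5-D marginals need larger epoch
  budgets than the default to match MCMC quality.
* The NSVM architecture (two tanh hidden layers, widths 32/16) is a
  declared default, not an inference about the original models.
* The fixture phylogeny is a stand-in; phylogenetic-signal results on it
  validate the statistic, not any biological claim.
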