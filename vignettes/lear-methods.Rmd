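---
title: "Variance-matching correction of localization error in chromatin traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance-matching correction of localization error in chromatin traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lear)
```

## The problem and the model

Chromatin tracing images many identifiable genomic loci in each of many
chromosome copies ("traces"). Every localized spot is displaced from the
true locus position by a random localization error whose per-axis standard
deviation is typically 25–100 nm. Because distances relevant to gene
regulation are of the same order, this error inflates pairwise distances,
suppresses contact frequencies computed with a distance threshold, and
virtually erases higher-order (3-way, 4-way) contacts.

The key observation is that the loci are *distinguishable*. For one imaging
dimension, write the observed coordinates of locus $\ell$ over $N$ traces as
$O^\ell = T^\ell + \epsilon^\ell$. If errors are independent between loci,

$$\mathrm{Var}(O^\alpha - O^\beta)
  = \mathrm{Var}(T^\alpha - O^\beta) + \mathrm{Var}(\epsilon^\alpha).$$

Given an estimate of $\mathrm{Var}(\epsilon^\alpha)$, the *goal variance*
$\mu_{\alpha\beta} = \mathrm{Var}(T^\alpha - O^\beta)$ — what the
displacement variance would be if locus $\alpha$ carried no error — is
directly computable. Each of the $L-1$ partners of $\alpha$ supplies one
such constraint. The correction seeks per-trace adjustments
$A^\alpha = O^\alpha + C^\alpha$ whose displacement variances match all
goals simultaneously, scored by the likelihood

$$l[A^\alpha] \propto \prod_\beta
  \mathcal{N}\!\left(\mathrm{Var}(A^\alpha - O^\beta)\,\middle|\,
  \mu_{\alpha\beta}, \sigma_{\alpha\beta}\right),$$

where $\sigma_{\alpha\beta}$ is the sampling uncertainty of a variance
estimated from $n$ pairwise-complete traces. Each locus and dimension is
optimized independently against the *observed* partner positions, so locus
runs share no state and parallel or serial execution gives identical
results.

### Assumptions

* Localization errors are independent between loci and traces, with zero
  mean. Systematic shifts (chromatic offsets, drift) are not corrected —
  the likelihood is invariant under a constant shift of a locus column, and
  the gauge is fixed by mean-centering the corrections.
* The error variance estimate refers to the focal locus only; the partner's
  error remains inside the goal (the goal is
  $\mathrm{Var}(T^\alpha - O^\beta)$, not
  $\mathrm{Var}(T^\alpha - T^\beta)$).
* The sampling distribution of a displacement variance is approximately
  normal (CLT), which holds at the $n \gtrsim 50$ sample sizes enforced by
  `min_n`.

## Uncertainty of the goal: a distribution-free choice

The scale $\sigma_{\alpha\beta}$ uses the moment-based standard error of a
sample variance, $\sqrt{(m_4 - m_2^2)/n}$, with $m_2, m_4$ the central
moments of the observed differences. The normal-theory alternative
$s^2\sqrt{2/n}$ is simpler but assumes Gaussian displacement differences,
which chromatin does not guarantee (distances between distal loci are
heavy-tailed). The moment form is valid without that assumption and reduces
to the normal-theory value when the data are Gaussian. It is floored at
`var_floor / 10` so that degenerate (near-constant) difference columns
cannot produce infinite densities.

## The optimizer

The likelihood is maximized by greedy stochastic descent, reconstructed as
follows (the tunables live in `optimizer_config()`):

* per sweep, traces are visited in a seeded random order;
* one proposal per localized spot: $C_i \leftarrow C_i + \delta$ with
  $\delta \sim \mathcal{N}(0, \texttt{proposal\_frac} \times
  \sigma_\epsilon^\alpha)$, default fraction 0.5 of the locus error STD —
  coarse enough to traverse the error scale, fine enough to settle;
* a proposal is accepted only if the summed log-density improves (ties
  retain the incumbent), so the likelihood trace is non-decreasing by
  construction;
* the proposal scale is annealed by 0.95 per sweep; with the default 200
  sweeps the final scale is $\sim 10^{-5}$ of the initial one;
* convergence is declared after three consecutive sweeps whose total
  likelihood gain falls below `tol` ($10^{-6}$ per datum). A single quiet
  sweep is not convergence: with few traces, an early sweep can reject
  every proposal by chance while the scale is still coarse.

Each proposal updates the $O(L)$ affected variances incrementally in
constant time per partner (running sums), which is what makes the
$O(\text{sweeps} \times N \times L)$ inner loop tractable; it is
implemented in C++ with R's own RNG stream, so `set.seed()` semantics and
bit-reproducibility are preserved. Running sums are refreshed once per
sweep to keep floating-point drift out of the reported likelihood.
Per-(locus, dimension, round) seeds derive from the master seed by a fixed
counter scheme, so results are independent of locus processing order.
Doubling the sweep budget or slowing the annealing changes the benchmark
relative error by under one percentage point, so the defaults are treated
as converged.

### Numerical choices and degenerate inputs

* **Negative goal variances.** If the error estimate exceeds the empirical
  displacement variance (possible for adjacent loci when the error is
  overestimated), the goal is floored at `var_floor` (1 nm²) and a warning
  is emitted.
* **Missing spots** contribute to no variance, receive no proposals, and
  keep zero correction — no imputation anywhere.
* **Data-poor pairs** ($n <$ `min_n`, default 50) are unusable; a locus
  with no usable partner passes through unadjusted with a warning.
* **Gauge.** Corrections are mean-centered over localized spots per locus:
  the likelihood cannot determine a constant offset, and zero-mean
  corrections preserve ensemble centroids.
* **Multi-round refinement** (`rounds > 1`) recomputes goal variances
  against previously adjusted partners. It is off by default: within a
  round the likelihood literally uses observed partner positions, and
  re-subtracting the full error variance from already-corrected data
  over-corrects; the option exists for exploration only.

## Error estimation

`estimate_error_from_repeats()` uses loci imaged twice in the same cell.
Both copies share a true position, so per dimension
$\mathrm{Var}(O^a - O^r) = \mathrm{Var}(\epsilon^a) +
\mathrm{Var}(\epsilon^r)$, and averaging
$\mathrm{Var}(O^a - O^\beta) - \mathrm{Var}(O^r - O^\beta)$ over third loci
$\beta$ isolates $\mathrm{Var}(\epsilon^a) - \mathrm{Var}(\epsilon^r)$.
The two moment equations solve for both rounds; this is a reconstruction —
it is the unique moment-based solution using only displacement variances —
and negative solutions from sampling noise are clamped to zero with a
warning. Repeat rounds are typically *noisier* than initial rounds
(re-hybridized spots are dimmer), which this estimator quantifies; the
correction itself is applied to initially imaged loci only, since repeat
localizations also carry more off-target events.

Without repeats, `worst_case_error_bound()` uses
$\mathrm{Var}(O^\alpha - O^\beta) \ge \mathrm{Var}(\epsilon^\alpha) +
\mathrm{Var}(\epsilon^\beta)$: half the smallest adjacent-pair displacement
variance bounds a homogeneous error variance from above. The bound is tight
when adjacent loci co-move and conservative otherwise; feeding it to the
correction over-corrects mildly but still improves data whose true spatial
scale is below the error scale.

## Filtering

Off-target localizations (mis-assigned spots) sit far from *both* genomic
neighbors. The metric is the minimum distance to the previous/next
localized neighbor, skipping missing loci up to a genomic gap of two
positions — beyond that a "neighbor" no longer constrains plausibility and
the metric is undefined (flagged, never removed). Repeat-imaged loci use
the neighbors of their initially imaged twin. The default cutoff is the
0.995 quantile of the pooled metric, a conservative choice given that no
absolute threshold generalizes across genomic resolutions; absolute nm
thresholds are supported for reproduction studies, and removing more than
20% of spots requires `force = TRUE` (a units guard). The
detection-efficiency filter (share of localized loci per trace, boundary
inclusive) matters mainly for multi-way contact analyses, which need
near-complete traces (typically ≥ 95%).

## What the synthetic generator does and does not emulate

`generate_polymer_traces()` draws independent Gaussian chains: successive
loci displaced by $\mathcal{N}(0, s)$ per axis, optionally rescaled per
trace to the ensemble radius of gyration ("confined"). The default
$s = 30$ nm per axis mimics the compaction of kilobase-resolution tracing
data, where the mean 3D neighbor distance ($\approx s\sqrt{3} \approx
52$ nm) sits below typical errors — the regime where the method matters
most. Dropout is i.i.d. per spot.

This emulates the *distance scales and missingness* the correction
responds to, not chromatin biology: no loop extrusion or CTCF structure,
no TADs, no correlated dropout, no off-target process (off-targets are
planted explicitly in filtering tests), and no heavy-tailed error
component. Passing tests therefore demonstrate that the estimator and
optimizer recover known ground truth under the stated error model; they do
not certify performance on data whose errors are correlated or
non-Gaussian.

Validation problem sizes were chosen to keep every check comfortably
converged: 100 loci × 500 traces for the end-to-end benchmark (where
relative-error and contact-map claims are made), $N = 2000$ for moment
identities and repeat-imaging recovery (the 5%-accuracy scale), and small
exhaustively checkable instances (e.g. 4 traces × 2 loci against a full
grid search) for optimizer correctness.

## Analysis conventions

* Contact frequency: share of traces with both (all) loci localized and
  within the threshold; 150 and 200 nm are the standard thresholds.
  Pairs with fewer than `min_n` (default 50) co-localized traces are
  masked; k-way tuples additionally require ≥ 1000 co-localized traces for
  *every* member pair.
* The independence baseline for a k-tuple is the product of its
  $\binom{k}{2}$ pairwise frequencies — a k-way contact is the conjunction
  of its pairwise contact events; excess over the product measures
  cooperativity.
* Relative error per locus is the ratio of mean Euclidean distances to
  truth (corrected / raw); per trace it is the mean of per-spot ratios,
  skipping spots whose raw error is below $10^{-6}$ nm. The per-spot ratio
  uses Euclidean norms; a signed 1-D reading of the per-trace formula is
  possible but was rejected as it can cancel errors of opposite sign.

## Known limitations

* The error estimate must come from somewhere: repeat-imaged loci, a
  worst-case bound, or prior knowledge. Mis-specified error transfers
  directly into mis-set goals (the benchmark's `bound` mode quantifies the
  over-correction).
* Corrections are driven by second moments only; per-spot error
  heterogeneity (photon counts) is not used.
* The improvement shrinks as inter-locus distances grow relative to the
  error; at 50 kb-scale resolutions gains are small.
* Off-target filtering is heuristic; a polymer-model-based filter is out
  of scope.
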