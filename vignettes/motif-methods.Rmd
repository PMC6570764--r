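---
title: "Grade-of-Membership motifs: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grade-of-Membership motifs: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecomotifs)
```

## The model

`ecomotifs` decomposes ecological matrices with mixed-membership ("Grade of
Membership", GoM) models, the same family as ADMIXTURE models in population
genetics and topic models in text analysis. Every sample (a survey site or a
map cell) carries a membership vector $\omega_{n\cdot}$ over $K$ latent
*motifs*, and every motif is a feature profile $\theta_{k\cdot}$ over the
species (or clades, or map cells) observed:

* **Multinomial model** (abundance counts, dispersion fields, clade counts):
  the counts in row $n$ are a multinomial draw of size $c_{n+}$ with cell
  probabilities $p_{ng} = \sum_k \omega_{nk}\theta_{kg}$, where each
  $\theta_{k\cdot}$ lies on the simplex — motif $k$ is a relative-abundance
  profile.
* **Bernoulli model** (presence–absence bioregionalization): each entry is
  an independent Bernoulli draw with the same mixture form for $p_{ng}$, but
  $\theta_{kg} \in [0,1]$ is now the occurrence probability of species $g$
  under motif $k$.

Both models assume features are conditionally independent given the motif —
nothing in the likelihood knows that two species are close relatives or that
two map cells are neighbours. That simplicity is what makes the models fast
and the motifs interpretable, but it also means spatial and phylogenetic
autocorrelation are unmodelled (see *Limitations*).

## Estimation

Estimation is MAP EM with a per-observation latent motif
indicator: for the multinomial model every censused individual carries a
latent motif, for the Bernoulli model every matrix entry does. The marginal
of that augmented model is exactly the mixture above, so EM maximizes the
true posterior and the objective (log likelihood without the data-constant
multinomial coefficient, plus log priors) is non-decreasing — a property the
test suite asserts on every fit.

Priors are conjugate and flat by default: symmetric Dirichlet(1) on
membership rows and on multinomial profiles, Beta(1, 1) on Bernoulli
profiles. "Flat" is a deliberate reading of non-informativeness: with
concentration 1 the MAP estimate equals the MLE, and any smoothing is opt-in
via the `prior_omega` / `prior_theta` arguments (values above 1 shrink
toward uniformity; values below 1 sharpen and are truncated at zero in the
M-step, the standard MAP-EM device).

Numerical guards: mixture probabilities are clipped to
$[10^{-12}, 1-10^{-12}]$ inside the Bernoulli E-step, profiles are floored
at $10^{-12}$ before row normalization, and convergence is declared when
the relative objective change drops below `tol` ($10^{-8}$ by default,
`max_iter` 1000). All-zero rows are rejected at load time — an empty site
carries no likelihood contribution and almost always signals an upstream
join error — and all-zero feature columns are tolerated (their profile
entries go to the floor).

EM only finds local optima, so `multistart_fit()` refits from seeded random
starts (memberships from Dirichlet(1); profiles from normalized Gamma draws
or Uniform(0.1, 0.9)) and keeps the restart with the best approximate log
Bayes factor. Child seeds are `seed + restart_index - 1`; every stochastic
entry point takes an explicit seed and restores the session RNG, so whole
pipelines are bit-reproducible.

## Model comparison

Fits at different $K$ (and partition-constrained competitors) are ranked by
a Laplace/BIC-style approximation to the log Bayes factor against the
$K = 1$ fit on the same data:
$$\log \mathrm{BF}(K) = [\mathrm{obj}(K) - \mathrm{obj}(1)] -
\tfrac{1}{2}\,\Delta_{\text{params}}\,\log n_{\text{obs}},$$
with $N(K-1) + K(G-1)$ free parameters for the multinomial model
($N(K-1) + KG$ for Bernoulli) and $n_{\text{obs}}$ the number of censused
individuals (multinomial) or matrix entries (Bernoulli). Two caveats are
built into the design. First, the absolute value depends on the
approximation and the priors, so only *comparisons between fits of the same
data* are meaningful; this is also why `constrained_partition_fit()` (preset
partitions, e.g. splitting sites at a fixed elevation) computes its BF with
the identical formula, counting only the profile parameters as free.
Second, because the underlying independence assumptions are crude, a single
"best $K$" should be read loosely: patterns stable across neighbouring $K$
values are the trustworthy signal.

Mixture likelihoods are invariant to relabelling motifs, so fits are
compared after `align_motifs()`, which maximizes the summed correlation of
matched profile rows (exhaustive over $K!$ permutations up to $K = 7$,
greedy beyond, ties broken lexicographically).

## Null models

`null_bf_distribution()` asks whether the observed BF at a given $K$ exceeds
what marginal structure alone produces, by refitting the model on matrices
permuted under one of four community null models: `frequency` (shuffle
within columns), `richness` (shuffle within rows), and the two
checkerboard-swap nulls (`independentswap` counts successful 2×2 swaps,
`trialswap` counts attempts; on binary matrices both preserve row and
column sums exactly). The default swap effort, ten times the number of
occupied cells, is an explicit burn-in heuristic and configurable. For
count matrices the swap carries each occupied value intact across the
anti-diagonal, preserving row sums and the occupancy pattern — the
convention of the classic fixed-fixed abundance null.

`compare_to_null()` reports both the empirical tail probability
$(1 + \#\{\text{null} \ge \min(\text{observed})\})/(n_{\text{null}}+1)$ and
a Mann–Whitney rank-sum test. The rank-sum test needs a *list* of observed
values to be well defined; per-restart BFs of the observed matrix are the
natural choice, and the report records which inputs were used.

One subtlety the test suite documents: which null is the right calibration
reference depends on what structure the data lack. For structure-free data
(every row drawn from one shared profile) the frequency null preserves
exactly that situation, and observed BFs fall inside the null range; the
richness null instead *creates* apparent between-row structure by
scattering each row's abundances across unrelated columns, so its null BFs
sit far above a structureless observation. When testing for real
co-occurrence structure that conservatism is harmless (the blocked-data
check passes against richness nulls by a wide margin), but calibration
checks use the frequency null for this reason.

## Geography: dispersion fields

For survey sites embedded in a broader region, `dispersion_field()` turns a
site's species list plus per-species binary range grids into the assemblage
dispersion field — the grid counting how many of the site's species reach
each map cell. Fields are vectorized row-major from the north-west corner
(`cell_<row>_<col>` ids fix the column order; `unstack_dispersion_row()`
inverts it exactly) and stacked into a site-by-cell count matrix for the
multinomial model. The Himalayan frame of reference, 50–120°E / 5–50°N at
1/8°, yields the 360 × 560 = 201,600-cell layout.

`build_presence_matrix()` applies the two cell filters for global
bioregionalization — at least 10% land cover and at least three overlapping
breeding ranges, both inclusive thresholds — before handing the cell-by-
species binary matrix to the Bernoulli model. Range grids are read from
ESRI ASCII rasters (one per species, shared header geometry); species names
are matched after case and underscore/space normalization only — no fuzzy
matching, because silent fuzzy joins corrupt matrices. Rasterization of
range polygons is upstream of this package.

## Phylogeny: time slices

`slice_tree()` cuts a rooted ultrametric tree (branch lengths in Myr) at
age $T$: the lineages alive at $T$ are the edges with child age $< T \le$
parent age, and each becomes a clade of its subtended species. $T = 0$ is
the identity map; $T \ge$ root age is a single clade, and a node exactly at
the slice belongs with the lineage above it so the root boundary is the
limiting case. Clade ids (`T<T>_<smallest member tip>`) are deterministic.
Non-ultrametric trees are rejected with the offending tips listed, rather
than silently extended. `collapse_counts()` then sums member-species
columns, preserving per-site totals exactly, and the multinomial model runs
unchanged on the clade matrix. `T` is an ordinary parameter — sweeping it
from 0 to the root age traces how motif structure persists as taxonomy
coarsens into deep clades.

## Synthetic data: what it does and does not emulate

The generators exist so that every pipeline stage has inputs with known
ground truth:

* `simulate_gom()` samples exactly from the fitted models. Motif profiles
  blend a shared baseline with motif-private feature blocks; `separation`
  (default 0.8) moves from identical profiles (0) to near-disjoint ones
  (1), and `alpha_omega` (default 0.5) controls how mixed memberships are.
  The defaults describe a community with strong but not caricatured
  structure: profile overlap is substantial and most sites are mixtures.
* `simulate_ranges()` builds rectangular ranges; with `banded = TRUE`,
  species and sites split into a southern low-elevation and a northern
  high-elevation pool, a minimal two-regime world whose dispersion-field
  and presence–absence motifs have a known $K = 2$ truth.
* `simulate_timetree()` draws a pure-birth tree rescaled to a chosen root
  age.

What passing recovery tests on these data shows is that the estimator is
correct *under its own assumptions*. Real censuses violate them in known
ways — phylogenetically and functionally correlated species, spatially
autocorrelated cells, detection error, range-map imprecision — and none of
those are emulated here. Recovery on synthetic data is therefore evidence
of implementation correctness, not of ecological validity of any particular
fit.

## Problem sizes used by the tests

The test suite and the acceptance script size their simulations to make the
statistical properties sharp while staying quick to run: recovery and
model-selection checks use 200 sites × 100 species at sequencing depth
1000 (10 seeds, 10–20 restarts); null-model checks use blocked 20 × 30
matrices with 50 replicate ensembles; marginal-conservation checks run 250
random matrices per null method; oracle equivalences (brute-force
likelihood sums, exhaustive permutation alignment, 3×3 swap-space
enumeration, exact rank-sum enumeration) run on deliberately tiny cases
where exhaustive computation is feasible. Checks against the published
descriptors of the deposited Himalayan census (38 × 304 table, ~90%
sparsity, 67 clades at the 20-Myr slice) run only when those deposited
files are placed under `inst/extdata/deposited/`; they are not
redistributable with the package.

## Limitations

* Feature independence given the motif: no phylogenetic, functional, or
  spatial correlation structure; motifs over map cells ignore cell
  adjacency.
* The Bayes factor is an approximation for ranking fits on one data set;
  absolute values are not comparable across data sets or priors.
* EM is a local optimizer; the multistart count is the only defence, and
  hard problems may need many restarts.
* Binary swap nulls assume the checkerboard-swap space is well mixed after
  the default effort; for very dense or very sparse matrices users should
  raise `n` and check convergence of the null BF distribution.
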