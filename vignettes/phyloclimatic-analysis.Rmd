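---
title: "Phyloclimatic analysis with phyloenm: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phyloclimatic analysis with phyloenm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloenm)
```

`phyloenm` chains five analyses that are usually run with separate tools:
presence-background niche modelling, niche-overlap statistics, predicted
niche occupancy (PNO) profiles, Brownian-motion ancestral reconstruction,
and disparity-through-time (DTT).  This vignette documents the models and
the conventions that tie the stages together — the things a user needs to
know to interpret output or to disagree with a design choice.

## The niche model and the RAW convention

Each species' model is a Gibbs (maximum-entropy) distribution over the
valid cells of the study grid,

$$P(i) = \frac{e^{\lambda \cdot f(i)}}{\sum_j e^{\lambda \cdot f(j)}},$$

with features $f$ the standardized value of each climate variable and its
square, standardization taken on the background sample only.  The weights
maximize the L1-penalized presence log-likelihood; the quadratic term
gives each variable a bell-shaped response, so the implied optimum for a
variable is $x^* = m + s\,(-\lambda_{lin}/2\lambda_{quad})$ in the
variable's own units.  Hinge, product and threshold features, clamping,
and projection to other regions or time slices are deliberately out of
scope: every downstream statistic consumes only the *RAW* surface, the
normalized distribution $p$ over cells, and that surface is what the
minimal feature set has to get right.

Fitting is proximal gradient ascent with step halving and
soft-thresholding, so the penalized objective is non-decreasing (the test
suite asserts this) and weights can be driven exactly to zero.
Convergence is a subgradient max-norm below `1e-6`, with an iteration cap
of 5000.  Zero-variance variables on the background are dropped with a
warning; a presence falling on an invalid cell is an error, never
silently dropped.

Background cells are drawn uniformly, without replacement, from the valid
cells whose centers fall inside the minimum convex polygon around *all*
species' occurrences (default 10000; if fewer cells are eligible, all are
used with a warning).  Normalization of the RAW surface is over all valid
study cells — the same universe the overlap and PNO sums run over, which
keeps their unit-mass premises exact.

Species with fewer than 10 spatially unique points are rejected.  Species
with 10–12 points are fit by leave-one-out cross-validation; larger
species by 20 re-seeded 80/20 split replicates.  In both cases the final
surface is the cell-wise mean of the replicate surfaces, renormalized,
and the reported AUC is the mean held-out AUC.  AUC is the rank-based
(Mann–Whitney) probability that a presence cell outranks a background
cell, with mid-ranks for ties.

Variable "contribution" is permutation importance: the AUC drop when both
features of a variable are permuted across cells, averaged over
permutations, floored at zero and normalized to 100%.  This is a
deliberate stand-in for MaxEnt's path-dependent percent-contribution
heuristic, which is not well defined for this optimizer; a variable with
zero weights contributes exactly 0%.

## Overlap, PNO, and their shared conventions

Schoener's $D = 1 - \tfrac12\sum_i |p_i - q_i|$ and the Hellinger-based
$I = 1 - \tfrac12\sum_i (\sqrt{p_i}-\sqrt{q_i})^2$ are computed after
restricting both surfaces to their common valid cells and renormalizing,
so both arguments are genuine unit-mass distributions.  Values are kept
at full precision internally and rounded to 2 decimals only in the CSV.

PNO profiles bin a variable's study-wide range into 50 equal bins and
deposit each cell's suitability mass in the bin holding the cell's value
(half-open bins, last bin closed).  The bin range is *global* — shared by
every species on a layer — rather than per-species: profiles are only
comparable on a common axis, and the reconstruction plots all species on
one scale.  This was a genuinely open choice; per-species ranges would
sharpen individual profiles but break cross-species comparability.
Draws from a profile return bin midpoints (mass-weighted), the simplest
faithful reading of "draws of values from the profiles"; uniform
within-bin jitter is available via `jitter = TRUE`.

## Ancestral reconstruction

`bm_ancestral_ml()` computes maximum-likelihood ancestral states under
Brownian motion by two-pass Gaussian message passing: a pruning downpass
(yielding the GLS root estimate and, via the contrast decomposition, the
ML rate $\hat\sigma^2 = Q/n$) and an uppass that conditions each internal
node on the data outside its subtree.  The estimates are identical to the
explicit GLS/BLUP formula with the full phylogenetic covariance matrix —
the tests check equality to `1e-8` on random trees, and agreement with an
independent implementation — but cost $O(n)$ per trait.  $\sigma^2$ is ML
(divide by $n$) to match the maximum-likelihood framing; the REML variant
(divide by $n-1$) is returned alongside.  Estimates are
translation-equivariant and invariant to rescaling all branch lengths.

`reconstruct_history()` repeats the reconstruction over 100 independent
draws from each species' PNO profile and summarizes each node by the mean
and the 80% central-density interval (the empirical 10%–90% quantile
interval and the mean of the values inside it).  Node summaries are the
mean across draws rather than one reconstruction of the mean profile
value — the reading that matches "reconstruction based on 100 random
samples of the PNO profiles".  Draws are independent across species
within a replicate; no spatial covariance between species' samples is
modelled.

A limitation worth stating plainly: the across-draw interval quantifies
only the sampling variability of the PNO profiles.  It does not include
the Brownian sampling error of the root/node estimates themselves, nor
the systematic shift of PNO means toward climatically common conditions
(availability weighting), so it should not be read as a confidence
interval for the true ancestral state — under the package's own
generator it covers the true root state in well under 80% of replicate
datasets.

## DTT and MDI

Disparity is the mean *squared* pairwise difference between tip values.
The methods literature the pipeline follows describes the metric both as
squared pairwise differences and as mean pairwise Euclidean distance;
the squared form is the default here (and what the null calibration is
tested against), with `metric = "euclidean"` as a switch.

The observed curve is evaluated at each branching time $t$ (node heights
relative to tree height): the mean, over every lineage alive immediately
*before* the split at $t$, of the lineage's relative subclade disparity.
Just before the root split the single lineage is the whole tree, so the
curve starts at exactly 1; a final point $(1, 0)$ is appended for the
present.  Two details differ from other implementations and are worth
knowing: lineages subtending a single tip are included as zero-disparity
contributors (they are alive, and their subclade variance is zero), and
the evaluation is anchored at each branching time's own configuration
rather than the previous one's.  All tip values equal is a degenerate
input and an error, not a zero curve.

The null is 1000 Brownian simulations on the *same* tree (only traits
are simulated), with the rate estimated from the observed tips; each
simulated dataset is evaluated at the observed node times and the
pointwise median forms the reference curve.  MDI is the trapezoid
integral over relative time of observed minus null median.  Under pure
Brownian data the expected MDI is approximately zero (the residual
mean-median asymmetry of the disparity distribution is small at these
tree sizes), which the test suite verifies by simulation.

Clade-based DTT extracts each clade's subtree at its MRCA with branch
lengths preserved and rescales relative time to the subtree's own height
— each clade's curve runs from its own root (0) to the present (1)
independently, which is the natural reading when clades of very
different ages are compared side by side.  Clades with fewer than 3 tips
are skipped with a warning.

## The synthetic-data generator

The generator emulates the study inputs: a Yule tree with a fixed tip
count (pure birth, uniformly chosen splitting lineage, tips extended by
the waiting time to the would-be next event, rescaled to a 10 Myr
height); 19 climate layers as Gaussian random fields (white noise
smoothed by an isotropic Gaussian kernel, autocorrelation length 0.3°)
min-max rescaled to plausible tropical-Asian bioclim ranges on a 60×60
grid at 0.0417°; species niche optima evolving by Brownian motion along
the tree with per-variable rate $(0.12 \cdot \mathrm{range})^2 /
\mathrm{height}$ (tip spread ~12% of each variable's range — clades
structured but overlapping); Gaussian suitability responses with
tolerance $\tau = 0.15 \cdot \mathrm{range}$ (a 2$\tau$ response breadth
of ~60% of the regional climate axis, comparable to the broad occupancy
profiles seen in real montane birds); and 20 occurrence points per
species sampled without replacement at cell level, proportional to
suitability.

What the generator does *not* emulate: topography and elevation,
correlated climate variables (fields are independent), sampling bias,
species interactions, and range cohesion (occurrences follow suitability
alone).  Passing tests therefore demonstrate that the statistical
machinery is correct and calibrated under a known generative model — not
that any particular field dataset satisfies that model.

## Numerical conventions and degenerate inputs

* Grids are stored north-to-south (row 1 = northernmost), matching the
  ASCII-grid format; points snap to cells by `floor((x - x_ll)/cell)`
  with half-open intervals, so boundary points are deterministic.
* Occurrences are deduplicated at cell resolution ("spatially unique"),
  since the model operates on cells.
* Readers reject malformed input (header errors name the line; token
  counts are checked) rather than repairing it; grid round-trips are
  written at 15 significant digits.
* Ultrametricity is validated within `1e-6` of tree height, naming the
  worst tip; trees must be rooted, binary, and fully branch-lengthed.
* Every stochastic operation takes an explicit seed; pipeline stages and
  per-species operations derive their seeds from one master seed by
  stable string hashing, so results are independent of processing order
  and reruns are byte-identical (the manifest records MD5 hashes).
* Tied mean contributions in variable selection break alphabetically
  (reported via a message).

## Problem sizes used by the test suite

The suite exercises the full chain at deliberately small scale so it
runs quickly anywhere: demo pipelines use 8–12 taxa, 30×40-cell grids
and a few hundred background cells; calibration checks use 29-taxon
trees with 50–100 replicate datasets, 200-replicate Brownian nulls, and
100×100-cell grids with 200 presences for optimum recovery.  Defaults in
the package itself (10000 background points, 20 replicates, 50 bins,
100 draws, 1000 simulations) are the study-scale values.
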