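# phyloenm

Comparative phyloclimatic analysis in R: how do the climatic niches of a
clade's species evolve over its phylogenetic history?  `phyloenm` takes a
dated ultrametric phylogeny, georeferenced occurrence points, and a stack
of co-registered climate rasters, and carries them through the full
analysis chain used in comparative studies of niche evolution:

1. **Ecological niche models** — a minimal MaxEnt-style presence-background
   model per species: a Gibbs distribution over the valid cells of the
   study area, `P(i) ∝ exp(λ·f(i))` with standardized linear and quadratic
   climate features and an L1 penalty, trained against background cells
   drawn from the minimum convex polygon around all occurrences.  Output
   is the "RAW" convention: a suitability surface `p` that sums to 1 over
   the study cells, with rank-based AUC evaluation, 80/20 split or
   leave-one-out cross-validation, replicate averaging, permutation-based
   variable contributions, and minimum-training-presence binary maps.
2. **Niche overlap** — Schoener's `D = 1 − ½ Σᵢ |pᵢ − qᵢ|` and the
   Hellinger-based `I = 1 − ½ Σᵢ (√pᵢ − √qᵢ)²` between all pairs of RAW
   surfaces, assembled into a matrix with D above and I below the diagonal.
3. **Predicted niche occupancy (PNO)** — each climate layer integrated
   over each species' suitability distribution: a unit-mass histogram over
   50 equally spaced bins spanning the variable's study-wide range.
4. **History of climatic tolerances** — maximum-likelihood ancestral
   states under Brownian motion at every internal node, repeated over 100
   draws from the PNO profiles, summarized per node by the mean and the
   80% central-density interval.
5. **Disparity through time (DTT)** — the observed relative-disparity
   curve (mean squared pairwise tip difference within each lineage alive
   at each branching time, relative to whole-tree disparity; 1 at the
   root, 0 at the tips), a 1000-replicate Brownian-motion null on the same
   tree, and the MDI statistic (signed area between observed curve and
   null median), whole-tree and per clade.

A first-class synthetic-data generator (spatially autocorrelated Gaussian
climate fields rescaled to bioclim-like ranges, Yule trees, niche optima
evolving by Brownian motion, occurrences sampled proportional to
suitability) produces complete datasets with known ground truth, so every
stage is testable without downloading anything.

## Worked example

Simulate a 12-species, 5-layer dataset and run every stage:

```r
library(phyloenm)
cfg <- sim_config(n_taxa = 12, n_clades = 2, n_layers = 5, n_rows = 40,
                  n_cols = 40, n_points = 15, seed = 42)
res <- run_pipeline(pipeline_config(
  out_dir = "example", inputs = cfg,
  background_n = 2000, replicates = 5, n_permutations = 3,
  n_keep_variables = 4, n_draws = 100, n_sim = 200, seed = 42))

head(res$report[, c("species", "n_points", "auc", "method")], 4)
#>  species n_points       auc          method
#>     sp08       15 0.9081062 5 x 80/20 split
#>     sp09       15 0.9382949 5 x 80/20 split
#>     sp02       15 0.8372001 5 x 80/20 split
#>     sp01       15 0.9038202 5 x 80/20 split
```

Each species' model is fit 5 times on re-seeded 80/20 splits and the
surfaces averaged; AUC near 0.9 says test presences outrank background
cells about 90% of the time.  The overlap matrix reports D above and I
below the diagonal (1 = identical niches):

```r
res$overlap$values[1:3, 1:3]
#>      sp08 sp09 sp02
#> sp08 1.00 0.63 0.68
#> sp09 0.86 1.00 0.67
#> sp02 0.90 0.89 1.00
```

and the DTT stage prints one MDI per retained variable:

```r
subset(res$dtt$table, scope == "all")
#>  variable scope         mdi n_sim    seed
#>     bio01   all 0.008347917   200 4632310
#>     bio03   all 0.022356701   200 4632310
#>     bio04   all 0.089785487   200 4632310
#>     bio05   all 0.515935390   200 4632310
```

Positive MDI means observed disparity sits above the Brownian null —
climatic disparity concentrated within subclades (niche evolution inside
clades); negative values would indicate conservatism.  All stage outputs
(surfaces as `.asc`, overlap/PNO/node/MDI tables as CSV) land in
`out_dir`, together with a `manifest.json` of seeds and file hashes; a
rerun with the same config is byte-identical.

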