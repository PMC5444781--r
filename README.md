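# reefscape

Habitat-explicit simulation of marine population genetic structure —
"reefscape genetics". The package asks how much of the spatial genetic
structure of a benthic reef species (its motivating case: a giant clam with
a ~9-day precompetency larval stage) is explained by the composition and
configuration of its reef habitat, combined with a model of larval
dispersal.

## What it does

- **Habitat**: grids a reef habitat map into 0.25° patches; attaches
  per-class reef areas (hectares, cosine-latitude corrected); draws patch
  abundances `N_i` from a 3-level geomorphological density typology
  (shallow classes from field surveys; variable-depth classes fixed at a
  hundredth of their shallow counterpart); degrades maps to coarser
  typology levels and fragments them by seeded random patch removal.
- **Geographic distance**: shortest over-water paths between patch
  centroids on a 0.1° land raster (8-neighbour water graph, great-circle
  edge weights) — paths never cross land.
- **Dispersal**: an isolation-by-distance kernel `P_ij = a^d_ij` (`d` in
  km, `a` scanned over 0.40–0.99 in steps of 0.01), or a Lagrangian
  transport surrogate on a gridded current field with precompetency (9 d),
  a competency window (9–19 d), exponential larval survival and
  settle-on-first-habitat rules.
- **Gene flow**: projects allele frequencies over generations with the
  migration matrix model `Q_{t+1} = normalize(A Q_t + N Q_t)`, where
  `A[dest, source] = f · N_source · D[source, dest]` counts expected
  migrants per generation.
- **Comparison**: Cavalli-Sforza & Edwards chord distances (standardized to
  maximum 1) between simulated and observed site pairs, compared by Mantel
  correlation with permutation tests; kernel scans ranked by median r;
  a full composition × fragmentation sensitivity design.
- **Pop-gen statistics**: GENEPOP reader/writer, allele frequencies,
  observed and Nei-unbiased expected heterozygosity, Weir & Cockerham
  `F_IS`/`F_ST`.
- **Synthetic data**: multi-archipelago reefscapes, divergence-free current
  fields, and "observed" genotype datasets generated under a known kernel
  with Wright–Fisher drift — every stage is testable without downloads.

## Worked example

```r
library(reefscape)

# a small synthetic reefscape with a known true kernel (a* = 0.95)
sc  <- reefscape_scenario(preset = "toy", a_star = 0.95, seed = 1)
length(patch_ids(sc$grid))      # about twenty habitat patches
#> [1] 19

# "observed" genotypes: gene flow under a* with drift, then sampling
obs <- make_observed_genotypes(sc)
om  <- observed_distance_matrix(obs$genotypes, sites = sc$sites$site_code)

# scan candidate kernels against the observed structure
cfg  <- gene_flow_config(n_replicates = 6, generations = 50, f = sc$f,
                         seed = 2)
scan <- scan_kernels(om, sc$grid, sc$dist, cfg, typology = sc$typology)
glance(scan)
#> # A tibble: 1 x 3
#>   best_a r_median_best n_kernels
#>    <dbl>         <dbl>     <int>
#> 1   0.94         0.920        60
```

The scan recovers a best-fitting base of 0.94 for a truth of 0.95: the
kernel base sets the e-folding dispersal range (`1/ln(1/a)` km), and the
median Mantel r (0.92 here) measures how well the simulated divergence
pattern among the 14 sampled sites matches the observed one. `autoplot(scan)`
draws the r(a) profile;
`sensitivity_experiment()` then quantifies how the fit erodes when the
habitat map is degraded to coarser typology levels or fragmented — the
package's core scientific claim is that this erosion is measurable and
directional.

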