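---
title: "Reefscape genetics: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reefscape genetics: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefscape)
```

## The problem

Marine invertebrates with a pelagic larval stage disperse between patches of
benthic habitat. Over generations, restricted dispersal plus genetic drift
builds up spatial genetic structure. `reefscape` asks how much of that
structure is explained by the *reefscape* — the composition (habitat classes
and their population densities) and configuration (spatial arrangement,
fragmentation) of the reef habitat mosaic — and by the dispersal model
imposed on it. The workflow is:

1. grid a habitat map into 0.25° patches and attach per-class areas;
2. draw patch abundances from a density typology;
3. compute over-water geographic distances on a 0.1° land raster;
4. build a dispersal matrix, either a distance kernel or a particle-tracking
   surrogate on a current field;
5. project allele frequencies forward with a migration matrix model;
6. compare simulated with observed genetic distance matrices (Mantel
   correlation of standardized Cavalli-Sforza & Edwards chord distances);
7. repeat the comparison under degraded habitat maps (coarser typologies,
   random fragmentation) to quantify how much the reefscape detail matters.

## The dispersal and gene-flow model

**Distance kernel.** The probability that a larva released at patch $i$
reaches patch $j$ decays geometrically with their over-water distance
$d_{ij}$ (km):

$$P_{ij} = a^{d_{ij}}, \qquad 0 < a < 1 .$$

The base $a$ is the single tunable parameter; the standard scan covers
$a \in \{0.40, 0.41, \dots, 0.99\}$ (60 kernels). Distances are shortest
over-water paths: water cells of a 0.1° land raster form a graph with
8-neighbour connectivity and great-circle edge lengths, so paths never cross
land. We row-normalize $P$ by default so each source row is a settlement
distribution; the fertility parameter then controls migration intensity
alone.

**Transport surrogate.** As an alternative kernel, particles are released
from each patch, advected through a gridded current field (bilinear
interpolation, second-order midpoint stepping, 1 h default step), forbidden
to settle before day 9 (precompetency), allowed to settle on the first
reef-bearing cell entered between days 9 and 19, and weighted by exponential
survival $e^{-\lambda(t-9)}$ with default $\lambda = \ln(20)/10 \approx
0.30\ \mathrm{day^{-1}}$, i.e. 5% survival at the end of the competency
window. Particles hitting land are reflected to their previous position;
particles leaving the domain are lost. Row sums of the resulting matrix may
be below one — larval loss is real loss.

**Gene flow.** For each locus, allele frequencies across the $n$ patches are
a matrix $Q_t$. One generation is

$$Q_{t+1} = \overline{A\,Q_t + N\,Q_t},$$

where $N_i$ is the patch abundance (area × a density drawn per habitat
class), $A[\mathrm{dest},\mathrm{source}] = f\,N_\mathrm{source}\,
D[\mathrm{source},\mathrm{dest}]$ is the expected number of migrants per
generation, $f$ is the fertility rate, and the bar denotes per-patch,
per-locus renormalization to the simplex. Migration is the only evolutionary
force in the projection: drift, mutation and selection are deliberately
absent, so connected systems homogenize monotonically and the *rate* at
which pairs of patches converge carries the signal. Patches with zero
abundance and zero inflow carry their frequencies forward unchanged rather
than producing NaNs.

The orientation of $A$ is destination-major so that the projection is a
plain inflow sum; the transpose relation to the source-major dispersal
matrix $D$ is fixed inside `build_migrant_matrix()`.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| grid resolution | 0.25 | degrees | patch size of the habitat mosaic |
| land raster resolution | 0.1 | degrees | over-water path accuracy |
| kernel base $a$ | scanned 0.40–0.99 | per km | sets dispersal range; $1/\ln(1/a)$ km e-folding |
| fertility $f$ | 0.1 | adults per adult per generation | migration intensity; scan rankings are insensitive over two orders of magnitude |
| generations $T$ | 100 | – | projection horizon; rankings should be stable between $T$ and $2T$ |
| replicates | 99 | – | random initial states (and density draws) per scenario |
| loci × alleles | 15 × 10 | – | matches a microsatellite panel of 15 loci |
| precompetency / competency end | 9 / 19 | days | larval biology of the focal clam |
| survival rate $\lambda$ | $\ln(20)/10$ | day$^{-1}$ | 5% alive at day 19 |

Density draws are truncated at zero (several typology classes have sd larger
than the mean, e.g. 256 ± 272 ind ha⁻¹, so negative draws are inevitable),
and one draw per class per realization is shared across patches — a
realization represents one plausible regional density field, not independent
patch noise. Cell areas use a spherical cosine-latitude correction.

## The synthetic study system

`make_reefscape()` builds a caricature of a Southwest-Pacific reef system: a
continental island wrapped by fringing reef, a variable-depth lagoon belt
and an outer barrier; a cluster of atolls to the northwest; and an isolated
oceanic island to the east. Shallow and variable-depth classes differ a
hundred-fold in density, so composition degradation (L3 → L2 → L1) has
real consequences. `make_currents()` derives a divergence-free field (zonal
jet + Gaussian eddies) from a streamfunction by central differences, so the
discrete divergence vanishes identically.

"Observed" data come from `make_observed_genotypes()`: the truth is a
gene-flow run under a known kernel base $a^\*$ **with per-patch
Wright–Fisher resampling** (effective size capped at 500 by default), then
individuals are drawn per site (two multinomial gametes per locus) with the
classic 23-site sample-size profile (11–48 individuals). Drift is essential
here: the deterministic projection homogenizes completely, so without drift
the synthetic "observed" matrix would be flat and recovery impossible. This
is also the main respect in which synthetic data are *easier* than real
data: real datasets add null alleles, genotyping error, selection and
demographic history that the generator does not emulate, so passing
recovery tests demonstrates internal consistency of the method, not field
performance.

**Scenario fertility.** The toy recovery scenario uses $f = 1$ (the fitted
model's default elsewhere is 0.1). With 0.25° patch spacing and an effective
size cap of 500, $f = 1$ places neighbouring patches at $N_e m \approx$ 1–10
across the scanned kernel range — the regime where the drift–migration
balance actually varies with distance. At much smaller $f$ every pair
saturates at high divergence and the kernel base is unidentifiable; a
recovery experiment run there would measure noise. The same $f$ is used to
generate truth and to fit, as in any self-consistent simulation study.

**Problem sizes.** The packaged experiments run at deliberately small scale:
the toy reefscape grids to ~20 patches with 14 sampled sites, scans use 6
replicate trajectories of 50 generations, and the sensitivity design uses 30
repetitions per scenario. These sizes keep full pipeline runs interactive
while leaving the statistical assertions (recovery rate, directional
sensitivity) comfortably powered.

## Comparison statistics

Observed genotypes (GENEPOP input) yield per-site allele frequencies,
observed and Nei-unbiased expected heterozygosity, Weir & Cockerham
variance-component $F_{IS}$ and $F_{ST}$, and pairwise chord distances

$$d_\ell = \frac{2\sqrt{2}}{\pi}\sqrt{1 - \sum_a \sqrt{p_a q_a}}$$

averaged over loci (several chord variants circulate; standardizing each
matrix to maximum 1 makes the scale constant immaterial for Mantel
comparison). The Mantel statistic is the Pearson correlation of
lower-triangle entries; the permutation test is one-tailed (greater) with
the $+1$ correction, or exact enumeration for very small systems. Because
the Mantel test is known to be fragile under spatial autocorrelation, a
Spearman-based statistic is reported alongside but never used for ranking.

Pairwise $F_{ST}$ is computed on each two-site subset (common pairwise
practice) rather than from global components. Null-allele corrections are
out of scope: the synthetic generator produces no null alleles, which is a
documented divergence from empirical microsatellite practice.

## Sensitivity design

`sensitivity_experiment()` crosses composition (L3, L2, L1) with
fragmentation (0–80% of reef area removed, whole patches, sampled patches
protected). Every repetition freshly fragments, re-draws densities,
projects gene flow from a fresh random state and correlates against the
observed matrix; medians and 5%/95% quantiles summarize the repetitions.
Fragmentation removal order is a seeded permutation, so removal sets are
nested across fractions under a fixed seed — fragmentation levels are
comparable within a repetition.

## Numerical choices and degenerate inputs

- Initial allele frequencies are flat-Dirichlet on the simplex; a single
  allele per locus degenerates to fixation (frequency 1) throughout.
- Renormalization after every projection step restores the simplex to
  1e-10; chord computations clamp rounding noise below 1e-12 so identical
  populations yield exactly zero distance.
- All-zero distance matrices skip standardization with a warning; Mantel
  correlations against degenerate (constant) matrices are reported as NA.
- Replicate aggregation: kernel scans standardize each replicate's distance
  matrix and rank kernels by the median of the per-replicate correlations;
  `simulated_distance_matrix()` instead averages distances across replicates
  *before* standardizing (the natural order when a single summary matrix is
  wanted). Both orders are defensible; the scan uses per-replicate values so
  its quantiles mean something.
- Genetic sites whose coordinates fall in reef-free cells snap to the
  nearest reef-bearing cell with a warning.
- Unreachable patch pairs get infinite distance and zero kernel weight.
- Fragmentation overshoots its area target by at most one patch; requesting
  more removal than the unprotected area is an error.

## Known limitations

- The transport surrogate is a 2-D, passive, surface-layer tracker. Lagoon
  circulation, vertical behaviour, swimming and tides are not modelled.
- Generations are non-overlapping; long-lived adults (a giant clam reality)
  would smear migration over age classes.
- The projection has no drift; equilibrium structure in the data is matched
  against transient structure in the model. The recovery experiments show
  this still identifies the kernel base under the packaged conditions, but
  the mapping between the best-fit base and a *demographic* dispersal
  kernel should be interpreted with care.
- Mantel correlation compares matrices globally; spatial autocorrelation
  can bias its magnitude, which is why conclusions rest on comparisons
  *between* scenarios rather than absolute correlation values.
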