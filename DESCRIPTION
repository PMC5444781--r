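Package: reefscape
Title: Reefscape Genetics: Habitat-Explicit Simulation of Marine Genetic Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reefscape genetics: build patch-level habitat and
    abundance grids from a reef geomorphology typology, compute over-water
    least-cost geographic distances on a rasterized land mask, construct larval
    dispersal matrices from an isolation-by-distance kernel or a Lagrangian
    transport surrogate with competency and survival rules, project allele
    frequencies across habitat patches with a migration matrix model, and
    compare simulated against observed genetic structure (Cavalli-Sforza and
    Edwards chord distances, Mantel correlation). Includes kernel scans,
    habitat composition-degradation and fragmentation sensitivity experiments,
    a GENEPOP reader/writer, Weir and Cockerham F-statistics, and synthetic
    reefscape, current-field and genotype generators with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
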