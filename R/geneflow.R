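#' Gene-flow simulation configuration
#'
#' @param n_replicates Independent replicate trajectories (default 99), each
#'   with a fresh random initial state and fresh density draws.
#' @param n_loci Number of unlinked loci (default 15).
#' @param alleles_per_locus Alleles segregating per locus (default 10).
#' @param generations Projection horizon T (default 100).
#' @param f Fertility rate: adults produced per adult per generation
#'   (default 0.1).
#' @param seed Master seed; replicate seeds are derived from it.
#' @param drift Optional demographic drift: `NULL` (pure migration,
#'   deterministic) or a list `list(mode = "wright_fisher", ne_cap = 500)`
#'   resampling each patch's allele frequencies from a finite pool of
#'   `2 * min(N_i, ne_cap)` gametes every generation.
#' @return A `gene_flow_config` list.
#' @export
gene_flow_config <- function(n_replicates = 99, n_loci = 15,
                             alleles_per_locus = 10, generations = 100,
                             f = 0.1, seed = NULL, drift = NULL) {
  stopifnot(n_replicates >= 1, n_loci >= 1, alleles_per_locus >= 1,
            generations >= 1, f > 0)
  structure(list(n_replicates = n_replicates, n_loci = n_loci,
                 alleles_per_locus = alleles_per_locus,
                 generations = generations, f = f, seed = seed, drift = drift),
            class = "gene_flow_config")
}

#' Random initial allele-frequency state
#'
#' Each patch x locus frequency vector is drawn from a flat Dirichlet over
#' the allele set (uniform on the simplex), mirroring a random initial
#' distribution of alleles among habitat patches.
#'
#' @param n_patches,n_loci,alleles_per_locus Dimensions.
#' @param seed Optional seed.
#' @return An `allele_state`: array `[patch, locus, allele]` with attribute
#'   `generation = 0`.
#' @export
init_state <- function(n_patches, n_loci, alleles_per_locus, seed = NULL) {
  q <- with_seed_or_not(seed, {
    g <- array(stats::rgamma(n_patches * n_loci * alleles_per_locus, 1, 1),
               dim = c(n_patches, n_loci, alleles_per_locus))
    if (alleles_per_locus == 1) g[] <- 1
    g
  })
  s <- apply(q, c(1, 2), sum)
  q <- q / array(rep(s, alleles_per_locus),
                 dim = c(n_patches, n_loci, alleles_per_locus))
  structure(q, generation = 0L, class = "allele_state")
}

#' Migrant matrix from abundances and a dispersal matrix
#'
#' `A[dest, source] = f * N_source * D[source, dest]`: expected migrants
#' arriving at `dest` from `source` per generation, time-invariant. The
#' destination-major orientation makes the projection step a standard
#' inflow sum.
#'
#' @param grid A `patch_grid` with abundances `N` filled (or a named
#'   abundance vector).
#' @param D A `dispersal_matrix` aligned with the grid.
#' @param f Fertility rate (> 0).
#' @return A `migrant_matrix` list: `A` (dest x source), `N`, `f`.
#' @export
build_migrant_matrix <- function(grid, D, f) {
  if (f <= 0) abort("fertility rate f must be positive")
  N <- if (is.numeric(grid)) grid else {
    ps <- patch_summary(grid)
    stats::setNames(ps$N, ps$patch_id)
  }
  if (anyNA(N)) abort("grid abundances are not filled; run compute_abundance()")
  ids <- names(N)
  if (!is.null(rownames(D))) {
    if (!setequal(rownames(D), ids)) abort("dispersal matrix ids do not match grid")
    D <- D[ids, ids]
  }
  A <- t(f * N * unclass(D))  # row i of D scaled by N_i, then transposed
  dimnames(A) <- list(ids, ids)
  structure(list(A = A, N = N, f = f), class = "migrant_matrix")
}

# one projection step on the flattened state matrix Q [patch, locus*allele]:
# raw inflow + resident parents, then per patch x locus renormalization
project_step_matrix <- function(Qm, A, N, n_loci, n_alleles) {
  np <- nrow(Qm)
  # no migration at all: the parent generation is an exact fixed point
  if (!any(A != 0)) return(Qm)
  raw <- A %*% Qm + N * Qm
  # columns are (locus, allele) with locus fastest, so a (np*L) x K view
  # puts each patch x locus simplex on one row
  dim(raw) <- c(np * n_loci, n_alleles)
  tot <- rowSums(raw)
  zero <- tot == 0
  if (any(zero)) {
    # empty patches with no inflow carry their frequencies forward
    old <- Qm; dim(old) <- c(np * n_loci, n_alleles)
    raw[zero, ] <- old[zero, , drop = FALSE]
    tot[zero] <- 1
  }
  raw <- raw / tot
  dim(raw) <- c(np, n_loci * n_alleles)
  raw
}

#' Advance an allele-frequency state one generation
#'
#' Implements the projection `Q_{t+1} = normalize(A Q_t + N Q_t)`: migrant
#' inflow plus the resident parent generation, renormalized per patch and
#' locus so frequencies stay on the simplex. Patches with zero total (empty
#' and no inflow) carry frequencies forward unchanged.
#'
#' @param state An `allele_state` array.
#' @param M A `migrant_matrix`.
#' @return The state at `t + 1`.
#' @export
project_step <- function(state, M) {
  dm <- dim(state)
  Qm <- unclass(state); dim(Qm) <- c(dm[1], dm[2] * dm[3])
  out <- project_step_matrix(Qm, M$A, M$N, dm[2], dm[3])
  dim(out) <- dm
  structure(out, generation = attr(state, "generation") + 1L,
            class = "allele_state")
}

# Wright-Fisher resampling of each patch x locus from 2*Ne gametes;
# patches without a standing population (Ne < 1, e.g. a class density drawn
# at zero) have nothing to drift and carry their frequencies forward
wf_resample <- function(Qm, ne, n_loci, n_alleles) {
  np <- nrow(Qm)
  dim(Qm) <- c(np, n_loci, n_alleles)
  for (i in seq_len(np)) {
    if (ne[i] < 1) next
    pool <- max(2L, round(2 * ne[i]))
    for (l in seq_len(n_loci)) {
      p <- Qm[i, l, ]
      if (sum(p) > 0) Qm[i, l, ] <- stats::rmultinom(1, pool, p)[, 1] / pool
    }
  }
  dim(Qm) <- c(np, n_loci * n_alleles)
  Qm
}

#' Run the gene-flow simulation ensemble
#'
#' Projects `n_replicates` independent trajectories to the configured
#' horizon. Each replicate draws a fresh random initial state and, when a
#' typology is supplied, fresh habitat densities (and hence a fresh migrant
#' matrix); otherwise the grid's stored abundances are reused.
#'
#' @param grid A `patch_grid` (abundances filled unless `typology` given).
#' @param D A `dispersal_matrix`.
#' @param config A [gene_flow_config()].
#' @param typology Optional `habitat_typology` for per-replicate density
#'   draws.
#' @return A `gene_flow_ensemble`: list of final `allele_state`s plus the
#'   config and patch ids.
#' @export
run_simulation <- function(grid, D, config = gene_flow_config(),
                           typology = NULL) {
  ps <- patch_summary(grid)
  np <- nrow(ps)
  seeds <- derive_seeds(config$seed, 2 * config$n_replicates)
  states <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    g <- if (!is.null(typology)) {
      compute_abundance(grid, typology, seed = seeds[2 * r - 1])
    } else grid
    M <- build_migrant_matrix(g, D, config$f)
    st <- init_state(np, config$n_loci, config$alleles_per_locus,
                     seed = seeds[2 * r])
    Qm <- unclass(st); dim(Qm) <- c(np, config$n_loci * config$alleles_per_locus)
    drift <- config$drift
    run_one <- function() {
      for (t in seq_len(config$generations)) {
        Qm <- project_step_matrix(Qm, M$A, M$N, config$n_loci,
                                  config$alleles_per_locus)
        if (!is.null(drift) && identical(drift$mode, "wright_fisher")) {
          ne <- pmin(M$N, drift$ne_cap %||% 500)
          Qm <- wf_resample(Qm, ne, config$n_loci, config$alleles_per_locus)
        }
      }
      Qm
    }
    Qm <- if (is.null(drift)) run_one() else
      with_seed_or_not(seeds[2 * r] + 1L, run_one())
    dim(Qm) <- c(np, config$n_loci, config$alleles_per_locus)
    states[[r]] <- structure(Qm, generation = config$generations,
                             class = "allele_state")
  }
  structure(list(states = states, patch_ids = ps$patch_id, config = config,
                 sampled = stats::setNames(ps$sampled_site_code, ps$patch_id)),
            class = "gene_flow_ensemble")
}

# chord-distance matrix between patch rows of one allele state
state_chord_matrix <- function(state, rows, labels = NULL) {
  q <- unclass(state)[rows, , , drop = FALSE]
  n <- length(rows); L <- dim(q)[2]
  sq <- sqrt(q)
  d <- matrix(0, n, n)
  for (l in seq_len(L)) {
    s <- sq[, l, ] %*% t(sq[, l, ])  # Gram matrix of sqrt-frequencies
    val <- pmax(0, 1 - pmin(s, 1))
    val[val < 1e-12] <- 0            # rounding noise on identical rows
    d <- d + (2 * sqrt(2) / pi) * sqrt(val)
  }
  d <- d / L
  diag(d) <- 0
  if (!is.null(labels)) dimnames(d) <- list(labels, labels)
  d
}

#' Per-replicate simulated chord-distance matrices
#'
#' @param ensemble A `gene_flow_ensemble`.
#' @param sampled_patches Patch ids to compare (default: patches carrying a
#'   sampling site; site codes label the result).
#' @return List of symmetric chord-distance matrices, one per replicate.
#' @export
replicate_distance_matrices <- function(ensemble, sampled_patches = NULL) {
  ids <- ensemble$patch_ids
  if (is.null(sampled_patches)) {
    sampled_patches <- ids[!is.na(ensemble$sampled[ids])]
  }
  rows <- match(sampled_patches, ids)
  if (anyNA(rows)) abort("sampled patches absent from the ensemble grid")
  if (length(rows) < 2) abort("need at least two sampled patches")
  labels <- unname(ensemble$sampled[sampled_patches])
  labels[is.na(labels)] <- sampled_patches[is.na(labels)]
  lapply(ensemble$states, state_chord_matrix, rows = rows, labels = labels)
}

#' Simulated standardized genetic distance matrix
#'
#' Chord distances between sampled patches are computed from each
#' replicate's final allele frequencies, averaged across replicates, and
#' standardized to maximum one.
#'
#' @inheritParams replicate_distance_matrices
#' @return A symmetric matrix with maximum off-diagonal entry 1 (unless all
#'   distances are zero, in which case it is returned unscaled with a
#'   warning).
#' @export
simulated_distance_matrix <- function(ensemble, sampled_patches = NULL) {
  mats <- replicate_distance_matrices(ensemble, sampled_patches)
  avg <- Reduce(`+`, mats) / length(mats)
  standardize_distance(avg)
}
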