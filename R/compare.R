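#' Mantel correlation between two distance matrices
#'
#' The statistic is the Pearson correlation between corresponding
#' lower-triangle off-diagonal entries. Significance is assessed one-tailed
#' (greater) by permuting the row/column labels of `Y`:
#' `p = (1 + #(r_perm >= r_obs)) / (1 + n_perm)`. With `exact = TRUE`
#' (feasible for small n) all `n!` relabelings are enumerated and the +1
#' correction is dropped. A Spearman-based statistic is reported alongside
#' as a robustness check but never used for ranking.
#'
#' @param X,Y Symmetric zero-diagonal matrices over the same ordered ids.
#' @param n_perm Number of label permutations (default 9999).
#' @param seed Optional seed for the permutations.
#' @param exact Enumerate all permutations instead of sampling.
#' @return A `mantel_result` list: `r`, `p`, `r_spearman`, `n_perm`, `seed`.
#' @export
mantel_test <- function(X, Y, n_perm = 9999, seed = NULL, exact = FALSE) {
  n <- nrow(X)
  if (n < 3) abort("Mantel test needs at least 3 sites")
  if (!is.null(rownames(X)) && !is.null(rownames(Y)) &&
      !identical(rownames(X), rownames(Y))) {
    abort("matrices must share the same ordered ids")
  }
  x <- lower_tri(X)
  r_obs <- stats::cor(x, lower_tri(Y))
  r_sp <- suppressWarnings(stats::cor(x, lower_tri(Y), method = "spearman"))
  r_of_perm <- function(perm) stats::cor(x, lower_tri(Y[perm, perm]))
  if (exact) {
    perms <- all_permutations(n)
    r_perm <- vapply(perms, r_of_perm, numeric(1))
    p <- mean(r_perm >= r_obs - 1e-12)
    n_perm <- length(perms)
  } else {
    r_perm <- with_seed_or_not(seed, {
      vapply(seq_len(n_perm), function(k) r_of_perm(sample(n)), numeric(1))
    })
    p <- (1 + sum(r_perm >= r_obs - 1e-12)) / (1 + n_perm)
  }
  structure(list(r = r_obs, p = p, r_spearman = r_sp, n_perm = n_perm,
                 seed = seed, exact = exact, n = n),
            class = "mantel_result")
}

all_permutations <- function(n) {
  if (n > 8) abort("exact enumeration supported for n <= 8")
  rec <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (tail in rec(v[-i])) out[[length(out) + 1]] <- c(v[i], tail)
    }
    out
  }
  rec(seq_len(n))
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel r = %.4f (Spearman %.4f), one-tailed p = %.4g [%s, n = %d]\n",
              x$r, x$r_spearman, x$p,
              if (x$exact) "exact" else paste0(x$n_perm, " permutations"), x$n))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.mantel_result <- function(x, ...) {
  tibble(statistic = x$r, p.value = x$p, method = "Mantel (Pearson, greater)",
         statistic.spearman = x$r_spearman, n.permutations = x$n_perm)
}

#' @export
glance.mantel_result <- function(x, ...) tidy(x)

# Pearson r between lower triangles, no test (fast path for scans)
mantel_r <- function(X, Y) stats::cor(lower_tri(X), lower_tri(Y))

#' Scan distance-kernel parameters against observed genetic structure
#'
#' For every kernel base `a` in the scan grid, builds the dispersal matrix,
#' runs the gene-flow ensemble, computes per-replicate standardized chord
#' distances between sampled sites, and correlates each against the
#' observed standardized matrix. Kernels are ranked by median Mantel r.
#'
#' @param observed Standardized observed distance matrix, site x site, with
#'   site codes matching the grid's `sampled_site_code`s.
#' @param grid A `patch_grid` with sites attached.
#' @param dist Over-water distance matrix for the grid (km).
#' @param config A [gene_flow_config()].
#' @param scan_grid Kernel bases to scan (default [ibd_scan_grid()]).
#' @param typology Optional typology for per-replicate density draws.
#' @return A `kernel_scan` tibble: `a`, `r_median`, `r_q05`, `r_q95`, `r`
#'   (list-column of replicate values), sorted by `r_median` descending;
#'   attribute `best_a`.
#' @export
scan_kernels <- function(observed, grid, dist, config = gene_flow_config(),
                         scan_grid = ibd_scan_grid(), typology = NULL) {
  if (length(scan_grid) == 0) abort("scan grid is empty")
  sites <- rownames(observed)
  obs_lt <- lower_tri(observed)
  if (stats::sd(obs_lt) == 0) {
    warn("observed distance matrix is degenerate (all equal); r undefined")
  }
  rows <- list()
  for (a in scan_grid) {
    D <- ibd_matrix(dist, a, normalize = TRUE)
    ens <- run_simulation(grid, D, config, typology = typology)
    mats <- replicate_distance_matrices(ens)
    # fully homogenized replicates stay all-zero and are scored NA below
    mats <- lapply(mats, function(m) {
      if (max(m) > 0) m <- m / max(m)
      m[sites, sites]
    })
    rs <- vapply(mats, function(m) {
      if (stats::sd(obs_lt) == 0 || stats::sd(lower_tri(m)) == 0) NA_real_
      else mantel_r(m, observed)
    }, numeric(1))
    rows[[length(rows) + 1]] <- tibble(
      a = a, r_median = stats::median(rs, na.rm = FALSE),
      r_q05 = stats::quantile(rs, 0.05, na.rm = TRUE, names = FALSE),
      r_q95 = stats::quantile(rs, 0.95, na.rm = TRUE, names = FALSE),
      r = list(rs))
  }
  out <- dplyr::bind_rows(rows) %>% dplyr::arrange(dplyr::desc(.data$r_median))
  structure(out, best_a = out$a[1],
            class = c("kernel_scan", class(out)))
}

#' Best kernel base of a scan
#' @param scan A `kernel_scan`.
#' @return The base `a` with the highest median Mantel r.
#' @export
best_kernel <- function(scan) attr(scan, "best_a")

#' Habitat composition and fragmentation sensitivity experiment
#'
#' Runs the full factorial design of composition degradation (L3, L2, L1)
#' by habitat fragmentation (0-80% area removal), using the best-fitting
#' distance kernel. Every scenario is repeated `n_replicates` times; each
#' repetition freshly fragments the map (sampled patches protected), draws
#' densities under the scenario's typology, projects gene flow from a fresh
#' random state, and correlates the simulated against the observed
#' standardized chord distances. Medians and the 5%/95% quantiles of the
#' replicate Mantel r are reported. An optional externally supplied
#' dispersal matrix adds a transport-driven scenario at the intact L3 map.
#'
#' @param observed Standardized observed distance matrix (site codes).
#' @param grid_l3 The intact `patch_grid` built under the L3 typology, with
#'   sites attached.
#' @param typology_l3 The L3 `habitat_typology` used to build `grid_l3`.
#' @param dist Over-water distance matrix of `grid_l3`.
#' @param best_a Kernel base to use (pick with [scan_kernels()] first).
#' @param fragmentation_levels Fractions of reef area to remove.
#' @param composition_levels Typology levels to degrade to.
#' @param n_replicates Repetitions per scenario (default 99).
#' @param config A [gene_flow_config()] (its `n_replicates` is ignored; one
#'   trajectory per repetition).
#' @param seed Master seed.
#' @param external_D Optional `dispersal_matrix` for the extra scenario.
#' @return A `sensitivity_result` tibble: `scenario`, `kernel`,
#'   `fragmentation`, `composition`, `r_median`, `r_q05`, `r_q95`, `r`
#'   (list-column).
#' @export
sensitivity_experiment <- function(observed, grid_l3, typology_l3, dist,
                                   best_a,
                                   fragmentation_levels = c(0, 0.2, 0.4, 0.6, 0.8),
                                   composition_levels = c("L3", "L2", "L1"),
                                   n_replicates = 99,
                                   config = gene_flow_config(),
                                   seed = NULL, external_D = NULL) {
  sites <- rownames(observed)
  ps <- patch_summary(grid_l3)
  missing_sites <- setdiff(sites, stats::na.omit(ps$sampled_site_code))
  if (length(missing_sites) > 0) {
    abort(paste0("observed sites absent from grid: ",
                 paste(missing_sites, collapse = ", ")))
  }
  typos <- list(L3 = typology_l3)
  for (lv in setdiff(composition_levels, "L3")) typos[[lv]] <- reef_typology(lv)
  master_seeds <- derive_seeds(seed, n_replicates)

  one_rep <- function(frag, comp, rep_seed) {
    sds <- derive_seeds(rep_seed, 3)
    g <- fragment(grid_l3, frag, seed = sds[1])
    if (comp != "L3") g <- degrade_composition(g, typology_l3, to = comp)
    g <- compute_abundance(g, typos[[comp]], seed = sds[2])
    ids <- patch_ids(g)
    D <- ibd_matrix(dist[ids, ids], best_a, normalize = TRUE)
    cfg <- gene_flow_config(n_replicates = 1, n_loci = config$n_loci,
                            alleles_per_locus = config$alleles_per_locus,
                            generations = config$generations, f = config$f,
                            seed = sds[3], drift = config$drift)
    ens <- run_simulation(g, D, cfg)
    m <- replicate_distance_matrices(ens)[[1]]
    if (max(m) > 0) m <- m / max(m)
    m <- m[sites, sites]
    if (stats::sd(lower_tri(m)) == 0) NA_real_ else mantel_r(m, observed)
  }

  rows <- list(); sc <- 0
  for (comp in composition_levels) for (frag in fragmentation_levels) {
    sc <- sc + 1
    rs <- vapply(seq_len(n_replicates),
                 function(k) one_rep(frag, comp, master_seeds[k]), numeric(1))
    rows[[sc]] <- tibble(scenario = sc, kernel = sprintf("IBD(a=%.2f)", best_a),
                         fragmentation = frag, composition = comp,
                         r_median = stats::median(rs, na.rm = TRUE),
                         r_q05 = stats::quantile(rs, 0.05, names = FALSE,
                                                 na.rm = TRUE),
                         r_q95 = stats::quantile(rs, 0.95, names = FALSE,
                                                 na.rm = TRUE),
                         r = list(rs))
  }
  if (!is.null(external_D)) {
    sc <- sc + 1
    rs <- vapply(seq_len(n_replicates), function(k) {
      sds <- derive_seeds(master_seeds[k], 3)
      g <- compute_abundance(grid_l3, typology_l3, seed = sds[2])
      cfg <- gene_flow_config(n_replicates = 1, n_loci = config$n_loci,
                              alleles_per_locus = config$alleles_per_locus,
                              generations = config$generations, f = config$f,
                              seed = sds[3], drift = config$drift)
      ens <- run_simulation(g, external_D, cfg)
      m <- replicate_distance_matrices(ens)[[1]]
      if (max(m) > 0) m <- m / max(m)
      m <- m[sites, sites]
      if (stats::sd(lower_tri(m)) == 0) NA_real_ else mantel_r(m, observed)
    }, numeric(1))
    rows[[sc]] <- tibble(scenario = sc, kernel = "IBOD",
                         fragmentation = 0, composition = "L3",
                         r_median = stats::median(rs, na.rm = TRUE),
                         r_q05 = stats::quantile(rs, 0.05, names = FALSE,
                                                 na.rm = TRUE),
                         r_q95 = stats::quantile(rs, 0.95, names = FALSE,
                                                 na.rm = TRUE),
                         r = list(rs))
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("sensitivity_result", class(out)))
}

#' @export
tidy.kernel_scan <- function(x, ...) {
  as_tibble(x) %>% dplyr::select(-"r")
}

#' @export
glance.kernel_scan <- function(x, ...) {
  tibble(best_a = attr(x, "best_a"),
         r_median_best = x$r_median[1],
         n_kernels = nrow(x))
}

#' @export
tidy.sensitivity_result <- function(x, ...) {
  as_tibble(x) %>% dplyr::select(-"r")
}
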