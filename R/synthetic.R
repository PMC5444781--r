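#' Generate a synthetic multi-archipelago reefscape
#'
#' Builds a habitat-class raster and a matching land mask emulating the
#' geography the pipeline targets: a continental "mainland" wrapped by
#' fringing reef, a variable-depth lagoon belt and an outer barrier reef;
#' a cluster of atolls offset to the northwest; and an isolated oceanic
#' island to the east. The layout guarantees habitat classes of strongly
#' contrasting density (shallow vs variable-depth) and at least two groups
#' separated by open water.
#'
#' @param domain List with `lon` and `lat` ranges (degrees).
#' @param habitat_res Habitat raster resolution (default 0.05 degrees).
#' @param land_res Land mask resolution (default 0.1 degrees).
#' @param n_archipelagos 1-3: mainland; + atolls; + isolated island.
#' @param seed Seed for the (small) stochastic displacement of atolls.
#' @param scale Linear scale factor applied to all feature sizes.
#' @return List with `habitat` ([reef_raster()]) and `land`
#'   ([land_raster()]).
#' @export
make_reefscape <- function(domain = list(lon = c(0, 8), lat = c(-20, -15)),
                           habitat_res = 0.05, land_res = 0.1,
                           n_archipelagos = 3, seed = NULL, scale = 1) {
  ax_h <- new_grid_axes(domain$lon, domain$lat, habitat_res)
  ax_l <- new_grid_axes(domain$lon, domain$lat, land_res)
  cx <- domain$lon[1] + 0.3 * diff(domain$lon)
  cy <- mean(domain$lat)

  # class codes
  cls <- c("fringing", "intermediate_vd", "outer_barrier",
           "atoll_bank", "atoll_bank_vd", "oceanic_island")
  code <- stats::setNames(seq_along(cls), cls)

  # elliptical distance to the mainland core (degrees)
  main_d <- function(lon, lat) {
    sqrt(((lon - cx) / 1.6)^2 + ((lat - cy) / 0.8)^2)
  }
  atoll_centers <- with_seed_or_not(seed, {
    k <- 3
    base_lon <- domain$lon[1] + c(0.12, 0.20, 0.16) * diff(domain$lon)
    base_lat <- domain$lat[2] - c(0.15, 0.25, 0.35) * diff(domain$lat)
    cbind(base_lon + stats::runif(k, -0.1, 0.1),
          base_lat + stats::runif(k, -0.1, 0.1))
  })
  iso_lon <- domain$lon[2] - 0.12 * diff(domain$lon)
  iso_lat <- cy + 0.2 * diff(domain$lat)

  classify <- function(lon, lat) {
    d <- main_d(lon, lat) / scale
    out <- 0L
    if (d <= 0.55) return(0L)                        # mainland interior = land
    if (d <= 0.70) return(code[["fringing"]])
    if (d <= 0.95) return(code[["intermediate_vd"]]) # lagoon, variable depth
    if (d <= 1.10) return(code[["outer_barrier"]])
    if (n_archipelagos >= 2) {
      for (k in seq_len(nrow(atoll_centers))) {
        da <- sqrt((lon - atoll_centers[k, 1])^2 +
                     (lat - atoll_centers[k, 2])^2) / scale
        if (da <= 0.18) return(code[["atoll_bank_vd"]])
        if (da <= 0.32) return(code[["atoll_bank"]])
      }
    }
    if (n_archipelagos >= 3) {
      di <- sqrt((lon - iso_lon)^2 + (lat - iso_lat)^2) / scale
      if (di <= 0.10) return(0L)                     # island core = land
      if (di <= 0.28) return(code[["oceanic_island"]])
    }
    out
  }

  hv <- matrix(0L, length(ax_h$lat), length(ax_h$lon))
  for (i in seq_along(ax_h$lat)) for (j in seq_along(ax_h$lon)) {
    hv[i, j] <- classify(ax_h$lon[j], ax_h$lat[i])
  }
  is_land <- function(lon, lat) {
    if (main_d(lon, lat) / scale <= 0.55) return(TRUE)
    if (n_archipelagos >= 3 &&
        sqrt((lon - iso_lon)^2 + (lat - iso_lat)^2) / scale <= 0.10) return(TRUE)
    FALSE
  }
  lv <- matrix(FALSE, length(ax_l$lat), length(ax_l$lon))
  for (i in seq_along(ax_l$lat)) for (j in seq_along(ax_l$lon)) {
    lv[i, j] <- is_land(ax_l$lon[j], ax_l$lat[i])
  }
  # reef never overlaps land: blank habitat wherever its cell falls inside a
  # land cell of the (coarser) mask, keeping the two layers consistent
  lr <- land_raster(ax_l$lon, ax_l$lat, lv)
  for (i in seq_along(ax_h$lat)) for (j in seq_along(ax_h$lon)) {
    if (hv[i, j] > 0) {
      idx <- raster_cell_index(lr, ax_h$lon[j], ax_h$lat[i])
      if (!is.na(idx$row) && lr$land[idx$row, idx$col]) hv[i, j] <- 0L
    }
  }
  list(habitat = reef_raster(ax_h$lon, ax_h$lat, hv, cls), land = lr)
}

#' Generate a synthetic current field
#'
#' A divergence-free field built from a streamfunction: a zonal jet of peak
#' speed `jet_speed` plus `n_eddies` Gaussian eddies with random (seeded)
#' centres. Velocities are obtained by central differencing the
#' streamfunction on a one-cell-padded grid, so the discrete (central
#' difference) divergence vanishes identically on the returned grid
#' interior.
#'
#' @param domain List with `lon` and `lat` ranges.
#' @param resolution Grid resolution in degrees (default 0.1).
#' @param jet_speed Peak zonal jet speed, m/s.
#' @param jet_lat Jet axis latitude (default domain centre).
#' @param jet_width Jet half-width, degrees.
#' @param n_eddies Number of eddies.
#' @param eddy_speed Peak eddy azimuthal speed, m/s.
#' @param eddy_radius Eddy e-folding radius, degrees.
#' @param eddy_centers Optional matrix of eddy centres (lon, lat); random
#'   within the domain when NULL.
#' @param seed Seed for eddy placement and spin.
#' @return A [current_field()].
#' @export
make_currents <- function(domain, resolution = 0.1, jet_speed = 0.3,
                          jet_lat = NULL, jet_width = 0.6, n_eddies = 3,
                          eddy_speed = 0.3, eddy_radius = 0.5,
                          eddy_centers = NULL, seed = NULL) {
  ax <- new_grid_axes(domain$lon, domain$lat, resolution)
  jet_lat <- jet_lat %||% mean(domain$lat)
  m_per_deg <- KM_PER_DEG * 1000 * cos(mean(domain$lat) * pi / 180)
  m_per_deg_lat <- KM_PER_DEG * 1000

  eddies <- with_seed_or_not(seed, {
    if (n_eddies == 0) NULL
    else if (!is.null(eddy_centers)) {
      tibble(lon = eddy_centers[, 1], lat = eddy_centers[, 2],
             spin = rep_len(c(1, -1), n_eddies))
    } else {
      tibble(lon = stats::runif(n_eddies, domain$lon[1], domain$lon[2]),
             lat = stats::runif(n_eddies, domain$lat[1], domain$lat[2]),
             spin = sample(c(-1, 1), n_eddies, replace = TRUE))
    }
  })
  psi_at <- function(lon, lat) {
    # jet: u = jet_speed * sech^2((lat - jet_lat)/w); psi = -U w tanh(...)
    w_m <- jet_width * m_per_deg_lat
    p <- -jet_speed * w_m * tanh((lat - jet_lat) / jet_width)
    if (!is.null(eddies)) {
      for (k in seq_len(nrow(eddies))) {
        r2 <- ((lon - eddies$lon[k])^2 + (lat - eddies$lat[k])^2) / eddy_radius^2
        amp <- eddies$spin[k] * eddy_speed * eddy_radius * m_per_deg_lat *
          exp(0.5)
        p <- p + amp * exp(-r2 / 2)  # Gaussian vortex, peak speed at r = R
      }
    }
    p
  }
  lon_p <- c(ax$lon[1] - resolution, ax$lon, ax$lon[length(ax$lon)] + resolution)
  lat_p <- c(ax$lat[1] - resolution, ax$lat, ax$lat[length(ax$lat)] + resolution)
  psi <- outer(lat_p, lon_p, function(la, lo) psi_at(lo, la))
  ny <- length(ax$lat); nx <- length(ax$lon)
  ii <- seq_len(ny) + 1L; jj <- seq_len(nx) + 1L
  dy <- 2 * resolution * m_per_deg_lat
  dx <- 2 * resolution * m_per_deg
  u <- -(psi[ii + 1L, jj] - psi[ii - 1L, jj]) / dy
  v <- (psi[ii, jj + 1L] - psi[ii, jj - 1L]) / dx
  current_field(ax$lon, ax$lat, u, v)
}

#' Assemble a fully specified synthetic scenario
#'
#' Bundles a reefscape, its patch grid, over-water distances, a sampled-site
#' layout and a ground-truth dispersal model into one object that every
#' later pipeline stage can consume. Sampled sites are spread over the
#' reef by farthest-point placement (always including the archipelago
#' extremes), and receive the classic 23-site sample-size profile recycled
#' to the requested number of sites.
#'
#' @param preset `"toy"` (small domain, about twenty patches) or
#'   `"archipelago"` (the full three-group layout).
#' @param a_star True kernel base generating the "observed" data.
#' @param n_sites Number of sampled sites.
#' @param n_loci,alleles_per_locus Genotype dimensions.
#' @param t_truth Generations projected when generating truth.
#' @param f Fertility rate used for the scenario (truth run and any fitting
#'   against it). The default 1 places the scenario's drift-migration
#'   balance (`Ne m` of order 1-10 across the patch spacing) in a regime
#'   where the dispersal kernel is identifiable from the genetic pattern.
#' @param ne_cap Effective-size cap for Wright-Fisher drift in the truth run
#'   (`drift_mode = "none"` disables drift).
#' @param drift_mode `"wright_fisher"` (default) or `"none"`.
#' @param individuals_per_site Sample sizes; default recycles the packaged
#'   23-site profile.
#' @param seed Master seed.
#' @return A `reefscape_scenario` list: `habitat`, `land`, `grid` (sites
#'   attached), `dist`, `typology`, `sites`, and the truth parameters.
#' @export
reefscape_scenario <- function(preset = c("toy", "archipelago"),
                               a_star = 0.95, n_sites = NULL,
                               n_loci = 15, alleles_per_locus = 10,
                               t_truth = 50, f = 1, ne_cap = 500,
                               drift_mode = c("wright_fisher", "none"),
                               individuals_per_site = NULL, seed = 1L) {
  preset <- match.arg(preset)
  drift_mode <- match.arg(drift_mode)
  seeds <- derive_seeds(seed, 4)
  if (preset == "toy") {
    rs <- make_reefscape(domain = list(lon = c(0, 4), lat = c(-18.3, -15.7)),
                         habitat_res = 0.05, n_archipelagos = 3,
                         seed = seeds[1], scale = 0.3)
    n_sites <- n_sites %||% 14
  } else {
    rs <- make_reefscape(seed = seeds[1])
    n_sites <- n_sites %||% 23
  }
  typology <- reef_typology("L3")
  grid <- grid_habitat(rs$habitat, resolution = 0.25)
  ps <- patch_summary(grid)
  if (n_sites > nrow(ps)) abort("more sites requested than patches available")

  # farthest-point site placement, seeded start at the westernmost patch
  chosen <- which.min(ps$lon)
  while (length(chosen) < n_sites) {
    dmin <- apply(cbind(vapply(chosen, function(c0)
      haversine_km(ps$lon, ps$lat, ps$lon[c0], ps$lat[c0]), numeric(nrow(ps)))),
      1, min)
    dmin[chosen] <- -1
    chosen <- c(chosen, which.max(dmin))
  }
  site_tbl <- tridacna_sites()
  nvec <- rep_len(individuals_per_site %||% site_tbl$n, n_sites)
  codes <- rep_len(site_tbl$site_code, n_sites)
  sites <- tibble(site_code = codes[seq_len(n_sites)],
                  lon = ps$lon[chosen], lat = ps$lat[chosen],
                  n = nvec)
  grid <- attach_sites(grid, sites)
  dist <- overwater_distance(grid, rs$land)
  structure(list(habitat = rs$habitat, land = rs$land, grid = grid,
                 dist = dist, typology = typology, sites = sites,
                 a_star = a_star, n_loci = n_loci,
                 alleles_per_locus = alleles_per_locus, t_truth = t_truth,
                 f = f, ne_cap = ne_cap, drift_mode = drift_mode,
                 seed = seed, seeds = seeds),
            class = "reefscape_scenario")
}

#' Generate an "observed" genotype dataset with known ground truth
#'
#' Projects gene flow under the scenario's true kernel for `t_truth`
#' generations — with per-patch Wright-Fisher resampling injecting drift
#' unless disabled — then draws each sampled individual's two alleles per
#' locus multinomially from its site's final frequencies (random union of
#' gametes). Optionally writes a GENEPOP file plus a JSON truth manifest.
#'
#' @param scenario A [reefscape_scenario()].
#' @param genepop_path,manifest_path Optional output paths.
#' @return List: `genotypes` (a `genotype_tbl`), `truth` (manifest list),
#'   `state` (final truth `allele_state`), `ensemble`.
#' @export
make_observed_genotypes <- function(scenario, genepop_path = NULL,
                                    manifest_path = NULL) {
  sc <- scenario
  seeds <- derive_seeds(sc$seed, 6)
  grid <- compute_abundance(sc$grid, sc$typology, seed = seeds[2])
  D <- ibd_matrix(sc$dist, sc$a_star, normalize = TRUE)
  drift <- if (sc$drift_mode == "wright_fisher") {
    list(mode = "wright_fisher", ne_cap = sc$ne_cap)
  } else NULL
  cfg <- gene_flow_config(n_replicates = 1, n_loci = sc$n_loci,
                          alleles_per_locus = sc$alleles_per_locus,
                          generations = sc$t_truth, f = sc$f,
                          seed = seeds[3], drift = drift)
  ens <- run_simulation(grid, D, cfg)
  state <- ens$states[[1]]
  ps <- patch_summary(grid)
  site_rows <- which(!is.na(ps$sampled_site_code))
  gts <- with_seed_or_not(seeds[4], {
    recs <- list()
    for (k in site_rows) {
      code <- ps$sampled_site_code[k]
      n_ind <- sc$sites$n[match(code, sc$sites$site_code)]
      for (ind in seq_len(n_ind)) {
        id <- sprintf("%s_%03d", code, ind)
        a1 <- integer(sc$n_loci); a2 <- integer(sc$n_loci)
        for (l in seq_len(sc$n_loci)) {
          p <- state[k, l, ]
          draws <- sample.int(sc$alleles_per_locus, 2, replace = TRUE, prob = p)
          a1[l] <- draws[1]; a2[l] <- draws[2]
        }
        recs[[length(recs) + 1]] <- tibble(
          site = code, id = id, locus = sprintf("Locus%02d", seq_len(sc$n_loci)),
          a1 = a1, a2 = a2)
      }
    }
    genotype_table(dplyr::bind_rows(recs))
  })
  truth <- list(a_star = sc$a_star, t_truth = sc$t_truth, f = sc$f,
                drift_mode = sc$drift_mode, ne_cap = sc$ne_cap,
                n_loci = sc$n_loci, alleles_per_locus = sc$alleles_per_locus,
                seed = sc$seed, sites = sc$sites$site_code,
                individuals_per_site = sc$sites$n)
  if (!is.null(genepop_path)) {
    write_genepop(gts, genepop_path, digits = if (sc$alleles_per_locus > 99) 3 else 2,
                  title = "synthetic reefscape genotypes")
  }
  if (!is.null(manifest_path)) {
    jsonlite::write_json(truth, manifest_path, auto_unbox = TRUE, digits = NA)
  }
  list(genotypes = gts, truth = truth, state = state, ensemble = ens)
}

#' Observed standardized chord-distance matrix from genotypes
#'
#' Convenience wrapper: allele frequencies, chord distances, standardize.
#'
#' @param gt A `genotype_tbl`.
#' @param sites Optional site ordering.
#' @return Standardized symmetric distance matrix.
#' @export
observed_distance_matrix <- function(gt, sites = NULL) {
  standardize_distance(chord_distance(allele_freqs(gt), sites = sites))
}
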