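#' Default decay-base scan grid for the distance kernel
#'
#' The standard scan runs the kernel base from 0.40 to 0.99 in steps of
#' 0.01, i.e. 60 candidate kernels.
#'
#' @param from,to,by Scan bounds and step.
#' @return Sorted numeric vector of kernel bases.
#' @export
ibd_scan_grid <- function(from = 0.40, to = 0.99, by = 0.01) {
  g <- round(seq(from, to, by = by), 10)
  if (any(g <= 0 | g >= 1)) abort("scan grid values must lie in (0, 1)")
  unique(sort(g))
}

#' Distance-kernel dispersal matrix
#'
#' Dispersal probability between patches i and j decays geometrically with
#' their over-water distance: raw weight `a^d_ij` (d in km), 1 on the
#' diagonal (self-recruitment at distance zero) and 0 for unreachable pairs.
#' With `normalize = TRUE` (default) each row with any reachable destination
#' is scaled to a settlement distribution summing to one.
#'
#' @param dist Square over-water distance matrix (km) with patch-id dimnames.
#' @param a Decay base in (0, 1); per km of separation.
#' @param normalize Row-normalize to a settlement distribution (default TRUE).
#' @return A `dispersal_matrix`: square numeric matrix, entries in `[0, 1]`,
#'   rows summing to at most 1.
#' @export
ibd_matrix <- function(dist, a, normalize = TRUE) {
  if (!is.numeric(a) || length(a) != 1 || a <= 0 || a >= 1) {
    abort("kernel base `a` must be a single number in (0, 1)")
  }
  w <- a^dist
  w[!is.finite(dist)] <- 0
  if (normalize) {
    rs <- rowSums(w)
    pos <- rs > 0
    w[pos, ] <- w[pos, , drop = FALSE] / rs[pos]
  }
  new_dispersal_matrix(w, normalized = normalize)
}

new_dispersal_matrix <- function(m, normalized = FALSE) {
  structure(m, class = c("dispersal_matrix", class(m)), normalized = normalized)
}

#' Larval life-history parameters for the transport surrogate
#'
#' @param precompetency_days Days of obligatory drift before settlement is
#'   possible (default 9, the precompetency duration of the focal clam).
#' @param competency_end_days Last day settlement remains possible
#'   (default 19).
#' @param decay_rate Exponential mortality rate lambda (day^-1) applied over
#'   the competency window; the default `log(20)/10` leaves 5% survival at
#'   day 19.
#' @param release_per_day Particles released per patch per release day.
#' @param timestep_hours Advection step (<= 24 h).
#' @param release_days Number of daily release events (default 365).
#' @return A `larval_params` list.
#' @export
larval_params <- function(precompetency_days = 9, competency_end_days = 19,
                          decay_rate = log(20) / 10, release_per_day = 1,
                          timestep_hours = 1, release_days = 365) {
  if (precompetency_days >= competency_end_days) {
    abort("precompetency_days must be smaller than competency_end_days")
  }
  if (decay_rate <= 0) abort("decay_rate must be positive")
  if (timestep_hours > 24) abort("timestep must not exceed 24 hours")
  structure(list(precompetency_days = precompetency_days,
                 competency_end_days = competency_end_days,
                 decay_rate = decay_rate, release_per_day = release_per_day,
                 timestep_hours = timestep_hours, release_days = release_days),
            class = "larval_params")
}

#' Lagrangian transport surrogate dispersal matrix
#'
#' Releases particles from every patch centroid and advects them through the
#' supplied current field (bilinear interpolation in space, explicit
#' two-stage midpoint integration). Before the precompetency age no
#' settlement occurs; within the competency window a particle settles in the
#' first patch-bearing grid cell it enters, contributing weight
#' `exp(-lambda * (t - precompetency))` to its source row. Particles hitting
#' land are reflected to their previous position; particles leaving the
#' domain or outliving the competency window are lost. Rows are normalized
#' by total released particles per source and may sum to less than one.
#'
#' @param grid A `patch_grid`.
#' @param currents A [current_field()] covering the domain.
#' @param land A [land_raster()].
#' @param params A [larval_params()].
#' @param seed Optional seed for the sub-cell release jitter.
#' @param jitter Scatter release positions uniformly within the natal cell
#'   (default TRUE); FALSE releases all particles exactly at the centroid.
#' @return A `dispersal_matrix` with attribute `accounting` (released,
#'   settled weight, lost weight per source patch; settled + lost = released).
#' @export
surrogate_transport <- function(grid, currents, land, params = larval_params(),
                                seed = NULL, jitter = TRUE) {
  ps <- patch_summary(grid)
  res <- attr(grid, "resolution")
  np <- nrow(ps)
  dt_h <- params$timestep_hours
  dt_s <- dt_h * 3600
  n_steps <- ceiling(params$competency_end_days * 24 / dt_h)
  n_rel <- params$release_per_day * params$release_days
  # patch lookup for settlement: grid-cell index -> patch row
  patch_key <- paste(floor(ps$lon / res), floor(ps$lat / res))
  patch_of_cell <- stats::setNames(seq_len(np), patch_key)

  jit <- if (jitter) {
    with_seed_or_not(seed, matrix(stats::runif(2 * np * n_rel, -0.45, 0.45) * res,
                                  ncol = 2))
  } else matrix(0, np * n_rel, 2)
  src <- rep(seq_len(np), times = n_rel)
  x <- rep(ps$lon, times = n_rel) + jit[, 1]
  y <- rep(ps$lat, times = n_rel) + jit[, 2]
  # stagger releases over release days
  birth_day <- rep(rep(seq_len(params$release_days) - 1,
                       each = params$release_per_day), each = np)
  alive <- rep(TRUE, length(x))

  D <- matrix(0, np, np, dimnames = list(ps$patch_id, ps$patch_id))
  released <- rep(n_rel, np)
  settled_w <- rep(0, np)

  lon_rng <- range(land$lon) + c(-0.5, 0.5) * land$resolution
  lat_rng <- range(land$lat) + c(-0.5, 0.5) * land$resolution

  is_land_at <- function(lon, lat) {
    idx <- raster_cell_index(land, lon, lat)
    out <- rep(FALSE, length(lon))
    ok <- !is.na(idx$row)
    out[ok] <- land$land[cbind(idx$row[ok], idx$col[ok])]
    out
  }

  m_per_deg_lat <- KM_PER_DEG * 1000
  for (step in seq_len(n_steps)) {
    if (!any(alive)) break
    t_day <- step * dt_h / 24
    act <- which(alive & birth_day <= (step - 1) * dt_h / 24)
    if (length(act) == 0) next
    age <- t_day - birth_day[act]
    cx <- x[act]; cy <- y[act]
    # midpoint advection
    v1 <- interp_current(currents, cx, cy, t_day)
    mx <- cx + v1$u * (dt_s / 2) / (m_per_deg_lat * cos(cy * pi / 180))
    my <- cy + v1$v * (dt_s / 2) / m_per_deg_lat
    v2 <- interp_current(currents, mx, my, t_day)
    nx <- cx + v2$u * dt_s / (m_per_deg_lat * cos(cy * pi / 180))
    ny <- cy + v2$v * dt_s / m_per_deg_lat
    # reflect off land: stay at previous position
    hit <- is_land_at(nx, ny)
    nx[hit] <- cx[hit]; ny[hit] <- cy[hit]
    # leaving the domain is fatal
    out_dom <- nx < lon_rng[1] | nx > lon_rng[2] | ny < lat_rng[1] | ny > lat_rng[2]
    alive[act[out_dom]] <- FALSE
    x[act] <- nx; y[act] <- ny
    # settlement within the competency window
    comp <- !out_dom & age >= params$precompetency_days &
      age <= params$competency_end_days
    if (any(comp)) {
      ci <- act[comp]
      dest <- patch_of_cell[paste(floor(x[ci] / res), floor(y[ci] / res))]
      landed <- !is.na(dest)
      if (any(landed)) {
        idx <- ci[landed]
        w <- exp(-params$decay_rate *
                   (age[comp][landed] - params$precompetency_days))
        for (u in seq_along(idx)) {
          D[src[idx[u]], dest[landed][u]] <- D[src[idx[u]], dest[landed][u]] + w[u]
          settled_w[src[idx[u]]] <- settled_w[src[idx[u]]] + w[u]
        }
        alive[idx] <- FALSE
      }
    }
    # past the competency window: lost
    alive[act[age > params$competency_end_days]] <- FALSE
  }
  D <- D / released
  acct <- tibble(patch_id = ps$patch_id, released = released,
                 settled = settled_w, lost = released - settled_w)
  out <- new_dispersal_matrix(D, normalized = FALSE)
  attr(out, "accounting") <- acct
  out
}

#' Load and validate an externally produced dispersal matrix
#'
#' Entry point for dispersal matrices produced by full hydrodynamic particle
#' tracking outside this package. The matrix is checked (non-negative,
#' rows summing to at most 1) and reordered to the grid's patch order.
#'
#' @param x CSV path (id header row/column) or a matrix with id dimnames.
#' @param grid A `patch_grid` whose patch ids the matrix must match.
#' @return A `dispersal_matrix` in grid order.
#' @export
load_external_dispersal <- function(x, grid) {
  m <- if (is.character(x)) read_distance_matrix(x) else as.matrix(x)
  ids <- patch_ids(grid)
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    if (nrow(m) != length(ids)) abort("dispersal matrix size does not match grid")
    dimnames(m) <- list(ids, ids)
  }
  if (!setequal(rownames(m), ids) || !setequal(colnames(m), ids)) {
    abort("dispersal matrix ids do not match the patch grid")
  }
  m <- m[ids, ids]
  if (any(m < 0)) abort("dispersal matrix has negative entries")
  if (any(rowSums(m) > 1 + 1e-9)) abort("dispersal matrix rows must sum to at most 1")
  new_dispersal_matrix(m, normalized = all(abs(rowSums(m) - 1) < 1e-9))
}
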