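# Independent oracles used to cross-check the implementation. These are
# deliberately written from the defining formulas/algorithms, not by calling
# package internals.

# --- single-pair Dijkstra on a water raster (8-connectivity, haversine) -----
# land: logical matrix [lat, lon]; lon/lat: cell-centre coords
oracle_dijkstra_km <- function(land, lon, lat, from_rc, to_rc) {
  nr <- nrow(land); nc <- ncol(land)
  idx <- function(r, c) (c - 1L) * nr + r
  n <- nr * nc
  distv <- rep(Inf, n)
  done <- rep(FALSE, n)
  done[land] <- TRUE  # land nodes never enter the search
  s <- idx(from_rc[1], from_rc[2]); t <- idx(to_rc[1], to_rc[2])
  distv[s] <- 0
  hav <- function(lo1, la1, lo2, la2) {
    geosphere::distHaversine(cbind(lo1, la1), cbind(lo2, la2),
                             r = 6371008.8) / 1000
  }
  repeat {
    u <- which.min(ifelse(done, Inf, distv))
    if (!is.finite(distv[u]) || done[u]) break
    if (u == t) break
    done[u] <- TRUE
    r0 <- (u - 1L) %% nr + 1L; c0 <- (u - 1L) %/% nr + 1L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r1 <- r0 + dr; c1 <- c0 + dc
      if (r1 < 1 || r1 > nr || c1 < 1 || c1 > nc) next
      if (land[r1, c1]) next
      v <- idx(r1, c1)
      w <- hav(lon[c0], lat[r0], lon[c1], lat[r1])
      if (distv[u] + w < distv[v]) distv[v] <- distv[u] + w
    }
  }
  distv[t]
}

# --- Weir & Cockerham (1984) components, literal transcription -------------
# counts: data.frame(site, a1, a2) for ONE locus
oracle_wc_locus <- function(counts) {
  sites <- unique(counts$site)
  r <- length(sites)
  alleles <- sort(unique(c(counts$a1, counts$a2)))
  total <- c(a = 0, b = 0, c = 0)
  for (al in alleles) {
    n_i <- p_i <- h_i <- numeric(r)
    for (k in seq_len(r)) {
      g <- counts[counts$site == sites[k], ]
      n_i[k] <- nrow(g)
      p_i[k] <- (sum(g$a1 == al) + sum(g$a2 == al)) / (2 * n_i[k])
      h_i[k] <- mean((g$a1 == al) != (g$a2 == al))
    }
    nbar <- mean(n_i)
    nc_ <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    pbar <- sum(n_i * p_i) / (r * nbar)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    a <- (nbar / nc_) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    total <- total + c(a = a, b = b, c = cc)
  }
  total
}

oracle_theta <- function(gt_df) {
  # gt_df: data.frame(site, id, locus, a1, a2), complete calls only
  tot <- c(a = 0, b = 0, c = 0)
  for (l in unique(gt_df$locus)) {
    sub <- gt_df[gt_df$locus == l, ]
    tot <- tot + oracle_wc_locus(sub)
  }
  unname(tot["a"] / sum(tot))
}

# single-site F_IS oracle from the r = 1 variance components
oracle_fis_site <- function(gt_df) {
  bsum <- csum <- 0
  for (l in unique(gt_df$locus)) {
    g <- gt_df[gt_df$locus == l, ]
    n <- nrow(g)
    for (al in sort(unique(c(g$a1, g$a2)))) {
      p <- (sum(g$a1 == al) + sum(g$a2 == al)) / (2 * n)
      h <- mean((g$a1 == al) != (g$a2 == al))
      bsum <- bsum + (n / (n - 1)) * (p * (1 - p) - (2 * n - 1) / (4 * n) * h)
      csum <- csum + h / 2
    }
  }
  1 - csum / (bsum + csum)
}

# --- chord distance from the defining formula -------------------------------
oracle_chord <- function(p_by_locus, q_by_locus) {
  stopifnot(length(p_by_locus) == length(q_by_locus))
  d <- mapply(function(p, q) {
    (2 * sqrt(2) / pi) * sqrt(1 - sum(sqrt(p * q)))
  }, p_by_locus, q_by_locus)
  mean(d)
}

# --- random genotype tables --------------------------------------------------
random_genotype_table <- function(n_sites = 3, n_loci = 3, n_ind = 12,
                                  n_alleles = 4) {
  recs <- list()
  for (s in seq_len(n_sites)) {
    p <- t(replicate(n_loci, {
      x <- stats::rgamma(n_alleles, 1); x / sum(x)
    }))
    for (i in seq_len(n_ind)) {
      a1 <- a2 <- integer(n_loci)
      for (l in seq_len(n_loci)) {
        dr <- sample.int(n_alleles, 2, replace = TRUE, prob = p[l, ])
        a1[l] <- dr[1]; a2[l] <- dr[2]
      }
      recs[[length(recs) + 1]] <- data.frame(
        site = paste0("S", s), id = sprintf("S%d_%03d", s, i),
        locus = paste0("L", seq_len(n_loci)), a1 = a1, a2 = a2)
    }
  }
  genotype_table(do.call(rbind, recs))
}

# --- small hand-built fixtures ----------------------------------------------
# patch grid with explicit centroids/areas; class defaults to "reef"
manual_patch_grid <- function(lon, lat, area_ha = 100, N = NULL,
                              site_codes = NULL, class_id = "reef",
                              resolution = 0.25) {
  n <- length(lon)
  tb <- tibble::tibble(
    patch_id = sprintf("P%03d", seq_len(n)),
    lon = lon, lat = lat,
    class_id = rep_len(class_id, n),
    area_ha = rep_len(area_ha, n),
    N = if (is.null(N)) NA_real_ else rep_len(N, n),
    sampled_site_code = if (is.null(site_codes)) NA_character_ else site_codes)
  reefscape:::new_patch_grid(tb, resolution)
}

# uniform-distance line of patches (km apart along a meridian, no land)
line_distance_matrix <- function(n, step_km = 30) {
  d <- abs(outer(seq_len(n), seq_len(n), "-")) * step_km
  ids <- sprintf("P%03d", seq_len(n))
  dimnames(d) <- list(ids, ids)
  d
}

random_land_raster <- function(nr = 10, nc = 10, p_land = 0.3, res = 0.1,
                               lon0 = 0, lat0 = -20) {
  m <- matrix(stats::runif(nr * nc) < p_land, nr, nc)
  # keep at least one water cell
  if (all(m)) m[1, 1] <- FALSE
  land_raster(lon = seq(lon0 + res / 2, by = res, length.out = nc),
              lat = seq(lat0 + res / 2, by = res, length.out = nr),
              land = m)
}
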