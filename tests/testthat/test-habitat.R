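make_simple_raster <- function(cells, res = 0.05, class_ids = "fringing") {
  # cells: data.frame(lon, lat, code)
  ax <- reefscape:::new_grid_axes(range(cells$lon) + c(-res, res),
                                  range(cells$lat) + c(-res, res), res)
  v <- matrix(0L, length(ax$lat), length(ax$lon))
  idx <- reefscape:::raster_cell_index(
    list(lon = ax$lon, lat = ax$lat, resolution = res), cells$lon, cells$lat)
  v[cbind(idx$row, idx$col)] <- cells$code
  reef_raster(ax$lon, ax$lat, v, class_ids)
}

test_that("gridding a raster counts patches and conserves area", {
  # 7 reef cells spread over distinct 0.25-degree cells
  cells <- data.frame(lon = c(0.1, 0.4, 0.6, 0.9, 1.1, 1.4, 1.6),
                      lat = rep(-17.125, 7), code = 1L)
  r <- make_simple_raster(cells)
  g <- grid_habitat(r, 0.25)
  expect_equal(length(patch_ids(g)), 7L)
  expect_equal(sum(g$area_ha),
               sum(reefscape:::cell_area_ha(cells$lat, 0.05)),
               tolerance = 1e-12)
})

test_that("polygon gridding conserves area across cell boundaries", {
  # rectangle strictly inside one cell
  poly1 <- data.frame(poly_id = 1, class_id = "fringing",
                      lon = c(0.05, 0.20, 0.20, 0.05),
                      lat = c(-17.20, -17.20, -17.05, -17.05))
  g1 <- grid_habitat(poly1, 0.25)
  expect_equal(length(patch_ids(g1)), 1L)
  # rectangle straddling two cells: areas sum to the full polygon area
  poly2 <- data.frame(poly_id = 1, class_id = "fringing",
                      lon = c(0.15, 0.35, 0.35, 0.15),
                      lat = c(-17.20, -17.20, -17.05, -17.05))
  g2 <- grid_habitat(poly2, 0.25)
  expect_equal(length(patch_ids(g2)), 2L)
  full <- sum(g1$area_ha) * (0.35 - 0.15) / (0.20 - 0.05)
  expect_lt(abs(sum(g2$area_ha) - full) / full, 0.001)
})

test_that("gridding rejects degenerate inputs", {
  cells <- data.frame(lon = 0.1, lat = -17.1, code = 2L)
  r <- make_simple_raster(cells)  # only one class id declared
  expect_error(grid_habitat(r, 0.25), "unknown habitat class")
  empty <- make_simple_raster(data.frame(lon = 0.1, lat = -17.1, code = 1L))
  empty$values[] <- 0L
  expect_error(grid_habitat(empty, 0.25), "no reef")
})

test_that("abundance is density times area with truncation at zero", {
  g <- manual_patch_grid(lon = c(0.125, 0.375), lat = c(-17.125, -17.125),
                         area_ha = 2, class_id = "fringing")
  t3 <- reef_typology("L3")
  # sd = 0: deterministic product, independent of seed
  t0 <- t3
  t0$density_sd <- 0
  g1 <- compute_abundance(g, t0, seed = 1)
  g2 <- compute_abundance(g, t0, seed = 999)
  expect_equal(patch_summary(g1)$N, rep(256 * 2, 2))
  expect_identical(patch_summary(g1)$N, patch_summary(g2)$N)
  # negative draws truncate to zero, never negative N
  tneg <- t3
  tneg$density_mean <- 0.01
  tneg$density_sd <- 1000
  for (s in 1:10) {
    gN <- compute_abundance(g, tneg, seed = s)
    expect_true(all(patch_summary(gN)$N >= 0))
  }
})

test_that("one density draw per class is shared across patches", {
  g <- manual_patch_grid(lon = c(0.125, 0.375, 0.625),
                         lat = rep(-17.125, 3), area_ha = 1,
                         class_id = "fringing")
  t3 <- reef_typology("L3")
  gN <- compute_abundance(g, t3, seed = 42)
  Ns <- patch_summary(gN)$N
  expect_equal(Ns[1], Ns[2])
  expect_equal(Ns[1], Ns[3])
})

test_that("variable-depth classes use the hundredth density", {
  g <- manual_patch_grid(lon = 0.125, lat = -17.125, area_ha = 10,
                         class_id = "atoll_bank_vd")
  t3 <- reef_typology("L3")
  t0 <- t3; t0$density_sd <- 0
  gN <- compute_abundance(g, t0)
  expect_equal(patch_summary(gN)$N, 2.34 * 10)
})

test_that("composition degradation re-aggregates areas, keeps geometry", {
  tb <- tibble::tibble(
    patch_id = c("P001", "P001", "P002"),
    lon = c(0.125, 0.125, 0.375), lat = rep(-17.125, 3),
    class_id = c("fringing", "atoll_bank", "fringing_vd"),
    area_ha = c(10, 5, 8), N = NA_real_,
    sampled_site_code = NA_character_)
  g <- reefscape:::new_patch_grid(tb, 0.25)
  t3 <- reef_typology("L3")
  g1 <- degrade_composition(g, t3, to = "L1")
  expect_equal(sort(unique(g1$class_id)), "reef")
  expect_equal(length(patch_ids(g1)), 2L)
  expect_equal(sum(g1$area_ha), sum(g$area_ha))
  expect_equal(g1$area_ha[g1$patch_id == "P001"], 15)
  g2 <- degrade_composition(g, t3, to = "L2")
  expect_setequal(unique(g2$class_id), c("shallow_reefs", "variable_depth_reefs"))
  # degrading an L1 grid to L1 is the identity on areas
  t1 <- reef_typology("L1")
  g11 <- degrade_composition(g1, t1, to = "L1")
  expect_equal(g11$area_ha, g1$area_ha)
  # orphan class errors
  gbad <- g
  gbad$class_id[1] <- "unknown_class"
  expect_error(degrade_composition(gbad, t3, to = "L1"), "orphan")
})

test_that("fragmentation removes the requested area share, protecting sites", {
  g <- manual_patch_grid(lon = seq(0.125, by = 0.25, length.out = 100),
                         lat = rep(-17.125, 100), area_ha = 1)
  expect_identical(fragment(g, 0, seed = 1), g)
  gf <- fragment(g, 0.8, seed = 1)
  expect_true(abs(length(patch_ids(gf)) - 20) <= 1)
  # protected sites are never removed
  gs <- manual_patch_grid(lon = seq(0.125, by = 0.25, length.out = 10),
                          lat = rep(-17.125, 10), area_ha = 1,
                          site_codes = c("A", rep(NA, 9)))
  for (s in 1:5) {
    gfs <- fragment(gs, 0.5, seed = s)
    expect_true("P001" %in% patch_ids(gfs))
  }
  gall <- manual_patch_grid(lon = c(0.125, 0.375), lat = rep(-17.125, 2),
                            site_codes = c("A", "B"))
  expect_error(fragment(gall, 0.2, seed = 1), "unprotected")
})

test_that("removal sets are nested for increasing fractions at fixed seed", {
  g <- manual_patch_grid(lon = seq(0.125, by = 0.25, length.out = 50),
                         lat = rep(-17.125, 50), area_ha = 1)
  kept <- lapply(c(0.2, 0.4, 0.6, 0.8),
                 function(fr) patch_ids(fragment(g, fr, seed = 7)))
  for (k in 2:4) expect_true(all(kept[[k]] %in% kept[[k - 1]]))
})

test_that("patch grids round-trip through CSV", {
  g <- manual_patch_grid(lon = c(0.125, 0.375), lat = rep(-17.125, 2),
                         N = c(10, 20), site_codes = c("A", NA))
  f <- withr::local_tempfile(fileext = ".csv")
  write_patch_grid(g, f)
  g2 <- read_patch_grid(f)
  expect_equal(as.data.frame(g2), as.data.frame(g))
  expect_equal(attr(g2, "resolution"), 0.25)
})

test_that("sites snap to the containing or nearest reef cell", {
  g <- manual_patch_grid(lon = c(0.125, 2.125), lat = rep(-17.125, 2))
  sites <- data.frame(site_code = c("IN", "OFF"),
                      lon = c(0.13, 1.8), lat = c(-17.2, -17.1))
  expect_warning(gs <- attach_sites(g, sites), "snapped")
  ps <- patch_summary(gs)
  expect_equal(ps$sampled_site_code[ps$patch_id == "P001"], "IN")
  expect_equal(ps$sampled_site_code[ps$patch_id == "P002"], "OFF")
})
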