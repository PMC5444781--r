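test_that("initial states sit on the simplex and are seed-reproducible", {
  s1 <- init_state(5, 3, 4, seed = 11)
  s2 <- init_state(5, 3, 4, seed = 11)
  s3 <- init_state(5, 3, 4, seed = 12)
  expect_identical(unclass(s1), unclass(s2))
  expect_false(identical(unclass(s1), unclass(s3)))
  sums <- apply(unclass(s1), c(1, 2), sum)
  expect_equal(unname(sums), matrix(1, 5, 3), tolerance = 1e-12)
  expect_true(all(s1 >= 0))
  # a single allele is always fixed
  s <- init_state(3, 2, 1, seed = 1)
  expect_equal(as.vector(s), rep(1, 6))
})

test_that("the migrant matrix is fertility x abundance x dispersal", {
  g <- manual_patch_grid(lon = c(0.125, 0.375, 0.625), lat = rep(-17.125, 3),
                         N = c(100, 0, 50))
  ids <- patch_ids(g)
  I3 <- diag(3); dimnames(I3) <- list(ids, ids)
  M <- build_migrant_matrix(g, I3, f = 1)
  expect_equal(unname(diag(M$A)), c(100, 0, 50))
  # empty patches send no migrants: zero column
  D <- matrix(1 / 3, 3, 3, dimnames = list(ids, ids))
  M2 <- build_migrant_matrix(g, D, f = 0.5)
  expect_equal(unname(M2$A[, 2]), rep(0, 3))
  # 3-patch hand computation: A[dest, source] = f * N_source * D[source, dest]
  D3 <- matrix(c(0.8, 0.1, 0.1,
                 0.2, 0.7, 0.1,
                 0.3, 0.3, 0.4), 3, 3, byrow = TRUE,
               dimnames = list(ids, ids))
  M3 <- build_migrant_matrix(g, D3, f = 2)
  for (i in 1:3) for (j in 1:3) {
    expect_equal(M3$A[i, j], 2 * c(100, 0, 50)[j] * D3[j, i])
  }
  expect_error(build_migrant_matrix(g, D3, f = 0), "positive")
})

test_that("a zero migrant matrix is an exact fixed point", {
  s <- init_state(4, 2, 3, seed = 5)
  M <- list(A = matrix(0, 4, 4), N = rep(10, 4), f = 1)
  s2 <- project_step(s, M)
  expect_identical(as.vector(s2), as.vector(s))
  expect_equal(attr(s2, "generation"), 1L)
})

test_that("complete symmetric exchange averages two patches in one step", {
  # A[i, j] = N with equal N: inflow equals residents, so the next state is
  # the unweighted mean of the two initial rows
  s <- init_state(2, 2, 4, seed = 9)
  N <- c(50, 50)
  M <- list(A = matrix(50, 2, 2) - diag(c(50, 50)), N = N, f = 1)
  s2 <- project_step(s, M)
  expected <- (unclass(s)[1, , ] + unclass(s)[2, , ]) / 2
  expect_equal(unclass(s2)[1, , ], expected, tolerance = 1e-12)
  expect_equal(unclass(s2)[2, , ], expected, tolerance = 1e-12)
})

test_that("every projection step restores the simplex", {
  withr::local_seed(31)
  for (k in 1:10) {
    np <- sample(3:8, 1)
    s <- init_state(np, 2, 5)
    A <- matrix(stats::runif(np^2, 0, 20), np, np)
    M <- list(A = A, N = stats::runif(np, 0, 100), f = 1)
    s2 <- project_step(s, M)
    sums <- apply(unclass(s2), c(1, 2), sum)
    expect_equal(unname(sums), matrix(1, np, 2), tolerance = 1e-10)
    expect_true(all(s2 >= 0 & s2 <= 1))
  }
})

test_that("zero-inflow empty patches carry frequencies forward", {
  s <- init_state(3, 1, 3, seed = 2)
  A <- matrix(0, 3, 3); A[1, 2] <- 5; A[2, 1] <- 5
  M <- list(A = A, N = c(10, 10, 0), f = 1)  # patch 3 empty, no inflow
  s2 <- project_step(s, M)
  expect_equal(unclass(s2)[3, , ], unclass(s)[3, , ])
})

test_that("connected positive migration homogenizes all patches", {
  d <- line_distance_matrix(6, step_km = 20)
  g <- manual_patch_grid(lon = seq(0.125, by = 0.25, length.out = 6),
                         lat = rep(-17.125, 6), N = 100)
  D <- ibd_matrix(d, 0.92)
  cfg <- gene_flow_config(n_replicates = 1, n_loci = 2, alleles_per_locus = 3,
                          generations = 1500, f = 1, seed = 3)
  ens <- run_simulation(g, D, cfg)
  q <- unclass(ens$states[[1]])
  spread <- max(apply(q, c(2, 3), function(col) diff(range(col))))
  expect_lt(spread, 1e-6)
})

test_that("disconnected components keep their differences", {
  ids <- sprintf("P%03d", 1:4)
  d <- matrix(Inf, 4, 4, dimnames = list(ids, ids))
  d[1:2, 1:2] <- line_distance_matrix(2)[1:2, 1:2]
  d[3:4, 3:4] <- line_distance_matrix(2)[1:2, 1:2]
  diag(d) <- 0
  g <- manual_patch_grid(lon = c(0.125, 0.375, 5.125, 5.375),
                         lat = rep(-17.125, 4), N = 100)
  D <- ibd_matrix(d, 0.9)
  cfg <- gene_flow_config(n_replicates = 1, n_loci = 1, alleles_per_locus = 2,
                          generations = 900, f = 1, seed = 8)
  ens <- run_simulation(g, D, cfg)
  q <- unclass(ens$states[[1]])
  within_1 <- abs(q[1, 1, 1] - q[2, 1, 1])
  between <- abs(q[1, 1, 1] - q[3, 1, 1])
  expect_lt(within_1, 1e-8)
  expect_gt(between, 1e-3)
})

test_that("the two-patch decay rate matches the closed form", {
  # symmetric exchange (no self term) with equal N: per-step contraction of
  # the frequency difference in the normalized system is (1 - m) / (1 + m)
  # with exchange rate m = f * D_off
  ids <- c("P001", "P002")
  for (m in c(0.02, 0.1, 0.3)) {
    Dm <- matrix(c(0, m, m, 0), 2, 2, dimnames = list(ids, ids))
    g <- manual_patch_grid(lon = c(0.125, 0.375), lat = rep(-17.125, 2),
                           N = 100)
    s <- init_state(2, 1, 2, seed = 4)
    M <- build_migrant_matrix(g, Dm, f = 1)
    s1 <- project_step(s, M)
    d0 <- unclass(s)[1, 1, 1] - unclass(s)[2, 1, 1]
    d1 <- unclass(s1)[1, 1, 1] - unclass(s1)[2, 1, 1]
    expect_equal(d1 / d0, (1 - m) / (1 + m), tolerance = 1e-8)
  }
})

test_that("raising migration intensity speeds homogenization", {
  d <- line_distance_matrix(5, step_km = 40)
  g <- manual_patch_grid(lon = seq(0.125, by = 0.25, length.out = 5),
                         lat = rep(-17.125, 5), N = 100)
  D <- ibd_matrix(d, 0.95)
  mean_dist <- vapply(c(0.01, 0.1, 1), function(f_) {
    cfg <- gene_flow_config(n_replicates = 3, n_loci = 3,
                            alleles_per_locus = 4, generations = 40,
                            f = f_, seed = 77)
    ens <- run_simulation(g, D, cfg)
    mats <- replicate_distance_matrices(ens, patch_ids(g))
    mean(vapply(mats, function(m) mean(lower_tri(m)), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_dist) < 0))
})

test_that("relabelling patches permutes the projection consistently", {
  ids <- sprintf("P%03d", 1:4)
  set.seed(13)
  A <- matrix(stats::runif(16, 0, 5), 4, 4)
  N <- stats::runif(4, 10, 100)
  s <- init_state(4, 2, 3, seed = 21)
  s1 <- project_step(s, list(A = A, N = N, f = 1))
  perm <- c(3, 1, 4, 2)
  sp <- structure(unclass(s)[perm, , , drop = FALSE], generation = 0L,
                  class = "allele_state")
  s1p <- project_step(sp, list(A = A[perm, perm], N = N[perm], f = 1))
  expect_equal(unclass(s1p), unclass(s1)[perm, , , drop = FALSE],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("simulated distance matrices are standardized and well-formed", {
  d <- line_distance_matrix(5, step_km = 60)
  g <- manual_patch_grid(lon = seq(0.125, by = 0.25, length.out = 5),
                         lat = rep(-17.125, 5), N = 100,
                         site_codes = c("A", "B", NA, "C", "D"))
  D <- ibd_matrix(d, 0.9)
  cfg <- gene_flow_config(n_replicates = 4, n_loci = 3, alleles_per_locus = 4,
                          generations = 10, f = 0.1, seed = 6)
  ens <- run_simulation(g, D, cfg)
  m <- simulated_distance_matrix(ens)
  expect_equal(rownames(m), c("A", "B", "C", "D"))
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(0, 4))
  expect_equal(max(lower_tri(m)), 1)
  expect_error(replicate_distance_matrices(ens, "P003"), "at least two")
  # identical frequencies across patches give an all-zero matrix, unscaled
  s_flat <- init_state(5, 3, 4, seed = 1)
  for (i in 2:5) s_flat[i, , ] <- s_flat[1, , ]
  ens$states <- list(s_flat)
  expect_warning(m0 <- simulated_distance_matrix(ens), "all zero")
  expect_equal(max(m0), 0)
})

test_that("same seed reproduces the ensemble bitwise", {
  d <- line_distance_matrix(4)
  g <- manual_patch_grid(lon = seq(0.125, by = 0.25, length.out = 4),
                         lat = rep(-17.125, 4), N = 50)
  D <- ibd_matrix(d, 0.9)
  cfg <- gene_flow_config(n_replicates = 2, n_loci = 2, alleles_per_locus = 3,
                          generations = 5, f = 0.2, seed = 42,
                          drift = list(mode = "wright_fisher", ne_cap = 100))
  e1 <- run_simulation(g, D, cfg)
  e2 <- run_simulation(g, D, cfg)
  expect_identical(lapply(e1$states, unclass), lapply(e2$states, unclass))
})
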