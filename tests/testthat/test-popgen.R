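toy_genepop <- function(path) {
  writeLines(c(
    "toy dataset",
    "LocA",
    "LocB",
    "pop",
    "i1 ,  0101 0102",
    "i2 ,  0102 0202",
    "siteA ,  0101 0000",
    "pop",
    "i4 ,  0202 0101",
    "siteB ,  0000 0000"), path)
  path
}

test_that("GENEPOP files parse with pops, loci and missing calls", {
  f <- withr::local_tempfile(fileext = ".gen")
  gt <- read_genepop(toy_genepop(f))
  expect_s3_class(gt, "genotype_tbl")
  expect_setequal(unique(gt$locus), c("LocA", "LocB"))
  expect_equal(length(unique(gt$id[gt$site == "siteA"])), 3L)
  expect_equal(length(unique(gt$id[gt$site == "siteB"])), 2L)
  # 0000 parsed as missing; the all-missing individual is retained
  i5 <- gt[gt$id == "siteB" & gt$site == "siteB", ]
  expect_true(all(is.na(i5$a1)))
  expect_equal(sum(is.na(gt$a1[gt$site == "siteA"])), 1L)
})

test_that("malformed GENEPOP lines are reported with their line number", {
  f <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("t", "LocA", "LocB", "pop", "i1 , 0101"), f)
  expect_error(read_genepop(f), "line 5.*2 loci")
  writeLines(c("t", "LocA", "pop", "i1 , 01xx"), f)
  expect_error(read_genepop(f), "line 4")
  writeLines(c("t", "LocA", "LocB"), f)
  expect_error(read_genepop(f), "pop")
})

test_that("3-digit tables round-trip bit-identically through the writer", {
  withr::local_seed(7)
  gt <- random_genotype_table(n_sites = 2, n_loci = 3, n_ind = 5,
                              n_alleles = 120)
  f1 <- withr::local_tempfile(fileext = ".gen")
  f2 <- withr::local_tempfile(fileext = ".gen")
  write_genepop(gt, f1, digits = 3)
  back <- read_genepop(f1)
  write_genepop(back, f2, digits = 3)
  expect_identical(readLines(f1)[-1], readLines(f2)[-1])  # title aside
  expect_equal(attr(back, "allele_digits"), 3L)
})

test_that("allele frequencies count calls and exclude missing", {
  gt <- genotype_table(data.frame(
    site = "S", id = c("i1", "i1", "i2", "i2", "i3", "i3"),
    locus = rep(c("L1", "L2"), 3),
    a1 = c(1L, 1L, 1L, NA, 1L, 2L), a2 = c(1L, 1L, 2L, NA, 2L, 2L)))
  fr <- allele_freqs(gt)
  # L1: AA, AB, AB -> p(A) = 4/6
  expect_equal(fr$freq[fr$locus == "L1" & fr$allele == 1], 4 / 6)
  # L2: one missing individual excluded from the denominator
  expect_equal(unique(fr$n[fr$locus == "L2"]), 2L)
  sums <- tapply(fr$freq, paste(fr$site, fr$locus), sum)
  expect_equal(as.numeric(sums), rep(1, 2), tolerance = 1e-12)
})

test_that("heterozygosity follows the unbiased formula", {
  # 10 individuals, biallelic, p = 0.5 -> H_exp = (20/19) * 0.5
  gt <- genotype_table(data.frame(
    site = "S", id = sprintf("i%02d", 1:10), locus = "L1",
    a1 = rep(1L, 10), a2 = c(rep(1L, 5), rep(2L, 5))))
  dv <- diversity(gt)
  p <- (10 + 5) / 20
  expect_equal(dv$H_exp, (20 / 19) * (1 - p^2 - (1 - p)^2))
  expect_equal(dv$H_obs, 0.5)
  # all homozygous: zeros and undefined F_IS
  gt0 <- genotype_table(data.frame(
    site = "S", id = sprintf("i%02d", 1:6), locus = "L1",
    a1 = 1L, a2 = 1L))
  dv0 <- diversity(gt0)
  expect_equal(dv0$H_obs, 0)
  expect_equal(dv0$H_exp, 0)
  expect_true(is.na(dv0$F_IS))
})

test_that("F_IS is near zero for Hardy-Weinberg genotype counts", {
  # exact HWE counts: p = 0.5, n = 100 -> 25 AA, 50 AB, 25 BB
  gt <- genotype_table(data.frame(
    site = "S", id = sprintf("i%03d", 1:100), locus = "L1",
    a1 = c(rep(1L, 25), rep(1L, 50), rep(2L, 25)),
    a2 = c(rep(1L, 25), rep(2L, 50), rep(2L, 25))))
  dv <- diversity(gt)
  oracle <- oracle_fis_site(as.data.frame(gt))
  expect_equal(dv$F_IS, oracle, tolerance = 1e-12)
  expect_lt(abs(dv$F_IS), 0.01)
})

test_that("theta is one for fixed alternate alleles and <= 0 for clones", {
  gt <- genotype_table(data.frame(
    site = rep(c("A", "B"), each = 10),
    id = sprintf("i%02d", 1:20), locus = "L1",
    a1 = rep(c(1L, 2L), each = 10), a2 = rep(c(1L, 2L), each = 10)))
  expect_equal(fst_wc(gt)$theta, 1)
  # identical genotype tables in both pops: no differentiation
  half <- data.frame(site = "A", id = sprintf("i%02d", 1:10), locus = "L1",
                     a1 = rep(c(1L, 2L), 5), a2 = rep(c(2L, 1L), 5))
  other <- half; other$site <- "B"; other$id <- sprintf("j%02d", 1:10)
  gt2 <- genotype_table(rbind(half, other))
  expect_lte(fst_wc(gt2)$theta, 1e-12)
})

test_that("variance components match the independent oracle on random tables", {
  withr::local_seed(2024)
  for (k in 1:50) {
    gt <- random_genotype_table(n_sites = sample(2:4, 1),
                                n_loci = sample(1:3, 1),
                                n_ind = sample(c(8, 12, 20), 1),
                                n_alleles = sample(2:5, 1))
    df <- as.data.frame(gt)
    expect_equal(fst_wc(gt)$theta, oracle_theta(df), tolerance = 1e-10)
  }
  # single-site F_IS against its oracle on a further batch
  for (k in 1:10) {
    gt <- random_genotype_table(n_sites = 1, n_loci = 2, n_ind = 15,
                                n_alleles = 4)
    dv <- diversity(gt)
    expect_equal(dv$F_IS, oracle_fis_site(as.data.frame(gt)),
                 tolerance = 1e-10)
  }
})

test_that("chord distance matches the closed form and is a semimetric", {
  # identical frequencies -> 0; opposite fixation -> 2 sqrt(2) / pi
  gt <- genotype_table(data.frame(
    site = rep(c("A", "B"), each = 6),
    id = sprintf("i%02d", 1:12), locus = "L1",
    a1 = rep(c(1L, 2L), each = 6), a2 = rep(c(1L, 2L), each = 6)))
  d <- chord_distance(gt)
  expect_equal(d["A", "B"], 2 * sqrt(2) / pi, tolerance = 1e-12)
  same <- chord_distance(genotype_table(data.frame(
    site = rep(c("A", "B"), each = 4), id = sprintf("i%02d", 1:8),
    locus = "L1", a1 = rep(c(1L, 2L), 4), a2 = rep(c(1L, 2L), 4))))
  expect_equal(same["A", "B"], 0, tolerance = 1e-12)
  # random pairs: oracle agreement, symmetry, identity, relabel invariance
  withr::local_seed(5)
  for (k in 1:20) {
    nA <- 4
    p <- stats::rgamma(nA, 1); p <- p / sum(p)
    q <- stats::rgamma(nA, 1); q <- q / sum(q)
    freqs <- tibble::tibble(
      site = rep(c("X", "Y"), each = nA), locus = "L1",
      allele = rep(1:nA, 2), count = 0, n = 10, freq = c(p, q))
    d1 <- chord_distance(freqs)["X", "Y"]
    expect_equal(d1, oracle_chord(list(p), list(q)), tolerance = 1e-12)
    # relabeling alleles leaves the distance unchanged
    perm <- sample(nA)
    freqs2 <- freqs; freqs2$freq <- c(p[perm], q[perm])
    expect_equal(chord_distance(freqs2)["X", "Y"], d1, tolerance = 1e-12)
  }
})

test_that("standardization rescales to maximum one, preserving ratios", {
  m <- matrix(c(0, 0.45, 0.09, 0.45, 0, 0.18, 0.09, 0.18, 0), 3, 3)
  s <- standardize_distance(m)
  expect_equal(max(s), 1)
  expect_equal(s[1, 3] / s[1, 2], m[1, 3] / m[1, 2])
  z <- matrix(0, 3, 3)
  expect_warning(z2 <- standardize_distance(z), "all zero")
  expect_equal(z2, z)
})
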