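#' Build a genotype table
#'
#' The package-wide genotype container is a long tibble of diploid
#' codominant calls: one row per individual x locus with unordered allele
#' pair (`a1`, `a2`, positive integers; both NA when missing).
#'
#' @param x Data frame with columns `site`, `id`, `locus`, `a1`, `a2`.
#' @return A `genotype_tbl`.
#' @export
genotype_table <- function(x) {
  need <- c("site", "id", "locus", "a1", "a2")
  if (!all(need %in% names(x))) {
    abort(paste0("genotype table needs columns: ", paste(need, collapse = ", ")))
  }
  if (any(stats::na.omit(c(x$a1, x$a2)) <= 0)) {
    abort("allele codes must be positive integers")
  }
  structure(as_tibble(x[, need]),
            class = c("genotype_tbl", class(as_tibble(x))))
}

#' Read a GENEPOP file
#'
#' Parses the classic GENEPOP dialect: a title line, one locus name per line
#' (or a single comma-separated line), `pop` separators, and per-individual
#' lines `id , 0101 0202 ...` in the 2-digit (4 characters per locus) or
#' 3-digit (6 characters) encoding. `00`/`000` alleles mark missing calls.
#'
#' @param file Path to a GENEPOP text file.
#' @return A `genotype_tbl`; sites are named by the last individual id of
#'   each `pop` block (the GENEPOP convention), falling back to `pop1`,
#'   `pop2`, ... when ids repeat.
#' @export
read_genepop <- function(file) {
  lines <- readr::read_lines(file)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3) abort("GENEPOP file too short")
  body <- lines[-1]
  is_pop <- grepl("^\\s*pop\\s*$", body, ignore.case = TRUE)
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) abort("GENEPOP file has no 'pop' separator")
  loc_lines <- body[seq_len(first_pop - 1)]
  loci <- unlist(strsplit(paste(loc_lines, collapse = ","), ","))
  loci <- trimws(loci); loci <- loci[nzchar(loci)]
  if (length(loci) == 0) abort("GENEPOP file declares no loci")

  recs <- list(); pop_idx <- 0; last_ids <- character(0); digits_seen <- 2L
  for (k in seq(first_pop, length(body))) {
    line_no <- k + 1  # position in the original file
    if (is_pop[k]) { pop_idx <- pop_idx + 1; last_ids[pop_idx] <- ""; next }
    parts <- strsplit(body[k], ",")[[1]]
    if (length(parts) < 2) {
      abort(sprintf("line %d: expected 'id , genotypes'", line_no))
    }
    id <- trimws(parts[1])
    toks <- strsplit(trimws(paste(parts[-1], collapse = " ")), "\\s+")[[1]]
    if (length(toks) != length(loci)) {
      abort(sprintf("line %d: %d genotype fields for %d loci",
                    line_no, length(toks), length(loci)))
    }
    wid <- unique(nchar(toks))
    if (length(wid) != 1 || !wid %in% c(4, 6) || any(grepl("\\D", toks))) {
      abort(sprintf("line %d: genotypes must be uniform 4- or 6-digit numeric codes",
                    line_no))
    }
    half <- wid / 2
    digits_seen <- max(digits_seen, half)
    a1 <- as.integer(substr(toks, 1, half))
    a2 <- as.integer(substr(toks, half + 1, wid))
    a1[a1 == 0] <- NA_integer_; a2[a2 == 0] <- NA_integer_
    miss <- is.na(a1) | is.na(a2)
    a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
    recs[[length(recs) + 1]] <- tibble(pop = pop_idx, id = id, locus = loci,
                                       a1 = a1, a2 = a2)
    last_ids[pop_idx] <- id
  }
  tb <- dplyr::bind_rows(recs)
  site_names <- if (anyDuplicated(last_ids) || any(!nzchar(last_ids))) {
    paste0("pop", seq_along(last_ids))
  } else last_ids
  tb$site <- site_names[tb$pop]
  gt <- genotype_table(tb[, c("site", "id", "locus", "a1", "a2")])
  attr(gt, "allele_digits") <- as.integer(digits_seen)
  gt
}

#' Write a genotype table in GENEPOP format
#'
#' @param gt A `genotype_tbl`.
#' @param file Output path.
#' @param digits Allele code width, 2 or 3 (default 3).
#' @param title Title line.
#' @return `file`, invisibly.
#' @export
write_genepop <- function(gt, file, digits = 3, title = "reefscape export") {
  stopifnot(digits %in% c(2, 3))
  loci <- unique(gt$locus)
  fmt <- function(a) ifelse(is.na(a), strrep("0", digits),
                            formatC(a, width = digits, flag = "0"))
  out <- c(title, loci)
  for (s in unique(gt$site)) {
    out <- c(out, "pop")
    sub <- gt %>% dplyr::filter(.data$site == s)
    for (ind in unique(sub$id)) {
      g <- sub %>% dplyr::filter(.data$id == ind)
      g <- g[match(loci, g$locus), ]
      out <- c(out, paste0(ind, " ,  ",
                           paste0(fmt(g$a1), fmt(g$a2), collapse = " ")))
    }
  }
  readr::write_lines(out, file)
  invisible(file)
}

#' Per-site allele frequencies
#'
#' Frequencies are allele counts over `2 n` where `n` counts individuals
#' with a callable genotype at that site and locus; missing calls never
#' enter the denominator.
#'
#' @param gt A `genotype_tbl`.
#' @return A `site_freqs` tibble: `site`, `locus`, `allele`, `count`,
#'   `freq`, `n` (callable diploid individuals).
#' @export
allele_freqs <- function(gt) {
  called <- strip_tbl(gt) %>% dplyr::filter(!is.na(.data$a1) & !is.na(.data$a2))
  long <- dplyr::bind_rows(
    called %>% dplyr::select("site", "locus", allele = "a1"),
    called %>% dplyr::select("site", "locus", allele = "a2"))
  nn <- called %>% dplyr::count(.data$site, .data$locus, name = "n")
  out <- long %>%
    dplyr::count(.data$site, .data$locus, .data$allele, name = "count") %>%
    dplyr::left_join(nn, by = c("site", "locus")) %>%
    dplyr::mutate(freq = .data$count / (2 * .data$n)) %>%
    dplyr::arrange(.data$site, .data$locus, .data$allele)
  structure(out, class = c("site_freqs", class(out)))
}

# genotype summaries per site-locus used by the variance-component machinery:
# n, allele freqs p_a, and observed heterozygote frequency per allele h_a
wc_site_locus_stats <- function(gt) {
  called <- strip_tbl(gt) %>% dplyr::filter(!is.na(.data$a1) & !is.na(.data$a2))
  called %>%
    dplyr::group_by(.data$site, .data$locus) %>%
    dplyr::group_map(function(df, key) {
      alleles <- sort(unique(c(df$a1, df$a2)))
      n <- nrow(df)
      p <- vapply(alleles, function(a) sum(df$a1 == a) + sum(df$a2 == a),
                  numeric(1)) / (2 * n)
      h <- vapply(alleles, function(a) {
        sum((df$a1 == a) != (df$a2 == a))
      }, numeric(1)) / n
      tibble(site = key$site, locus = key$locus, allele = alleles,
             n = n, p = p, h = h)
    }) %>% dplyr::bind_rows()
}

# Weir & Cockerham (1984) variance components for one allele across r samples
wc_components <- function(n_i, p_i, h_i) {
  r <- length(n_i)
  nbar <- mean(n_i)
  pbar <- sum(n_i * p_i) / (r * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  if (r > 1) {
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                          (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
  } else {
    a <- 0
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
  }
  c_ <- hbar / 2
  c(a = a, b = b, c = c_)
}

#' Within-sample diversity and inbreeding statistics
#'
#' Per site: observed heterozygosity, Nei's unbiased expected
#' heterozygosity `(2n/(2n-1)) (1 - sum p^2)` averaged over loci, and the
#' multilocus Weir & Cockerham within-sample fixation index
#' `F_IS = 1 - sum(c) / sum(b + c)` with components summed over alleles and
#' loci. Loci with fewer than two called individuals are excluded from
#' `H_exp` (with a message in the result's `n_loci_hexp`).
#'
#' @param gt A `genotype_tbl`.
#' @param by `"site"` (default) for multilocus site summaries or
#'   `"locus"` for per site x locus statistics.
#' @return A tibble of diversity statistics.
#' @export
diversity <- function(gt, by = c("site", "locus")) {
  by <- match.arg(by)
  st <- wc_site_locus_stats(gt)
  called <- strip_tbl(gt) %>% dplyr::filter(!is.na(.data$a1) & !is.na(.data$a2))
  hobs <- called %>%
    dplyr::group_by(.data$site, .data$locus) %>%
    dplyr::summarise(n = dplyr::n(),
                     H_obs = mean(.data$a1 != .data$a2), .groups = "drop")
  hexp <- st %>%
    dplyr::group_by(.data$site, .data$locus) %>%
    dplyr::summarise(n = .data$n[1],
                     H_exp = ifelse(.data$n[1] >= 2,
                                    (2 * .data$n[1] / (2 * .data$n[1] - 1)) *
                                      (1 - sum(.data$p^2)), NA_real_),
                     .groups = "drop")
  comps <- st %>%
    dplyr::group_by(.data$site, .data$locus) %>%
    dplyr::summarise(
      b = sum(vapply(seq_along(.data$allele), function(i)
        wc_components(.data$n[i], .data$p[i], .data$h[i])["b"], numeric(1))),
      c = sum(vapply(seq_along(.data$allele), function(i)
        wc_components(.data$n[i], .data$p[i], .data$h[i])["c"], numeric(1))),
      .groups = "drop")
  locus_tbl <- hobs %>%
    dplyr::left_join(hexp %>% dplyr::select(-"n"), by = c("site", "locus")) %>%
    dplyr::left_join(comps, by = c("site", "locus")) %>%
    dplyr::mutate(F_IS = ifelse(.data$b + .data$c > 0,
                                1 - .data$c / (.data$b + .data$c), NA_real_))
  if (by == "locus") {
    return(locus_tbl %>% dplyr::select("site", "locus", "n", "H_obs",
                                       "H_exp", "F_IS"))
  }
  locus_tbl %>%
    dplyr::group_by(.data$site) %>%
    dplyr::summarise(
      n = max(.data$n),
      H_obs = mean(.data$H_obs),
      H_exp = mean(.data$H_exp, na.rm = TRUE),
      n_loci_hexp = sum(!is.na(.data$H_exp)),
      F_IS = ifelse(sum(.data$b + .data$c) > 0,
                    1 - sum(.data$c) / sum(.data$b + .data$c), NA_real_),
      .groups = "drop")
}

#' Weir & Cockerham fixation index theta (F_ST)
#'
#' Multilocus theta is the ratio of summed variance components
#' `sum(a) / sum(a + b + c)` over alleles and loci (Weir & Cockerham 1984).
#' Loci monomorphic across the compared samples contribute zero components
#' and are effectively skipped.
#'
#' @param gt A `genotype_tbl` with at least two sites.
#' @param pairwise If TRUE, additionally return the site x site matrix of
#'   pairwise theta computed on each two-site subset.
#' @return A list with `theta` (multilocus global), `per_locus` tibble, and
#'   (optionally) `pairwise` matrix.
#' @export
fst_wc <- function(gt, pairwise = FALSE) {
  sites <- unique(gt$site)
  if (length(sites) < 2) abort("fst_wc needs at least two sites")
  global <- wc_theta(gt)
  out <- list(theta = global$theta, per_locus = global$per_locus)
  if (pairwise) {
    m <- matrix(NA_real_, length(sites), length(sites),
                dimnames = list(sites, sites))
    diag(m) <- 0
    for (i in seq_along(sites)) for (j in seq_len(i - 1)) {
      sub <- gt %>% dplyr::filter(.data$site %in% sites[c(i, j)])
      m[i, j] <- m[j, i] <- wc_theta(sub)$theta
    }
    out$pairwise <- m
  }
  out
}

wc_theta <- function(gt) {
  st <- wc_site_locus_stats(gt)
  # union of alleles per locus across sites; absent alleles enter with p = 0
  per_locus <- st %>%
    dplyr::group_by(.data$locus) %>%
    dplyr::group_map(function(df, key) {
      sites <- unique(df$site)
      if (length(sites) < 2) return(tibble(locus = key$locus,
                                           a = 0, b = 0, c = 0))
      alleles <- sort(unique(df$allele))
      nn <- df %>% dplyr::distinct(.data$site, .data$n)
      acc <- c(a = 0, b = 0, c = 0)
      for (al in alleles) {
        sub <- df %>% dplyr::filter(.data$allele == al)
        p_i <- stats::setNames(rep(0, length(sites)), sites)
        h_i <- p_i
        p_i[sub$site] <- sub$p; h_i[sub$site] <- sub$h
        n_i <- nn$n[match(sites, nn$site)]
        acc <- acc + wc_components(n_i, p_i, h_i)
      }
      tibble(locus = key$locus, a = acc["a"], b = acc["b"], c = acc["c"])
    }) %>% dplyr::bind_rows()
  denom <- sum(per_locus$a + per_locus$b + per_locus$c)
  theta <- if (denom > 0) sum(per_locus$a) / denom else NA_real_
  list(theta = theta,
       per_locus = per_locus %>%
         dplyr::mutate(theta = ifelse(.data$a + .data$b + .data$c > 0,
                                      .data$a / (.data$a + .data$b + .data$c),
                                      NA_real_)))
}

# per-locus chord distance between two frequency vectors over a shared
# allele set: (2*sqrt(2)/pi) * sqrt(1 - sum(sqrt(p*q)))
chord_locus <- function(p, q) {
  s <- sum(sqrt(p * q))
  (2 * sqrt(2) / pi) * sqrt(max(0, 1 - s))
}

#' Cavalli-Sforza & Edwards chord distance between sites
#'
#' For each locus the chord distance
#' `(2 sqrt(2) / pi) sqrt(1 - sum_a sqrt(p_a q_a))` is evaluated over the
#' union of alleles observed in the two sites (absent alleles count as
#' frequency zero); the reported distance is the mean over loci. Loci with
#' no callable genotypes in either site are dropped.
#'
#' @param freqs A `site_freqs` tibble from [allele_freqs()], or a
#'   `genotype_tbl` (frequencies are computed first).
#' @param sites Optional subset/ordering of site codes.
#' @return A symmetric matrix of chord distances with zero diagonal.
#' @export
chord_distance <- function(freqs, sites = NULL) {
  if (inherits(freqs, "genotype_tbl")) freqs <- allele_freqs(freqs)
  sites <- sites %||% unique(freqs$site)
  loci <- unique(freqs$locus)
  d <- matrix(0, length(sites), length(sites), dimnames = list(sites, sites))
  fl <- split(freqs, freqs$locus)
  for (i in seq_along(sites)) for (j in seq_len(i - 1)) {
    vals <- vapply(fl, function(df) {
      pi_ <- df %>% dplyr::filter(.data$site == sites[i])
      qj <- df %>% dplyr::filter(.data$site == sites[j])
      if (nrow(pi_) == 0 || nrow(qj) == 0) return(NA_real_)
      alleles <- union(pi_$allele, qj$allele)
      p <- stats::setNames(rep(0, length(alleles)), alleles)
      q <- p
      p[as.character(pi_$allele)] <- pi_$freq
      q[as.character(qj$allele)] <- qj$freq
      chord_locus(p, q)
    }, numeric(1))
    d[i, j] <- d[j, i] <- mean(vals, na.rm = TRUE)
  }
  d
}

#' Standardize a distance matrix to maximum one
#'
#' Divides by the largest off-diagonal entry. An all-zero matrix is returned
#' unchanged with a warning (no structure to standardize).
#'
#' @param m Non-negative symmetric matrix.
#' @return The rescaled matrix.
#' @export
standardize_distance <- function(m) {
  off <- m; diag(off) <- 0
  mx <- max(off)
  if (mx == 0) {
    warn("distance matrix is all zero; standardization skipped")
    return(m)
  }
  m / mx
}
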