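# Queller-Goodnight pairwise relatedness.
#
# Per locus, for genotypes x = {a, b} and y = {c, d} at reference
# frequencies p: num_x = (I(a=c) + I(a=d) + I(b=c) + I(b=d))/2 - p_a - p_b,
# den_x = 1 + I(a=b) - p_a - p_b. The multilocus estimate is the ratio of
# sums r_xy = sum(num_x) / sum(den_x) (not the mean of per-locus ratios,
# which is undefined for heterozygotes whose two alleles exhaust the
# frequency mass), symmetrized as r = (r_xy + r_yx) / 2. Loci where both
# directional denominators vanish are skipped; loci not fully typed in both
# individuals are skipped. For locus-identical genotypes each per-locus
# numerator equals its denominator, so r = 1 exactly, for any frequencies.

#' Queller-Goodnight relatedness for paired genotypes
#'
#' `x` and `y` are wide genotype tibbles with the same number of rows; the
#' estimator is evaluated row by row (row i of `x` against row i of `y`).
#' Use [qg_matrix()] for all cross pairs.
#'
#' @param x,y Wide genotype tibbles, aligned by row.
#' @param freqs Reference allele frequencies (`locus`, `allele`, `freq`),
#'   typically [allele_frequencies()] of the designated cohort. Alleles
#'   absent from the table get frequency 0.
#' @return Numeric vector of symmetrized relatedness estimates; values lie
#'   near 0 for unrelated pairs and equal 1 for identical genotypes.
#'   Errors if a pair shares no informative locus.
#' @export
qg_relatedness <- function(x, y, freqs) {
  if (nrow(x) != nrow(y)) abort("`x` and `y` must have the same number of rows.")
  loci <- intersect(str_loci(x), str_loci(y))
  if (!length(loci)) abort("`x` and `y` share no loci.")
  mx <- allele_matrices(x, loci)
  my <- allele_matrices(y, loci)
  lookup <- freq_lookup(freqs)

  nx_sum <- dx_sum <- ny_sum <- dy_sum <- numeric(nrow(x))
  n_loci_used <- integer(nrow(x))
  for (li in seq_along(loci)) {
    l <- loci[li]
    a <- as.vector(mx$a1[, li])
    b <- as.vector(mx$a2[, li])
    c_ <- as.vector(my$a1[, li])
    d <- as.vector(my$a2[, li])
    typed <- a != 0L & b != 0L & c_ != 0L & d != 0L
    s <- ((a == c_) + (a == d) + (b == c_) + (b == d)) / 2
    px <- lookup(l, a) + lookup(l, b)
    py <- lookup(l, c_) + lookup(l, d)
    num_x <- s - px
    den_x <- 1 + (a == b) - px
    num_y <- s - py
    den_y <- 1 + (c_ == d) - py
    use <- typed & !(den_x == 0 & den_y == 0)
    nx_sum <- nx_sum + ifelse(use, num_x, 0)
    dx_sum <- dx_sum + ifelse(use, den_x, 0)
    ny_sum <- ny_sum + ifelse(use, num_y, 0)
    dy_sum <- dy_sum + ifelse(use, den_y, 0)
    n_loci_used <- n_loci_used + use
  }
  if (any(n_loci_used == 0)) {
    abort("A pair has no informative loci (all denominators zero or untyped).")
  }
  r <- (nx_sum / dx_sum + ny_sum / dy_sum) / 2
  attr(r, "loci_used") <- n_loci_used
  r
}

#' Relatedness matrix between two cohorts
#'
#' Evaluates the symmetrized Queller-Goodnight estimator for every (row of
#' `x`) x (row of `y`) pair, e.g. port samples against the full farm cohort
#' of the year.
#'
#' @inheritParams qg_relatedness
#' @return Numeric matrix (rows: `x$sample_id`, columns: `y$sample_id`)
#'   with attribute `loci_used` (matrix of locus counts per pair). Pairs
#'   with no informative locus are `NA`.
#' @export
qg_matrix <- function(x, y, freqs) {
  loci <- intersect(str_loci(x), str_loci(y))
  if (!length(loci)) abort("`x` and `y` share no loci.")
  mx <- allele_matrices(x, loci)
  my <- allele_matrices(y, loci)
  lookup <- freq_lookup(freqs)
  n1 <- nrow(x)
  n2 <- nrow(y)

  nx_sum <- dx_sum <- ny_sum <- dy_sum <- matrix(0, n1, n2)
  used <- matrix(0L, n1, n2)
  for (li in seq_along(loci)) {
    l <- loci[li]
    a <- as.vector(mx$a1[, li])
    b <- as.vector(mx$a2[, li])
    c_ <- as.vector(my$a1[, li])
    d <- as.vector(my$a2[, li])
    s <- (outer(a, c_, "==") + outer(a, d, "==") +
      outer(b, c_, "==") + outer(b, d, "==")) / 2
    px <- lookup(l, a) + lookup(l, b) # length n1
    py <- lookup(l, c_) + lookup(l, d) # length n2
    den_x <- 1 + (a == b) - px
    den_y <- 1 + (c_ == d) - py
    typed <- outer(a != 0L & b != 0L, c_ != 0L & d != 0L, "&")
    use <- typed & !outer(den_x == 0, den_y == 0, "&")
    nx_sum <- nx_sum + use * (s - px)
    dx_sum <- dx_sum + use * matrix(den_x, n1, n2)
    ny_sum <- ny_sum + use * sweep(s, 2, py)
    dy_sum <- dy_sum + use * matrix(den_y, n1, n2, byrow = TRUE)
    used <- used + use
  }
  r <- (nx_sum / dx_sum + ny_sum / dy_sum) / 2
  r[used == 0L] <- NA_real_
  dimnames(r) <- list(x$sample_id, y$sample_id)
  attr(r, "loci_used") <- used
  r
}

#' Write a relatedness matrix as TSV
#'
#' Heatmap-style export: row ids in the first column, one column per
#' comparison sample.
#'
#' @param r A [qg_matrix()] result.
#' @param path Output path.
#' @export
write_relatedness_matrix <- function(r, path) {
  df <- as_tibble(as.data.frame(r), rownames = "sample_id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
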