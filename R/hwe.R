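#' Exact test of Hardy-Weinberg equilibrium at one locus
#'
#' Exact conditional test: the probability, under the Levene distribution of
#' genotype tables conditional on the observed allele counts, of tables
#' whose probability is less than or equal to that of the observed table.
#' All tables are enumerated when their number stays below `max_tables`;
#' otherwise a seeded Monte-Carlo sample of random pairings of the allele
#' copies is used, with `p = (1 + #\{P_perm <= P_obs\}) / (reps + 1)`.
#'
#' @param x A wide genotype tibble (with `locus` naming the locus to test)
#'   or a symmetric genotype count matrix (entry `[i, j] + [j, i]` counting
#'   heterozygotes `i/j` for `i != j`, diagonal counting homozygotes).
#' @param locus Locus name when `x` is a genotype table.
#' @param mc_reps Monte-Carlo replicates for large tables (default 1e5).
#' @param max_tables Enumeration bound (default 1e6 tables).
#' @param seed Optional integer seed for the Monte-Carlo branch.
#' @return List of class `hwe_test`: `p_value` in `(0, 1]`, `method`
#'   (`"enumeration"` or `"monte-carlo"`), `n_tables` or `reps`, and the
#'   observed table's log-probability.
#' @export
hwe_exact <- function(x, locus = NULL, mc_reps = 1e5, max_tables = 1e6,
                      seed = NULL) {
  counts <- if (is.matrix(x)) {
    if (nrow(x) != ncol(x)) abort("Genotype count matrix must be square.")
    m <- x
    up <- m
    up[lower.tri(up)] <- 0
    diag(up) <- diag(m)
    up + t(m * lower.tri(m))
  } else {
    if (is.null(locus)) abort("`locus` is required with a genotype table.")
    genotype_count_matrix(x, locus)
  }
  k <- nrow(counts)
  if (k < 2) abort("HWE test requires at least 2 alleles.")
  n <- sum(counts[upper.tri(counts, diag = TRUE)])
  if (n < 1) abort("HWE test requires at least 1 individual.")
  m_allele <- allele_copy_counts(counts)
  obs_lp <- levene_log_prob(counts, m_allele, n)

  enum <- enumerate_hwe_tables(m_allele, n, max_tables)
  if (!is.null(enum)) {
    keep <- enum$log_prob <= obs_lp + 1e-9
    p <- sum(exp(enum$log_prob[keep]))
    out <- list(
      p_value = min(1, p), method = "enumeration",
      n_tables = length(enum$log_prob), log_prob_obs = obs_lp
    )
  } else {
    p <- with_seed_if(seed, {
      copies <- rep(seq_len(k), times = m_allele)
      const <- lgamma(n + 1) + sum(lgamma(m_allele + 1)) - lgamma(2 * n + 1)
      hits <- 0L
      for (r in seq_len(mc_reps)) {
        perm <- sample(copies)
        t1 <- perm[seq_len(n)]
        t2 <- perm[n + seq_len(n)]
        code <- (pmin(t1, t2) - 1L) * k + pmax(t1, t2)
        cnt <- tabulate(code, k * k)
        lp <- const + sum(t1 != t2) * log(2) - sum(lgamma(cnt[cnt > 0L] + 1))
        if (lp <= obs_lp + 1e-9) hits <- hits + 1L
      }
      (1 + hits) / (mc_reps + 1)
    })
    out <- list(
      p_value = p, method = "monte-carlo", reps = mc_reps,
      log_prob_obs = obs_lp
    )
  }
  structure(out, class = "hwe_test")
}

#' @export
print.hwe_test <- function(x, ...) {
  cat(sprintf(
    "Exact HWE test (%s): p = %.4g\n", x$method, x$p_value
  ))
  invisible(x)
}

# Upper-triangular genotype count matrix at one locus (typed individuals).
genotype_count_matrix <- function(genotypes, locus) {
  a1 <- genotypes[[paste0(locus, ".1")]]
  a2 <- genotypes[[paste0(locus, ".2")]]
  if (is.null(a1)) abort(sprintf("Locus not present: %s.", locus))
  typed <- a1 != 0 & a2 != 0
  a1 <- a1[typed]
  a2 <- a2[typed]
  alleles <- sort(unique(c(a1, a2)))
  k <- length(alleles)
  i1 <- match(pmin(a1, a2), alleles)
  i2 <- match(pmax(a1, a2), alleles)
  tab <- matrix(0L, k, k, dimnames = list(alleles, alleles))
  for (r in seq_along(i1)) {
    tab[i1[r], i2[r]] <- tab[i1[r], i2[r]] + 1L
  }
  tab
}

allele_copy_counts <- function(counts) {
  k <- nrow(counts)
  vapply(seq_len(k), function(i) {
    row_i <- sum(counts[i, i:k])
    col_i <- if (i > 1) sum(counts[seq_len(i - 1), i]) else 0L
    as.integer(row_i + col_i + counts[i, i])
  }, integer(1))
}

# Levene conditional probability of a genotype table given allele counts:
# P = n! * prod(m_i!) * 2^h / ((2n)! * prod(n_ij!)), h = heterozygote count.
levene_log_prob <- function(counts, m_allele, n) {
  k <- nrow(counts)
  het <- sum(counts[upper.tri(counts)])
  cells <- counts[upper.tri(counts, diag = TRUE)]
  lgamma(n + 1) + sum(lgamma(m_allele + 1)) + het * log(2) -
    lgamma(2 * n + 1) - sum(lgamma(cells + 1))
}

# Enumerate every genotype table consistent with the allele copy counts,
# parameterized by the off-diagonal (heterozygote) cells: the homozygote
# diagonal is then determined by the allele counts. Fully vectorized.
# Returns NULL when the candidate grid or the realized table count exceeds
# the enumeration bound (the caller falls back to Monte-Carlo).
enumerate_hwe_tables <- function(m_allele, n, max_tables) {
  k <- length(m_allele)
  if (k == 2L) {
    # closed biallelic case: the heterozygote count fixes the table
    h <- seq(min(m_allele) %% 2L, min(m_allele), by = 2L)
    if (length(h) > max_tables) {
      return(NULL)
    }
    n11 <- (m_allele[1] - h) %/% 2L
    n22 <- (m_allele[2] - h) %/% 2L
    const <- lgamma(n + 1) + sum(lgamma(m_allele + 1)) - lgamma(2 * n + 1)
    lp <- const + h * log(2) -
      (lgamma(h + 1) + lgamma(n11 + 1) + lgamma(n22 + 1))
    return(list(log_prob = lp))
  }
  pairs <- which(upper.tri(diag(k)), arr.ind = TRUE)
  bounds <- pmin(m_allele[pairs[, 1]], m_allele[pairs[, 2]])
  grid_size <- prod(bounds + 1)
  if (!is.finite(grid_size) || grid_size > 4 * max_tables) {
    return(NULL)
  }
  het <- as.matrix(expand.grid(lapply(bounds, function(b) 0:b)))
  # copies of allele i consumed by heterozygote cells
  consumed <- matrix(0, nrow(het), k)
  for (p in seq_len(nrow(pairs))) {
    consumed[, pairs[p, 1]] <- consumed[, pairs[p, 1]] + het[, p]
    consumed[, pairs[p, 2]] <- consumed[, pairs[p, 2]] + het[, p]
  }
  rem <- matrix(m_allele, nrow(het), k, byrow = TRUE) - consumed
  ok <- rowSums(rem < 0 | rem %% 2 != 0) == 0
  if (sum(ok) > max_tables) {
    return(NULL)
  }
  het <- het[ok, , drop = FALSE]
  hom <- rem[ok, , drop = FALSE] / 2
  const <- lgamma(n + 1) + sum(lgamma(m_allele + 1)) - lgamma(2 * n + 1)
  lp <- const + rowSums(het) * log(2) -
    rowSums(lgamma(het + 1)) - rowSums(lgamma(hom + 1))
  list(log_prob = lp)
}
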