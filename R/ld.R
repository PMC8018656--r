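#' Permutation test of linkage disequilibrium between two loci
#'
#' G-statistic (log-likelihood ratio) on the two-locus genotype contingency
#' table, with the null distribution obtained by permuting one locus's
#' genotypes across individuals. Only individuals fully typed at both loci
#' enter; `p = (1 + #\{G_perm >= G_obs\}) / (reps + 1)`.
#'
#' @param genotypes Wide genotype tibble.
#' @param locus_a,locus_b Locus names.
#' @param reps Number of permutations (>= 100; default 999).
#' @param seed Optional integer seed.
#' @return List of class `ld_test`: `p_value`, `G`, `reps`, `n`.
#' @export
ld_permutation <- function(genotypes, locus_a, locus_b, reps = 999,
                           seed = NULL) {
  if (reps < 100) abort("`reps` must be at least 100.")
  ga <- genotype_factor(genotypes, locus_a)
  gb <- genotype_factor(genotypes, locus_b)
  keep <- !is.na(ga) & !is.na(gb)
  if (sum(keep) < 10) {
    abort("At least 10 individuals typed at both loci are required.")
  }
  ga <- factor(ga[keep])
  gb <- factor(gb[keep])
  g_obs <- g_statistic(table(ga, gb))
  p <- with_seed_if(seed, {
    hits <- 0L
    for (r in seq_len(reps)) {
      if (g_statistic(table(ga, sample(gb))) >= g_obs - 1e-12) hits <- hits + 1L
    }
    (1 + hits) / (reps + 1)
  })
  structure(
    list(p_value = p, G = g_obs, reps = reps, n = length(ga)),
    class = "ld_test"
  )
}

#' @export
print.ld_test <- function(x, ...) {
  cat(sprintf(
    "LD permutation test: G = %.3f, p = %.4g (%d permutations, n = %d)\n",
    x$G, x$p_value, x$reps, x$n
  ))
  invisible(x)
}

# Multilocus genotype as a factor; NA for not-fully-typed individuals.
genotype_factor <- function(genotypes, locus) {
  a1 <- genotypes[[paste0(locus, ".1")]]
  a2 <- genotypes[[paste0(locus, ".2")]]
  if (is.null(a1)) abort(sprintf("Locus not present: %s.", locus))
  out <- paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
  out[a1 == 0 | a2 == 0] <- NA
  out
}

g_statistic <- function(tab) {
  o <- as.vector(tab)
  e <- as.vector(outer(rowSums(tab), colSums(tab)) / sum(tab))
  nz <- o > 0
  2 * sum(o[nz] * log(o[nz] / e[nz]))
}

#' Genotype accumulation curve
#'
#' For each panel size `m = 1, ..., L`, draws `n_reps` random locus subsets
#' of size `m` (without replacement) and counts the distinct multilocus
#' genotypes they resolve. A missing locus acts as a wildcard that matches
#' anything, so individuals indistinguishable up to missing data are
#' counted once. The curve's plateau indicates how many loci suffice to
#' individualize the cohort.
#'
#' @param genotypes Wide genotype tibble (>= 2 individuals).
#' @param n_reps Subsets per panel size (default 100).
#' @param seed Optional integer seed.
#' @return Tibble of class `genotype_accumulation`: `n_loci`,
#'   `mean_distinct`, `min_distinct`, `max_distinct`.
#' @export
genotype_accumulation <- function(genotypes, n_reps = 100, seed = NULL) {
  loci <- str_loci(genotypes)
  n_loci <- length(loci)
  m <- allele_matrices(genotypes, loci)
  with_seed_if(seed, {
    rows <- purrr::map(seq_len(n_loci), function(sz) {
      counts <- vapply(seq_len(n_reps), function(r) {
        sel <- sample.int(n_loci, sz)
        count_distinct_profiles(m$a1[, sel, drop = FALSE], m$a2[, sel, drop = FALSE])
      }, numeric(1))
      tibble(
        n_loci = sz, mean_distinct = mean(counts),
        min_distinct = min(counts), max_distinct = max(counts)
      )
    })
    structure(dplyr::bind_rows(rows),
      class = c("genotype_accumulation", class(tibble()))
    )
  })
}

# Distinct multilocus profiles. Complete data: unique row keys. With
# missing loci (wildcards) indistinguishability is not transitive, so
# profiles are merged by single-linkage over pairwise compatibility and
# connected components are counted.
count_distinct_profiles <- function(a1, a2) {
  n <- nrow(a1)
  if (n <= 1) {
    return(n)
  }
  if (all(a1 != 0L) && all(a2 != 0L)) {
    key <- do.call(paste, c(
      lapply(seq_len(ncol(a1)), function(j) paste(a1[, j], a2[, j])),
      sep = "|"
    ))
    return(length(unique(key)))
  }
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      typed <- a1[i, ] != 0L & a2[i, ] != 0L & a1[j, ] != 0L & a2[j, ] != 0L
      same <- all(a1[i, typed] == a1[j, typed] & a2[i, typed] == a2[j, typed])
      if (same) {
        ri <- find(i)
        rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}
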