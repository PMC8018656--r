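# Marker validation statistics certifying the panel's discriminatory power.

#' Allele frequencies at one or all loci
#'
#' Counts allele copies (missing copies, coded 0, are excluded) and
#' normalizes per locus.
#'
#' @param genotypes Wide genotype tibble.
#' @param locus Optional single locus name; default all loci.
#' @return Tibble `locus`, `allele`, `count`, `freq`.
#' @export
allele_frequencies <- function(genotypes, locus = NULL) {
  loci <- if (is.null(locus)) str_loci(genotypes) else locus
  if (!all(paste0(loci, ".1") %in% names(genotypes))) {
    abort(sprintf("Locus not present: %s.", setdiff(loci, str_loci(genotypes))[1]))
  }
  out <- purrr::map(loci, function(l) {
    copies <- c(genotypes[[paste0(l, ".1")]], genotypes[[paste0(l, ".2")]])
    copies <- copies[copies != 0]
    if (!length(copies)) {
      abort(sprintf("No typed individuals at locus %s.", l))
    }
    counts <- table(copies)
    tibble(
      locus = l,
      allele = as.integer(names(counts)),
      count = as.integer(counts),
      freq = as.vector(counts / sum(counts))
    )
  })
  dplyr::bind_rows(out)
}

#' Per-locus marker summary statistics
#'
#' For one locus: sample size, allele counts, heterozygosities, polymorphic
#' information content, probability of identity, exclusion probabilities and
#' the Chakraborty null-allele estimate, plus (optionally) the exact
#' Hardy-Weinberg p-value.
#'
#' Definitions over allele frequencies `p` (`S_k = sum(p^k)`): effective
#' alleles `A_e = 1/S_2`; expected heterozygosity `H_E = 1 - S_2`
#' (uncorrected, so the identity `PIC <= H_E` is exact; the `2n/(2n-1)`
#' unbiased form is available via `unbiased`); `PIC = 1 - S_2 - (S_2^2 -
#' S_4)`; `PID = 2 S_2^2 - S_4` (the probability two unrelated individuals
#' share the genotype); null-allele frequency `max(0, (H_E - H_O)/(H_E +
#' H_O))`; exclusion probabilities Pe1 (one parent known) and Pe2 (both
#' parents known) computed by exact enumeration over parent-offspring
#' genotype configurations at the given frequencies.
#'
#' @param genotypes Wide genotype tibble.
#' @param locus Single locus name.
#' @param include_hwe Compute the exact HWE p-value (default TRUE).
#' @param unbiased Apply the small-sample `2n/(2n-1)` correction to `H_E`
#'   (default FALSE).
#' @param hwe_mc_reps,hwe_max_tables,seed Forwarded to [hwe_exact()].
#' @return One-row tibble: `locus`, `n_typed`, `A_n`, `A_e`, `H_O`, `H_E`,
#'   `PIC`, `PID`, `Pe1`, `Pe2`, `null_freq`, `null_flag`, `hwe_p`.
#' @export
locus_stats <- function(genotypes, locus, include_hwe = TRUE,
                        unbiased = FALSE,
                        hwe_mc_reps = 1e5, hwe_max_tables = 1e6,
                        seed = NULL) {
  a1 <- genotypes[[paste0(locus, ".1")]]
  a2 <- genotypes[[paste0(locus, ".2")]]
  if (is.null(a1) || is.null(a2)) abort(sprintf("Locus not present: %s.", locus))
  typed <- a1 != 0 & a2 != 0
  n_typed <- sum(typed)
  fr <- allele_frequencies(genotypes, locus)
  p <- fr$freq
  s2 <- sum(p^2)
  s4 <- sum(p^4)
  a_n <- length(p)
  h_o <- if (n_typed > 0) mean(a1[typed] != a2[typed]) else NA_real_
  h_e <- 1 - s2
  if (unbiased && n_typed > 0) {
    h_e <- h_e * 2 * n_typed / (2 * n_typed - 1)
  }
  pic <- 1 - s2 - (s2^2 - s4)
  pid <- 2 * s2^2 - s4
  pe <- pe_exclusion(p)
  mono <- a_n < 2
  null_flag <- mono || (h_e + h_o) == 0
  null_freq <- if (null_flag) 0 else max(0, (h_e - h_o) / (h_e + h_o))
  hwe_p <- NA_real_
  if (include_hwe && !mono && n_typed >= 2) {
    hwe_p <- hwe_exact(genotypes,
      locus = locus, mc_reps = hwe_mc_reps,
      max_tables = hwe_max_tables, seed = seed
    )$p_value
  }
  tibble(
    locus = locus, n_typed = n_typed, A_n = a_n, A_e = 1 / s2,
    H_O = h_o, H_E = h_e, PIC = pic, PID = if (mono) 1 else pid,
    Pe1 = pe$Pe1, Pe2 = pe$Pe2,
    null_freq = null_freq, null_flag = null_flag, hwe_p = hwe_p
  )
}

#' Marker statistics for every locus
#'
#' @inheritParams locus_stats
#' @return Tibble with one [locus_stats()] row per locus, class
#'   `marker_stats`.
#' @export
marker_stats <- function(genotypes, include_hwe = TRUE, unbiased = FALSE,
                         hwe_mc_reps = 1e5, hwe_max_tables = 1e6,
                         seed = NULL) {
  loci <- str_loci(genotypes)
  seeds <- if (is.null(seed)) rep(list(NULL), length(loci)) else as.list(seed + seq_along(loci))
  out <- purrr::map2(loci, seeds, function(l, s) {
    locus_stats(genotypes, l,
      include_hwe = include_hwe, unbiased = unbiased,
      hwe_mc_reps = hwe_mc_reps, hwe_max_tables = hwe_max_tables, seed = s
    )
  })
  structure(dplyr::bind_rows(out), class = c("marker_stats", class(tibble())))
}

#' Cumulative multilocus probability of identity
#'
#' Product of per-locus PID values under locus independence: the
#' probability that two unrelated individuals share an entire multilocus
#' profile.
#'
#' @param stats A [marker_stats()] tibble, or a numeric vector of per-locus
#'   PID values.
#' @return A single probability.
#' @export
cumulative_pid <- function(stats) {
  pid <- if (is.numeric(stats)) stats else stats$PID
  if (!length(pid)) abort("At least one locus is required.")
  prod(pid)
}

#' Write the per-locus statistics table
#'
#' Tab-separated summary mirroring the structure of published
#' marker-validation supplements.
#'
#' @param stats A [marker_stats()] tibble.
#' @param path Output path.
#' @export
write_marker_stats <- function(stats, path) {
  readr::write_tsv(as_tibble(stats), path, progress = FALSE)
  invisible(path)
}

# Exact exclusion probabilities by enumeration.
#
# Pe1 (one parent known): probability that a random unrelated individual is
# excluded as the second parent of an offspring whose first parent is known,
# averaging over HWE parent genotypes and Mendelian transmission. Pe2 (both
# parents known): probability that a random unrelated pair is excluded as
# the parent pair of an HWE offspring. Exclusion is genotype incompatibility
# (the candidate cannot carry a feasible transmitted allele).
pe_exclusion <- function(p) {
  k <- length(p)
  if (k == 1) {
    return(list(Pe1 = 0, Pe2 = 0))
  }
  carry <- p * (2 - p) # P(random genotype carries allele i)

  pe1 <- 0
  for (i in seq_len(k)) {
    for (j in i:k) {
      pm <- if (i == j) p[i]^2 else 2 * p[i] * p[j]
      for (x in unique(c(i, j))) { # maternal transmitted allele
        px <- if (i == j) 1 else 0.5
        for (y in seq_len(k)) { # paternal allele
          # feasible paternal alleles for offspring {x, y} given mother {i, j}
          feas <- unique(c(
            if (x %in% c(i, j)) y,
            if (y %in% c(i, j)) x
          ))
          p_f <- sum(p[feas])
          pe1 <- pe1 + pm * px * p[y] * (1 - p_f)^2
        }
      }
    }
  }

  pe2 <- 0
  for (u in seq_len(k)) {
    for (v in u:k) {
      po <- if (u == v) p[u]^2 else 2 * p[u] * p[v]
      compat <- if (u == v) {
        carry[u]^2
      } else {
        2 * carry[u] * carry[v] - (2 * p[u] * p[v])^2
      }
      pe2 <- pe2 + po * (1 - compat)
    }
  }
  list(Pe1 = pe1, Pe2 = pe2)
}
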