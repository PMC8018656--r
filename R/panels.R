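#' Build lion and tiger allele-frequency panels with diagnostic SNP loci
#'
#' Constructs the parametric population model the synthetic cohorts are drawn
#' from: one allele-frequency table per species over a shared set of
#' microsatellite loci, plus three fixed-difference mitochondrial SNP loci
#' (control region, 12S and 16S rRNA) whose alleles separate lion from tiger.
#'
#' Each locus receives an allele count drawn uniformly from
#' `allele_count_range`; allele sizes are even base-pair lengths. A fraction
#' `divergence` of each locus's alleles is private to the lion and the same
#' fraction private to the tiger; frequencies are symmetric Dirichlet(1, ...)
#' draws over the union, with the other species' private alleles masked to
#' zero and the remainder renormalized. With `divergence = 0` the two species
#' share one identical frequency table (no private alleles, a single draw).
#'
#' @param n_loci Number of microsatellite loci (default 18).
#' @param allele_count_range Inclusive integer range of allele counts per
#'   locus (default `c(5, 11)`), within `[2, 30]`.
#' @param divergence Fraction of each locus's alleles private to each
#'   species, in `[0, 1]` (default 0.35, which reproduces a private-allele
#'   share near three quarters of the union, the regime reported for
#'   lion/tiger reference panels).
#' @param seed Optional integer seed; fixed seed gives identical panels.
#' @return An object of class `species_panels`: a list with elements `lion`
#'   and `tiger` (tibbles with columns `species`, `locus`, `allele`, `freq`)
#'   and `snp` (tibble with `locus`, `lion_allele`, `tiger_allele`).
#' @examples
#' p <- make_species_panels(n_loci = 4, seed = 1)
#' dplyr::count(p$lion, locus)
#' @export
make_species_panels <- function(n_loci = 18,
                                allele_count_range = c(5, 11),
                                divergence = 0.35,
                                seed = NULL) {
  if (!is.numeric(n_loci) || n_loci < 1) {
    abort("`n_loci` must be >= 1.")
  }
  r <- as.integer(allele_count_range)
  if (length(r) != 2L || any(is.na(r)) || r[1] > r[2]) {
    abort("`allele_count_range` must be an inclusive integer range c(lo, hi).")
  }
  if (r[1] < 2 || r[2] > 30) {
    abort("`allele_count_range` must lie within [2, 30].")
  }
  if (!is.numeric(divergence) || divergence < 0 || divergence > 1) {
    abort("`divergence` must lie in [0, 1].")
  }
  n_loci <- as.integer(n_loci)
  loci <- sprintf("L%02d", seq_len(n_loci))

  with_seed_if(seed, {
    per_locus <- purrr::map(loci, function(locus) {
      k <- sample(seq(r[1], r[2]), 1L)
      sizes <- sort(sample(seq(100L, 100L + 2L * 60L, by = 2L), k))
      # Partition the union: first block lion-private, last block
      # tiger-private, middle shared. round() keeps d = 0 -> all shared.
      n_priv <- round(divergence * k)
      n_priv <- min(n_priv, floor((k - (k %% 2 == 1)) / 2))
      owner <- rep("shared", k)
      if (n_priv > 0) {
        owner[seq_len(n_priv)] <- "lion"
        owner[seq(k - n_priv + 1L, k)] <- "tiger"
      }
      draw_freq <- function(species_keep) {
        repeat {
          g <- rdirichlet1(k)
          g[!(owner %in% c("shared", species_keep))] <- 0
          if (sum(g) > 0) {
            return(g / sum(g))
          }
        }
      }
      lion_f <- draw_freq("lion")
      tiger_f <- if (divergence == 0) lion_f else draw_freq("tiger")
      tibble(
        locus = locus, allele = sizes,
        lion = lion_f, tiger = tiger_f
      )
    })
    tbl <- dplyr::bind_rows(per_locus)

    bases <- c("A", "C", "G", "T")
    snp <- tibble(
      locus = SNP_LOCI,
      lion_allele = sample(bases, length(SNP_LOCI), replace = TRUE),
      tiger_allele = NA_character_
    )
    snp$tiger_allele <- purrr::map_chr(
      snp$lion_allele,
      function(b) sample(setdiff(bases, b), 1L)
    )

    out <- list(
      lion = tbl |>
        dplyr::filter(.data$lion > 0) |>
        dplyr::transmute(
          species = "LION", locus = .data$locus,
          allele = .data$allele, freq = .data$lion
        ),
      tiger = tbl |>
        dplyr::filter(.data$tiger > 0) |>
        dplyr::transmute(
          species = "TIGER", locus = .data$locus,
          allele = .data$allele, freq = .data$tiger
        ),
      snp = snp
    )
    structure(out,
      class = "species_panels",
      n_loci = n_loci, divergence = divergence
    )
  })
}

validate_panel <- function(panel, name = "panel") {
  need <- c("locus", "allele", "freq")
  if (!all(need %in% names(panel))) {
    abort(sprintf("`%s` must have columns locus, allele, freq.", name))
  }
  if (nrow(panel) == 0) {
    abort(sprintf("`%s` is empty.", name))
  }
  sums <- tapply(panel$freq, panel$locus, sum)
  if (any(abs(sums - 1) > 1e-9)) {
    abort(sprintf("`%s` frequencies must sum to 1 per locus.", name))
  }
  if (any(panel$allele <= 0 | panel$allele != round(panel$allele))) {
    abort(sprintf("`%s` allele sizes must be positive integers.", name))
  }
  invisible(panel)
}

#' @export
print.species_panels <- function(x, ...) {
  cat(sprintf(
    "<species_panels> %d STR loci, divergence %.2f, %d SNP loci\n",
    attr(x, "n_loci"), attr(x, "divergence"), nrow(x$snp)
  ))
  cat(sprintf(
    "  lion: %d alleles | tiger: %d alleles\n",
    nrow(x$lion), nrow(x$tiger)
  ))
  invisible(x)
}

#' Draw reference genotypes from a species' frequency panel
#'
#' Simulates unrelated diploid reference individuals under Hardy-Weinberg
#' proportions from one species' allele-frequency table, in the wide genotype
#' layout used throughout the package. These emulate the 20-lion / 20-tiger
#' reference sets used to anchor species assignment.
#'
#' @param panel A per-species frequency tibble (`locus`, `allele`, `freq`),
#'   e.g. `make_species_panels(...)$lion`.
#' @param n Number of individuals (default 20).
#' @param id_prefix Prefix for generated sample ids.
#' @param seed Optional integer seed.
#' @return A wide genotype tibble with columns `sample_id`, `species`, then
#'   two allele columns per locus.
#' @export
simulate_reference_genotypes <- function(panel, n = 20, id_prefix = "REF",
                                         seed = NULL) {
  validate_panel(panel)
  species <- if ("species" %in% names(panel)) panel$species[1] else NA_character_
  with_seed_if(seed, {
    geno <- draw_hw_genotypes(panel, n)
    dplyr::bind_cols(
      tibble(
        sample_id = sprintf("%s-%s-%03d", id_prefix, species, seq_len(n)),
        species = species
      ),
      geno
    )
  })
}

# Draw n diploid genotypes under HWE from a frequency panel; returns the
# wide two-columns-per-locus tibble with sorted pairs.
draw_hw_genotypes <- function(panel, n) {
  loci <- unique(panel$locus)
  cols <- purrr::map(loci, function(l) {
    sub <- panel[panel$locus == l, ]
    a1 <- sample(sub$allele, n, replace = TRUE, prob = sub$freq)
    a2 <- sample(sub$allele, n, replace = TRUE, prob = sub$freq)
    p <- sort_allele_pairs(a1, a2)
    setNames(
      list(as.integer(p$a1), as.integer(p$a2)),
      paste0(l, c(".1", ".2"))
    )
  })
  as_tibble(purrr::flatten(cols))
}

#' Empirical allele frequencies of a reference panel
#'
#' Counts allele copies per locus in a wide genotype table (missing copies,
#' coded 0, excluded) and normalizes. The number of individuals is attached
#' as attribute `n_ref`, used downstream to set the unseen-allele floor in
#' admixture estimation.
#'
#' @param genotypes Wide genotype tibble.
#' @return Tibble `locus`, `allele`, `count`, `freq` with attribute `n_ref`.
#' @export
panel_frequencies <- function(genotypes) {
  freqs <- allele_frequencies(genotypes)
  attr(freqs, "n_ref") <- nrow(genotypes)
  freqs
}
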