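# Shared internal helpers: wide genotype-table introspection and RNG scoping.
#
# A genotype table is a tibble with sample metadata columns followed by two
# integer columns per microsatellite locus, named "<locus>.1" and "<locus>.2".
# Allele 0 encodes a missing (non-amplified) allele copy.

SNP_LOCI <- c("control_region", "rRNA_12S", "rRNA_16S")
SITE_LEVELS <- c("FARM", "PORT")
SPECIES_LEVELS <- c("LION", "TIGER")

#' Locus names of a wide genotype table
#'
#' @param x A genotype table (tibble with `<locus>.1` / `<locus>.2` columns).
#' @return Character vector of locus names in column order.
#' @export
str_loci <- function(x) {
  nm <- names(x)
  first <- grep("\\.1$", nm, value = TRUE)
  loci <- sub("\\.1$", "", first)
  loci[paste0(loci, ".2") %in% nm]
}

# Extract the two allele matrices (n x L) for the given loci.
allele_matrices <- function(x, loci = str_loci(x)) {
  a1 <- as.matrix(x[paste0(loci, ".1")])
  a2 <- as.matrix(x[paste0(loci, ".2")])
  storage.mode(a1) <- "integer"
  storage.mode(a2) <- "integer"
  colnames(a1) <- colnames(a2) <- loci
  list(a1 = a1, a2 = a2)
}

# Sorted-pair normalization: stores each unordered pair ascending, keeping
# the missing code 0 in the first slot of half-called loci.
sort_allele_pairs <- function(a1, a2) {
  lo <- pmin(a1, a2)
  hi <- pmax(a1, a2)
  list(a1 = lo, a2 = hi)
}

# Frequency lookup closure for a (locus, allele, freq) tibble. Alleles absent
# from the table get frequency `absent`.
freq_lookup <- function(freqs, absent = 0) {
  stopifnot(all(c("locus", "allele", "freq") %in% names(freqs)))
  split_tbl <- split(freqs[c("allele", "freq")], freqs$locus)
  function(locus, alleles) {
    tbl <- split_tbl[[locus]]
    if (is.null(tbl)) {
      return(rep(absent, length(alleles)))
    }
    f <- tbl$freq[match(alleles, tbl$allele)]
    f[is.na(f)] <- absent
    f
  }
}

# Run `expr` under a locally-seeded RNG when `seed` is non-NULL; otherwise
# use the current RNG state.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) {
    expr
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}

assert_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number.", name))
  }
  invisible(x)
}

# Dirichlet(1, ..., 1) draw of length k.
rdirichlet1 <- function(k) {
  g <- stats::rexp(k)
  g / sum(g)
}
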