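# Delimited-text formats and chain-of-custody bookkeeping.
#
# The genotype CSV dialect: header sample_id, tag, facility_id, site, year,
# claimed_species, then two integer columns per locus named LOCUS.1/LOCUS.2.
# Allele 0 is the missing code (GENEPOP convention); a locus is fully typed
# (two nonzero), missing (both zero) or half-called (one zero).

META_COLS <- c("sample_id", "tag", "facility_id", "site", "year", "claimed_species")

#' Read a genotype table
#'
#' Strict parser for the package's genotype CSV dialect. Unknown site
#' values, non-integer allele cells, ragged rows, duplicated
#' `(tag, site, year)` keys and missing header columns are errors, reported
#' with their row and column.
#'
#' @param path Path to a CSV genotype table.
#' @return A wide genotype tibble (metadata columns then allele pairs).
#' @export
read_genotype_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- suppressWarnings(readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  ))
  prob <- readr::problems(df)
  if (nrow(prob) > 0) {
    abort(sprintf(
      "Malformed genotype table %s: row %d, column %d: expected %s.",
      path, prob$row[1] - 1L, prob$col[1], prob$expected[1] # row 1 = header
    ))
  }
  if (!all(META_COLS %in% names(df))) {
    abort(sprintf(
      "Missing header column(s): %s.",
      paste(setdiff(META_COLS, names(df)), collapse = ", ")
    ))
  }
  allele_cols <- setdiff(names(df), META_COLS)
  bad_names <- allele_cols[!grepl("\\.[12]$", allele_cols)]
  if (length(bad_names)) {
    abort(sprintf(
      "Columns are neither metadata nor LOCUS.1/LOCUS.2 pairs: %s.",
      paste(bad_names, collapse = ", ")
    ))
  }
  loci <- unique(sub("\\.[12]$", "", allele_cols))
  missing_pair <- loci[!(paste0(loci, ".1") %in% allele_cols &
    paste0(loci, ".2") %in% allele_cols)]
  if (length(missing_pair)) {
    abort(sprintf("Locus without both allele columns: %s.", paste(missing_pair, collapse = ", ")))
  }

  parse_int_col <- function(col) {
    x <- df[[col]]
    out <- suppressWarnings(as.integer(x))
    bad <- which(is.na(out) | as.character(out) != x | out < 0)
    if (length(bad)) {
      abort(sprintf(
        "Malformed allele cell at row %d, column %s: '%s' is not a non-negative integer.",
        bad[1], col, x[bad[1]]
      ))
    }
    out
  }
  for (col in allele_cols) df[[col]] <- parse_int_col(col)

  bad_site <- which(!df$site %in% SITE_LEVELS &
    !df$site %in% c("REFERENCE"))
  if (length(bad_site)) {
    abort(sprintf(
      "Unknown site value at row %d, column site: '%s'.",
      bad_site[1], df$site[bad_site[1]]
    ))
  }
  df$year <- parse_int_col("year")

  key <- paste(df$tag, df$site, df$year)
  if (anyDuplicated(key)) {
    abort(sprintf(
      "Duplicate (tag, site, year) at row %d: %s.",
      which(duplicated(key))[1], key[which(duplicated(key))[1]]
    ))
  }

  # normalize unordered pairs ascending (keeps 0 first for half-calls)
  m <- allele_matrices(df, loci)
  p <- sort_allele_pairs(m$a1, m$a2)
  for (i in seq_along(loci)) {
    df[[paste0(loci[i], ".1")]] <- as.vector(p$a1[, i])
    df[[paste0(loci[i], ".2")]] <- as.vector(p$a2[, i])
  }
  df
}

#' Write a genotype table
#'
#' Deterministic, comma-delimited, UTF-8; rows in input order, metadata
#' columns first then locus pairs. Two writes of the same data are
#' byte-identical and a write/read round trip is the identity.
#'
#' @param genotypes Wide genotype tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(genotypes, path) {
  meta <- intersect(META_COLS, names(genotypes))
  loci <- str_loci(genotypes)
  cols <- c(meta, as.vector(rbind(paste0(loci, ".1"), paste0(loci, ".2"))))
  extra <- setdiff(names(genotypes), cols)
  readr::write_csv(genotypes[c(cols, extra)], path, progress = FALSE)
  invisible(path)
}

#' Read / write SNP call tables
#'
#' CSV with columns `sample_id`, `tag`, `site`, `year` and one column per
#' diagnostic mtDNA locus holding `LION`, `TIGER` or `UNDETERMINED`.
#'
#' @param path File path.
#' @param snp_loci Expected SNP locus columns.
#' @export
read_snp_table <- function(path, snp_loci = SNP_LOCI) {
  df <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  missing <- setdiff(snp_loci, names(df))
  if (length(missing)) {
    abort(sprintf("SNP table lacks locus column(s): %s.", paste(missing, collapse = ", ")))
  }
  for (l in snp_loci) {
    bad <- which(!df[[l]] %in% c("LION", "TIGER", "UNDETERMINED"))
    if (length(bad)) {
      abort(sprintf(
        "Invalid SNP call at row %d, column %s: '%s'.",
        bad[1], l, df[[l]][bad[1]]
      ))
    }
  }
  df$year <- as.integer(df$year)
  df
}

#' @rdname read_snp_table
#' @param snp_calls SNP call tibble.
#' @export
write_snp_table <- function(snp_calls, path) {
  readr::write_csv(snp_calls, path, progress = FALSE)
  invisible(path)
}

#' Read / write weight manifests
#'
#' CSV with columns `tag`, `facility_id`, `trader_id`, `consignment_id`,
#' `year`, `farm_weight_kg`, `port_gross_weight_kg`, `packaging_weight_kg`.
#' Weights must be positive where present; packaging non-negative.
#'
#' @param path File path.
#' @export
read_weight_manifest <- function(path) {
  df <- readr::read_csv(path,
    col_types = readr::cols(
      tag = readr::col_character(),
      facility_id = readr::col_character(),
      trader_id = readr::col_character(),
      consignment_id = readr::col_character(),
      year = readr::col_integer(),
      farm_weight_kg = readr::col_double(),
      port_gross_weight_kg = readr::col_double(),
      packaging_weight_kg = readr::col_double()
    ),
    progress = FALSE
  )
  if (any(df$farm_weight_kg <= 0, na.rm = TRUE) ||
    any(df$port_gross_weight_kg <= 0, na.rm = TRUE)) {
    abort("Weights must be positive where present.")
  }
  if (any(df$packaging_weight_kg < 0, na.rm = TRUE)) {
    abort("Packaging weights must be non-negative.")
  }
  df
}

#' @rdname read_weight_manifest
#' @param weights Weight-manifest tibble.
#' @export
write_weight_manifest <- function(weights, path) {
  readr::write_csv(weights, path, progress = FALSE)
  invisible(path)
}

#' Export genotypes in GENEPOP format
#'
#' Writes the GENEPOP dialect: a title line, one locus name per line, then
#' one `Pop` block per facility with three-digit allele coding (`000` for a
#' missing copy). Allele sizes above 999 cannot be represented and are an
#' error.
#'
#' @param genotypes Wide genotype tibble; `facility_id` (or `species` for
#'   reference panels) defines the population blocks.
#' @param path Output path.
#' @param title Title line content.
#' @return `path`, invisibly.
#' @export
export_genepop <- function(genotypes, path, title = "bonematch export") {
  loci <- str_loci(genotypes)
  m <- allele_matrices(genotypes, loci)
  if (any(m$a1 > 999 | m$a2 > 999)) {
    abort("GENEPOP three-digit coding cannot represent allele sizes > 999.")
  }
  pop_col <- if ("facility_id" %in% names(genotypes)) {
    genotypes$facility_id
  } else if ("species" %in% names(genotypes)) {
    genotypes$species
  } else {
    rep("POP1", nrow(genotypes))
  }
  lines <- c(title, loci)
  for (pop in unique(pop_col)) {
    lines <- c(lines, "Pop")
    rows <- which(pop_col == pop)
    coded <- vapply(rows, function(i) {
      paste(sprintf("%03d%03d", m$a1[i, ], m$a2[i, ]), collapse = " ")
    }, character(1))
    ids <- genotypes$sample_id[rows]
    lines <- c(lines, paste0(ids, " , ", coded))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Chain-of-custody checksum manifest
#'
#' SHA-256 digest per input file plus a retrieval timestamp, for embedding
#' in compliance reports and verifying that evidence files are unchanged
#' between runs. Digests are stable across reruns on unchanged files; the
#' timestamp records when the digest was taken.
#'
#' @param paths Character vector of file paths.
#' @return Tibble `path`, `sha256`, `bytes`, `timestamp`.
#' @export
custody_digest <- function(paths) {
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    abort(sprintf("Unreadable file(s): %s.", paste(missing, collapse = ", ")))
  }
  sums <- vapply(paths, function(p) {
    con <- file(p, "rb")
    on.exit(close(con))
    as.character(openssl::sha256(con))
  }, character(1))
  tibble(
    path = paths,
    sha256 = unname(sums),
    bytes = unname(file.size(paths)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
}
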