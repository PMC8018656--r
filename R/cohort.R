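#' Configuration for a synthetic export-quota cohort
#'
#' Bundles the study conditions of one annual quota: quota size, the port
#' spot-check fraction, marker-panel dimensions, planted-anomaly counts and
#' genotyping-error rates. Defaults mirror the 2018 compliance round: an
#' 800-skeleton quota with at least one-eighth (12.5%) of every consignment
#' spot-checked at the port of exit, 18 microsatellite loci with 5-11
#' alleles each, and three diagnostic mtDNA SNP loci.
#'
#' @param quota_size Number of farm skeletons in the quota (default 800).
#' @param spot_fraction Fraction of each consignment spot-checked, in
#'   `(0, 1]` (default 0.125); at least one skeleton per consignment.
#' @param n_str_loci,allele_count_range,n_snp_loci Marker-panel dimensions,
#'   forwarded to [make_species_panels()] when panels are built from a
#'   config.
#' @param anomaly_rates Named list of planted-anomaly counts:
#'   `non_target_species` (tiger skeletons at farm), `reassigned_tag` (port
#'   sample carrying another same-facility individual's genotype),
#'   `pooled_no_match` (port sample from an individual absent from the farm
#'   cohort), `duplicate_individual` (farm tag pairs sharing one genotype).
#' @param genotyping_error Named list: `dropout` (per-allele-copy missing
#'   probability) and `false_allele` (per-locus miscall probability).
#'   Defaults 0 so matching on clean cohorts is exact.
#' @param n_facilities Number of source farms.
#' @param n_traders Number of exporting traders (default 7, as observed in
#'   the 2018 quota).
#' @param consignment_size_range Inclusive range of consignment sizes.
#' @param year Calendar year stamped on records.
#' @param seed Integer seed; a fixed seed makes every simulated artefact
#'   byte-identical across reruns.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(quota_size = 800,
                          spot_fraction = 0.125,
                          n_str_loci = 18,
                          allele_count_range = c(5, 11),
                          n_snp_loci = 3,
                          anomaly_rates = list(),
                          genotyping_error = list(dropout = 0, false_allele = 0),
                          n_facilities = 10,
                          n_traders = 7,
                          consignment_size_range = c(30, 60),
                          year = 2018,
                          seed = 1) {
  rates <- modifyList(
    list(
      non_target_species = 0, reassigned_tag = 0,
      pooled_no_match = 0, duplicate_individual = 0
    ),
    anomaly_rates
  )
  err <- modifyList(list(dropout = 0, false_allele = 0), genotyping_error)
  cfg <- list(
    quota_size = as.integer(quota_size),
    spot_fraction = spot_fraction,
    n_str_loci = as.integer(n_str_loci),
    allele_count_range = as.integer(allele_count_range),
    n_snp_loci = as.integer(n_snp_loci),
    anomaly_rates = lapply(rates, as.integer),
    genotyping_error = err,
    n_facilities = as.integer(n_facilities),
    n_traders = as.integer(n_traders),
    consignment_size_range = as.integer(consignment_size_range),
    year = as.integer(year),
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  if (cfg$quota_size < 1) abort("`quota_size` must be >= 1.")
  if (!(cfg$spot_fraction > 0 && cfg$spot_fraction <= 1)) {
    abort("`spot_fraction` must lie in (0, 1].")
  }
  n_anom <- sum(unlist(cfg$anomaly_rates)) + cfg$anomaly_rates$duplicate_individual
  if (n_anom > cfg$quota_size) {
    abort("Planted anomaly counts exceed the quota size.")
  }
  for (p in c("dropout", "false_allele")) {
    v <- cfg$genotyping_error[[p]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      abort(sprintf("`genotyping_error$%s` must lie in [0, 1].", p))
    }
  }
  invisible(cfg)
}

#' The 2018-like quota configuration
#'
#' Preset matching the anomaly pattern uncovered in the 2018 round: one
#' tiger skeleton at a source farm, one port sample mislabelled with another
#' same-farm individual's tag, four port samples with no matching farm
#' skeleton, and one farm tag pair from a single individual.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed on to [cohort_config()].
#' @export
cohort_config_2018 <- function(seed = 1, ...) {
  cohort_config(
    anomaly_rates = list(
      non_target_species = 1, reassigned_tag = 1,
      pooled_no_match = 4, duplicate_individual = 1
    ),
    seed = seed,
    ...
  )
}

#' Read a cohort configuration from YAML or JSON
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file whose keys are
#'   [cohort_config()] arguments.
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(cohort_config, raw)
}

#' Simulate a quota cohort with planted anomalies
#'
#' Draws the full annual cohort: farm genotypes under Hardy-Weinberg from
#' the lion panel, a per-consignment port spot-check subset of at least
#' `ceiling(spot_fraction * size)` skeletons per consignment, SNP call sets,
#' and the planted anomalies requested in the config. A machine-readable
#' truth table records every planted class for downstream validation.
#'
#' Anomaly realizations: `non_target_species` farm tags carry a tiger
#' genotype and tiger mtDNA alleles (and are withheld from port sampling,
#' emulating interception before export); `reassigned_tag` port samples
#' carry the declared tag but the genotype of a different individual from
#' the same facility; `pooled_no_match` port samples carry the genotype of
#' an individual absent from all farm samples; `duplicate_individual` plants
#' farm tag pairs sharing one genotype. Genotyping error (allelic dropout,
#' false alleles) is applied after truth assignment.
#'
#' @param config A [cohort_config()].
#' @param panels A [make_species_panels()] result.
#' @return A list of class `cohort_sim`: `farm` and `port` wide genotype
#'   tibbles (with sample metadata), `farm_snp` and `port_snp` SNP call
#'   tibbles, `consignments` (tag to trader/consignment map) and `truth`
#'   (list of `farm` and `port` truth tibbles).
#' @export
simulate_cohort <- function(config, panels) {
  stopifnot(inherits(config, "cohort_config"))
  validate_panel(panels$lion, "panels$lion")
  validate_panel(panels$tiger, "panels$tiger")
  n <- config$quota_size

  with_seed_if(config$seed, {
    year <- config$year
    tags <- sprintf("ZA%d-%04d", year, seq_len(n))
    ind_ids <- sprintf("IND%d-%04d", year, seq_len(n))
    facilities <- sprintf("FAC%02d", sample.int(config$n_facilities, n, replace = TRUE))

    # Trader consignments: contiguous blocks of random size per trader.
    traders <- sprintf("TR%02d", sort(sample.int(config$n_traders, n, replace = TRUE)))
    consign <- integer(n)
    cid <- 0L
    i <- 1L
    while (i <= n) {
      cid <- cid + 1L
      size <- sample(seq(
        config$consignment_size_range[1],
        config$consignment_size_range[2]
      ), 1L)
      block <- seq(i, min(n, i + size - 1L))
      # keep consignments within one trader
      block <- block[traders[block] == traders[i]]
      consign[block] <- cid
      i <- max(block) + 1L
    }
    consignment_id <- sprintf("CON%d-%03d", year, consign)

    rates <- config$anomaly_rates

    # -- pick anomaly tags (mutually exclusive classes per tag) -------------
    avail <- seq_len(n)
    take <- function(k) {
      if (k == 0) {
        return(integer(0))
      }
      picked <- sample(avail, k)
      avail <<- setdiff(avail, picked)
      picked
    }
    idx_tiger <- take(rates$non_target_species)
    idx_dup_a <- take(rates$duplicate_individual) # keeps its own individual
    idx_dup_b <- take(rates$duplicate_individual) # shares idx_dup_a's genotype

    species <- rep("LION", n)
    species[idx_tiger] <- "TIGER"

    # -- farm genotypes -----------------------------------------------------
    farm_geno <- draw_hw_genotypes(panels$lion, n)
    if (length(idx_tiger)) {
      farm_geno[idx_tiger, ] <- draw_hw_genotypes(panels$tiger, length(idx_tiger))
    }
    if (length(idx_dup_b)) {
      farm_geno[idx_dup_b, ] <- farm_geno[idx_dup_a, ]
      ind_ids[idx_dup_b] <- ind_ids[idx_dup_a]
    }

    farm_class <- rep("none", n)
    farm_class[idx_tiger] <- "non_target_species"
    farm_class[c(idx_dup_a, idx_dup_b)] <- "duplicate_individual"

    farm <- dplyr::bind_cols(
      tibble(
        sample_id = sprintf("F%d-%04d", year, seq_len(n)),
        tag = tags, facility_id = facilities, site = "FARM",
        year = year, claimed_species = "LION"
      ),
      farm_geno
    )

    # -- port spot-check subset (lions only; the tiger is intercepted) ------
    spot <- unlist(lapply(split(seq_len(n), consign), function(block) {
      eligible <- setdiff(block, idx_tiger)
      k <- min(length(eligible), ceiling(config$spot_fraction * length(block)))
      if (k == 0) {
        return(integer(0))
      }
      sample(eligible, k)
    }), use.names = FALSE)
    spot <- sort(spot)

    # port-level anomalies live on spot-checked lion tags
    port_pool <- setdiff(spot, c(idx_dup_a, idx_dup_b))
    need <- rates$reassigned_tag + rates$pooled_no_match
    if (need > length(port_pool)) {
      abort("Anomaly counts exceed the available spot-checked tags.")
    }
    picked <- if (need) sample(port_pool, need) else integer(0)
    idx_reassigned <- head(picked, rates$reassigned_tag)
    idx_pooled <- setdiff(picked, idx_reassigned)

    n_port <- length(spot)
    port_source <- ind_ids[spot] # true source individual per port sample
    port_geno <- farm_geno[spot, , drop = FALSE]
    port_class <- rep("none", n_port)

    for (i_re in idx_reassigned) {
      j <- match(i_re, spot)
      # source: a clean same-facility lion (an anomalous tag would make the
      # matched individual ambiguous across tags)
      others <- setdiff(
        which(facilities == facilities[i_re] & farm_class == "none"), i_re
      )
      if (!length(others)) abort("No same-facility individual available for a reassigned tag.")
      src <- sample(others, 1L)
      port_geno[j, ] <- farm_geno[src, ]
      port_source[j] <- ind_ids[src]
      port_class[j] <- "reassigned_tag"
    }
    if (length(idx_pooled)) {
      ext_geno <- draw_hw_genotypes(panels$lion, length(idx_pooled))
      for (m in seq_along(idx_pooled)) {
        j <- match(idx_pooled[m], spot)
        port_geno[j, ] <- ext_geno[m, ]
        port_source[j] <- sprintf("EXT%d-%03d", year, m)
        port_class[j] <- "pooled_no_match"
      }
    }

    port <- dplyr::bind_cols(
      tibble(
        sample_id = sprintf("P%d-%04d", year, seq_len(n_port)),
        tag = tags[spot], facility_id = facilities[spot], site = "PORT",
        year = year, claimed_species = "LION"
      ),
      port_geno
    )

    # -- SNP call sets -------------------------------------------------------
    snp_calls <- function(sp) {
      calls <- lapply(SNP_LOCI, function(l) {
        ifelse(sp == "LION", "LION", "TIGER")
      })
      as_tibble(setNames(calls, SNP_LOCI))
    }
    farm_snp <- dplyr::bind_cols(
      farm[c("sample_id", "tag", "site", "year")], snp_calls(species)
    )
    port_snp <- dplyr::bind_cols(
      port[c("sample_id", "tag", "site", "year")], snp_calls(rep("LION", n_port))
    )

    # -- genotyping error (after truth assignment) --------------------------
    farm <- apply_genotyping_error(farm, panels$lion, config$genotyping_error)
    port <- apply_genotyping_error(port, panels$lion, config$genotyping_error)

    truth <- list(
      farm = tibble(
        tag = tags, individual_id = ind_ids, species = species,
        anomaly_class = farm_class
      ),
      port = tibble(
        sample_id = port$sample_id, tag = port$tag,
        individual_id = port_source, anomaly_class = port_class
      )
    )
    consignments <- tibble(
      tag = tags, facility_id = facilities, trader_id = traders,
      consignment_id = consignment_id, year = year
    )

    structure(
      list(
        farm = farm, port = port, farm_snp = farm_snp, port_snp = port_snp,
        consignments = consignments, truth = truth
      ),
      class = "cohort_sim", config = config
    )
  })
}

# Per-allele-copy dropout (-> 0) and per-locus false allele (one copy
# replaced by a random panel allele), preserving the sorted-pair layout.
apply_genotyping_error <- function(geno_tbl, panel, err) {
  if (err$dropout == 0 && err$false_allele == 0) {
    return(geno_tbl)
  }
  loci <- str_loci(geno_tbl)
  n <- nrow(geno_tbl)
  for (l in loci) {
    c1 <- paste0(l, ".1")
    c2 <- paste0(l, ".2")
    a1 <- geno_tbl[[c1]]
    a2 <- geno_tbl[[c2]]
    if (err$false_allele > 0) {
      hit <- runif(n) < err$false_allele
      if (any(hit)) {
        sub <- panel[panel$locus == l, ]
        repl <- sample(sub$allele, sum(hit), replace = TRUE, prob = sub$freq)
        which_copy <- runif(sum(hit)) < 0.5
        a1[hit][which_copy] <- repl[which_copy]
        a2[hit][!which_copy] <- repl[!which_copy]
      }
    }
    if (err$dropout > 0) {
      a1[runif(n) < err$dropout] <- 0L
      a2[runif(n) < err$dropout] <- 0L
    }
    p <- sort_allele_pairs(as.integer(a1), as.integer(a2))
    geno_tbl[[c1]] <- p$a1
    geno_tbl[[c2]] <- p$a2
  }
  geno_tbl
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf(
    "<cohort_sim> %d farm + %d port samples, %d loci, year %d\n",
    nrow(x$farm), nrow(x$port), length(str_loci(x$farm)),
    attr(x, "config")$year
  ))
  anom <- table(c(
    x$truth$farm$anomaly_class[x$truth$farm$anomaly_class != "none"],
    x$truth$port$anomaly_class[x$truth$port$anomaly_class != "none"]
  ))
  if (length(anom)) {
    cat("  planted:", paste(names(anom), anom, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
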