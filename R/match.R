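# Farm-to-port individual matching, duplicate detection and the anomaly
# taxonomy.

#' Matching parameters
#'
#' @param alpha ESD significance level (default 0.05).
#' @param k_max Maximum outliers per ESD run (default 5): a port sample can
#'   have at most a handful of near-identical relatives in the cohort.
#' @param r_identity_floor Minimum relatedness for a non-same-tag candidate
#'   to count as "same individual" (default 0.9). Captive cohorts can hold
#'   full sibs near r = 0.5, which must not be auto-matched.
#' @export
match_params <- function(alpha = 0.05, k_max = 5, r_identity_floor = 0.9) {
  list(alpha = alpha, k_max = k_max, r_identity_floor = r_identity_floor)
}

#' Match one port sample against the farm cohort
#'
#' Computes the port sample's relatedness to every farm sample of the year,
#' runs the generalized ESD test on that distribution, and classifies:
#' candidate matches are ESD-flagged values above the cohort mean (the test
#' is two-sided but only the upper tail can be a match); if the same-tag
#' farm sample is a candidate and attains the maximum relatedness the
#' outcome is `MATCH`; otherwise a candidate with `r >= r_identity_floor`
#' gives `REASSIGNED_SAME_FARM` (or `REASSIGNED_CROSS_FARM`, with the
#' matched facility recorded); otherwise `NO_MATCH`. A declared tag absent
#' from the farm cohort is its own outcome class.
#'
#' @param port_sample One-row wide genotype tibble (with `tag`).
#' @param farm_cohort Wide genotype tibble of the year's farm samples
#'   (>= 10 rows).
#' @param freqs Reference allele frequencies; default computed from the
#'   full farm cohort, the designated reference population.
#' @param params A [match_params()] list.
#' @return One-row tibble (`match_result`): `port_sample_id`,
#'   `declared_tag`, `match_class`, `matched_farm_sample`, `best_farm_tag`,
#'   `matched_facility`, `esd_significant`, `r_same_tag`, `r_best`.
#' @export
match_port_sample <- function(port_sample, farm_cohort,
                              freqs = allele_frequencies(farm_cohort),
                              params = match_params()) {
  if (nrow(farm_cohort) < 10) abort("Farm cohort must hold at least 10 samples.")
  r <- qg_matrix(port_sample, farm_cohort, freqs)[1, ]
  classify_port_r(
    r,
    port_sample_id = port_sample$sample_id[1],
    declared_tag = port_sample$tag[1],
    farm_tags = farm_cohort$tag,
    farm_ids = farm_cohort$sample_id,
    farm_facilities = farm_cohort$facility_id,
    declared_facility = port_sample$facility_id[1],
    params = params
  )
}

#' Match every port sample
#'
#' Vectorized driver over the whole spot-check set; one relatedness matrix,
#' one ESD run per port sample.
#'
#' @param port Wide genotype tibble of port samples.
#' @inheritParams match_port_sample
#' @return Tibble with one [match_port_sample()] row per port sample, plus
#'   the relatedness matrix as attribute `r_matrix`.
#' @export
match_port_samples <- function(port, farm_cohort,
                               freqs = allele_frequencies(farm_cohort),
                               params = match_params()) {
  if (nrow(farm_cohort) < 10) abort("Farm cohort must hold at least 10 samples.")
  r_mat <- qg_matrix(port, farm_cohort, freqs)
  rows <- purrr::map(seq_len(nrow(port)), function(i) {
    classify_port_r(
      r_mat[i, ],
      port_sample_id = port$sample_id[i],
      declared_tag = port$tag[i],
      farm_tags = farm_cohort$tag,
      farm_ids = farm_cohort$sample_id,
      farm_facilities = farm_cohort$facility_id,
      declared_facility = port$facility_id[i],
      params = params
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "r_matrix") <- r_mat
  out
}

classify_port_r <- function(r, port_sample_id, declared_tag, farm_tags,
                            farm_ids, farm_facilities, declared_facility,
                            params) {
  same_idx <- which(farm_tags == declared_tag)
  esd <- esd_outliers(r, k_max = params$k_max, alpha = params$alpha)
  candidates <- esd$outliers[r[esd$outliers] > mean(r)]

  res <- tibble(
    port_sample_id = port_sample_id,
    declared_tag = declared_tag,
    match_class = "PENDING",
    matched_farm_sample = NA_character_,
    best_farm_tag = NA_character_,
    matched_facility = NA_character_,
    esd_significant = FALSE,
    r_same_tag = if (length(same_idx)) unname(r[same_idx[1]]) else NA_real_,
    r_best = unname(max(r))
  )
  if (length(candidates)) {
    best_c <- candidates[which.max(r[candidates])]
    res$best_farm_tag <- farm_tags[best_c]
  }
  if (!length(same_idx)) {
    res$match_class <- "DECLARED_TAG_ABSENT"
    return(res)
  }
  same_idx <- same_idx[1]

  if (same_idx %in% candidates && r[same_idx] >= max(r)) {
    res$match_class <- "MATCH"
    res$matched_farm_sample <- farm_ids[same_idx]
    res$best_farm_tag <- farm_tags[same_idx]
    res$matched_facility <- farm_facilities[same_idx]
    res$esd_significant <- TRUE
    return(res)
  }
  strong <- candidates[r[candidates] >= params$r_identity_floor]
  strong <- setdiff(strong, same_idx)
  if (length(strong)) {
    best <- strong[which.max(r[strong])]
    same_farm <- !is.na(declared_facility) &&
      farm_facilities[best] == declared_facility
    res$match_class <- if (same_farm) "REASSIGNED_SAME_FARM" else "REASSIGNED_CROSS_FARM"
    res$matched_farm_sample <- farm_ids[best]
    res$best_farm_tag <- farm_tags[best]
    res$matched_facility <- farm_facilities[best]
    res$esd_significant <- TRUE
    return(res)
  }
  res$match_class <- "NO_MATCH"
  res
}

#' Find farm tags sharing one individual
#'
#' All pairs of farm samples whose genotypes disagree at no more than
#' `mismatch_tolerance` loci (both samples fully typed at the locus).
#' Tolerance 0 uses exact profile hashing; a positive tolerance absorbs
#' allelic dropout at the cost of a quadratic scan. The cumulative PID of
#' the marker panel quantifies the weight of evidence that a reported pair
#' is one individual rather than a chance profile collision.
#'
#' @param farm_cohort Wide genotype tibble (>= 2 rows).
#' @param mismatch_tolerance Maximum disagreeing loci (default 0).
#' @param freqs Optional reference frequencies for the pairwise relatedness
#'   reported with each pair (default: cohort frequencies).
#' @return Tibble `tag_a`, `tag_b`, `sample_a`, `sample_b`, `n_mismatch`,
#'   `r`, with attribute `cumulative_pid`.
#' @export
find_duplicates <- function(farm_cohort, mismatch_tolerance = 0,
                            freqs = allele_frequencies(farm_cohort)) {
  if (nrow(farm_cohort) < 2) abort("Cohort must hold at least 2 samples.")
  loci <- str_loci(farm_cohort)
  m <- allele_matrices(farm_cohort, loci)
  n <- nrow(farm_cohort)

  pairs <- if (mismatch_tolerance == 0) {
    typed_all <- rowSums(m$a1 == 0L | m$a2 == 0L) == 0
    key <- do.call(paste, c(
      lapply(seq_along(loci), function(j) paste(m$a1[, j], m$a2[, j])),
      sep = "|"
    ))
    key[!typed_all] <- paste0("__half__", which(!typed_all)) # opt out of hashing
    idx <- split(seq_len(n), key)
    idx <- idx[lengths(idx) > 1]
    if (length(idx)) {
      dplyr::bind_rows(purrr::map(idx, function(g) {
        cmb <- utils::combn(g, 2)
        tibble(i = cmb[1, ], j = cmb[2, ], n_mismatch = 0L)
      }))
    } else {
      tibble(i = integer(0), j = integer(0), n_mismatch = integer(0))
    }
  } else {
    mism <- matrix(0L, n, n)
    for (j in seq_along(loci)) {
      typed <- m$a1[, j] != 0L & m$a2[, j] != 0L
      diff1 <- outer(m$a1[, j], m$a1[, j], "!=") | outer(m$a2[, j], m$a2[, j], "!=")
      both_typed <- outer(typed, typed, "&")
      mism <- mism + (diff1 & both_typed)
    }
    hit <- which(upper.tri(mism) & mism <= mismatch_tolerance, arr.ind = TRUE)
    tibble(
      i = hit[, 1], j = hit[, 2],
      n_mismatch = mism[cbind(hit[, 1], hit[, 2])]
    )
  }

  out <- tibble(
    tag_a = farm_cohort$tag[pairs$i],
    tag_b = farm_cohort$tag[pairs$j],
    sample_a = farm_cohort$sample_id[pairs$i],
    sample_b = farm_cohort$sample_id[pairs$j],
    n_mismatch = pairs$n_mismatch,
    r = NA_real_
  )
  if (nrow(out)) {
    out$r <- as.numeric(qg_relatedness(
      farm_cohort[pairs$i, ], farm_cohort[pairs$j, ], freqs
    ))
  }
  attr(out, "cumulative_pid") <- tryCatch(
    cumulative_pid(marker_stats(farm_cohort, include_hwe = FALSE)),
    error = function(e) NA_real_
  )
  out
}

#' Classify detected anomalies into the compliance taxonomy
#'
#' Maps detection outcomes onto the two irregularity classes: pooled or
#' mixed skeletons (Type I: a port profile with no farm match, or two farm
#' tags on one individual) and mislabelling or tag-swapping (Type II: a
#' port profile matching a different tag). Non-target species detections
#' are counted separately. Counts and proportions are reported per site and
#' year, in the shape of a compliance summary table.
#'
#' @param match_results A [match_port_samples()] tibble.
#' @param duplicates A [find_duplicates()] tibble.
#' @param species_assignments An [assign_species()] tibble joined with
#'   `site` and `year` columns (every farm and port sample).
#' @return List of class `anomaly_ledger`: `anomalies` (tibble `site`,
#'   `year`, `id`, `tag`, `class`, `type_interpretation`) and `summary`
#'   (tibble `site`, `year`, `n_anomalies`, `n_total`, `proportion`,
#'   `label`).
#' @export
classify_anomalies <- function(match_results, duplicates, species_assignments) {
  if (any(match_results$match_class == "PENDING")) {
    abort("All port samples must be resolved before classification.")
  }
  need <- c("sample_id", "site", "year", "final_call")
  if (!all(need %in% names(species_assignments))) {
    abort("`species_assignments` needs sample_id, site, year and final_call columns.")
  }
  sa <- species_assignments
  farm_n <- sum(sa$site == "FARM")
  port_n <- sum(sa$site == "PORT")
  years <- unique(sa$year)
  yr <- years[1]

  anomalies <- list()
  non_target <- sa[sa$final_call %in% c("TIGER", "HYBRID_SUSPECT") &
    sa$final_call != "LION", ]
  if (nrow(non_target)) {
    anomalies$non_target <- tibble(
      site = non_target$site, year = non_target$year,
      id = non_target$sample_id,
      tag = if ("tag" %in% names(non_target)) non_target$tag else NA_character_,
      class = "non_target_species",
      type_interpretation = "UNRESOLVED"
    )
  }
  if (nrow(duplicates)) {
    anomalies$dups <- tibble(
      site = "FARM", year = yr,
      id = c(duplicates$sample_a, duplicates$sample_b),
      tag = c(duplicates$tag_a, duplicates$tag_b),
      class = "duplicate_individual",
      type_interpretation = "TYPE_I_POOLING"
    )
  }
  mr <- match_results
  bad <- mr[mr$match_class %in%
    c("REASSIGNED_SAME_FARM", "REASSIGNED_CROSS_FARM", "NO_MATCH"), ]
  if (nrow(bad)) {
    anomalies$port <- tibble(
      site = "PORT", year = yr,
      id = bad$port_sample_id, tag = bad$declared_tag,
      class = ifelse(bad$match_class == "NO_MATCH", "pooled_no_match", "reassigned_tag"),
      type_interpretation = ifelse(
        bad$match_class == "NO_MATCH", "TYPE_I_POOLING", "TYPE_II_MISLABEL"
      )
    )
  }
  anomalies <- dplyr::bind_rows(anomalies)
  if (!nrow(anomalies)) {
    anomalies <- tibble(
      site = character(0), year = integer(0), id = character(0),
      tag = character(0), class = character(0), type_interpretation = character(0)
    )
  }

  summary <- tibble(site = SITE_LEVELS, year = yr) |>
    dplyr::mutate(
      n_anomalies = vapply(
        .data$site,
        function(s) sum(anomalies$site == s), integer(1), USE.NAMES = FALSE
      ),
      n_total = c(farm_n, port_n),
      proportion = ifelse(.data$n_total > 0, .data$n_anomalies / .data$n_total, NA_real_),
      label = sprintf(
        "%d/%d (%.1f%%)", .data$n_anomalies, .data$n_total,
        100 * .data$proportion
      )
    )
  structure(
    list(anomalies = anomalies, summary = summary),
    class = "anomaly_ledger"
  )
}

#' @export
print.anomaly_ledger <- function(x, ...) {
  cat("<anomaly_ledger>\n")
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf(
      "  %s %d: %s anomalies\n",
      x$summary$site[i], x$summary$year[i], x$summary$label[i]
    ))
  }
  invisible(x)
}
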