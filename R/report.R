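# Pipeline orchestration and compliance reporting.

#' Run the full compliance pipeline
#'
#' Executes the analysis stages in their mandated order — species
#' assignment, duplicate detection, farm-to-port matching, weight audit,
#' anomaly ledger — on one year's cohort. Species gating precedes matching:
#' a non-lion farm sample is excluded from lion matching and reported as a
#' non-target-species detection (the interception path). Errors in
#' cross-referencing (a weight tag absent from the genotype table) are
#' accumulated and reported, not fatal: a compliance review needs the
#' complete picture of partial data.
#'
#' @param inputs List with elements `farm` and `port` (wide genotype
#'   tibbles), `farm_snp` and `port_snp` (SNP call tibbles), optionally
#'   `weights` (weight manifest), `lion_reference` / `tiger_reference`
#'   (reference genotype panels for nuclear follow-up), and
#'   `input_files` (paths to digest for the audit trail). A
#'   [simulate_cohort()] result is accepted directly.
#' @param params List of stage parameters: `match` ([match_params()]),
#'   `mismatch_tolerance` (duplicates), `weight_threshold_kg`,
#'   `packaging_policy`, `thresholds` (species), `include_marker_qc`
#'   (default FALSE), `hwe_mc_reps`.
#' @param seed Integer seed covering any Monte-Carlo stage (marker QC).
#' @return Object of class `compliance_report`.
#' @export
run_pipeline <- function(inputs, params = list(), seed = 1) {
  if (inherits(inputs, "cohort_sim")) {
    inputs <- list(
      farm = inputs$farm, port = inputs$port,
      farm_snp = inputs$farm_snp, port_snp = inputs$port_snp,
      weights = inputs$weights, lion_reference = inputs$lion_reference,
      tiger_reference = inputs$tiger_reference
    )
  }
  p <- modifyList(
    list(
      match = match_params(), mismatch_tolerance = 0,
      weight_threshold_kg = 0.6, packaging_policy = 0,
      thresholds = list(q_lion_min = 0.95, q_tiger_max = 0.05),
      include_marker_qc = FALSE, hwe_mc_reps = 2000
    ),
    params
  )
  errors <- character(0)
  year <- inputs$farm$year[1]

  # -- stage 1: species (gating precedes matching) -------------------------
  sa_farm <- assign_species(
    inputs$farm_snp,
    genotypes = inputs$farm,
    lion_panel = inputs$lion_reference, tiger_panel = inputs$tiger_reference,
    thresholds = p$thresholds
  )
  sa_port <- assign_species(
    inputs$port_snp,
    genotypes = inputs$port,
    lion_panel = inputs$lion_reference, tiger_panel = inputs$tiger_reference,
    thresholds = p$thresholds
  )
  species <- dplyr::bind_rows(
    dplyr::mutate(sa_farm, site = "FARM", year = year,
      tag = inputs$farm$tag[match(sa_farm$sample_id, inputs$farm$sample_id)]
    ),
    dplyr::mutate(sa_port, site = "PORT", year = year,
      tag = inputs$port$tag[match(sa_port$sample_id, inputs$port$sample_id)]
    )
  )

  farm_lion <- inputs$farm[sa_farm$final_call == "LION", ]
  port_lion <- inputs$port[sa_port$final_call == "LION", ]
  excluded_farm <- inputs$farm$sample_id[sa_farm$final_call != "LION"]

  # -- stage 2: marker QC (optional) ---------------------------------------
  marker_qc <- NULL
  if (isTRUE(p$include_marker_qc)) {
    marker_qc <- marker_stats(farm_lion,
      hwe_mc_reps = p$hwe_mc_reps, seed = seed
    )
  }

  # -- stage 3: duplicates at farm -----------------------------------------
  freqs <- allele_frequencies(farm_lion)
  duplicates <- find_duplicates(farm_lion,
    mismatch_tolerance = p$mismatch_tolerance, freqs = freqs
  )

  # -- stage 4: farm-to-port matching --------------------------------------
  match_results <- match_port_samples(port_lion, farm_lion,
    freqs = freqs, params = p$match
  )
  non_target_port <- inputs$port$sample_id[sa_port$final_call != "LION"]
  if (length(non_target_port)) {
    match_results <- dplyr::bind_rows(
      match_results,
      tibble(
        port_sample_id = non_target_port,
        declared_tag = inputs$port$tag[match(non_target_port, inputs$port$sample_id)],
        match_class = "NON_TARGET_SPECIES",
        matched_farm_sample = NA_character_, best_farm_tag = NA_character_,
        matched_facility = NA_character_, esd_significant = FALSE,
        r_same_tag = NA_real_, r_best = NA_real_
      )
    )
  }

  # -- stage 5: weight audit ----------------------------------------------
  weight_audit <- NULL
  if (!is.null(inputs$weights)) {
    missing_tags <- setdiff(inputs$weights$tag, inputs$farm$tag)
    if (length(missing_tags)) {
      errors <- c(errors, sprintf(
        "weight manifest tag(s) absent from genotype table: %s",
        paste(head(missing_tags, 5), collapse = ", ")
      ))
    }
    spot <- inputs$weights[!is.na(inputs$weights$port_gross_weight_kg), ]
    if (nrow(spot)) {
      weight_audit <- audit_pairs(spot,
        threshold_kg = p$weight_threshold_kg,
        packaging_policy = p$packaging_policy
      )
    }
  }

  # -- stage 6: anomaly ledger ---------------------------------------------
  ledger <- classify_anomalies(match_results, duplicates, species)

  detail <- dplyr::left_join(
    species[c("sample_id", "tag", "site", "year", "snp_call", "q_lion", "final_call")],
    match_results[c("port_sample_id", "match_class", "best_farm_tag", "r_same_tag", "r_best")],
    by = c(sample_id = "port_sample_id")
  )
  if (!is.null(weight_audit)) {
    detail <- dplyr::left_join(
      detail,
      dplyr::mutate(weight_audit$pairs[c("tag", "delta_kg", "flag")], site = "PORT"),
      by = c("tag", "site")
    )
  }

  structure(
    list(
      meta = list(
        schema = "bonematch-report/1",
        seed = seed,
        year = year,
        n_farm = nrow(inputs$farm), n_port = nrow(inputs$port),
        params_digest = as.character(openssl::sha256(
          jsonlite::toJSON(p, auto_unbox = TRUE, force = TRUE, digits = 10)
        )),
        input_checksums = if (!is.null(inputs$input_files)) {
          d <- custody_digest(inputs$input_files)
          d[c("path", "sha256", "bytes")]
        } else {
          NULL
        }
      ),
      species_summary = dplyr::count(species, .data$site, .data$final_call),
      species = species,
      marker_qc = marker_qc,
      duplicates = duplicates,
      match_results = match_results,
      weight_audit = weight_audit,
      ledger = ledger,
      detail = detail,
      errors = errors,
      excluded_from_matching = excluded_farm
    ),
    class = "compliance_report"
  )
}

#' @export
print.compliance_report <- function(x, ...) {
  cat(sprintf(
    "<compliance_report> year %s: %d farm + %d port samples\n",
    x$meta$year, x$meta$n_farm, x$meta$n_port
  ))
  print(x$ledger)
  if (!is.null(x$weight_audit)) {
    cat(sprintf("  weight flags: %d\n", x$weight_audit$n_flagged))
  }
  if (length(x$errors)) cat("  errors:", length(x$errors), "\n")
  invisible(x)
}

#' Does a report contain anomalies?
#'
#' @param report A `compliance_report`.
#' @return TRUE when any anomaly (including weight flags) was detected.
#' @export
has_anomalies <- function(report) {
  sum(report$ledger$summary$n_anomalies) > 0 ||
    (!is.null(report$weight_audit) && report$weight_audit$n_flagged > 0)
}

#' Render a compliance report
#'
#' Machine-readable JSON (lossless round trip, byte-identical across
#' renders of one report) or a human-readable Markdown summary.
#'
#' @param report A `compliance_report`.
#' @param format `"json"` or `"markdown"`.
#' @param path Optional output file.
#' @return The rendered text (invisibly when written to `path`).
#' @export
render_report <- function(report, format = c("json", "markdown"), path = NULL) {
  format <- match.arg(format)
  text <- if (format == "json") {
    body <- list(
      meta = report$meta,
      species_summary = report$species_summary,
      ledger = list(
        anomalies = report$ledger$anomalies,
        summary = report$ledger$summary
      ),
      duplicates = as_tibble(report$duplicates),
      match_results = report$match_results,
      weight_audit = if (!is.null(report$weight_audit)) {
        list(
          n_flagged = report$weight_audit$n_flagged,
          threshold_kg = report$weight_audit$threshold_kg,
          flagged_tags = report$weight_audit$pairs$tag[report$weight_audit$pairs$flag],
          paired_t = if (!is.null(report$weight_audit$paired_t)) {
            list(
              statistic = unname(report$weight_audit$paired_t$statistic),
              p_value = report$weight_audit$paired_t$p.value
            )
          } else {
            NULL
          }
        )
      } else {
        NULL
      },
      detail = report$detail,
      errors = report$errors
    )
    as.character(jsonlite::toJSON(
      body,
      auto_unbox = TRUE, digits = 10, pretty = TRUE, na = "null"
    ))
  } else {
    render_markdown_report(report)
  }
  if (!is.null(path)) {
    writeLines(text, path, useBytes = TRUE)
    return(invisible(text))
  }
  text
}

render_markdown_report <- function(report) {
  s <- report$ledger$summary
  lines <- c(
    sprintf("# Compliance report, %s quota", report$meta$year),
    "",
    sprintf(
      "- Samples analysed: %d farm, %d port.",
      report$meta$n_farm, report$meta$n_port
    ),
    "- Anomalies by site:",
    sprintf("  - %s: %s", s$site, s$label),
    ""
  )
  nt <- report$species[report$species$final_call != "LION", ]
  if (nrow(nt)) {
    lines <- c(lines, sprintf(
      "- Non-target species / escalations: %s.",
      paste(sprintf("%s (%s)", nt$sample_id, nt$final_call), collapse = ", ")
    ))
  }
  if (nrow(report$duplicates)) {
    lines <- c(lines, sprintf(
      "- Farm tag pairs from one individual: %s.",
      paste(sprintf("%s/%s", report$duplicates$tag_a, report$duplicates$tag_b),
        collapse = ", "
      )
    ))
  }
  if (!is.null(report$weight_audit)) {
    lines <- c(lines, sprintf(
      "- Weight audit: %d of %d pairs flagged (> %.1f kg gain).",
      report$weight_audit$n_flagged, nrow(report$weight_audit$pairs),
      report$weight_audit$threshold_kg
    ))
  }
  if (length(report$errors)) {
    lines <- c(lines, "- Cross-reference errors:", sprintf("  - %s", report$errors))
  }
  paste(lines, collapse = "\n")
}

#' Write the report's tabular artefacts
#'
#' TSV exports of the per-sample detail table, match results, duplicates
#' and ledger, plus the JSON report, into a directory.
#'
#' @param report A `compliance_report`.
#' @param dir Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_report_tables <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(report$detail, file.path(dir, "detail.tsv"), progress = FALSE)
  readr::write_tsv(report$match_results, file.path(dir, "match_results.tsv"),
    progress = FALSE
  )
  readr::write_tsv(as_tibble(report$duplicates), file.path(dir, "duplicates.tsv"),
    progress = FALSE
  )
  readr::write_tsv(report$ledger$anomalies, file.path(dir, "anomalies.tsv"),
    progress = FALSE
  )
  readr::write_tsv(report$ledger$summary, file.path(dir, "anomaly_summary.tsv"),
    progress = FALSE
  )
  if (!is.null(report$marker_qc)) {
    write_marker_stats(report$marker_qc, file.path(dir, "marker_stats.tsv"))
  }
  render_report(report, "json", file.path(dir, "report.json"))
  render_report(report, "markdown", file.path(dir, "report.md"))
  invisible(dir)
}
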