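#' Parameters for the skeleton-weight generator
#'
#' Defaults follow the 2018 farm inspections (mean 16.6 kg, SD 5.5 kg) with
#' a hard 5 kg truncation floor (observed skeletons ranged 6.0-38.0 kg), a
#' deterministic farm-to-port desiccation factor of 0.88 (skeletons are
#' cleaned and dry out between inspections; the observed reduction was on
#' the order of 12%), and a 1.1 kg mean packaging weight per skeleton.
#'
#' @param farm_mean,farm_sd Mean and SD (kg) of the truncated-normal farm
#'   weight distribution.
#' @param floor_kg Lower truncation bound (kg), must be positive.
#' @param desiccation_mean Multiplicative farm-to-port nett factor.
#' @param desiccation_sd SD of the per-skeleton desiccation factor
#'   (default 0: the factor is deterministic).
#' @param packaging_mean,packaging_sd Additive packaging weight (kg) at
#'   port; packaging is truncated at 0.
#' @export
weight_params <- function(farm_mean = 16.6, farm_sd = 5.5, floor_kg = 5,
                          desiccation_mean = 0.88, desiccation_sd = 0,
                          packaging_mean = 1.1, packaging_sd = 0) {
  assert_positive_scalar(farm_mean, "farm_mean")
  assert_positive_scalar(farm_sd, "farm_sd")
  assert_positive_scalar(floor_kg, "floor_kg")
  if (desiccation_mean <= 0) abort("`desiccation_mean` must be positive.")
  if (packaging_mean < 0) abort("`packaging_mean` must be non-negative.")
  list(
    farm_mean = farm_mean, farm_sd = farm_sd, floor_kg = floor_kg,
    desiccation_mean = desiccation_mean, desiccation_sd = desiccation_sd,
    packaging_mean = packaging_mean, packaging_sd = packaging_sd
  )
}

#' Simulate a paired farm/port weight manifest
#'
#' Per skeleton: a truncated-normal farm weight, a port nett weight equal to
#' the farm weight times a desiccation factor, and a port gross weight equal
#' to nett plus packaging. Port weights are only recorded for spot-checked
#' tags (those present in `port_tags`), mirroring the compliance data. An
#' optional anomalous inflation can be planted on selected tags, which the
#' weight audit's >0.6 kg rule should flag.
#'
#' @param consignments The `consignments` tibble of a [simulate_cohort()]
#'   result (columns `tag`, `facility_id`, `trader_id`, `consignment_id`,
#'   `year`).
#' @param params A [weight_params()] list.
#' @param port_tags Character vector of spot-checked tags receiving port
#'   weights (default: all tags).
#' @param inflate_tags Tags whose port nett weight is inflated.
#' @param inflate_kg Inflation in kg (default 2).
#' @param seed Optional integer seed.
#' @return A weight-manifest tibble: `tag`, `facility_id`, `trader_id`,
#'   `consignment_id`, `year`, `farm_weight_kg`, `port_gross_weight_kg`,
#'   `packaging_weight_kg` (port columns `NA` off the spot-check).
#' @export
simulate_weights <- function(consignments, params = weight_params(),
                             port_tags = consignments$tag,
                             inflate_tags = character(0),
                             inflate_kg = 2,
                             seed = NULL) {
  n <- nrow(consignments)
  with_seed_if(seed, {
    farm_w <- rnorm_truncated(n, params$farm_mean, params$farm_sd, params$floor_kg)
    dfac <- if (params$desiccation_sd > 0) {
      rnorm_truncated(n, params$desiccation_mean, params$desiccation_sd, 1e-6)
    } else {
      rep(params$desiccation_mean, n)
    }
    pack <- if (params$packaging_sd > 0) {
      rnorm_truncated(n, params$packaging_mean, params$packaging_sd, 0)
    } else {
      rep(params$packaging_mean, n)
    }
    nett <- farm_w * dfac
    nett[consignments$tag %in% inflate_tags] <-
      nett[consignments$tag %in% inflate_tags] + inflate_kg
    gross <- nett + pack
    spot <- consignments$tag %in% port_tags
    dplyr::mutate(
      consignments,
      farm_weight_kg = farm_w,
      port_gross_weight_kg = ifelse(spot, gross, NA_real_),
      packaging_weight_kg = ifelse(spot, pack, NA_real_)
    )
  })
}

# Truncated-normal sampler by rejection; lower bound only.
rnorm_truncated <- function(n, mean, sd, lower) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower]
  }
  out
}
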