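# Cohort simulator: planted anomalies, determinism, error model.

panels <- make_species_panels(n_loci = 10, seed = 21)

test_that("null config produces a cohort where every port sample is its own tag", {
  cfg <- cohort_config(quota_size = 120, seed = 22)
  sim <- simulate_cohort(cfg, panels)
  expect_true(all(sim$truth$farm$anomaly_class == "none"))
  expect_true(all(sim$truth$port$anomaly_class == "none"))
  # port genotypes locus-for-locus identical to same-tag farm genotypes
  loci_cols <- unlist(lapply(str_loci(sim$farm), paste0, c(".1", ".2")))
  farm_rows <- sim$farm[match(sim$port$tag, sim$farm$tag), loci_cols]
  expect_equal(as.data.frame(sim$port[loci_cols]), as.data.frame(farm_rows),
    ignore_attr = TRUE
  )
})

test_that("seed-fixed reruns are identical; planted classes match the request", {
  cfg <- cohort_config_2018(seed = 23, quota_size = 250)
  s1 <- simulate_cohort(cfg, panels)
  s2 <- simulate_cohort(cfg, panels)
  expect_identical(s1, s2)

  tf <- table(s1$truth$farm$anomaly_class)
  tp <- table(s1$truth$port$anomaly_class)
  expect_equal(unname(tf["non_target_species"]), 1)
  expect_equal(unname(tf["duplicate_individual"]), 2) # one pair = two tags
  expect_equal(unname(tp["reassigned_tag"]), 1)
  expect_equal(unname(tp["pooled_no_match"]), 4)

  # classes are mutually exclusive per tag, and every non-pooled port sample's
  # individual exists at the farm
  expect_equal(anyDuplicated(s1$truth$farm$tag), 0)
  on_farm <- s1$truth$port$individual_id %in% s1$truth$farm$individual_id
  expect_true(all(on_farm[s1$truth$port$anomaly_class != "pooled_no_match"]))
  expect_true(all(!on_farm[s1$truth$port$anomaly_class == "pooled_no_match"]))

  # spot-check size: at least ceiling(12.5%) per consignment
  sizes <- table(s1$consignments$consignment_id)
  checked <- table(s1$consignments$consignment_id[
    s1$consignments$tag %in% s1$port$tag
  ])
  expect_true(all(checked[names(sizes)] >= ceiling(0.125 * sizes) - 1))
})

test_that("allelic dropout rate matches its nominal probability", {
  cfg <- cohort_config(
    quota_size = 600, seed = 24,
    genotyping_error = list(dropout = 0.05)
  )
  sim <- simulate_cohort(cfg, panels)
  m <- bonematch:::allele_matrices(sim$farm)
  n_entries <- length(m$a1) + length(m$a2)
  expect_gte(n_entries, 10000)
  frac <- (sum(m$a1 == 0L) + sum(m$a2 == 0L)) / n_entries
  se <- sqrt(0.05 * 0.95 / n_entries)
  expect_lt(abs(frac - 0.05), 4 * se)
})

test_that("anomaly requests beyond the quota are rejected", {
  expect_error(
    cohort_config(quota_size = 4, anomaly_rates = list(pooled_no_match = 5)),
    "exceed"
  )
})

test_that("weight generator calibration, identity case and planted inflation", {
  cfg <- cohort_config(quota_size = 800, seed = 1)
  sim <- simulate_cohort(cfg, panels)
  w <- simulate_weights(sim$consignments,
    params = weight_params(
      farm_mean = 16.6, farm_sd = 5.5,
      desiccation_mean = 0.88, packaging_mean = 1.1
    ),
    seed = 1
  )
  se <- 5.5 / sqrt(800)
  expect_lt(abs(mean(w$farm_weight_kg) - 16.6), 3 * se)
  expect_true(all(w$farm_weight_kg > 0))
  # nett = farm * desiccation; gross = nett + packaging
  nett <- w$port_gross_weight_kg - w$packaging_weight_kg
  expect_equal(nett, w$farm_weight_kg * 0.88, tolerance = 1e-12)

  w_id <- simulate_weights(sim$consignments,
    params = weight_params(desiccation_mean = 1, packaging_mean = 0),
    seed = 2
  )
  expect_equal(
    w_id$port_gross_weight_kg - w_id$packaging_weight_kg,
    w_id$farm_weight_kg,
    tolerance = 1e-12
  )

  w_inf <- simulate_weights(sim$consignments,
    params = weight_params(desiccation_mean = 1, packaging_mean = 0),
    inflate_tags = sim$consignments$tag[5], inflate_kg = 2, seed = 3
  )
  delta <- w_inf$port_gross_weight_kg[5] - w_inf$packaging_weight_kg[5] -
    w_inf$farm_weight_kg[5]
  expect_gt(delta, 0.6)

  expect_error(weight_params(farm_mean = -2), "positive")
  expect_error(weight_params(farm_sd = 0), "positive")
})
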