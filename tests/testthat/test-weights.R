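# Weight audit and consignment regressions.

test_that("published spot-check pairs fall under the 0.6 kg rule; gains are flagged", {
  w <- tibble::tibble(
    tag = c("A", "B", "C"),
    facility_id = "F1", trader_id = "T1", consignment_id = "C1", year = 2018L,
    farm_weight_kg = c(14.0, 19.2, 10.0),
    port_gross_weight_kg = c(10.35, 14.9, 12.0),
    packaging_weight_kg = c(0, 0, 0)
  )
  audit <- audit_pairs(w)
  expect_equal(audit$pairs$delta_kg, c(-3.65, -4.3, 2.0), tolerance = 1e-12)
  expect_equal(audit$pairs$flag, c(FALSE, FALSE, TRUE))
  expect_equal(audit$n_flagged, 1L)
  expect_error(audit_pairs(w, threshold_kg = -1), "positive")
})

test_that("flags are invariant to recorded packaging and the paired t flips sign on swap", {
  base <- tibble::tibble(
    tag = sprintf("T%02d", 1:20),
    trader_id = rep(c("TR1", "TR2"), 10), year = 2018L,
    farm_weight_kg = withr::with_seed(101, runif(20, 10, 25))
  )
  nett <- base$farm_weight_kg * 0.9
  packed <- dplyr::mutate(base,
    packaging_weight_kg = withr::with_seed(102, runif(20, 0.5, 2)),
    port_gross_weight_kg = nett + packaging_weight_kg
  )
  unpacked <- dplyr::mutate(base,
    packaging_weight_kg = 0, port_gross_weight_kg = nett
  )
  a1 <- audit_pairs(packed)
  a2 <- audit_pairs(unpacked)
  expect_equal(a1$pairs$flag, a2$pairs$flag)
  expect_equal(a1$pairs$delta_kg, a2$pairs$delta_kg, tolerance = 1e-12)

  swapped <- dplyr::mutate(unpacked,
    farm_weight_kg = nett, port_gross_weight_kg = base$farm_weight_kg
  )
  a3 <- audit_pairs(swapped)
  expect_equal(
    unname(a3$paired_t$statistic), -unname(a1$paired_t$statistic),
    tolerance = 1e-9
  )

  # trader mean applied where packaging is unrecorded
  half <- dplyr::mutate(packed, packaging_weight_kg = NA_real_)
  a4 <- audit_pairs(half, packaging_policy = c(TR1 = 1.0, TR2 = 1.5))
  expect_equal(
    a4$pairs$delta_kg,
    packed$port_gross_weight_kg - ifelse(base$trader_id == "TR1", 1.0, 1.5) -
      base$farm_weight_kg,
    tolerance = 1e-12
  )
})

test_that("no flags arise without desiccation or inflation, across seeds", {
  for (s in 111:115) {
    world <- simulate_world(s, quota = 60, anomalies = FALSE)
    w <- simulate_weights(world$consignments,
      params = weight_params(desiccation_mean = 1, packaging_mean = 1.1),
      seed = s
    )
    expect_equal(audit_pairs(w)$n_flagged, 0L)
  }
})

test_that("noiseless consignments recover their line exactly", {
  cons <- tibble::tibble(
    n_skeletons = c(4L, 10L, 20L, 40L),
    nett_weight_kg = c(60, 150, 300, 600) # count = weight / 15
  )
  fit <- fit_consignments(cons, year_group = "2017/8")
  expect_equal(fit$slope, 1 / 15, tolerance = 1e-12)
  expect_equal(fit$residual_sd, 0, tolerance = 1e-9)
  est <- estimate_count(fit, 150)
  expect_equal(est$count_estimate, 10L)
  expect_lt(est$upper - est$lower, 1e-6)

  expect_error(fit_consignments(cons[1:2, ]), "At least 3")
  degenerate <- dplyr::mutate(cons, nett_weight_kg = 100)
  expect_error(fit_consignments(degenerate), "Degenerate")
  expect_error(estimate_count(fit, -5), "positive")
})

test_that("cross-year estimates warn and differ; extrapolation widens the interval", {
  fit_a <- fit_consignments(
    tibble::tibble(n_skeletons = c(4L, 10L, 20L), nett_weight_kg = c(60, 150, 300)),
    year_group = "<=2014"
  )
  fit_b <- fit_consignments(
    tibble::tibble(n_skeletons = c(3L, 8L, 15L), nett_weight_kg = c(60, 160, 300)),
    year_group = "2016"
  )
  expect_warning(
    est_b <- estimate_count(fit_b, 150, year_group = "<=2014"),
    "differs"
  )
  est_a <- estimate_count(fit_a, 150)
  expect_false(est_a$count_estimate == est_b$count_estimate)
  expect_true(est_b$cross_year)

  noisy <- withr::with_seed(121, tibble::tibble(
    n_skeletons = 5:34,
    nett_weight_kg = 16.6 * (5:34) + rnorm(30, 0, 12)
  ))
  fit <- fit_consignments(noisy)
  centre <- mean(noisy$nett_weight_kg)
  inner <- estimate_count(fit, centre)
  outer_ <- estimate_count(fit, 2.5 * max(noisy$nett_weight_kg))
  expect_gt(outer_$upper - outer_$lower, inner$upper - inner$lower)
})

test_that("distinct per-skeleton weights in two year groups separate the slopes", {
  sig <- vapply(1:40, function(s) {
    withr::with_seed(s, {
      mk <- function(mean_w, label) {
        counts <- sample(5:60, 30, TRUE)
        tibble::tibble(
          n_skeletons = counts,
          nett_weight_kg = vapply(
            counts,
            function(cn) sum(pmax(rnorm(cn, mean_w, 5.5), 0.1)), numeric(1)
          ),
          year_group = label
        )
      }
      cmp <- compare_consignment_slopes(dplyr::bind_rows(mk(15, "A"), mk(20, "B")))
      cmp$p_value < 0.05
    })
  }, logical(1))
  expect_gte(mean(sig), 0.95)
})
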