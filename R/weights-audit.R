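# Skeleton-weight compliance audit.

#' Paired farm/port weight audit
#'
#' Computes nett port weights (gross minus packaging; a configured trader
#' mean or default packaging weight is subtracted where packaging was not
#' recorded), flags every pair whose port nett weight exceeds the farm
#' weight by more than `threshold_kg` (default 0.6 kg, the enforcement
#' threshold triggering further investigation), and summarizes: paired
#' t-test of farm vs port nett means over complete pairs, per-trader
#' one-way ANOVA of farm weights, and mean +/- SD summaries by trader. No
#' multiple-testing correction is applied across flags: each flag triggers
#' an investigation, not a claim.
#'
#' @param weight_records Weight-manifest tibble (see
#'   [read_weight_manifest()]).
#' @param threshold_kg Positive flag threshold (default 0.6).
#' @param packaging_policy Either a single default packaging weight (kg)
#'   applied where `packaging_weight_kg` is `NA`, or a named numeric vector
#'   of per-trader means (default 0: gross treated as nett when packaging
#'   is unrecorded).
#' @return Object of class `weight_audit`: `pairs` (per-tag tibble with
#'   `delta_kg` and `flag`), `summary` (by trader), `paired_t` (htest),
#'   `trader_anova` (aov), `threshold_kg`, `n_flagged`.
#' @export
audit_pairs <- function(weight_records, threshold_kg = 0.6,
                        packaging_policy = 0) {
  if (!is.numeric(threshold_kg) || threshold_kg <= 0) {
    abort("`threshold_kg` must be positive.")
  }
  w <- weight_records
  pack <- w$packaging_weight_kg
  if (is.null(pack)) pack <- rep(NA_real_, nrow(w))
  fallback <- if (!is.null(names(packaging_policy))) {
    unname(packaging_policy[w$trader_id])
  } else {
    rep(packaging_policy, nrow(w))
  }
  fallback[is.na(fallback)] <- 0
  pack <- ifelse(is.na(pack), fallback, pack)
  port_nett <- w$port_gross_weight_kg - pack

  pairs <- tibble(
    tag = w$tag,
    trader_id = if ("trader_id" %in% names(w)) w$trader_id else NA_character_,
    year = if ("year" %in% names(w)) w$year else NA_integer_,
    farm_weight_kg = w$farm_weight_kg,
    port_nett_kg = port_nett,
    delta_kg = port_nett - w$farm_weight_kg
  ) |>
    dplyr::mutate(flag = !is.na(.data$delta_kg) & .data$delta_kg > threshold_kg)

  complete <- pairs[!is.na(pairs$farm_weight_kg) & !is.na(pairs$port_nett_kg), ]
  if (!nrow(complete)) abort("No complete farm/port weight pairs.")

  paired_t <- if (nrow(complete) >= 2 && sd(complete$delta_kg) > 0) {
    t.test(complete$farm_weight_kg, complete$port_nett_kg, paired = TRUE)
  } else {
    NULL
  }
  trader_anova <- if (length(unique(w$trader_id)) >= 2) {
    aov(farm_weight_kg ~ trader_id, data = w)
  } else {
    NULL
  }
  summary <- complete |>
    dplyr::group_by(.data$trader_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      farm_mean = mean(.data$farm_weight_kg),
      farm_sd = sd(.data$farm_weight_kg),
      port_mean = mean(.data$port_nett_kg),
      port_sd = sd(.data$port_nett_kg),
      n_flagged = sum(.data$flag),
      .groups = "drop"
    )
  structure(
    list(
      pairs = pairs, summary = summary, paired_t = paired_t,
      trader_anova = trader_anova, threshold_kg = threshold_kg,
      n_flagged = sum(pairs$flag)
    ),
    class = "weight_audit"
  )
}

#' @export
print.weight_audit <- function(x, ...) {
  cat(sprintf(
    "<weight_audit> %d pairs, %d flagged (port nett > farm + %.1f kg)\n",
    nrow(x$pairs), x$n_flagged, x$threshold_kg
  ))
  if (!is.null(x$paired_t)) {
    cat(sprintf(
      "  paired t = %.2f, p = %.3g\n",
      x$paired_t$statistic, x$paired_t$p.value
    ))
  }
  invisible(x)
}

#' Fit a consignment count-weight regression
#'
#' Ordinary least squares of skeleton count on nett consignment weight for
#' one year group. Within a year the relationship is linear with slope near
#' the reciprocal of the mean skeleton weight, and supports predicting the
#' number of skeletons in an unopened consignment; across years the slope
#' drifts with mean skeleton weight, so cross-year use is warned against.
#'
#' @param consignments Tibble with columns `n_skeletons` and
#'   `nett_weight_kg` (>= 3 rows, non-degenerate weights).
#' @param year_group Label for the fitted year grouping.
#' @return Object of class `consignment_fit`: `model` (lm), `year_group`,
#'   `data`, `slope`, `intercept`, `residual_sd`.
#' @export
fit_consignments <- function(consignments, year_group = "all") {
  need <- c("n_skeletons", "nett_weight_kg")
  if (!all(need %in% names(consignments))) {
    abort("`consignments` needs n_skeletons and nett_weight_kg columns.")
  }
  cc <- consignments[complete.cases(consignments[need]), ]
  if (nrow(cc) < 3) abort("At least 3 consignments are required.")
  if (sd(cc$nett_weight_kg) == 0) {
    abort("Degenerate design: all consignment weights equal.")
  }
  model <- lm(n_skeletons ~ nett_weight_kg, data = cc)
  # noiseless designs (audit constructions) trip summary.lm's perfect-fit
  # warning; sigma is still what we want
  sigma <- suppressWarnings(summary(model)$sigma)
  structure(
    list(
      model = model, year_group = year_group, data = cc,
      slope = unname(coef(model)[2]),
      intercept = unname(coef(model)[1]),
      residual_sd = sigma
    ),
    class = "consignment_fit"
  )
}

#' @export
print.consignment_fit <- function(x, ...) {
  cat(sprintf(
    "<consignment_fit> %s: count = %.3f + %.4f * nett_kg (residual SD %.2f, n = %d)\n",
    x$year_group, x$intercept, x$slope, x$residual_sd, nrow(x$data)
  ))
  invisible(x)
}

#' Estimate skeleton count from a consignment weight
#'
#' Point estimate (rounded to the nearest whole skeleton) with an
#' unrounded prediction interval. Prediction intervals widen away from the
#' fitted data's centroid; a warning is emitted when the consignment's year
#' group differs from the fit's, since slopes drift across years and
#' out-of-year regressions mis-estimate counts.
#'
#' @param fit A [fit_consignments()] object.
#' @param nett_weight Positive consignment nett weight (kg); vectorized.
#' @param year_group Optional year group of the queried consignment.
#' @param level Prediction-interval coverage (default 0.95).
#' @return Tibble `nett_weight_kg`, `count_estimate` (integer), `fit`
#'   (unrounded), `lower`, `upper`, `cross_year` (logical).
#' @export
estimate_count <- function(fit, nett_weight, year_group = NULL, level = 0.95) {
  if (any(nett_weight <= 0)) abort("`nett_weight` must be positive.")
  cross <- !is.null(year_group) && !identical(year_group, fit$year_group)
  if (cross) {
    warn(sprintf(
      "Consignment year group '%s' differs from the fit's '%s': slopes drift across years and the estimate may be biased.",
      year_group, fit$year_group
    ))
  }
  pr <- suppressWarnings(predict(
    fit$model,
    newdata = data.frame(nett_weight_kg = nett_weight),
    interval = "prediction", level = level
  ))
  tibble(
    nett_weight_kg = nett_weight,
    count_estimate = as.integer(round(pr[, "fit"])),
    fit = pr[, "fit"],
    lower = pr[, "lwr"],
    upper = pr[, "upr"],
    cross_year = cross
  )
}

#' Compare consignment slopes across year groups
#'
#' Tests whether the count-weight slope differs between year groups via the
#' interaction term of a pooled linear model.
#'
#' @param consignments Tibble with `n_skeletons`, `nett_weight_kg` and
#'   `year_group`.
#' @return List: `f_statistic`, `p_value`, `anova` (the model comparison).
#' @export
compare_consignment_slopes <- function(consignments) {
  need <- c("n_skeletons", "nett_weight_kg", "year_group")
  if (!all(need %in% names(consignments))) {
    abort("`consignments` needs n_skeletons, nett_weight_kg and year_group.")
  }
  full <- lm(n_skeletons ~ nett_weight_kg * year_group, data = consignments)
  reduced <- lm(n_skeletons ~ nett_weight_kg + year_group, data = consignments)
  cmp <- anova(reduced, full)
  list(
    f_statistic = cmp$F[2],
    p_value = cmp$`Pr(>F)`[2],
    anova = cmp
  )
}

#' Aggregate a weight manifest into consignment totals
#'
#' @param weights Weight-manifest tibble.
#' @param use Which weight to total: port nett (gross minus packaging,
#'   default) or farm.
#' @return Tibble `consignment_id`, `trader_id`, `year`, `n_skeletons`,
#'   `nett_weight_kg`.
#' @export
consignment_totals <- function(weights, use = c("port", "farm")) {
  use <- match.arg(use)
  w <- weights
  value <- if (use == "port") {
    w$port_gross_weight_kg - dplyr::coalesce(w$packaging_weight_kg, 0)
  } else {
    w$farm_weight_kg
  }
  tibble(
    consignment_id = w$consignment_id, trader_id = w$trader_id,
    year = w$year, value = value
  ) |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$consignment_id, .data$trader_id, .data$year) |>
    dplyr::summarise(
      n_skeletons = dplyr::n(),
      nett_weight_kg = sum(.data$value),
      .groups = "drop"
    )
}
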