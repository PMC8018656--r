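# broom-style tidiers for fitted objects.

#' @export
tidy.consignment_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p.value = s[, "Pr(>|t|)"]
  )
}

#' @export
glance.consignment_fit <- function(x, ...) {
  s <- summary(x$model)
  tibble(
    year_group = x$year_group,
    slope = x$slope,
    intercept = x$intercept,
    r.squared = s$r.squared,
    sigma = s$sigma,
    nobs = nrow(x$data)
  )
}

#' @export
tidy.admixture_fit <- function(x, ...) {
  x$curve
}

#' @export
glance.admixture_fit <- function(x, ...) {
  tibble(
    q_lion = x$q_lion, loglik = x$loglik,
    n_loci = x$n_loci, flat = x$flat
  )
}

#' @export
tidy.weight_audit <- function(x, ...) {
  x$pairs
}

#' @export
glance.weight_audit <- function(x, ...) {
  tibble(
    n_pairs = nrow(x$pairs),
    n_flagged = x$n_flagged,
    threshold_kg = x$threshold_kg,
    t_statistic = if (!is.null(x$paired_t)) unname(x$paired_t$statistic) else NA_real_,
    t_p_value = if (!is.null(x$paired_t)) x$paired_t$p.value else NA_real_,
    anova_f = if (!is.null(x$trader_anova)) {
      summary(x$trader_anova)[[1]]$`F value`[1]
    } else {
      NA_real_
    },
    anova_p = if (!is.null(x$trader_anova)) {
      summary(x$trader_anova)[[1]]$`Pr(>F)`[1]
    } else {
      NA_real_
    }
  )
}

#' @export
tidy.esd_test <- function(x, ...) {
  x$steps
}

#' @export
glance.esd_test <- function(x, ...) {
  tibble(n_outliers = x$n_outliers, n_steps = nrow(x$steps))
}

#' @export
tidy.anomaly_ledger <- function(x, ...) {
  x$anomalies
}

#' @export
glance.anomaly_ledger <- function(x, ...) {
  tidyr::pivot_wider(
    x$summary[c("site", "n_anomalies")],
    names_from = "site", values_from = "n_anomalies",
    names_glue = "{tolower(site)}_anomalies"
  ) |>
    dplyr::mutate(total = sum(x$summary$n_anomalies))
}

#' @export
tidy.hwe_test <- function(x, ...) {
  tibble(p.value = x$p_value, method = x$method)
}
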