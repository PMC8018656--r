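# ggplot2 visualizations for the main result types.

#' @export
autoplot.genotype_accumulation <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n_loci, y = .data$mean_distinct)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$min_distinct, ymax = .data$max_distinct),
      fill = "grey80"
    ) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Loci in panel",
      y = "Distinct multilocus genotypes",
      title = "Genotype accumulation curve"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.consignment_fit <- function(object, level = 0.95, ...) {
  rng <- range(object$data$nett_weight_kg)
  grid <- tibble(nett_weight_kg = seq(rng[1], rng[2], length.out = 100))
  pr <- suppressWarnings(predict(object$model,
    newdata = grid,
    interval = "prediction", level = level
  ))
  grid$fit <- pr[, "fit"]
  grid$lwr <- pr[, "lwr"]
  grid$upr <- pr[, "upr"]
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$nett_weight_kg, y = .data$n_skeletons)) +
    ggplot2::geom_ribbon(
      data = grid,
      ggplot2::aes(y = .data$fit, ymin = .data$lwr, ymax = .data$upr),
      fill = "grey85"
    ) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fit), colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Nett consignment weight (kg)", y = "Skeletons in consignment",
      title = sprintf("Consignment regression (%s)", object$year_group)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.admixture_fit <- function(object, ...) {
  p <- ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$q, y = .data$loglik)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = expression(q[lion]), y = "log-likelihood",
      title = "Supervised admixture likelihood"
    ) +
    ggplot2::theme_minimal()
  if (!object$flat) {
    p <- p + ggplot2::geom_vline(xintercept = object$q_lion, linetype = 2)
  }
  p
}

#' @export
autoplot.weight_audit <- function(object, ...) {
  ggplot2::ggplot(
    object$pairs,
    ggplot2::aes(x = .data$farm_weight_kg, y = .data$delta_kg, colour = .data$flag)
  ) +
    ggplot2::geom_hline(yintercept = object$threshold_kg, linetype = 2) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "red")) +
    ggplot2::labs(
      x = "Farm weight (kg)", y = "Port nett - farm (kg)",
      colour = "Flagged",
      title = "Paired weight audit"
    ) +
    ggplot2::theme_minimal()
}

#' Relatedness heatmap between port and farm samples
#'
#' @param r A [qg_matrix()] result.
#' @param ... Ignored.
#' @export
plot_relatedness_heatmap <- function(r, ...) {
  df <- as_tibble(as.data.frame(as.table(r)), .name_repair = "minimal")
  names(df) <- c("port", "farm", "r")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$farm, y = .data$port, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "navy", mid = "white", high = "firebrick", midpoint = 0
    ) +
    ggplot2::labs(
      x = "Farm sample", y = "Port sample", fill = "r",
      title = "Queller-Goodnight relatedness"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_blank(),
      axis.text.y = ggplot2::element_blank()
    )
}

#' Per-locus heterozygosity profile
#'
#' @param stats A [marker_stats()] tibble.
#' @export
plot_marker_heterozygosity <- function(stats) {
  df <- tidyr::pivot_longer(
    as_tibble(stats)[c("locus", "H_O", "H_E")],
    cols = c("H_O", "H_E"), names_to = "measure", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$locus, y = .data$value, fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = NULL, y = "Heterozygosity", fill = NULL,
      title = "Observed vs expected heterozygosity by locus"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
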