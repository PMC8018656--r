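#' Generalized extreme studentized deviate (ESD) outlier test
#'
#' Rosner's iterative procedure for up to `k_max` outliers: at each step the
#' value maximizing `|x - mean| / sd` is removed and its test statistic
#' `R_i` compared with the critical value
#' `lambda_i = (n - i) * t / sqrt((n - i - 1 + t^2) * (n - i + 1))`, where
#' `t` is the `1 - alpha / (2 * (n - i + 1))` quantile of the t distribution
#' with `n - i - 1` degrees of freedom. The largest `i` with `R_i >
#' lambda_i` fixes the flagged set (all removals up to and including step
#' `i`). A zero standard deviation at any step stops the procedure with the
#' flags accumulated so far; a constant vector yields no flags.
#'
#' @param values Numeric vector, `n >= 3`.
#' @param k_max Maximum number of outliers tested (`< n / 2`; default 5).
#' @param alpha Significance level (default 0.05).
#' @return List of class `esd_test`: `outliers` (indices into `values`,
#'   possibly empty), `n_outliers`, and `steps` (tibble `i`, `index`,
#'   `value`, `R`, `lambda`, `exceeds`).
#' @export
esd_outliers <- function(values, k_max = 5, alpha = 0.05) {
  n <- length(values)
  if (n < 3) abort("ESD test requires n >= 3.")
  if (k_max >= n / 2) abort("`k_max` must be below n / 2.")
  if (k_max < 1) abort("`k_max` must be at least 1.")

  remaining <- seq_len(n)
  steps <- vector("list", k_max)
  n_steps <- 0L
  for (i in seq_len(k_max)) {
    x <- values[remaining]
    s <- sd(x)
    if (!is.finite(s) || s == 0) break
    dev <- abs(x - mean(x))
    j <- which.max(dev)
    r_i <- dev[j] / s
    ni <- n - i + 1 # sample size entering step i
    p <- 1 - alpha / (2 * ni)
    tq <- qt(p, df = ni - 2)
    lambda_i <- (ni - 1) * tq / sqrt((ni - 2 + tq^2) * ni)
    n_steps <- i
    steps[[i]] <- tibble(
      i = i, index = remaining[j], value = x[j],
      R = r_i, lambda = lambda_i, exceeds = r_i > lambda_i
    )
    remaining <- remaining[-j]
  }
  steps <- dplyr::bind_rows(steps[seq_len(n_steps)])
  last <- if (n_steps > 0 && any(steps$exceeds)) max(which(steps$exceeds)) else 0L
  outliers <- if (last > 0) steps$index[seq_len(last)] else integer(0)
  structure(
    list(outliers = outliers, n_outliers = length(outliers), steps = steps),
    class = "esd_test"
  )
}

#' @export
print.esd_test <- function(x, ...) {
  cat(sprintf(
    "Generalized ESD test: %d outlier(s) flagged of %d step(s) tested\n",
    x$n_outliers, nrow(x$steps)
  ))
  invisible(x)
}
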