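#' One-tailed Welch two-sample t-test
#'
#' Tests `H0: mean(x) - mean(y) <= 0` against the one-sided alternative
#' `mean(x) > mean(y)` without assuming equal variances:
#' `t = (mean(x) - mean(y)) / sqrt(s1^2/n1 + s2^2/n2)`, with
#' Welch-Satterthwaite degrees of freedom. Intended for differences of
#' log SOC stocks between rotation groups, where group variances differ.
#' The one-sided confidence interval is reported as `(lower, Inf)`.
#'
#' @param x,y Numeric samples (e.g. log total stocks of two groups),
#'   each of length >= 2.
#' @param conf_level Confidence level for the one-sided interval.
#'
#' @return A one-row tibble: `estimate` (mean difference), `statistic`,
#'   `df` (Welch-Satterthwaite), `p.value` (upper tail), `conf.low`,
#'   `conf.high` (`Inf`), `n_x`, `n_y`.
#' @examples
#' welch_one_tailed(rnorm(20, 1), rnorm(30))
#' @export
welch_one_tailed <- function(x, y, conf_level = 0.95) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 2 || n2 < 2) abort("Both samples need at least 2 observations.")
  v1 <- var(x)
  v2 <- var(y)
  if (v1 == 0 && v2 == 0) {
    abort("Both samples have zero variance; the Welch statistic is undefined.")
  }
  se2 <- v1 / n1 + v2 / n2
  estimate <- mean(x) - mean(y)
  statistic <- estimate / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- pt(statistic, df = df, lower.tail = FALSE)
  conf.low <- estimate - qt(conf_level, df = df) * sqrt(se2)
  tibble::tibble(
    estimate = estimate, statistic = statistic, df = df, p.value = p,
    conf.low = conf.low, conf.high = Inf, n_x = n1, n_y = n2
  )
}

#' Pairwise one-tailed Welch tests between rotation groups
#'
#' Runs [welch_one_tailed()] on log total 0-100 cm stocks for each
#' ordered pair of rotation groups (more corn years vs fewer), the
#' table of group contrasts the analysis reports.
#'
#' @param sites Site tibble with `log_soc_total` and `rotation_group`
#'   (join `sequences` first if needed).
#' @param groups Groups to compare, in increasing corn-year order.
#' @return A tibble with one row per ordered pair, columns
#'   `group_hi`, `group_lo` plus the [welch_one_tailed()] columns.
#' @export
welch_group_tests <- function(sites, groups = c("0c", "1c", "2c", "3c")) {
  if (!all(c("log_soc_total", "rotation_group") %in% names(sites))) {
    abort("`sites` must carry `log_soc_total` and `rotation_group`.")
  }
  pairs <- tidyr::expand_grid(hi = groups, lo = groups)
  pairs <- pairs[match(pairs$hi, groups) > match(pairs$lo, groups), ]
  purrr::pmap_dfr(pairs, function(hi, lo) {
    res <- welch_one_tailed(
      sites$log_soc_total[sites$rotation_group == hi],
      sites$log_soc_total[sites$rotation_group == lo]
    )
    dplyr::bind_cols(tibble::tibble(group_hi = hi, group_lo = lo), res)
  })
}
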