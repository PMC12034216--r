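# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: the t-CDF is computed by quadrature over the
# explicit density, OLS by the normal equations, raster lookups by cell
# loops.

# upper-tail probability of Student's t by numerical integration
t_upper_tail_quad <- function(t, df) {
  dens <- function(u) {
    exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df * pi) *
      (1 + u^2 / df)^(-(df + 1) / 2)
  }
  stats::integrate(dens, lower = t, upper = Inf, rel.tol = 1e-12,
                   abs.tol = 1e-14)$value
}

# Welch statistic, df and one-tailed p from the textbook formulas + quadrature
welch_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(statistic = t, df = df, p.value = t_upper_tail_quad(t, df))
}

# OLS coefficients by explicit normal equations
ols_oracle <- function(X, y) {
  drop(solve(crossprod(X), crossprod(X, y)))
}

# per-point raster lookup by scanning every cell's half-open interval
extract_oracle <- function(raster, x, y) {
  ext <- raster_extent(raster)
  cs <- raster$cell_size
  out <- rep(NA_integer_, length(x))
  for (k in seq_along(x)) {
    for (i in seq_len(nrow(raster$values))) {
      top <- ext[["ymax"]] - (i - 1) * cs
      bottom <- top - cs
      y_in <- (y[k] <= top && y[k] > bottom) ||
        (i == 1 && y[k] == ext[["ymax"]])
      if (!y_in) next
      for (j in seq_len(ncol(raster$values))) {
        left <- ext[["xmin"]] + (j - 1) * cs
        if (x[k] >= left && x[k] < left + cs) {
          v <- raster$values[i, j]
          out[k] <- if (v == raster$nodata) NA_integer_ else v
        }
      }
    }
  }
  out
}

# cell-by-cell transition counts
transition_oracle <- function(from, to) {
  counts <- list()
  for (i in seq_len(nrow(from$values))) {
    for (j in seq_len(ncol(from$values))) {
      a <- from$values[i, j]; b <- to$values[i, j]
      if (a == from$nodata || b == to$nodata) next
      key <- paste(a, b)
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
    }
  }
  keys <- do.call(rbind, strsplit(names(counts), " "))
  out <- tibble::tibble(
    code_from = as.integer(keys[, 1]),
    code_to = as.integer(keys[, 2]),
    n = as.integer(unlist(counts))
  )
  dplyr::arrange(out, code_from, code_to)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
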