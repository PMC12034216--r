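#' Aggregate depth-layer stocks to the 0-100 cm total
#'
#' Sums the 0-5, 5-30 and 30-100 cm layer stocks into the total 0-100 cm
#' stock and takes its natural logarithm (the regression outcome).
#' Negative layers are an error, as is a zero total (log undefined).
#'
#' @param sites Tibble with numeric columns `soc_0_5`, `soc_5_30`,
#'   `soc_30_100` (Mg C/ha).
#'
#' @return `sites` with (re)computed `soc_total` and `log_soc_total`.
#' @examples
#' aggregate_depth_layers(tibble::tibble(
#'   soc_0_5 = 10, soc_5_30 = 30, soc_30_100 = 60
#' ))
#' @export
aggregate_depth_layers <- function(sites) {
  layer_cols <- c("soc_0_5", "soc_5_30", "soc_30_100")
  missing_cols <- setdiff(layer_cols, names(sites))
  if (length(missing_cols)) {
    abort(paste0("Missing layer column(s): ", paste(missing_cols, collapse = ", ")))
  }
  layers <- as.matrix(sites[layer_cols])
  if (any(layers < 0, na.rm = TRUE)) {
    abort("Layer stocks must be non-negative.")
  }
  total <- rowSums(layers)
  if (any(total <= 0, na.rm = TRUE)) {
    abort("Total 0-100 cm stock must be positive (log is undefined at 0).")
  }
  sites$soc_total <- total
  sites$log_soc_total <- log(total)
  sites
}

#' Per-group, per-layer SOC summaries
#'
#' Arithmetic means with t-based 95% confidence intervals of the layer
#' stocks and the 0-100 cm total, by rotation group. Groups with fewer
#' than 2 sites are dropped with a warning (no CI is defined).
#'
#' @param sites Site tibble with layer stocks (and `soc_total`; computed
#'   if absent).
#' @param sequences Sequence tibble with `site_id`, `rotation_group`;
#'   omit if `sites` already carries `rotation_group`.
#' @param conf_level Confidence level (default 0.95).
#'
#' @return A tibble `rotation_group`, `layer`, `n`, `mean`, `sd`,
#'   `conf.low`, `conf.high` with layers `0-5`, `5-30`, `30-100`,
#'   `0-100` (cm).
#' @export
group_summaries <- function(sites, sequences = NULL, conf_level = 0.95) {
  if (!is.null(sequences)) {
    sites <- dplyr::left_join(
      dplyr::select(sites, -dplyr::any_of("rotation_group")),
      sequences[, c("site_id", "rotation_group")],
      by = "site_id"
    )
  }
  if (!"rotation_group" %in% names(sites)) {
    abort("`rotation_group` not found; supply `sequences`.")
  }
  if (!"soc_total" %in% names(sites)) sites <- aggregate_depth_layers(sites)

  long <- tidyr::pivot_longer(
    sites[, c("rotation_group", "soc_0_5", "soc_5_30", "soc_30_100", "soc_total")],
    cols = -"rotation_group", names_to = "layer", values_to = "stock"
  )
  long$layer <- c(
    soc_0_5 = "0-5", soc_5_30 = "5-30", soc_30_100 = "30-100",
    soc_total = "0-100"
  )[long$layer]

  out <- dplyr::summarise(
    dplyr::group_by(long, .data$rotation_group, .data$layer),
    n = dplyr::n(),
    mean = mean(.data$stock),
    sd = sd(.data$stock),
    .groups = "drop"
  )
  small <- unique(out$rotation_group[out$n < 2])
  if (length(small)) {
    warn(paste0(
      "Dropping group(s) with < 2 sites: ", paste(small, collapse = ", ")
    ))
    out <- out[!out$rotation_group %in% small, ]
  }
  tcrit <- qt(1 - (1 - conf_level) / 2, df = out$n - 1)
  se <- out$sd / sqrt(out$n)
  out$conf.low <- out$mean - tcrit * se
  out$conf.high <- out$mean + tcrit * se
  out$layer <- factor(out$layer, levels = c("0-5", "5-30", "30-100", "0-100"))
  dplyr::arrange(out, .data$rotation_group, .data$layer)
}
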