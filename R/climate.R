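#' Climate feature windows
#'
#' The climate covariates average monthly weather over two 12-month
#' windows counted back from the measurement month (exclusive; month 1 is
#' the calendar month immediately preceding measurement), split into warm
#' (April-September) and cold (October-March) calendar months. The
#' defaults are recent = months 1-12 and lag = months 7-18; each window
#' then contains exactly 6 warm and 6 cold months. An alternative
#' "historical" variant (e.g. lag = 13-24) can be configured, subject to
#' the same exactly-6-months-per-feature requirement.
#'
#' @param recent,lag Length-2 integer vectors `c(first, last)` of months
#'   before measurement.
#' @return A list with elements `recent` and `lag`.
#' @export
climate_windows <- function(recent = c(1, 12), lag = c(7, 18)) {
  for (w in list(recent, lag)) {
    if (length(w) != 2 || w[1] < 1 || w[2] < w[1]) {
      abort("Windows must be c(first, last) with 1 <= first <= last.")
    }
  }
  list(recent = as.integer(recent), lag = as.integer(lag))
}

warm_months <- function() 4:9

#' Compute windowed warm/cold climate features
#'
#' Builds the 8 weather covariates of the SOC regression from a monthly
#' series per site: mean temperature and precipitation over the warm
#' (April-September) and cold (October-March) months of a recent window
#' and of a lag window counted back from each site's measurement month.
#' Each feature must average exactly 6 months; any other count signals a
#' window misconfiguration and is an error, as is insufficient history.
#'
#' @param weather Monthly tibble with `site_id`, `months_before`,
#'   `month` (calendar), `tmean`, `ppt` (from [generate_weather()] or
#'   read from file).
#' @param windows A [climate_windows()] list.
#'
#' @return A tibble with one row per site: `site_id`,
#'   `warm_recent_temp`, `warm_lag_temp`, `cold_recent_temp`,
#'   `cold_lag_temp`, `warm_recent_precip`, `warm_lag_precip`,
#'   `cold_recent_precip`, `cold_lag_precip`.
#' @export
compute_climate_features <- function(weather, windows = climate_windows()) {
  need <- c("site_id", "months_before", "month", "tmean", "ppt")
  missing_cols <- setdiff(need, names(weather))
  if (length(missing_cols)) {
    abort(paste0("`weather` missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  max_needed <- max(windows$recent[2], windows$lag[2])
  depth <- dplyr::summarise(
    dplyr::group_by(weather, .data$site_id),
    max_back = max(.data$months_before), .groups = "drop"
  )
  shallow <- depth$site_id[depth$max_back < max_needed]
  if (length(shallow)) {
    abort(paste0(
      "Insufficient weather history (need ", max_needed, " months) for site(s): ",
      paste(head(shallow, 5), collapse = ", ")
    ))
  }

  long <- dplyr::bind_rows(
    dplyr::mutate(
      dplyr::filter(
        weather,
        .data$months_before >= windows$recent[1],
        .data$months_before <= windows$recent[2]
      ),
      window = "recent"
    ),
    dplyr::mutate(
      dplyr::filter(
        weather,
        .data$months_before >= windows$lag[1],
        .data$months_before <= windows$lag[2]
      ),
      window = "lag"
    )
  )
  long$season <- ifelse(long$month %in% warm_months(), "warm", "cold")

  agg <- dplyr::summarise(
    dplyr::group_by(long, .data$site_id, .data$season, .data$window),
    n_months = dplyr::n(),
    temp = mean(.data$tmean),
    precip = mean(.data$ppt),
    .groups = "drop"
  )
  bad <- agg[agg$n_months != 6, ]
  if (nrow(bad) > 0) {
    abort(sprintf(
      "Window '%s'/'%s' has %d qualifying months (expected 6); check `windows`.",
      bad$season[1], bad$window[1], bad$n_months[1]
    ))
  }
  wide <- tidyr::pivot_wider(
    agg[, c("site_id", "season", "window", "temp", "precip")],
    names_from = c("season", "window"),
    values_from = c("temp", "precip"),
    names_glue = "{season}_{window}_{.value}"
  )
  cols <- c(
    "warm_recent_temp", "warm_lag_temp", "cold_recent_temp", "cold_lag_temp",
    "warm_recent_precip", "warm_lag_precip", "cold_recent_precip",
    "cold_lag_precip"
  )
  missing_out <- setdiff(cols, names(wide))
  if (length(missing_out)) {
    abort(paste0(
      "Window produced no months for: ", paste(missing_out, collapse = ", ")
    ))
  }
  dplyr::select(wide, "site_id", dplyr::all_of(cols))
}

#' @export
#' @rdname compute_climate_features
climate_feature_names <- function() {
  c(
    "warm_recent_temp", "warm_lag_temp", "cold_recent_temp", "cold_lag_temp",
    "warm_recent_precip", "warm_lag_precip", "cold_recent_precip",
    "cold_lag_precip"
  )
}
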