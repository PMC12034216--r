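#' Sample random points from the valid cells of a raster stack
#'
#' Draws `n` points uniformly from the cells that are non-nodata in every
#' year of the stack (optionally restricted to one region of a layout —
#' the state-mask analogue) and records each point's crop code in every
#' year. Sampling is with replacement by default; the draw is fully
#' reproducible from `seed`.
#'
#' @param rasters_by_year Named list of [crop_raster()]s (names = years).
#' @param n Number of points (`>= 1`); the analysis convention is 40,000
#'   per region.
#' @param seed Integer seed.
#' @param layout Optional [region_layout()]; with `region`, restricts the
#'   valid cells to that region's extent.
#' @param region Optional region name (requires `layout`).
#' @param replace Sample cells with replacement (default `TRUE`).
#'
#' @return A tibble: `point_id`, `region`, `x`, `y`, and one
#'   `code_<year>` column per raster year.
#' @export
sample_points <- function(rasters_by_year, n, seed, layout = NULL,
                          region = NULL, replace = TRUE) {
  n <- as.integer(n)
  if (n < 1) abort("`n` must be >= 1.")
  r1 <- rasters_by_year[[1]]
  for (r in rasters_by_year[-1]) check_same_grid(r1, r)
  valid <- r1$values != r1$nodata
  for (r in rasters_by_year[-1]) valid <- valid & (r$values != r$nodata)

  region_label <- region %||% "all"
  if (!is.null(region)) {
    if (is.null(layout)) abort("`region` requires `layout`.")
    rg <- layout$regions[layout$regions$region == region, ]
    if (nrow(rg) == 0) abort(sprintf("Unknown region '%s'.", region))
    nr <- nrow(r1$values)
    nc <- ncol(r1$values)
    ctr <- cell_center(
      r1,
      row = matrix(seq_len(nr), nr, nc),
      col = matrix(seq_len(nc), nr, nc, byrow = TRUE)
    )
    inside <- ctr$x >= rg$xmin & ctr$x < rg$xmax &
      ctr$y > rg$ymin & ctr$y <= rg$ymax
    valid <- valid & inside
  }
  idx <- which(valid)
  if (length(idx) == 0) abort("No valid cells to sample from.")
  if (!replace && n > length(idx)) {
    abort(sprintf("n = %d exceeds the %d valid cells without replacement.",
                  n, length(idx)))
  }
  set.seed(seed)
  pick <- idx[sample.int(length(idx), n, replace = replace)]
  row <- ((pick - 1) %% nrow(r1$values)) + 1
  col <- ((pick - 1) %/% nrow(r1$values)) + 1
  ctr <- cell_center(r1, row, col)
  out <- tibble::tibble(
    point_id = seq_len(n), region = region_label, x = ctr$x, y = ctr$y
  )
  for (yr in names(rasters_by_year)) {
    out[[paste0("code_", yr)]] <-
      rasters_by_year[[yr]]$values[cbind(row, col)]
  }
  out
}

#' @rdname sample_points
#' @description `sample_points_by_region()` repeats the draw for every
#'   layout region (seeds offset by the region index) and binds the
#'   results.
#' @export
sample_points_by_region <- function(rasters_by_year, layout, n, seed,
                                    replace = TRUE) {
  purrr::imap_dfr(
    setNames(layout$regions$region, layout$regions$region),
    function(rg, nm) {
      i <- match(rg, layout$regions$region)
      sample_points(rasters_by_year, n, seed + i, layout = layout,
                    region = rg, replace = replace)
    }
  )
}

sample_year_cols <- function(samples) {
  yrs <- sort(as.integer(sub("^code_", "", grep("^code_", names(samples),
                                                value = TRUE))))
  if (length(yrs) == 0) abort("`samples` has no `code_<year>` columns.")
  yrs
}

#' Rotation-pattern proportions from sampled points
#'
#' Classifies each sampled point's crop sequence over a 3-year window
#' into `0c`/`1c`/`2c`/`3c`/`other` and estimates per-region pattern
#' proportions with binomial standard errors. Two denominators are
#' reported: all sampled valid points (`proportion`) and corn-soy points
#' only (`proportion_corn_soy`, `NA` for the `other` row).
#'
#' @param samples Output of [sample_points()] / [sample_points_by_region()].
#' @param window Integer vector of 3 consecutive years (default: the last
#'   3 years present in `samples`).
#' @param code_map Crop code dialect, see [cdl_code_map()].
#'
#' @return A tibble `region`, `pattern`, `n_points`, `proportion`, `se`,
#'   `proportion_corn_soy`.
#' @export
rotation_proportions <- function(samples, window = NULL,
                                 code_map = cdl_code_map()) {
  yrs <- sample_year_cols(samples)
  if (is.null(window)) window <- utils::tail(yrs, 3)
  window <- sort(as.integer(window))
  if (length(window) != 3 || any(diff(window) != 1)) {
    abort("`window` must be 3 consecutive years.")
  }
  missing_yrs <- setdiff(window, yrs)
  if (length(missing_yrs)) {
    abort(paste0("Sample lacks year(s): ", paste(missing_yrs, collapse = ", ")))
  }
  grp <- classify_rotation(
    samples[[paste0("code_", window[3])]],
    samples[[paste0("code_", window[2])]],
    samples[[paste0("code_", window[1])]],
    code_map
  )
  grp[grp == "excluded"] <- "other"
  patterns <- c("0c", "1c", "2c", "3c", "other")
  counts <- dplyr::count(
    tibble::tibble(region = samples$region,
                   pattern = factor(grp, levels = patterns)),
    .data$region, .data$pattern, .drop = FALSE, name = "n_points"
  )
  out <- dplyr::mutate(
    dplyr::group_by(counts, .data$region),
    n_total = sum(.data$n_points),
    proportion = .data$n_points / .data$n_total,
    se = sqrt(.data$proportion * (1 - .data$proportion) / .data$n_total),
    n_corn_soy = sum(.data$n_points[.data$pattern != "other"]),
    proportion_corn_soy = dplyr::if_else(
      .data$pattern == "other", NA_real_,
      .data$n_points / .data$n_corn_soy
    )
  )
  out <- dplyr::ungroup(out)
  out$pattern <- as.character(out$pattern)
  dplyr::select(
    out, "region", "pattern", "n_points", "proportion", "se",
    "proportion_corn_soy"
  )
}

#' Mean corn and soybean planting frequency from sampled points
#'
#' Counts, for every sampled point, the number of window years planted to
#' corn and to soybeans, and averages the counts per region.
#'
#' @param samples Output of [sample_points()] / [sample_points_by_region()].
#' @param window Years to count over (default: all years in `samples`;
#'   at least 2).
#' @param code_map Crop code dialect, see [cdl_code_map()].
#'
#' @return A tibble `region`, `crop` (`corn`/`soybeans`), `mean_years`.
#' @export
planting_frequency <- function(samples, window = NULL,
                               code_map = cdl_code_map()) {
  yrs <- sample_year_cols(samples)
  if (is.null(window)) window <- yrs
  window <- sort(as.integer(window))
  if (length(window) < 2) abort("`window` must span at least 2 years.")
  missing_yrs <- setdiff(window, yrs)
  if (length(missing_yrs)) {
    abort(paste0("Sample lacks year(s): ", paste(missing_yrs, collapse = ", ")))
  }
  codes <- as.matrix(samples[paste0("code_", window)])
  corn_years <- rowSums(codes == code_map$corn)
  soy_years <- rowSums(codes == code_map$soybeans)
  df <- tibble::tibble(
    region = rep(samples$region, 2),
    crop = rep(c("corn", "soybeans"), each = nrow(samples)),
    years = c(corn_years, soy_years)
  )
  dplyr::summarise(
    dplyr::group_by(df, .data$region, .data$crop),
    mean_years = mean(.data$years), .groups = "drop"
  )
}

#' Convert pattern proportions to implied areas
#'
#' Multiplies estimated rotation-pattern proportions by each region's
#' total (cropland) area in hectares.
#'
#' @param proportions Output of [rotation_proportions()].
#' @param region_areas Tibble with `region`, `total_area_ha` (`> 0`).
#'
#' @return `proportions` with an added `implied_area` column (ha).
#' @export
estimate_group_area <- function(proportions, region_areas) {
  if (!all(c("region", "total_area_ha") %in% names(region_areas))) {
    abort("`region_areas` needs columns `region` and `total_area_ha`.")
  }
  if (any(region_areas$total_area_ha < 0)) {
    abort("`total_area_ha` must be non-negative.")
  }
  missing_rg <- setdiff(unique(proportions$region), region_areas$region)
  if (length(missing_rg)) {
    abort(paste0("No total area for region(s): ",
                 paste(missing_rg, collapse = ", ")))
  }
  out <- dplyr::left_join(proportions, region_areas, by = "region")
  out$implied_area <- out$proportion * out$total_area_ha
  out
}
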