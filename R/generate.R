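#' Ground-truth parameters for the SOC generator
#'
#' Collects the simulation truth for [generate_soc()]: the log-scale
#' linear predictor of total 0-100 cm SOC stock and the decomposition of
#' the total into depth layers. On the log scale the model is
#' `log(SOC) = intercept + rotation effect + latitude + weather + texture +
#' region + month + N(0, sigma^2)`, matching the regression the analysis
#' fits, so parameter recovery can be checked against known truth.
#'
#' @param intercept_log Intercept, log(Mg C/ha), for the reference stratum
#'   (soybean mono-cropping, `0c`). The default is calibrated with
#'   [calibrate_intercept()] so the `0c` *arithmetic* mean is 109.73
#'   Mg C/ha under the default `sigma` (log-normal mean is
#'   `exp(mu + sigma^2/2)`).
#' @param group_log_effects Named additive log effects for groups `1c`,
#'   `2c`, `3c` relative to `0c`. Defaults `log(1.300)`, `log(1.424)`,
#'   `log(1.713)`, i.e. +30.0%, +42.4%, +71.3%.
#' @param per_year_log_effect Additive log effect per corn year, used when
#'   `effect_model = "per_year"`. Default `log(1.2508)` (+25.08%/year).
#' @param effect_model `"group"` (categorical rotation effects) or
#'   `"per_year"` (linear in the number of corn years).
#' @param latitude_coef Log effect per degree latitude.
#' @param weather_coefs Named vector of log effects for the 8 climate
#'   features (names as produced by [compute_climate_features()]); `NULL`
#'   means all zero.
#' @param texture_effects,region_effects,month_effects Named log-effect
#'   maps; levels not named get effect 0. `NULL` means all zero.
#' @param excluded_log_effect Log effect applied to sites whose 3-year
#'   sequence contains a non-corn/soy crop (rotation group `excluded`).
#' @param sigma Residual s.d. on the log scale (`>= 0`; 0 gives a
#'   noiseless, exactly identified simulation).
#' @param layer_fractions Expected shares of the 0-100 cm stock in the
#'   0-5, 5-30 and 30-100 cm layers; must be positive, sum to 1 and be
#'   strictly increasing with depth (deep > middle > shallow).
#' @param layer_dispersion Dirichlet concentration for per-site share
#'   noise; `Inf` makes every site's shares exactly `layer_fractions`.
#'
#' @return An object of class `generative_params`.
#' @examples
#' generative_params(sigma = 0.3)
#' @export
generative_params <- function(intercept_log = calibrate_intercept(109.73, sigma),
                              group_log_effects = c(
                                "1c" = log(1.300), "2c" = log(1.424),
                                "3c" = log(1.713)
                              ),
                              per_year_log_effect = log(1.2508),
                              effect_model = c("group", "per_year"),
                              latitude_coef = 0,
                              weather_coefs = NULL,
                              texture_effects = NULL,
                              region_effects = NULL,
                              month_effects = NULL,
                              excluded_log_effect = 0,
                              sigma = 0.5,
                              layer_fractions = c(0.08, 0.28, 0.64),
                              layer_dispersion = 50) {
  effect_model <- match.arg(effect_model)
  if (sigma < 0) abort("`sigma` must be >= 0.")
  if (length(layer_fractions) != 3 || any(layer_fractions <= 0)) {
    abort("`layer_fractions` must be 3 positive shares.")
  }
  if (abs(sum(layer_fractions) - 1) > 1e-9) {
    abort("`layer_fractions` must sum to 1.")
  }
  if (!(layer_fractions[3] > layer_fractions[2] &&
        layer_fractions[2] > layer_fractions[1])) {
    abort("`layer_fractions` must increase with depth (deep > middle > shallow).")
  }
  if (!is.infinite(layer_dispersion) && layer_dispersion <= 0) {
    abort("`layer_dispersion` must be > 0 (or Inf).")
  }
  if (!all(c("1c", "2c", "3c") %in% names(group_log_effects))) {
    abort("`group_log_effects` must name groups 1c, 2c and 3c.")
  }
  structure(
    list(
      intercept_log = intercept_log,
      group_log_effects = group_log_effects[c("1c", "2c", "3c")],
      per_year_log_effect = per_year_log_effect,
      effect_model = effect_model,
      latitude_coef = latitude_coef,
      weather_coefs = weather_coefs,
      texture_effects = texture_effects,
      region_effects = region_effects,
      month_effects = month_effects,
      excluded_log_effect = excluded_log_effect,
      sigma = sigma,
      layer_fractions = layer_fractions,
      layer_dispersion = layer_dispersion
    ),
    class = "generative_params"
  )
}

#' Calibrate the log-scale intercept to an arithmetic group mean
#'
#' Under log-normal noise the arithmetic mean of `exp(mu + N(0, sigma^2))`
#' is `exp(mu + sigma^2/2)`, so matching a target arithmetic mean requires
#' `mu = log(target) - sigma^2/2`.
#'
#' @param target_mean Target arithmetic mean stock (Mg C/ha), `> 0`.
#' @param sigma Residual s.d. on the log scale.
#' @return The calibrated log-scale intercept.
#' @examples
#' exp(calibrate_intercept(109.73, 0.5) + 0.5^2 / 2) # 109.73
#' @export
calibrate_intercept <- function(target_mean, sigma = 0.5) {
  if (target_mean <= 0) abort("`target_mean` must be > 0.")
  log(target_mean) - sigma^2 / 2
}

# per-patch 3-year crop-code templates for a vector of patterns
pattern_templates <- function(patterns, code_map) {
  n <- length(patterns)
  tmpl <- matrix(code_map$soybeans, nrow = n, ncol = 3)
  for (i in seq_len(n)) {
    p <- patterns[i]
    if (p == "other") {
      tmpl[i, ] <- sample(code_map$other, 1)
    } else {
      k <- corn_years_of_group(p)
      if (k > 0) {
        corn_pos <- sample.int(3, k)
        tmpl[i, corn_pos] <- code_map$corn
      }
    }
  }
  tmpl
}

#' Generate multi-year synthetic crop rasters
#'
#' Builds one categorical raster per year on the layout's grid. Each
#' region is tiled into square field patches (`layout$field_block` cells
#' on a side); every patch is assigned a 3-year rotation pattern drawn
#' from the region's [rotation_mix()] and carries a coherent crop sequence
#' across years (the 3-year template repeats cyclically for longer
#' spans). A fraction of patches is masked out as non-cropland (nodata).
#'
#' @param layout A [region_layout()].
#' @param years Integer vector of at least 3 consecutive years.
#' @param mix A [rotation_mix()] covering every layout region.
#' @param seed Integer seed; fixes patterns, mask and arrangements.
#' @param code_map Crop code dialect, see [cdl_code_map()].
#'
#' @return A list with elements
#'   * `rasters`: named list of [crop_raster()]s, one per year;
#'   * `truth`: tibble of configured and realized pattern proportions per
#'     region (`region`, `pattern`, `proportion`, `n_patches`,
#'     `proportion_realized`), realized values over non-nodata patches.
#' @export
generate_crop_rasters <- function(layout, years, mix, seed,
                                  code_map = cdl_code_map()) {
  stopifnot(inherits(layout, "region_layout"))
  years <- sort(as.integer(years))
  if (length(years) < 3 || any(diff(years) != 1)) {
    abort("`years` must be at least 3 consecutive years.")
  }
  mix <- tibble::as_tibble(mix)
  missing_regions <- setdiff(layout$regions$region, unique(mix$region))
  if (length(missing_regions)) {
    abort(paste0("`mix` missing region(s): ", paste(missing_regions, collapse = ", ")))
  }
  set.seed(seed)

  cs <- layout$cell_size
  xmin_all <- min(layout$regions$xmin)
  xmax_all <- max(layout$regions$xmax)
  ymin_all <- min(layout$regions$ymin)
  ymax_all <- max(layout$regions$ymax)
  ncol_all <- round((xmax_all - xmin_all) / cs)
  nrow_all <- round((ymax_all - ymin_all) / cs)

  # per-year value matrices, filled with nodata outside regions / masked patches
  nodata <- 0L
  vals <- replicate(length(years),
    matrix(nodata, nrow = nrow_all, ncol = ncol_all),
    simplify = FALSE
  )
  cycle_pos <- ((seq_along(years) - 1) %% 3) + 1

  truth_rows <- list()
  patterns_all <- c("0c", "1c", "2c", "3c", "other")
  for (i in seq_len(nrow(layout$regions))) {
    rg <- layout$regions[i, ]
    p <- mix$proportion[match(
      paste(rg$region, patterns_all),
      paste(mix$region, mix$pattern)
    )]
    p[is.na(p)] <- 0
    # cell window of this region in the full grid (rows count from the top)
    c0 <- round((rg$xmin - xmin_all) / cs) + 1
    c1 <- round((rg$xmax - xmin_all) / cs)
    r0 <- round((ymax_all - rg$ymax) / cs) + 1
    r1 <- round((ymax_all - rg$ymin) / cs)
    nr <- r1 - r0 + 1
    nc <- c1 - c0 + 1
    fb <- layout$field_block
    npr <- ceiling(nr / fb)
    npc <- ceiling(nc / fb)
    n_patch <- npr * npc

    patch_pattern <- sample(patterns_all, n_patch, replace = TRUE, prob = p)
    patch_na <- runif(n_patch) < layout$na_mask_fraction
    tmpl <- pattern_templates(patch_pattern, code_map)

    # map every region cell to its patch
    cell_r <- rep(seq_len(nr), times = nc)
    cell_c <- rep(seq_len(nc), each = nr)
    patch_idx <- (ceiling(cell_c / fb) - 1) * npr + ceiling(cell_r / fb)
    keep <- !patch_na[patch_idx]
    for (t in seq_along(years)) {
      codes <- ifelse(keep, tmpl[cbind(patch_idx, cycle_pos[t])], nodata)
      vals[[t]][cbind(r0 + cell_r - 1, c0 + cell_c - 1)] <- codes
    }

    counts <- table(factor(patch_pattern[!patch_na], levels = patterns_all))
    truth_rows[[i]] <- tibble::tibble(
      region = rg$region,
      pattern = patterns_all,
      proportion = p,
      n_patches = as.integer(counts),
      proportion_realized = as.integer(counts) / max(sum(counts), 1L)
    )
  }

  rasters <- purrr::map(vals, function(v) {
    crop_raster(v, xmin = xmin_all, ymax = ymax_all, cell_size = cs,
                nodata = nodata, crs = layout$crs)
  })
  names(rasters) <- as.character(years)
  list(rasters = rasters, truth = dplyr::bind_rows(truth_rows))
}

#' Generate synthetic SOC measurement sites
#'
#' Places sites on non-nodata raster cells (cell centers), assigns each a
#' measurement year and month, a latitude covariate mapped linearly from
#' the planar y coordinate, a soil texture class, and a region label.
#' SOC stocks are added later by [generate_soc()].
#'
#' @param n Number of sites (default 2105, the cropland site count of the
#'   national soil-carbon survey the table emulates).
#' @param layout The [region_layout()] the rasters were generated on.
#' @param rasters Named list of [crop_raster()]s (output of
#'   [generate_crop_rasters()]); sites are placed on cells valid in all.
#' @param seed Integer seed.
#' @param measurement_years Years to sample measurement dates from; must
#'   be covered by the rasters with two preceding years.
#' @param measurement_months Calendar months to sample from.
#' @param lat_range Degrees latitude mapped to the layout's y range.
#' @param replace Sample cells with replacement? With `replace = FALSE`
#'   (default) an error is raised when `n` exceeds the valid cell count.
#'
#' @return A tibble with columns `site_id`, `x`, `y`, `latitude`,
#'   `region`, `texture_class`, `measurement_year`, `measurement_month`.
#' @export
generate_sites <- function(n = 2105, layout, rasters, seed,
                           measurement_years = NULL,
                           measurement_months = 4:10,
                           lat_range = c(38, 46),
                           replace = FALSE) {
  stopifnot(inherits(layout, "region_layout"))
  n <- as.integer(n)
  if (n < 1) abort("`n` must be >= 1.")
  raster_years <- sort(as.integer(names(rasters)))
  if (is.null(measurement_years)) {
    measurement_years <- raster_years[raster_years >= raster_years[1] + 2]
  }
  if (any(!(measurement_years %in% raster_years) |
          !((measurement_years - 1) %in% raster_years) |
          !((measurement_years - 2) %in% raster_years))) {
    abort("Every measurement year needs rasters for itself and the two prior years.")
  }
  set.seed(seed)
  r1 <- rasters[[1]]
  valid <- r1$values != r1$nodata
  for (r in rasters[-1]) valid <- valid & (r$values != r$nodata)
  idx <- which(valid)
  if (length(idx) == 0) abort("No valid (non-nodata) cells to place sites on.")
  if (!replace && n > length(idx)) {
    abort(sprintf(
      "n = %d exceeds the %d valid cells (set replace = TRUE to allow reuse).",
      n, length(idx)
    ))
  }
  pick <- idx[sample.int(length(idx), n, replace = replace)]
  row <- ((pick - 1) %% nrow(r1$values)) + 1
  col <- ((pick - 1) %/% nrow(r1$values)) + 1
  ctr <- cell_center(r1, row, col)

  ymin_all <- min(layout$regions$ymin)
  ymax_all <- max(layout$regions$ymax)
  latitude <- lat_range[1] +
    (ctr$y - ymin_all) / (ymax_all - ymin_all) * diff(lat_range)

  region <- rep(NA_character_, n)
  for (i in seq_len(nrow(layout$regions))) {
    rg <- layout$regions[i, ]
    inside <- ctr$x >= rg$xmin & ctr$x < rg$xmax &
      ctr$y > rg$ymin & ctr$y <= rg$ymax
    region[inside] <- rg$region
  }

  tibble::tibble(
    site_id = sprintf("S%05d", seq_len(n)),
    x = ctr$x,
    y = ctr$y,
    latitude = latitude,
    region = region,
    texture_class = sample(soil_texture_classes(), n, replace = TRUE),
    measurement_year = sample(rep(measurement_years, 2), n, replace = TRUE),
    measurement_month = sample(rep(measurement_months, 2), n, replace = TRUE)
  )
}

#' Closed-form warm/cold seasonal temperature gap
#'
#' For the noiseless seasonal sinusoid `amplitude * cos(2*pi*(month - 7)/12)`
#' the April-September mean exceeds the October-March mean by
#' `amplitude * (2 + sqrt(3)) / 3` (the warm-month cosines sum to
#' `2 + sqrt(3)` and the cold-month ones to its negative).
#'
#' @param amplitude Seasonal amplitude (deg C).
#' @return The warm-minus-cold gap of 6-month means.
#' @export
seasonal_warm_cold_gap <- function(amplitude) {
  amplitude * (2 + sqrt(3)) / 3
}

#' Generate monthly site weather
#'
#' Simulates monthly mean temperature and precipitation for each site for
#' `months_back` calendar months preceding (and excluding) the measurement
#' month. Temperature is a July-peaked seasonal sinusoid plus a latitude
#' gradient and Gaussian noise; precipitation is a summer-peaked sinusoid
#' plus noise, floored at zero. At least 36 months are required so the
#' 7-18-month lag windows of the climate features can be built.
#'
#' @param sites Site tibble from [generate_sites()].
#' @param months_back Number of monthly rows per site (`>= 36`).
#' @param seed Integer seed.
#' @param base_temp Annual mean temperature (deg C) at `ref_latitude`.
#' @param lat_gradient Temperature change per degree latitude (deg C).
#' @param ref_latitude Latitude at which `base_temp` applies.
#' @param seasonal_amplitude Temperature seasonal amplitude (deg C).
#' @param temp_noise_sd Temperature noise s.d. (deg C); 0 gives the exact
#'   sinusoid.
#' @param base_precip Mean monthly precipitation (mm).
#' @param precip_amplitude Precipitation seasonal amplitude (mm).
#' @param precip_noise_sd Precipitation noise s.d. (mm).
#'
#' @return A tibble with columns `site_id`, `months_before` (1 = month
#'   immediately preceding measurement), `year`, `month`, `tmean`, `ppt`.
#' @export
generate_weather <- function(sites, months_back = 36, seed,
                             base_temp = 10, lat_gradient = -0.6,
                             ref_latitude = 42,
                             seasonal_amplitude = 12, temp_noise_sd = 2,
                             base_precip = 80, precip_amplitude = 30,
                             precip_noise_sd = 15) {
  if (months_back < 36) {
    abort("`months_back` must be >= 36 to cover the 7-18-month lag windows.")
  }
  set.seed(seed)
  k <- seq_len(months_back)
  grid <- tidyr::expand_grid(
    sites[, c("site_id", "latitude", "measurement_year", "measurement_month")],
    months_before = k
  )
  month_index <- grid$measurement_year * 12 + (grid$measurement_month - 1) -
    grid$months_before
  grid$year <- month_index %/% 12
  grid$month <- month_index %% 12 + 1
  seasonal <- cos(2 * pi * (grid$month - 7) / 12)
  grid$tmean <- base_temp + lat_gradient * (grid$latitude - ref_latitude) +
    seasonal_amplitude * seasonal +
    rnorm(nrow(grid), sd = temp_noise_sd)
  grid$ppt <- pmax(
    0,
    base_precip + precip_amplitude * seasonal +
      rnorm(nrow(grid), sd = precip_noise_sd)
  )
  tibble::as_tibble(
    grid[, c("site_id", "months_before", "year", "month", "tmean", "ppt")]
  )
}

#' Generate per-layer SOC stocks under known truth
#'
#' Completes a site table with SOC stocks: the log of the total 0-100 cm
#' stock is the linear predictor implied by `truth` plus `N(0, sigma^2)`
#' noise, and the total is split into the 0-5, 5-30 and 30-100 cm layers
#' by per-site Dirichlet-perturbed shares around `truth$layer_fractions`.
#'
#' @param sites Site tibble ([generate_sites()]).
#' @param sequences Crop-sequence tibble ([build_sequences()]) with
#'   `site_id` and `rotation_group`.
#' @param features Climate-feature tibble ([compute_climate_features()]),
#'   or `NULL` when `truth$weather_coefs` is `NULL`.
#' @param truth A [generative_params()] object.
#' @param seed Integer seed.
#'
#' @return `sites` with added columns `rotation_group`, `corn_years`,
#'   `soc_0_5`, `soc_5_30`, `soc_30_100`, `soc_total` (Mg C/ha) and
#'   `log_soc_total`.
#' @export
generate_soc <- function(sites, sequences, features = NULL,
                         truth = generative_params(), seed) {
  stopifnot(inherits(truth, "generative_params"))
  miss_seq <- setdiff(sites$site_id, sequences$site_id)
  if (length(miss_seq)) {
    abort(paste0(
      "No crop sequence for site(s): ",
      paste(head(miss_seq, 5), collapse = ", "),
      if (length(miss_seq) > 5) sprintf(" (and %d more)", length(miss_seq) - 5)
    ))
  }
  df <- dplyr::left_join(
    sites, sequences[, c("site_id", "rotation_group")],
    by = "site_id"
  )
  df$corn_years <- corn_years_of_group(df$rotation_group)

  lookup <- function(map, keys) {
    if (is.null(map)) return(rep(0, length(keys)))
    out <- unname(map[as.character(keys)])
    out[is.na(out)] <- 0
    out
  }

  eta <- rep(truth$intercept_log, nrow(df))
  if (truth$effect_model == "group") {
    eta <- eta + lookup(truth$group_log_effects, df$rotation_group)
  } else {
    cy <- df$corn_years
    cy[is.na(cy)] <- 0
    eta <- eta + truth$per_year_log_effect * cy
  }
  eta <- eta + ifelse(df$rotation_group == "excluded", truth$excluded_log_effect, 0)
  eta <- eta + truth$latitude_coef * df$latitude

  if (!is.null(truth$weather_coefs)) {
    if (is.null(features)) abort("`features` required when weather_coefs are set.")
    miss_feat <- setdiff(df$site_id, features$site_id)
    if (length(miss_feat)) {
      abort(paste0(
        "No climate features for site(s): ",
        paste(head(miss_feat, 5), collapse = ", ")
      ))
    }
    fcols <- names(truth$weather_coefs)
    bad <- setdiff(fcols, names(features))
    if (length(bad)) {
      abort(paste0("Unknown weather feature(s): ", paste(bad, collapse = ", ")))
    }
    fm <- dplyr::left_join(df["site_id"], features, by = "site_id")
    eta <- eta + as.numeric(as.matrix(fm[fcols]) %*% truth$weather_coefs)
  }
  eta <- eta + lookup(truth$texture_effects, df$texture_class)
  eta <- eta + lookup(truth$region_effects, df$region)
  eta <- eta + lookup(truth$month_effects, df$measurement_month)

  eta <- unname(eta)
  set.seed(seed)
  log_total <- eta + if (truth$sigma > 0) rnorm(nrow(df), sd = truth$sigma) else 0
  total <- exp(log_total)

  if (is.infinite(truth$layer_dispersion)) {
    shares <- matrix(truth$layer_fractions, nrow = nrow(df), ncol = 3, byrow = TRUE)
  } else {
    alpha <- truth$layer_dispersion * truth$layer_fractions
    g <- cbind(
      rgamma(nrow(df), shape = alpha[1]),
      rgamma(nrow(df), shape = alpha[2]),
      rgamma(nrow(df), shape = alpha[3])
    )
    shares <- g / rowSums(g)
  }

  df$soc_0_5 <- total * shares[, 1]
  df$soc_5_30 <- total * shares[, 2]
  df$soc_30_100 <- total * shares[, 3]
  df$soc_total <- total
  df$log_soc_total <- log_total
  tibble::as_tibble(df)
}
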