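# Small fixture builders shared by the unit tests.

make_raster <- function(values, cell_size = 30, nodata = 0L, crs = "local") {
  crop_raster(values, xmin = 0, ymax = nrow(values) * cell_size,
              cell_size = cell_size, nodata = nodata, crs = crs)
}

one_region_layout <- function(ncells = 10, cell_size = 30, field_block = 2,
                              na_mask_fraction = 0, region = "OH") {
  region_layout(
    tibble::tibble(
      region = region, xmin = 0, xmax = ncells * cell_size,
      ymin = 0, ymax = ncells * cell_size
    ),
    cell_size = cell_size, na_mask_fraction = na_mask_fraction,
    field_block = field_block
  )
}

uniform_mix <- function(region = "OH") {
  args <- list(c("0c" = 0.25, "1c" = 0.25, "2c" = 0.25, "3c" = 0.25))
  names(args) <- region
  do.call(rotation_mix, args)
}

# minimal site table (no stocks) for direct generate_soc() calls
make_sites <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    site_id = sprintf("S%05d", seq_len(n)),
    x = runif(n, 0, 300), y = runif(n, 0, 300),
    latitude = runif(n, 38, 46),
    region = sample(c("R1", "R2"), n, replace = TRUE),
    texture_class = sample(soil_texture_classes(), n, replace = TRUE),
    measurement_year = 2011L,
    measurement_month = sample(4:10, n, replace = TRUE)
  )
}

# sequence table realizing given rotation groups (codes chosen canonically)
make_sequences <- function(site_id, groups) {
  cm <- cdl_code_map()
  codes <- t(vapply(unname(groups), function(g) {
    switch(g,
      "0c" = rep(cm$soybeans, 3),
      "1c" = c(cm$corn, cm$soybeans, cm$soybeans),
      "2c" = c(cm$corn, cm$corn, cm$soybeans),
      "3c" = rep(cm$corn, 3),
      excluded = c(cm$corn, cm$other[1], cm$soybeans)
    )
  }, integer(3)))
  codes <- unname(codes)
  tibble::tibble(
    site_id = site_id,
    crop_y0 = codes[, 1], crop_y1 = codes[, 2], crop_y2 = codes[, 3],
    rotation_group = classify_rotation(codes[, 1], codes[, 2], codes[, 3]),
    corn_years = corn_years_of_group(groups)
  )
}

# monthly weather table built by hand: value_fun(month) gives tmean/ppt
make_weather <- function(site_id, meas_year, meas_month, months_back,
                         temp_fun = function(m) 10, ppt_fun = function(m) 50) {
  k <- seq_len(months_back)
  idx <- meas_year * 12 + (meas_month - 1) - k
  tibble::tibble(
    site_id = site_id,
    months_before = k,
    year = idx %/% 12,
    month = idx %% 12 + 1,
    tmean = vapply(idx %% 12 + 1, temp_fun, numeric(1)),
    ppt = vapply(idx %% 12 + 1, ppt_fun, numeric(1))
  )
}
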