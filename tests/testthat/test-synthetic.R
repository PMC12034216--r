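test_that("a degenerate all-0c mix yields soybeans everywhere, every year", {
  layout <- one_region_layout(ncells = 8, na_mask_fraction = 0.2)
  mix <- rotation_mix(OH = c("0c" = 1))
  gen <- generate_crop_rasters(layout, 2019:2021, mix, seed = 1)
  for (r in gen$rasters) {
    vals <- r$values[r$values != r$nodata]
    expect_true(all(vals == cdl_code_map()$soybeans))
  }
  expect_equal(gen$truth$proportion[gen$truth$pattern == "0c"], 1)
})

test_that("realized patch proportions are within 3 binomial s.e. of the mix", {
  layout <- one_region_layout(ncells = 80, field_block = 4,
                              na_mask_fraction = 0.1)
  gen <- generate_crop_rasters(layout, 2019:2021, uniform_mix(), seed = 11)
  tr <- gen$truth[gen$truth$pattern != "other", ]
  n_patch <- sum(gen$truth$n_patches)
  se <- sqrt(0.25 * 0.75 / n_patch)
  expect_true(all(abs(tr$proportion_realized - 0.25) <= 3 * se))
  # truth table records the configured proportions verbatim
  expect_equal(tr$proportion, rep(0.25, 4))
})

test_that("an Ohio-like configured 0c share is recorded in the truth table", {
  layout <- one_region_layout(ncells = 40)
  mix <- rotation_mix(OH = c(
    "0c" = 0.1056, "1c" = 0.28, "2c" = 0.33, "3c" = 0.0218, other = 0.2626
  ))
  gen <- generate_crop_rasters(layout, 2019:2021, mix, seed = 5)
  expect_equal(
    gen$truth$proportion[gen$truth$pattern == "0c"], 0.1056
  )
})

test_that("raster generation is deterministic in the seed and validates input", {
  layout <- one_region_layout(ncells = 12, na_mask_fraction = 0.15)
  mix <- uniform_mix()
  a <- generate_crop_rasters(layout, 2019:2021, mix, seed = 99)
  b <- generate_crop_rasters(layout, 2019:2021, mix, seed = 99)
  expect_identical(a, b)
  c <- generate_crop_rasters(layout, 2019:2021, mix, seed = 100)
  expect_false(identical(a$rasters, c$rasters))

  expect_error(generate_crop_rasters(layout, 2019:2020, mix, seed = 1),
               "3 consecutive")
  expect_error(rotation_mix(OH = c("0c" = 0.5, "1c" = 0.4)), "sum to 1")
  expect_error(region_layout(tibble::tibble(
    region = "X", xmin = 0, xmax = 0, ymin = 0, ymax = 30
  )), "positive width")
})

test_that("field patches carry coherent sequences realizing their pattern", {
  layout <- one_region_layout(ncells = 24, field_block = 3,
                              na_mask_fraction = 0)
  gen <- generate_crop_rasters(layout, 2019:2024, uniform_mix(), seed = 2)
  cm <- cdl_code_map()
  # classify each cell from the first 3 years and count patterns
  g <- classify_rotation(
    as.vector(gen$rasters[["2021"]]$values),
    as.vector(gen$rasters[["2020"]]$values),
    as.vector(gen$rasters[["2019"]]$values)
  )
  counts <- table(g) / length(g)
  tr <- gen$truth
  for (p in c("0c", "1c", "2c", "3c")) {
    cell_prop <- unname(counts[p])
    # cell-level proportions equal patch-level realized proportions exactly
    # (full blocks, no mask)
    expect_equal(cell_prop,
                 tr$proportion_realized[tr$pattern == p],
                 tolerance = 1e-12)
  }
  # the 3-year template repeats: years 2019 and 2022 are identical layers
  expect_identical(gen$rasters[["2019"]]$values, gen$rasters[["2022"]]$values)
})

test_that("site generation respects the raster mask and reproduces by seed", {
  layout <- one_region_layout(ncells = 20, na_mask_fraction = 0.3)
  gen <- generate_crop_rasters(layout, 2009:2011, uniform_mix(), seed = 4)
  sites <- generate_sites(50, layout, gen$rasters, seed = 8)
  expect_equal(nrow(sites), 50)
  codes <- extract_crop_at_points(gen$rasters[[1]], sites)
  expect_false(anyNA(codes)) # all sites on valid cells
  expect_true(all(sites$region == "OH"))
  expect_identical(sites, generate_sites(50, layout, gen$rasters, seed = 8))

  n_valid <- sum(gen$rasters[[1]]$values != gen$rasters[[1]]$nodata)
  expect_error(
    generate_sites(n_valid + 1, layout, gen$rasters, seed = 1),
    "exceeds"
  )
  one <- generate_sites(1, layout, gen$rasters, seed = 3)
  ext <- raster_extent(gen$rasters[[1]])
  expect_true(one$x > ext[["xmin"]] && one$x < ext[["xmax"]])
  expect_true(one$y > ext[["ymin"]] && one$y < ext[["ymax"]])
})

test_that("weather is seasonal, deterministic, and sized as requested", {
  sites <- make_sites(5)
  w <- generate_weather(sites, months_back = 36, seed = 10)
  expect_equal(nrow(w), 5 * 36)
  expect_equal(as.integer(table(w$site_id)), rep(36L, 5))
  expect_identical(w, generate_weather(sites, months_back = 36, seed = 10))
  expect_error(generate_weather(sites, months_back = 24, seed = 1), ">= 36")

  # noiseless series: warm-minus-cold gap equals the closed form, per year
  w0 <- generate_weather(sites[1, ], months_back = 36, seed = 1,
                         temp_noise_sd = 0, lat_gradient = 0)
  gap <- seasonal_warm_cold_gap(12)
  for (yr in unique(w0$year)) {
    sel <- w0[w0$year == yr, ]
    if (length(unique(sel$month)) < 12) next
    warm <- mean(sel$tmean[sel$month %in% 4:9])
    cold <- mean(sel$tmean[!sel$month %in% 4:9])
    expect_equal(warm - cold, gap, tolerance = 1e-12)
  }

  # noisy defaults still put warm above cold within every complete year
  wn <- generate_weather(sites, months_back = 48, seed = 2)
  by_year <- dplyr::summarise(
    dplyr::group_by(wn, site_id, year),
    n = dplyr::n(),
    gap = mean(tmean[month %in% 4:9]) - mean(tmean[!month %in% 4:9]),
    .groups = "drop"
  )
  expect_true(all(by_year$gap[by_year$n == 12] > 0))
})

test_that("noiseless SOC generation equals the closed-form predictor", {
  truth <- generative_params(
    intercept_log = log(109.73), sigma = 0, layer_dispersion = Inf
  )
  sites <- make_sites(8)
  seqs <- make_sequences(sites$site_id, rep(c("3c", "0c"), 4))
  soc <- generate_soc(sites, seqs, truth = truth, seed = 1)
  expect_equal(
    soc$soc_total[soc$rotation_group == "3c"],
    rep(109.73 * 1.713, 4),
    tolerance = 1e-12
  )
  expect_equal(
    soc$soc_total[soc$rotation_group == "0c"],
    rep(109.73, 4),
    tolerance = 1e-12
  )
  # degenerate Dirichlet: shares exactly the configured fractions
  expect_equal(soc$soc_0_5 / soc$soc_total, rep(0.08, 8), tolerance = 1e-12)
  expect_equal(soc$soc_30_100 / soc$soc_total, rep(0.64, 8), tolerance = 1e-12)
})

test_that("layer stocks always sum to the total and shares to one", {
  truth <- generative_params(sigma = 0.4, layer_dispersion = 30)
  sites <- make_sites(200)
  seqs <- make_sequences(sites$site_id,
                         sample(c("0c", "1c", "2c", "3c"), 200, TRUE))
  soc <- generate_soc(sites, seqs, truth = truth, seed = 21)
  expect_equal(soc$soc_0_5 + soc$soc_5_30 + soc$soc_30_100, soc$soc_total,
               tolerance = 1e-9)
  expect_true(all(soc$soc_total > 0))
  expect_true(all(soc$soc_0_5 > 0))
})

test_that("the calibrated intercept recovers the target arithmetic mean", {
  sigma <- 0.5
  truth <- generative_params(
    intercept_log = calibrate_intercept(109.73, sigma), sigma = sigma
  )
  sim <- simulate_rotation_study(4000, truth, seed = 31,
                                 group_probs = c("0c" = 1))
  m <- mean(sim$soc_total)
  se <- sd(sim$soc_total) / sqrt(nrow(sim))
  expect_lt(abs(m - 109.73), 3 * se)
})

test_that("missing sequences are reported by site id", {
  sites <- make_sites(3)
  seqs <- make_sequences(sites$site_id[1:2], c("0c", "1c"))
  expect_error(
    generate_soc(sites, seqs, truth = generative_params(), seed = 1),
    "S00003"
  )
})

test_that("generator parameter validation enforces the documented invariants", {
  expect_error(generative_params(sigma = -1), "sigma")
  expect_error(generative_params(layer_fractions = c(0.5, 0.3, 0.2)),
               "increase with depth")
  expect_error(generative_params(layer_fractions = c(0.1, 0.2, 0.6)),
               "sum to 1")
  expect_error(calibrate_intercept(-5), "> 0")
})
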