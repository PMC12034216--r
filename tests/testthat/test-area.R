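three_year_stack <- function(mat_fun, years = 2019:2021) {
  rs <- lapply(years, function(y) make_raster(mat_fun(y)))
  names(rs) <- years
  rs
}

test_that("a single valid cell yields identical samples", {
  vals <- matrix(0L, 4, 4)
  vals[2, 3] <- 5L
  rs <- three_year_stack(function(y) vals)
  s <- sample_points(rs, n = 25, seed = 1)
  expect_equal(nrow(s), 25)
  expect_equal(length(unique(s$x)), 1)
  expect_equal(length(unique(s$y)), 1)
  expect_true(all(s$code_2019 == 5L))
})

test_that("sampling is uniform over valid cells and seed-reproducible", {
  # left half corn mono (3c), right half soy mono (0c)
  vals <- cbind(matrix(1L, 20, 10), matrix(5L, 20, 10))
  rs <- three_year_stack(function(y) vals)
  s1 <- sample_points(rs, n = 40000, seed = 42)
  s2 <- sample_points(rs, n = 40000, seed = 42)
  expect_identical(s1, s2)
  p_corn <- mean(s1$code_2019 == 1L)
  expect_lt(abs(p_corn - 0.5), 3 * sqrt(0.25 / 40000))
})

test_that("rotation proportions classify sampled sequences correctly", {
  soy <- matrix(5L, 6, 6)
  rs <- three_year_stack(function(y) soy)
  s <- sample_points(rs, n = 200, seed = 3)
  pr <- rotation_proportions(s)
  expect_equal(pr$proportion[pr$pattern == "0c"], 1)
  expect_equal(sum(pr$proportion), 1)

  # alternating corn/soy years -> every point is 1c or 2c
  rs2 <- three_year_stack(function(y) {
    if (y %% 2 == 0) matrix(1L, 6, 6) else matrix(5L, 6, 6)
  })
  s2 <- sample_points(rs2, n = 100, seed = 4)
  pr2 <- rotation_proportions(s2)
  expect_equal(
    sum(pr2$proportion[pr2$pattern %in% c("1c", "2c")]), 1
  )
})

test_that("proportion vectors sum to one with correct corn-soy denominator", {
  layout <- one_region_layout(ncells = 40, na_mask_fraction = 0.1)
  mix <- rotation_mix(OH = c(
    "0c" = 0.2, "1c" = 0.2, "2c" = 0.2, "3c" = 0.2, other = 0.2
  ))
  gen <- generate_crop_rasters(layout, 2019:2021, mix, seed = 6)
  s <- sample_points(gen$rasters, n = 5000, seed = 7)
  pr <- rotation_proportions(s)
  expect_equal(sum(pr$proportion), 1, tolerance = 1e-9)
  cs <- pr[pr$pattern != "other", ]
  expect_equal(sum(cs$proportion_corn_soy), 1, tolerance = 1e-9)
  expect_true(all(cs$proportion_corn_soy >= cs$proportion))
  expect_true(all(pr$se >= 0))
})

test_that("planting frequency matches brute-force counting", {
  set.seed(31)
  years <- 2008:2021
  rs <- lapply(years, function(y) {
    make_raster(matrix(sample(c(1L, 5L, 24L), 36, replace = TRUE), 6, 6))
  })
  names(rs) <- years
  s <- sample_points(rs, n = 300, seed = 9)
  freq <- planting_frequency(s)
  codes <- as.matrix(s[paste0("code_", years)])
  expect_equal(freq$mean_years[freq$crop == "corn"],
               mean(rowSums(codes == 1L)))
  expect_equal(freq$mean_years[freq$crop == "soybeans"],
               mean(rowSums(codes == 5L)))

  # strict alternation over 14 years gives 7 and 7
  rs_alt <- lapply(years, function(y) {
    make_raster(matrix(if (y %% 2 == 0) 1L else 5L, 4, 4))
  })
  names(rs_alt) <- years
  s_alt <- sample_points(rs_alt, n = 50, seed = 10)
  f_alt <- planting_frequency(s_alt)
  expect_equal(f_alt$mean_years, c(7, 7), ignore_attr = TRUE)

  # all-corn raster
  rs_corn <- lapply(years, function(y) make_raster(matrix(1L, 4, 4)))
  names(rs_corn) <- years
  f_corn <- planting_frequency(sample_points(rs_corn, n = 20, seed = 11))
  expect_equal(f_corn$mean_years[f_corn$crop == "corn"], 14)
  expect_equal(f_corn$mean_years[f_corn$crop == "soybeans"], 0)
})

test_that("implied areas scale proportions by the regional total", {
  pr <- tibble::tibble(
    region = "OH", pattern = c("0c", "1c", "other"),
    n_points = c(10, 30, 60), proportion = c(0.1, 0.3, 0.6),
    se = 0, proportion_corn_soy = c(0.25, 0.75, NA)
  )
  areas <- estimate_group_area(
    pr, tibble::tibble(region = "OH", total_area_ha = 1e6)
  )
  expect_equal(areas$implied_area, c(1e5, 3e5, 6e5))
  expect_equal(sum(areas$implied_area), 1e6)
  expect_error(
    estimate_group_area(pr, tibble::tibble(region = "OH",
                                           total_area_ha = -1)),
    "non-negative"
  )
  expect_error(
    estimate_group_area(pr, tibble::tibble(region = "IA",
                                           total_area_ha = 1)),
    "OH"
  )
})

test_that("sampling error shrinks like n^(-1/2)", {
  vals <- cbind(matrix(1L, 20, 10), matrix(5L, 20, 10))
  rs <- three_year_stack(function(y) vals)
  mad_at <- function(n, seeds) {
    devs <- vapply(seeds, function(sd) {
      s <- sample_points(rs, n = n, seed = sd)
      abs(mean(s$code_2019 == 1L) - 0.5)
    }, numeric(1))
    mean(devs)
  }
  m_small <- mad_at(400, 1:50)
  m_big <- mad_at(10000, 51:100)
  ratio <- m_small / m_big # expect ~ sqrt(25) = 5
  expect_gt(ratio, 2.5)
  expect_lt(ratio, 10)
})

test_that("region masks restrict sampling and empty masks error", {
  layout <- region_layout(
    tibble::tibble(
      region = c("A", "B"), xmin = c(0, 300), xmax = c(300, 600),
      ymin = 0, ymax = 300
    ),
    na_mask_fraction = 0, field_block = 2
  )
  mix <- rotation_mix(A = c("0c" = 1), B = c("3c" = 1))
  gen <- generate_crop_rasters(layout, 2019:2021, mix, seed = 12)
  sA <- sample_points(gen$rasters, 100, seed = 13, layout = layout,
                      region = "A")
  expect_true(all(sA$x < 300))
  expect_true(all(sA$code_2019 == 5L))
  expect_error(
    sample_points(gen$rasters, 10, seed = 1, layout = layout, region = "Z"),
    "Unknown region"
  )
  empty <- three_year_stack(function(y) matrix(0L, 3, 3))
  expect_error(sample_points(empty, 10, seed = 1), "No valid cells")
})
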