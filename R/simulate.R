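#' Simulate a rotation-SOC study without rasters
#'
#' Convenience generator for simulation studies (parameter recovery,
#' power, coverage): draws rotation groups directly from `group_probs`
#' instead of sampling a raster, builds consistent crop sequences and a
#' minimal site table (latitude, texture, region, month), and completes
#' it with SOC stocks via [generate_soc()]. The raster-based path
#' ([generate_crop_rasters()] + [build_sequences()]) exercises the same
#' downstream code; this shortcut only replaces site placement.
#'
#' @param n Number of sites.
#' @param truth A [generative_params()].
#' @param seed Integer seed.
#' @param group_probs Named sampling probabilities over rotation groups
#'   (any subset of `0c`-`3c` and `excluded`).
#' @param lat_range Latitude range (degrees) sites are drawn from.
#' @param regions Region labels sites are assigned to uniformly.
#' @param code_map Crop code dialect, see [cdl_code_map()].
#'
#' @return A site tibble with crop sequence columns, `rotation_group`,
#'   `corn_years` and SOC stocks, ready for [fit_soc_model()].
#' @examples
#' sim <- simulate_rotation_study(200, generative_params(sigma = 0.2), seed = 1)
#' table(sim$rotation_group)
#' @export
simulate_rotation_study <- function(n, truth = generative_params(), seed,
                                    group_probs = c(
                                      "0c" = 0.25, "1c" = 0.25,
                                      "2c" = 0.25, "3c" = 0.25
                                    ),
                                    lat_range = c(38, 46),
                                    regions = c("R1", "R2"),
                                    code_map = cdl_code_map()) {
  if (abs(sum(group_probs) - 1) > 1e-9 || any(group_probs < 0)) {
    abort("`group_probs` must be non-negative and sum to 1.")
  }
  bad <- setdiff(names(group_probs), rotation_group_levels())
  if (length(bad)) {
    abort(paste0("Unknown group(s): ", paste(bad, collapse = ", ")))
  }
  set.seed(seed)
  group <- sample(names(group_probs), n, replace = TRUE, prob = group_probs)
  sites <- tibble::tibble(
    site_id = sprintf("S%05d", seq_len(n)),
    x = runif(n, 0, 1000), y = runif(n, 0, 1000),
    latitude = runif(n, lat_range[1], lat_range[2]),
    region = sample(regions, n, replace = TRUE),
    texture_class = sample(soil_texture_classes(), n, replace = TRUE),
    measurement_year = 2011L,
    measurement_month = sample(4:10, n, replace = TRUE)
  )
  cy <- corn_years_of_group(group)
  codes <- matrix(code_map$soybeans, nrow = n, ncol = 3)
  for (i in seq_len(n)) {
    if (is.na(cy[i])) {
      codes[i, 2] <- code_map$other[1]
    } else if (cy[i] > 0) {
      codes[i, sample.int(3, cy[i])] <- code_map$corn
    }
  }
  sequences <- tibble::tibble(
    site_id = sites$site_id,
    crop_y0 = codes[, 1], crop_y1 = codes[, 2], crop_y2 = codes[, 3],
    rotation_group = classify_rotation(
      codes[, 1], codes[, 2], codes[, 3], code_map
    ),
    corn_years = cy
  )
  stopifnot(identical(sequences$rotation_group, group))
  out <- generate_soc(sites, sequences, features = NULL, truth = truth,
                      seed = (seed + 1L) %% .Machine$integer.max)
  dplyr::left_join(
    out, sequences[, c("site_id", "crop_y0", "crop_y1", "crop_y2")],
    by = "site_id"
  )
}
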