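#' Classify a three-year corn-soybean rotation sequence
#'
#' A site's rotation group is `nc` where `n` is the number of corn years
#' among the measurement year and the two prior years, defined only when
#' all three crops are corn or soybeans; any other crop (or a missing
#' code) makes the sequence `excluded`. The group depends on the multiset
#' of codes only, not on their order.
#'
#' @param crop_y0,crop_y1,crop_y2 Integer crop codes for the measurement
#'   year, 1 year prior and 2 years prior (vectorized).
#' @param code_map Crop code dialect, see [cdl_code_map()].
#'
#' @return Character vector over `c("0c","1c","2c","3c","excluded")`.
#' @examples
#' classify_rotation(1L, 5L, 1L) # "2c"
#' classify_rotation(1L, 24L, 5L) # "excluded"
#' @export
classify_rotation <- function(crop_y0, crop_y1, crop_y2,
                              code_map = cdl_code_map()) {
  codes <- cbind(crop_y0, crop_y1, crop_y2)
  is_corn <- codes == code_map$corn
  is_soy <- codes == code_map$soybeans
  all_cs <- rowSums(is_corn | is_soy) == 3 & !apply(is.na(codes), 1, any)
  n_corn <- rowSums(is_corn)
  ifelse(all_cs, paste0(n_corn, "c"), "excluded")
}

#' Build crop sequences for sites from per-year rasters
#'
#' Extracts the crop code at each site's coordinates from the raster of
#' its measurement year and of the two preceding years, and classifies
#' the three-year rotation group.
#'
#' @param sites Site tibble with `site_id`, `x`, `y`, `measurement_year`.
#' @param rasters_by_year Named list of [crop_raster()]s (names = years);
#'   must cover `measurement_year`, `-1` and `-2` for every site.
#' @param code_map Crop code dialect, see [cdl_code_map()].
#'
#' @return A tibble with `site_id`, `crop_y0`, `crop_y1`, `crop_y2`,
#'   `rotation_group`, `corn_years` (`NA` for excluded sequences).
#' @export
build_sequences <- function(sites, rasters_by_year, code_map = cdl_code_map()) {
  need_years <- sort(unique(c(
    sites$measurement_year, sites$measurement_year - 1, sites$measurement_year - 2
  )))
  missing_yrs <- setdiff(as.character(need_years), names(rasters_by_year))
  if (length(missing_yrs)) {
    abort(paste0(
      "Missing raster year(s): ", paste(missing_yrs, collapse = ", ")
    ))
  }
  extract_year <- function(offset) {
    out <- rep(NA_integer_, nrow(sites))
    for (yr in unique(sites$measurement_year)) {
      sel <- sites$measurement_year == yr
      out[sel] <- extract_crop_at_points(
        rasters_by_year[[as.character(yr - offset)]],
        sites[sel, c("x", "y")]
      )
    }
    out
  }
  seqs <- tibble::tibble(
    site_id = sites$site_id,
    crop_y0 = extract_year(0),
    crop_y1 = extract_year(1),
    crop_y2 = extract_year(2)
  )
  seqs$rotation_group <- classify_rotation(
    seqs$crop_y0, seqs$crop_y1, seqs$crop_y2, code_map
  )
  seqs$corn_years <- corn_years_of_group(seqs$rotation_group)
  seqs
}
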