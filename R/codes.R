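#' Crop code dialect
#'
#' The pipeline follows the USDA Cropland Data Layer (CDL) integer code
#' dialect by default: corn = 1, soybeans = 5. A small set of non-corn/soy
#' codes (winter wheat = 24, alfalfa = 36) is used by the synthetic
#' generator for "other" crops so that the exclusion path of rotation
#' classification is exercised. All classification functions accept a
#' custom `code_map` so other dialects can be used.
#'
#' @param corn Integer code for corn.
#' @param soybeans Integer code for soybeans.
#' @param other Integer vector of codes for non-corn/soy crops used by the
#'   synthetic generator.
#'
#' @return A named list with elements `corn`, `soybeans`, `other`.
#' @examples
#' cdl_code_map()
#' @export
cdl_code_map <- function(corn = 1L, soybeans = 5L, other = c(24L, 36L)) {
  corn <- as.integer(corn)
  soybeans <- as.integer(soybeans)
  other <- as.integer(other)
  if (corn == soybeans) abort("`corn` and `soybeans` codes must differ.")
  if (any(other %in% c(corn, soybeans))) {
    abort("`other` codes must not include the corn or soybean code.")
  }
  list(corn = corn, soybeans = soybeans, other = other)
}

#' USDA soil texture classes
#'
#' The 16 categorical soil texture labels used for the texture dummy
#' variables (12 fine-earth USDA triangle classes plus coarse variants).
#'
#' @return Character vector of length 16.
#' @export
soil_texture_classes <- function() {
  c(
    "sand", "loamy_sand", "sandy_loam", "loam", "silt_loam", "silt",
    "sandy_clay_loam", "clay_loam", "silty_clay_loam", "sandy_clay",
    "silty_clay", "clay", "gravelly_loam", "gravelly_sandy_loam",
    "mucky_loam", "mucky_silt_loam"
  )
}

rotation_group_levels <- function() c("0c", "1c", "2c", "3c", "excluded")

# number of corn years implied by a group label ("0c".."3c"); NA for excluded
corn_years_of_group <- function(group) {
  out <- suppressWarnings(as.integer(sub("c$", "", group)))
  out[!group %in% c("0c", "1c", "2c", "3c")] <- NA_integer_
  out
}
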