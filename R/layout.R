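#' Region layout for synthetic rasters
#'
#' Describes the planar grid the synthetic crop rasters live on: a set of
#' named, non-overlapping rectangular regions (stand-ins for states), a
#' cell size, the fraction of cells masked out as non-cropland, and the
#' edge length (in cells) of the square field patches that carry a single
#' rotation pattern.
#'
#' @param regions Data frame with columns `region`, `xmin`, `xmax`,
#'   `ymin`, `ymax` (map units; each extent must be a whole number of
#'   cells and extents must not overlap).
#' @param cell_size Cell edge length in map units (default 30, the common
#'   CDL ground resolution).
#' @param na_mask_fraction Fraction of field patches masked out as
#'   non-cropland (`0 <= f < 1`).
#' @param field_block Edge length of a field patch, in cells (`>= 1`).
#' @param crs Coordinate-reference label carried by all generated rasters.
#'
#' @return An object of class `region_layout`.
#' @examples
#' region_layout(tibble::tibble(
#'   region = "OH", xmin = 0, xmax = 300, ymin = 0, ymax = 300
#' ))
#' @export
region_layout <- function(regions, cell_size = 30, na_mask_fraction = 0.1,
                          field_block = 4, crs = "local") {
  regions <- tibble::as_tibble(regions)
  need <- c("region", "xmin", "xmax", "ymin", "ymax")
  if (!all(need %in% names(regions))) {
    abort(paste0("`regions` must have columns: ", paste(need, collapse = ", ")))
  }
  if (nrow(regions) == 0) abort("`regions` must contain at least one region.")
  if (any(regions$xmax <= regions$xmin) || any(regions$ymax <= regions$ymin)) {
    abort("Every region must have positive width and height.")
  }
  spans <- c(
    regions$xmax - regions$xmin, regions$ymax - regions$ymin,
    regions$xmin, regions$ymin
  )
  if (any(abs(spans / cell_size - round(spans / cell_size)) > 1e-9)) {
    abort("Region extents must align to whole cells.")
  }
  if (nrow(regions) > 1) {
    for (i in seq_len(nrow(regions) - 1)) {
      for (j in (i + 1):nrow(regions)) {
        overlap_x <- regions$xmin[i] < regions$xmax[j] && regions$xmin[j] < regions$xmax[i]
        overlap_y <- regions$ymin[i] < regions$ymax[j] && regions$ymin[j] < regions$ymax[i]
        if (overlap_x && overlap_y) {
          abort(sprintf(
            "Regions '%s' and '%s' overlap.", regions$region[i], regions$region[j]
          ))
        }
      }
    }
  }
  if (na_mask_fraction < 0 || na_mask_fraction >= 1) {
    abort("`na_mask_fraction` must be in [0, 1).")
  }
  field_block <- as.integer(field_block)
  if (field_block < 1) abort("`field_block` must be >= 1.")
  structure(
    list(
      regions = regions, cell_size = cell_size,
      na_mask_fraction = na_mask_fraction, field_block = field_block,
      crs = crs
    ),
    class = "region_layout"
  )
}

#' Rotation-pattern mix per region
#'
#' The ground-truth proportions of three-year rotation patterns (`0c`,
#' `1c`, `2c`, `3c`, `other`) assigned to field patches in each region.
#' `nc` means corn is planted in `n` of the 3 years and soybeans in the
#' rest; `other` patches grow a non-corn/soy crop in all years.
#'
#' @param ... Named arguments, one per region: a named numeric vector of
#'   proportions over `c("0c","1c","2c","3c","other")` summing to 1.
#'   Missing patterns default to 0.
#'
#' @return An object of class `rotation_mix` (tibble region x pattern).
#' @examples
#' rotation_mix(OH = c(`0c` = 0.1056, `1c` = 0.25, `2c` = 0.3,
#'                     `3c` = 0.0218, other = 0.3226))
#' @export
rotation_mix <- function(...) {
  mixes <- list(...)
  if (length(mixes) == 0 || is.null(names(mixes)) || any(!nzchar(names(mixes)))) {
    abort("Provide one named proportion vector per region.")
  }
  patterns <- c("0c", "1c", "2c", "3c", "other")
  rows <- purrr::imap(mixes, function(p, region) {
    bad <- setdiff(names(p), patterns)
    if (length(bad)) {
      abort(paste0("Unknown pattern(s) for region ", region, ": ",
                   paste(bad, collapse = ", ")))
    }
    full <- setNames(rep(0, 5), patterns)
    full[names(p)] <- p
    if (any(full < 0)) abort(sprintf("Negative proportion in region %s.", region))
    if (abs(sum(full) - 1) > 1e-9) {
      abort(sprintf("Proportions for region %s must sum to 1 (got %.6f).",
                    region, sum(full)))
    }
    tibble::tibble(region = region, pattern = patterns, proportion = unname(full))
  })
  structure(dplyr::bind_rows(rows), class = c("rotation_mix", class(tibble::tibble())))
}
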