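#' Typed CSV readers and writers
#'
#' Thin readr wrappers that enforce the documented column schemas of the
#' pipeline's tables so that a write-then-read round trip preserves
#' values to full precision and malformed input fails loudly (header
#' mismatches list the missing columns; unparseable rows name the line).
#'
#' @param x A data frame.
#' @param path CSV file path.
#' @name rotsoc_io
NULL

# column name -> readr type, per table ("c" character, "d" double,
# "i" integer); typed parsing makes malformed cells loud instead of
# silently degrading a column to character
table_schemas <- function() {
  feat <- setNames(rep("d", 8), climate_feature_names())
  list(
    sites = c(site_id = "c", x = "d", y = "d", latitude = "d",
              region = "c", texture_class = "c",
              measurement_year = "i", measurement_month = "i"),
    weather = c(site_id = "c", months_before = "i", year = "i",
                month = "i", tmean = "d", ppt = "d"),
    sequences = c(site_id = "c", crop_y0 = "i", crop_y1 = "i",
                  crop_y2 = "i", rotation_group = "c", corn_years = "i"),
    features = c(c(site_id = "c"), feat),
    soc_sites = c(site_id = "c", soc_0_5 = "d", soc_5_30 = "d",
                  soc_30_100 = "d", soc_total = "d")
  )
}

read_checked <- function(path, schema) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  missing_cols <- setdiff(names(schema), header)
  if (length(missing_cols)) {
    abort(paste0(
      "File ", path, " is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  types <- do.call(
    readr::cols,
    c(as.list(schema), list(.default = readr::col_guess()))
  )
  df <- suppressWarnings(
    readr::read_csv(path, col_types = types, progress = FALSE)
  )
  probs <- readr::problems(df)
  if (nrow(probs)) {
    abort(sprintf(
      "Malformed value in %s at line %d, column %d (expected %s).",
      path, probs$row[1], probs$col[1], probs$expected[1]
    ))
  }
  df
}

#' @rdname rotsoc_io
#' @export
write_rotsoc_table <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' @rdname rotsoc_io
#' @export
read_sites_table <- function(path) read_checked(path, table_schemas()$sites)

#' @rdname rotsoc_io
#' @export
read_weather_table <- function(path) read_checked(path, table_schemas()$weather)

#' @rdname rotsoc_io
#' @export
read_sequences_table <- function(path) read_checked(path, table_schemas()$sequences)

#' @rdname rotsoc_io
#' @export
read_features_table <- function(path) read_checked(path, table_schemas()$features)

#' @rdname rotsoc_io
#' @export
read_soc_table <- function(path) read_checked(path, table_schemas()$soc_sites)
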