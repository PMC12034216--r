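#' Categorical crop raster
#'
#' A minimal single-band categorical raster: an integer matrix on a regular
#' planar grid with an affine extent. Row 1 of the matrix is the top row of
#' the map (north-up convention); cells are half-open intervals
#' `[left, right) x (bottom, top]` so every point in the extent belongs to
#' exactly one cell and points on the right/bottom outer edge fall outside.
#'
#' @param values Integer matrix (rows = map rows top to bottom).
#' @param xmin,ymax Coordinates of the top-left corner of the grid.
#' @param cell_size Cell edge length in map units (square cells).
#' @param nodata Integer value marking non-cropland / missing cells.
#' @param crs Free-text label of the coordinate reference; rasters combined
#'   by any operation must carry identical labels (no reprojection engine).
#'
#' @return An object of class `crop_raster`.
#' @examples
#' r <- crop_raster(matrix(1L, 2, 3), xmin = 0, ymax = 60, cell_size = 30)
#' raster_extent(r)
#' @export
crop_raster <- function(values, xmin = 0, ymax = nrow(values) * cell_size,
                        cell_size = 30, nodata = 0L, crs = "local") {
  if (!is.matrix(values)) abort("`values` must be a matrix.")
  storage.mode(values) <- "integer"
  if (!is.numeric(cell_size) || cell_size <= 0) {
    abort("`cell_size` must be a positive number.")
  }
  structure(
    list(
      values = values, xmin = as.numeric(xmin), ymax = as.numeric(ymax),
      cell_size = as.numeric(cell_size), nodata = as.integer(nodata),
      crs = as.character(crs)
    ),
    class = "crop_raster"
  )
}

#' @export
print.crop_raster <- function(x, ...) {
  ext <- raster_extent(x)
  cat(
    sprintf(
      "<crop_raster> %d x %d cells, cell %g, extent [%g, %g] x [%g, %g], crs '%s'\n",
      nrow(x$values), ncol(x$values), x$cell_size,
      ext[["xmin"]], ext[["xmax"]], ext[["ymin"]], ext[["ymax"]], x$crs
    )
  )
  codes <- table(x$values[x$values != x$nodata])
  if (length(codes)) {
    cat("codes:", paste(names(codes), "=", as.integer(codes), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname crop_raster
#' @param raster A `crop_raster`.
#' @return `raster_extent()`: named numeric vector `xmin, xmax, ymin, ymax`.
#' @export
raster_extent <- function(raster) {
  stopifnot(inherits(raster, "crop_raster"))
  c(
    xmin = raster$xmin,
    xmax = raster$xmin + ncol(raster$values) * raster$cell_size,
    ymin = raster$ymax - nrow(raster$values) * raster$cell_size,
    ymax = raster$ymax
  )
}

# (row, col) of the cells containing planar points; NA outside the extent.
# Half-open convention: left/top edges belong to a cell, right/bottom don't.
cell_index <- function(raster, x, y) {
  col <- floor((x - raster$xmin) / raster$cell_size) + 1
  row <- floor((raster$ymax - y) / raster$cell_size) + 1
  # top edge: y == ymax gives row 0 by the formula above; pull into row 1
  row[y == raster$ymax] <- 1
  outside <- col < 1 | col > ncol(raster$values) | row < 1 | row > nrow(raster$values)
  row[outside] <- NA_integer_
  col[outside] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

cell_center <- function(raster, row, col) {
  list(
    x = raster$xmin + (col - 0.5) * raster$cell_size,
    y = raster$ymax - (row - 0.5) * raster$cell_size
  )
}

check_same_grid <- function(a, b) {
  same <- identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(c(a$xmin, a$ymax, a$cell_size), c(b$xmin, b$ymax, b$cell_size))) &&
    identical(a$crs, b$crs)
  if (!same) abort("Rasters are not on the same grid / coordinate reference.")
  invisible(TRUE)
}

#' Extract crop codes at point locations
#'
#' Looks up the raster value of the cell containing each point. Nodata
#' cells yield `NA`; points outside the raster extent yield `NA` with a
#' warning (they are logged, not fatal).
#'
#' @param raster A [crop_raster()].
#' @param points Data frame with numeric columns `x` and `y` in the
#'   raster's coordinate reference.
#'
#' @return Integer vector, one code per point (`NA` = nodata or outside).
#' @examples
#' r <- crop_raster(matrix(c(1L, 5L, 5L, 1L), 2, 2), xmin = 0, ymax = 60)
#' extract_crop_at_points(r, data.frame(x = 15, y = 45))
#' @export
extract_crop_at_points <- function(raster, points) {
  stopifnot(inherits(raster, "crop_raster"))
  if (!all(c("x", "y") %in% names(points))) {
    abort("`points` must have columns `x` and `y`.")
  }
  idx <- cell_index(raster, points$x, points$y)
  outside <- is.na(idx$row)
  if (any(outside)) {
    warn(sprintf(
      "%d point(s) fall outside the raster extent; returning NA for them.",
      sum(outside)
    ))
  }
  out <- rep(NA_integer_, nrow(points))
  ok <- !outside
  out[ok] <- raster$values[cbind(idx$row[ok], idx$col[ok])]
  out[!is.na(out) & out == raster$nodata] <- NA_integer_
  out
}

#' Year-over-year crop transition table
#'
#' Cross-tabulates the crop code of every valid cell in one year against
#' the code of the same cell in the previous year, the raster analogue of a
#' rotation transition matrix. Cells that are nodata in either year are
#' dropped.
#'
#' @param rasters_by_year Named list of [crop_raster()]s, names = years.
#' @param year_pair Length-2 vector `c(to, from)` or `c(year_t, year_t_minus_1)`;
#'   order is (later year, earlier year).
#'
#' @return A tibble with columns `code_from`, `code_to`, `n`.
#' @export
transition_table <- function(rasters_by_year, year_pair) {
  yrs <- as.character(year_pair)
  missing_yrs <- setdiff(yrs, names(rasters_by_year))
  if (length(missing_yrs)) {
    abort(paste0("Missing raster year(s): ", paste(missing_yrs, collapse = ", ")))
  }
  to <- rasters_by_year[[yrs[1]]]
  from <- rasters_by_year[[yrs[2]]]
  check_same_grid(to, from)
  ok <- to$values != to$nodata & from$values != from$nodata
  tab <- table(code_from = from$values[ok], code_to = to$values[ok])
  out <- tibble::as_tibble(tab, .name_repair = "minimal")
  names(out) <- c("code_from", "code_to", "n")
  out$code_from <- as.integer(out$code_from)
  out$code_to <- as.integer(out$code_to)
  out$n <- as.integer(out$n)
  out <- out[out$n > 0, , drop = FALSE]
  dplyr::arrange(out, .data$code_from, .data$code_to)
}

#' Read and write plain-text rasters
#'
#' Rasters are serialized as ESRI ASCII grid (`.asc`), a standard
#' plain-text single-band raster format (header of `ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`, then rows top to
#' bottom). The coordinate-reference label is kept in a `.crs.txt` sidecar.
#'
#' @param raster A [crop_raster()].
#' @param path File path (conventionally `.asc`).
#' @return `write_ascii_grid()` returns `path` invisibly;
#'   `read_ascii_grid()` returns a [crop_raster()].
#' @export
write_ascii_grid <- function(raster, path) {
  stopifnot(inherits(raster, "crop_raster"))
  ext <- raster_extent(raster)
  header <- c(
    sprintf("ncols %d", ncol(raster$values)),
    sprintf("nrows %d", nrow(raster$values)),
    sprintf("xllcorner %.10g", ext[["xmin"]]),
    sprintf("yllcorner %.10g", ext[["ymin"]]),
    sprintf("cellsize %.10g", raster$cell_size),
    sprintf("NODATA_value %d", raster$nodata)
  )
  body <- apply(raster$values, 1, paste, collapse = " ")
  writeLines(c(header, body), path)
  writeLines(raster$crs, paste0(path, ".crs.txt"))
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  header <- lines[1:6]
  kv <- strsplit(trimws(header), "\\s+")
  keys <- tolower(vapply(kv, `[[`, "", 1))
  vals <- as.numeric(vapply(kv, `[[`, "", 2))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!all(need %in% keys)) {
    abort(paste0(
      "Malformed ASCII grid header; missing: ",
      paste(setdiff(need, keys), collapse = ", ")
    ))
  }
  body <- lines[-(1:6)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != vals[["nrows"]]) {
    abort(sprintf(
      "ASCII grid body has %d rows, header says %d.",
      length(body), as.integer(vals[["nrows"]])
    ))
  }
  values <- do.call(rbind, lapply(body, function(l) {
    as.integer(strsplit(trimws(l), "\\s+")[[1]])
  }))
  if (ncol(values) != vals[["ncols"]]) {
    abort("ASCII grid row length does not match `ncols` in header.")
  }
  crs_path <- paste0(path, ".crs.txt")
  crs <- if (file.exists(crs_path)) readLines(crs_path)[1] else "local"
  crop_raster(
    values,
    xmin = vals[["xllcorner"]],
    ymax = vals[["yllcorner"]] + vals[["nrows"]] * vals[["cellsize"]],
    cell_size = vals[["cellsize"]],
    nodata = as.integer(vals[["nodata_value"]]),
    crs = crs
  )
}
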