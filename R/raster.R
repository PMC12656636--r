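#' Lightweight projected-CRS raster
#'
#' `crast()` wraps a numeric matrix as a single-band raster on a regular grid
#' in a projected (metre) coordinate system. Row 1 is the northernmost row;
#' `NA` cells are NoData (sea, for island landscapes). Cell centers are at
#' `x = xmin + (col - 0.5) * cell_m`, `y = ymin + (nrow - row + 0.5) * cell_m`.
#'
#' @param values numeric matrix (row 1 = top/north).
#' @param cell_m cell edge length in metres (> 0).
#' @param xmin,ymin coordinates of the grid's lower-left corner (metres).
#' @param crs free-form CRS label carried as metadata (default a local
#'   projected system; the paper-scale workflow would use a UTM EPSG code).
#' @return an object of class `crast`.
#' @export
crast <- function(values, cell_m, xmin = 0, ymin = 0, crs = "local-metres") {
  stopifnot(is.matrix(values), is.numeric(cell_m), cell_m > 0)
  structure(
    list(v = values, cell_m = as.numeric(cell_m),
         xmin = as.numeric(xmin), ymin = as.numeric(ymin), crs = crs),
    class = "crast"
  )
}

#' @export
print.crast <- function(x, ...) {
  n_land <- sum(!is.na(x$v))
  cat(sprintf(
    "<crast> %d x %d cells @ %g m  (%d valid, %.4f km^2)\n",
    nrow(x$v), ncol(x$v), x$cell_m, n_land, n_land * x$cell_m^2 / 1e6))
  rng <- suppressWarnings(range(x$v, na.rm = TRUE))
  if (is.finite(rng[1])) cat(sprintf("  values: [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
dim.crast <- function(x) dim(x$v)

#' @rdname crast
#' @param x a `crast`.
#' @export
is_crast <- function(x) inherits(x, "crast")

cr_check_same_geom <- function(a, b) {
  stopifnot(all(dim(a$v) == dim(b$v)), a$cell_m == b$cell_m,
            isTRUE(all.equal(a$xmin, b$xmin)), isTRUE(all.equal(a$ymin, b$ymin)))
  invisible(TRUE)
}

#' Cell-center coordinates
#'
#' @param r a `crast`.
#' @param rows,cols integer vectors (recycled); defaults cover the full grid.
#' @return tibble with `row`, `col`, `x`, `y`.
#' @export
cr_coords <- function(r, rows = NULL, cols = NULL) {
  if (is.null(rows)) {
    idx <- which(!is.na(r$v) | is.na(r$v))  # full grid
    rows <- row(r$v)[idx]; cols <- col(r$v)[idx]
  }
  tibble::tibble(
    row = as.integer(rows), col = as.integer(cols),
    x = r$xmin + (cols - 0.5) * r$cell_m,
    y = r$ymin + (nrow(r$v) - rows + 0.5) * r$cell_m
  )
}

#' Map point coordinates to cell indices
#'
#' Points outside the grid get `NA` indices.
#' @param r a `crast`.
#' @param x,y point coordinates in metres.
#' @return tibble with `row`, `col` (NA outside the grid).
#' @export
cr_cell_at <- function(r, x, y) {
  col <- floor((x - r$xmin) / r$cell_m) + 1
  row <- nrow(r$v) - floor((y - r$ymin) / r$cell_m)
  bad <- col < 1 | col > ncol(r$v) | row < 1 | row > nrow(r$v) |
    !is.finite(col) | !is.finite(row)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  tibble::tibble(row = as.integer(row), col = as.integer(col))
}

#' Convert a raster to a long tibble of valid cells
#'
#' @param x a `crast`.
#' @param ... unused.
#' @param value_name name of the value column.
#' @param keep_na keep NoData cells too?
#' @method as_tibble crast
#' @export
as_tibble.crast <- function(x, ..., value_name = "value", keep_na = FALSE) {
  keep <- if (keep_na) rep(TRUE, length(x$v)) else !is.na(x$v)
  idx <- which(keep)
  out <- cr_coords(x, row(x$v)[idx], col(x$v)[idx])
  out[[value_name]] <- x$v[idx]
  out
}

#' Total area of valid (non-NoData) cells
#'
#' Areas are cell counts times `cell_m^2`, the projected-grid convention used
#' throughout the decision layer.
#' @param r a `crast`; for 0/1 rasters only cells equal to 1 are counted.
#' @param km2 return km^2 (default) instead of m^2.
#' @export
cr_area <- function(r, km2 = TRUE) {
  v <- r$v
  n <- if (all(v %in% c(0, 1, NA))) sum(v == 1, na.rm = TRUE) else sum(!is.na(v))
  a <- n * r$cell_m^2
  if (km2) a / 1e6 else a
}

#' Read / write ESRI ASCII grid
#'
#' Plain-text raster interchange (one header block, then rows north to
#' south). NoData is written as -9999.
#' @param r a `crast`.
#' @param path file path.
#' @export
write_ascii_grid <- function(r, path) {
  hdr <- sprintf(
    "ncols %d\nnrows %d\nxllcorner %.6f\nyllcorner %.6f\ncellsize %.6f\nNODATA_value -9999",
    ncol(r$v), nrow(r$v), r$xmin, r$ymin, r$cell_m)
  v <- r$v; v[is.na(v)] <- -9999
  body <- apply(v, 1, function(row) paste(formatC(row, format = "g", digits = 10), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- hdr[grepl(paste0("^", key, "\\b"), hdr, ignore.case = TRUE)]
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  nc <- val("ncols"); nr <- val("nrows"); nodata <- val("NODATA_value")
  m <- matrix(scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE),
              nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  crast(m, cell_m = val("cellsize"), xmin = val("xllcorner"), ymin = val("yllcorner"))
}

#' Raster heat map
#'
#' @param object a `crast`.
#' @param ... unused.
#' @method autoplot crast
#' @export
autoplot.crast <- function(object, ...) {
  df <- as_tibble.crast(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "x (m)", y = "y (m)")
}
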