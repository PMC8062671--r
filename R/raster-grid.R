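#' Georeferenced raster grid
#'
#' A minimal planar raster: a row-major cell lattice anchored at its
#' top-left corner. The centre of cell `(r, c)` (1-based) is at
#' `x = x0 + (c - 0.5) * cell_size`, `y = y0 - (r - 0.5) * cell_size`,
#' i.e. rows advance downward (north to south), columns rightward.
#'
#' @param values numeric matrix (`n_rows x n_cols`); `NA` encodes nodata.
#' @param origin `c(x0, y0)` of the top-left corner in metres.
#' @param cell_size cell edge in metres (> 0).
#' @param nodata value used to encode `NA` on disk (default -9999).
#' @return object of class `raster_grid`.
#' @export
raster_grid <- function(values, origin, cell_size, nodata = -9999) {
  stopifnot(is.matrix(values), length(origin) == 2, cell_size > 0)
  stopifnot(all(is.finite(values) | is.na(values)))
  structure(
    list(values = values, origin = as.numeric(origin),
         cell_size = as.numeric(cell_size),
         n_rows = nrow(values), n_cols = ncol(values),
         nodata = nodata),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("<raster_grid> %d x %d cells of %g m; origin (%g, %g); values [%g, %g]\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin[1], x$origin[2],
              rng[1], rng[2]))
  invisible(x)
}

#' Cell-centre coordinates of a raster grid
#'
#' @param raster a `raster_grid`.
#' @return list with vectors `x` (length `n_cols`) and `y` (length
#'   `n_rows`), in grid order.
#' @export
cell_centers <- function(raster) {
  stopifnot(inherits(raster, "raster_grid"))
  list(
    x = raster$origin[1] + (seq_len(raster$n_cols) - 0.5) * raster$cell_size,
    y = raster$origin[2] - (seq_len(raster$n_rows) - 0.5) * raster$cell_size
  )
}

#' Read and write ESRI ASCII grids
#'
#' Plain-text raster exchange format: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by
#' row-major cell values, top row first.
#'
#' @param raster a `raster_grid`.
#' @param path file path (conventionally `.asc`).
#' @return `read_ascii_grid()` returns a `raster_grid`;
#'   `write_ascii_grid()` returns `path` invisibly.
#' @export
write_ascii_grid <- function(raster, path) {
  stopifnot(inherits(raster, "raster_grid"))
  v <- raster$values
  v[is.na(v)] <- raster$nodata
  yll <- raster$origin[2] - raster$n_rows * raster$cell_size
  header <- c(
    paste("ncols", raster$n_cols),
    paste("nrows", raster$n_rows),
    paste("xllcorner", format(raster$origin[1], scientific = FALSE)),
    paste("yllcorner", format(yll, scientific = FALSE)),
    paste("cellsize", format(raster$cell_size, scientific = FALSE)),
    paste("NODATA_value", raster$nodata)
  )
  body <- apply(v, 1, function(row) paste(format(row, digits = 15,
                                                 trim = TRUE,
                                                 scientific = TRUE),
                                          collapse = " "))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("No such file: ", path), class = "firescape_io_error")
  }
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  vals <- setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  nc <- as.integer(vals["ncols"])
  nr <- as.integer(vals["nrows"])
  nodata <- vals["nodata_value"]
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(body) != nr * nc) {
    abort("ASCII grid body does not match declared dimensions",
          class = "firescape_io_error")
  }
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  origin <- c(vals[["xllcorner"]], vals[["yllcorner"]] + nr * vals[["cellsize"]])
  raster_grid(m, origin, vals[["cellsize"]], nodata = unname(nodata))
}
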