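#' Aligned multi-variable raster stack with an accessible-area mask
#'
#' An `env_stack` holds one or more environmental layers on a shared
#' north-up lon/lat grid (row 1 = northernmost row), plus a logical mask
#' marking the accessible area within which background points are drawn.
#' Cells are half-open: `[x, x + cs)` in longitude and `(y - cs, y]` in
#' latitude, so every point inside the extent belongs to exactly one cell.
#'
#' @param layers named list of numeric matrices, identical dimensions.
#' @param xll,yll coordinates of the lower-left corner of the grid (degrees).
#' @param cellsize cell edge length in degrees.
#' @param mask logical matrix of the same dimensions; `TRUE` = accessible.
#'   Default: all cells with finite values in every layer.
#' @param crs coordinate reference identifier (informational).
#' @return an object of class `env_stack`.
#' @export
env_stack <- function(layers, xll, yll, cellsize, mask = NULL,
                      crs = "EPSG:4326") {
  stopifnot(is.list(layers), length(layers) >= 1, !is.null(names(layers)))
  dims <- lapply(layers, dim)
  if (length(unique(dims)) != 1)
    stop("all layers must share the same dimensions")
  d <- dims[[1]]
  finite <- Reduce(`&`, lapply(layers, is.finite))
  if (is.null(mask)) mask <- finite
  stopifnot(identical(dim(mask), d))
  mask <- mask & finite  # masked-in cells must have finite values everywhere
  structure(list(layers = layers, mask = mask, xll = xll, yll = yll,
                 cellsize = cellsize, crs = crs,
                 nrow = d[1], ncol = d[2]),
            class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat("<env_stack> ", x$nrow, "x", x$ncol, " cells, ",
      length(x$layers), " layer(s): ",
      paste(names(x$layers), collapse = ", "), "\n", sep = "")
  cat("  extent: x [", x$xll, ", ", x$xll + x$ncol * x$cellsize,
      "], y [", x$yll, ", ", x$yll + x$nrow * x$cellsize,
      "], cell ", x$cellsize, "\n", sep = "")
  cat("  accessible cells: ", sum(x$mask), "\n", sep = "")
  invisible(x)
}

## Point -> (row, col) by floor arithmetic on the half-open cell convention.
## Returns NA for points outside the extent.
cell_index <- function(stack, lon, lat) {
  col <- floor((lon - stack$xll) / stack$cellsize) + 1
  row <- stack$nrow - ceiling((lat - stack$yll) / stack$cellsize) + 1
  bad <- !is.finite(lon) | !is.finite(lat) |
    col < 1 | col > stack$ncol | row < 1 | row > stack$nrow
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

## Linear cell id (1..nrow*ncol, column-major) or NA.
cell_id <- function(stack, lon, lat) {
  rc <- cell_index(stack, lon, lat)
  ifelse(is.na(rc[, 1]), NA_integer_,
         (rc[, 2] - 1L) * stack$nrow + rc[, 1])
}

## Center coordinates of cells given (row, col).
cell_center <- function(stack, row, col) {
  cbind(lon = stack$xll + (col - 0.5) * stack$cellsize,
        lat = stack$yll + (stack$nrow - row + 0.5) * stack$cellsize)
}

## Env values at cells: matrix with one row per (row, col) pair.
cell_values <- function(stack, row, col) {
  idx <- cbind(row, col)
  out <- vapply(stack$layers, function(m) m[idx], numeric(length(row)))
  if (length(row) == 1) out <- matrix(out, nrow = 1,
                                      dimnames = list(NULL, names(stack$layers)))
  out
}

## All masked-in cells as (row, col) pairs, column-major order.
masked_cells <- function(stack) {
  which(stack$mask, arr.ind = TRUE)
}

#' Environmental values of every accessible cell
#'
#' @param stack an [env_stack].
#' @return matrix (cells x layers) of the masked-in cells' values, in
#'   column-major cell order.
#' @export
background_env <- function(stack) {
  rc <- masked_cells(stack)
  cell_values(stack, rc[, 1], rc[, 2])
}

#' Read an ESRI ASCII grid
#'
#' Parses the standard 6-line header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `nodata_value`) followed by row-major values,
#' row 1 = northernmost. `nodata` cells become `NA`.
#'
#' @param path file path.
#' @return list with `values` (matrix), `xll`, `yll`, `cellsize`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, n = 6)
  hdr <- list()
  nhdr <- 0
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2 && is.na(suppressWarnings(as.numeric(parts[1])))) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      nhdr <- nhdr + 1
    } else break
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not an ESRI ASCII grid: missing header fields in ", path)
  vals <- scan(path, skip = nhdr, quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc)
    stop("ASCII grid ", path, ": expected ", nr * nc, " values, got ",
         length(vals))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- hdr[["nodata_value"]]
  if (!is.null(nodata)) m[m == nodata] <- NA_real_
  list(values = m, xll = hdr$xllcorner, yll = hdr$yllcorner,
       cellsize = hdr$cellsize)
}

#' Write a matrix as an ESRI ASCII grid
#'
#' @param values numeric matrix, row 1 = northernmost.
#' @param path output path.
#' @param xll,yll lower-left corner. @param cellsize cell size (degrees).
#' @param nodata value written for `NA` cells.
#' @export
write_ascii_grid <- function(values, path, xll, yll, cellsize,
                             nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(values)),
    paste("nrows", nrow(values)),
    paste("xllcorner", format(xll, digits = 15)),
    paste("yllcorner", format(yll, digits = 15)),
    paste("cellsize", format(cellsize, digits = 15)),
    paste("NODATA_value", nodata)), con)
  v <- values
  v[is.na(v)] <- nodata
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a set of single-variable ASCII grids as an aligned stack
#'
#' @param paths named character vector of ASCII-grid paths (names become
#'   layer names).
#' @param mask_path optional 0/1 ASCII grid on the same grid.
#' @param crs coordinate reference identifier.
#' @return an [env_stack].
#' @export
read_env_stack <- function(paths, mask_path = NULL, crs = "EPSG:4326") {
  stopifnot(length(paths) >= 1, !is.null(names(paths)))
  grids <- lapply(paths, read_ascii_grid)
  g1 <- grids[[1]]
  for (g in grids[-1]) {
    if (!identical(dim(g$values), dim(g1$values)) ||
        !isTRUE(all.equal(c(g$xll, g$yll, g$cellsize),
                          c(g1$xll, g1$yll, g1$cellsize))))
      stop("raster layers are not aligned on the same grid")
  }
  mask <- NULL
  if (!is.null(mask_path)) {
    mg <- read_ascii_grid(mask_path)
    if (!identical(dim(mg$values), dim(g1$values)))
      stop("mask grid does not match layer grid")
    mask <- !is.na(mg$values) & mg$values != 0
  }
  env_stack(lapply(grids, `[[`, "values"), xll = g1$xll, yll = g1$yll,
            cellsize = g1$cellsize, mask = mask, crs = crs)
}
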