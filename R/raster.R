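#' Lightweight in-memory raster
#'
#' A `land_raster` is a north-up, row-major single-band grid: a numeric matrix
#' (row 1 = northernmost row) plus a square cell size in metres and a lower-left
#' corner. Missing cells are `NA` in memory and a declared nodata code on disk.
#' All spatial objects in tipland (land cover, land systems, drivers,
#' suitability surfaces, masks) are `land_raster`s.
#'
#' @param values numeric or integer matrix, row 1 = top (north) row.
#' @param cell_size cell edge length in metres (> 0).
#' @param xll,yll coordinates of the lower-left corner of the grid.
#' @param layer optional layer name.
#' @return an object of class `land_raster`.
#' @examples
#' r <- land_raster(matrix(0:5, 2, 3), cell_size = 30)
#' dim(r)
#' @export
land_raster <- function(values, cell_size, xll = 0, yll = 0, layer = NULL) {
  if (!is.matrix(values)) stop("`values` must be a matrix", call. = FALSE)
  if (length(values) == 0L) stop("empty raster", call. = FALSE)
  if (!is.numeric(cell_size) || length(cell_size) != 1L || !is.finite(cell_size) ||
      cell_size <= 0) {
    stop("`cell_size` must be a single positive number", call. = FALSE)
  }
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         xll = as.numeric(xll), yll = as.numeric(yll), layer = layer),
    class = "land_raster"
  )
}

#' @export
dim.land_raster <- function(x) dim(x$values)

#' @export
print.land_raster <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<land_raster> %d x %d cells, cell size %g m%s\n", d[1], d[2],
              x$cell_size,
              if (!is.null(x$layer)) paste0(", layer '", x$layer, "'") else ""))
  v <- x$values[!is.na(x$values)]
  if (length(v)) {
    cat(sprintf("  values: [%g, %g], %d NA of %d cells\n", min(v), max(v),
                sum(is.na(x$values)), length(x$values)))
  } else {
    cat("  all cells NA\n")
  }
  invisible(x)
}

is_land_raster <- function(x) inherits(x, "land_raster")

#' Check that two rasters share geometry
#'
#' Same dimensions, cell size and origin. Used as a precondition by every
#' operation combining rasters; mismatches raise an error rather than being
#' silently recycled.
#'
#' @param a,b `land_raster`s.
#' @param what label used in the error message.
#' @return invisibly `TRUE`; errors on mismatch.
#' @export
check_same_geometry <- function(a, b, what = "rasters") {
  stopifnot(is_land_raster(a), is_land_raster(b))
  ok <- identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(c(a$xll, a$yll), c(b$xll, b$yll)))
  if (!ok) {
    stop(sprintf("geometry mismatch between %s (%dx%d @ %gm vs %dx%d @ %gm)",
                 what, nrow(a$values), ncol(a$values), a$cell_size,
                 nrow(b$values), ncol(b$values), b$cell_size), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a raster from an Esri ASCII grid file
#'
#' Plain-text single-band raster interchange: a six-line header (`ncols`,
#' `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by
#' the cell values, top row first. Integer-valued rasters round-trip
#' bit-exactly through [write_raster()].
#'
#' @param path file path.
#' @return a [land_raster()]; nodata cells are `NA`.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path, call. = FALSE)
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("not an ASCII grid (missing header fields): ", path, call. = FALSE)
  }
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  body <- scan(path, what = double(), skip = 6L, quiet = TRUE)
  if (length(body) != hdr$ncols * hdr$nrows) {
    stop(sprintf("ASCII grid body has %d values, expected %d", length(body),
                 hdr$ncols * hdr$nrows), call. = FALSE)
  }
  m <- matrix(body, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA
  land_raster(m, cell_size = hdr$cellsize, xll = hdr$xllcorner, yll = hdr$yllcorner)
}

#' Write a raster to an Esri ASCII grid file
#'
#' @param x a [land_raster()].
#' @param path output path.
#' @param nodata nodata code written for `NA` cells.
#' @return invisibly `path`.
#' @export
write_raster <- function(x, path, nodata = -9999) {
  stopifnot(is_land_raster(x))
  m <- x$values
  m[is.na(m)] <- nodata
  hdr <- c(
    paste("ncols", ncol(m)),
    paste("nrows", nrow(m)),
    paste("xllcorner", format(x$xll, scientific = FALSE)),
    paste("yllcorner", format(x$yll, scientific = FALSE)),
    paste("cellsize", format(x$cell_size, scientific = FALSE)),
    paste("NODATA_value", format(nodata, scientific = FALSE))
  )
  body <- apply(m, 1L, function(r) paste(format(r, scientific = FALSE, trim = TRUE),
                                         collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Nearest-neighbour resampling
#'
#' Resamples a raster to a new cell size by assigning each output cell the
#' value of the input cell whose centre is nearest to the output cell's centre.
#' Value-preserving: the output contains only values already present in the
#' input, which makes it the appropriate method for categorical grids (for
#' example the 990 m to 1 km step of the land system workflow).
#'
#' @param x a [land_raster()].
#' @param target_cell_size output cell size in metres (> 0).
#' @return a [land_raster()] covering the same extent at the new resolution.
#' @examples
#' r <- land_raster(matrix(1:4, 2, 2), cell_size = 990)
#' resample_nearest(r, 1000)
#' @export
resample_nearest <- function(x, target_cell_size) {
  stopifnot(is_land_raster(x))
  if (!is.numeric(target_cell_size) || length(target_cell_size) != 1L ||
      !is.finite(target_cell_size) || target_cell_size <= 0) {
    stop("`target_cell_size` must be a single positive number", call. = FALSE)
  }
  if (isTRUE(all.equal(target_cell_size, x$cell_size))) return(x)
  nr <- nrow(x$values); nc <- ncol(x$values)
  height <- nr * x$cell_size; width <- nc * x$cell_size
  nr_out <- max(1L, round(height / target_cell_size))
  nc_out <- max(1L, round(width / target_cell_size))
  # centres measured from the top-left corner; row i centre at (i - 0.5) * size
  src_row <- pmin(nr, pmax(1L, ceiling(((seq_len(nr_out) - 0.5) * target_cell_size) /
                                         x$cell_size)))
  src_col <- pmin(nc, pmax(1L, ceiling(((seq_len(nc_out) - 0.5) * target_cell_size) /
                                         x$cell_size)))
  land_raster(x$values[src_row, src_col, drop = FALSE],
              cell_size = target_cell_size, xll = x$xll, yll = x$yll,
              layer = x$layer)
}

#' Convert a raster to a tibble of cells
#'
#' One row per cell with grid indices, projected cell-centre coordinates and
#' the cell value; nodata cells can be kept or dropped. This is the bridge
#' from the matrix-backed raster to tidyverse workflows and ggplot2.
#'
#' @param x a [land_raster()].
#' @param na.rm drop nodata cells (default `FALSE`).
#' @param ... unused.
#' @return a tibble with columns `row`, `col`, `x`, `y`, `value`.
#' @method as_tibble land_raster
#' @export
as_tibble.land_raster <- function(x, ..., na.rm = FALSE) {
  nr <- nrow(x$values); nc <- ncol(x$values)
  out <- tibble::tibble(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr),
    value = as.vector(x$values)
  )
  out$x <- x$xll + (out$col - 0.5) * x$cell_size
  out$y <- x$yll + (nr - out$row + 0.5) * x$cell_size
  out <- out[, c("row", "col", "x", "y", "value")]
  if (na.rm) out <- out[!is.na(out$value), ]
  out
}

#' Plot a raster
#'
#' @param object a [land_raster()].
#' @param categorical render values as discrete classes (default guesses from
#'   the number of distinct values).
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot land_raster
#' @export
autoplot.land_raster <- function(object, categorical = NULL, ...) {
  d <- as_tibble.land_raster(object, na.rm = TRUE)
  if (is.null(categorical)) categorical <- length(unique(d$value)) <= 30
  if (categorical) d$value <- factor(d$value)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = object$layer %||% "value") +
    ggplot2::theme_minimal()
}
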