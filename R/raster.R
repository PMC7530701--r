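#' Raster: an intensity grid with metadata
#'
#' The common container for all signals in the package: a 1D numeric
#' vector or a 2D matrix of finite intensities, together with a nominal
#' value range and, optionally, the spatial resolution in pixels per
#' degree of visual angle (needed by stimuli expressed in degrees and by
#' bandpass noise in cycles per degree).
#'
#' @param values Numeric vector (1D signal) or matrix (2D image); all
#'   values must be finite and the grid non-empty.
#' @param value_range Nominal `c(lo, hi)` of the encoding (for I/O
#'   mapping); defaults to the data range.
#' @param ppd Pixels per degree of visual angle, or `NULL`.
#' @return An object of class `"inrf_raster"`.
#' @export
raster <- function(values, value_range = NULL, ppd = NULL) {
  if (is.raster_grid(values)) return(values)
  if (!is.numeric(values) || length(values) == 0L) {
    stop("raster values must be a non-empty numeric vector or matrix")
  }
  if (!all(is.finite(values))) stop("raster values must all be finite")
  if (is.null(value_range)) value_range <- range(values)
  structure(list(values = values, value_range = as.numeric(value_range),
                 ppd = ppd),
            class = "inrf_raster")
}

is.raster_grid <- function(x) inherits(x, "inrf_raster")

#' @export
print.inrf_raster <- function(x, ...) {
  d <- if (is.matrix(x$values)) paste(dim(x$values), collapse = " x ")
       else paste0(length(x$values), " (1D)")
  cat("<raster ", d, ", range [", format(x$value_range[1]), ", ",
      format(x$value_range[2]), "]",
      if (!is.null(x$ppd)) paste0(", ", format(x$ppd), " px/deg"),
      ">\n", sep = "")
  invisible(x)
}

# accept bare numerics anywhere a raster is expected
as_raster <- function(x, ...) if (is.raster_grid(x)) x else raster(x, ...)

raster_values <- function(x) if (is.raster_grid(x)) x$values else x

# carry metadata over to transformed values
raster_like <- function(values, template, value_range = NULL) {
  if (!is.raster_grid(template)) return(values)
  raster(values,
         value_range = if (is.null(value_range)) template$value_range
                       else value_range,
         ppd = template$ppd)
}

raster_ndim <- function(x) if (is.matrix(raster_values(x))) 2L else 1L

#' Read and write rasters
#'
#' 2D rasters are stored as 8- or 16-bit grayscale (or RGB) PNG with the
#' declared value range mapped linearly onto the bit depth; 1D signals
#' are stored as CSV with one `value` column.  A small YAML sidecar
#' (`<path>.meta.yaml`) preserves `value_range` and `ppd`.
#'
#' @param x A [raster()].
#' @param path Output file (`.png` or `.csv`).
#' @return `write_raster()` returns `path` invisibly; `read_raster()`
#'   returns a [raster()].
#' @export
write_raster <- function(x, path) {
  x <- as_raster(x)
  meta <- list(value_range = x$value_range, ppd = x$ppd)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    if (raster_ndim(x) != 1L) stop("CSV raster output is for 1D signals")
    utils::write.csv(data.frame(value = x$values), path, row.names = FALSE)
  } else if (grepl("\\.png$", path, ignore.case = TRUE)) {
    v <- raster_values(x)
    if (!is.matrix(v)) stop("PNG raster output is for 2D images")
    lo <- x$value_range[1]; hi <- x$value_range[2]
    u <- if (hi > lo) pmin(pmax((v - lo) / (hi - lo), 0), 1) else v * 0
    png::writePNG(u, path)
  } else {
    stop("unsupported raster format: ", path)
  }
  writeLines(yaml::as.yaml(meta), paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  meta_path <- paste0(path, ".meta.yaml")
  meta <- if (file.exists(meta_path)) yaml::yaml.load_file(meta_path) else list()
  vr <- if (!is.null(meta$value_range)) as.numeric(meta$value_range) else c(0, 1)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    v <- utils::read.csv(path)$value
    return(raster(v, value_range = vr, ppd = meta$ppd))
  }
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    u <- png::readPNG(path)
    if (length(dim(u)) == 3L) u <- u[, , 1]
    v <- vr[1] + u * (vr[2] - vr[1])
    return(raster(v, value_range = vr, ppd = meta$ppd))
  }
  stop("unsupported raster format: ", path)
}

#' Read an sRGB image file
#'
#' Reads an 8/16-bit sRGB PNG (or TIFF, if the tiff package is
#' installed) into an H x W x 3 array of display values in `[0, 1]`.
#' Grayscale files are expanded to three equal channels.
#'
#' @param path Image file.
#' @return Numeric array `c(height, width, 3)` in `[0, 1]`.
#' @export
read_srgb <- function(path) {
  img <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF requires the 'tiff' package")
    }
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 2L) {
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  }
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE] # drop alpha
  img
}
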