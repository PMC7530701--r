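#' Declarative kernel specification
#'
#' Describes one of the spatial summation kernels (`m`, `w`, `g`) of the
#' receptive-field models in this package without committing to a grid.
#' A spec is realized into a discrete, centered, odd-extent grid with
#' [realize_kernel()].
#'
#' Supported kinds:
#' \describe{
#'   \item{`delta`}{Dirac delta: a single 1 at the center sample.}
#'   \item{`box`}{constant kernel of extent `size_px`, each entry `1/size`
#'     in 1D (`1/size^2` in 2D).}
#'   \item{`gaussian`}{isotropic Gaussian of standard deviation `sigma_px`
#'     pixels, truncated at four standard deviations and renormalized.}
#'   \item{`dog`}{difference of Gaussians: narrow minus wide, each
#'     component individually normalized before subtraction;
#'     `sigma_px` is `c(narrow, wide)`.}
#'   \item{`constant_full`}{a box spanning the whole signal; `size_px` may
#'     be left `NULL` and is then resolved to the signal extent when the
#'     kernel is applied.}
#'   \item{`custom`}{an explicit centered grid supplied in `grid` (vector
#'     or matrix of odd extent); used e.g. for kernels produced by
#'     [reduce_to_linear()] or learned by the network layer.}
#' }
#'
#' @param kind One of `"delta"`, `"box"`, `"gaussian"`, `"dog"`,
#'   `"constant_full"`, `"custom"`.
#' @param size_px Integer extent for `box` (and optionally
#'   `constant_full`).  Even extents are rounded up to the next odd
#'   integer with a warning so the kernel can be centered.
#' @param sigma_px Positive standard deviation in pixels for `gaussian`,
#'   or a pair `c(narrow, wide)` for `dog`.
#' @param normalize Should the realized kernel sum to one?  Defaults to
#'   `TRUE` for `delta`, `box`, `gaussian` and `constant_full`; ignored
#'   for `dog` (whose components are normalized individually) and
#'   `custom`.
#' @param grid Explicit grid for `kind = "custom"`.
#' @return An object of class `"kernel_spec"`.
#' @seealso [realize_kernel()], [sigma_spec()]
#' @export
#' @examples
#' kernel_spec("box", size_px = 85)
#' kernel_spec("gaussian", sigma_px = 52)
#' kernel_spec("dog", sigma_px = c(30, 60))
kernel_spec <- function(kind = c("delta", "box", "gaussian", "dog",
                                 "constant_full", "custom"),
                        size_px = NULL, sigma_px = NULL, normalize = TRUE,
                        grid = NULL) {
  kind <- match.arg(kind)
  if (kind == "box") {
    if (is.null(size_px) || size_px < 1) {
      stop("invalid kernel spec: box kernel needs a positive 'size_px'")
    }
  }
  if (kind == "gaussian") {
    if (is.null(sigma_px) || length(sigma_px) != 1L || sigma_px <= 0) {
      stop("invalid kernel spec: gaussian kernel needs one positive 'sigma_px'")
    }
  }
  if (kind == "dog") {
    if (is.null(sigma_px) || length(sigma_px) != 2L || any(sigma_px <= 0)) {
      stop("invalid kernel spec: dog kernel needs sigma_px = c(narrow, wide) > 0")
    }
    if (sigma_px[1] >= sigma_px[2]) {
      stop("invalid kernel spec: dog narrow sigma must be smaller than wide sigma")
    }
  }
  if (kind == "custom") {
    if (is.null(grid)) stop("invalid kernel spec: custom kernel needs 'grid'")
    if (any(dim(as.matrix(grid)) %% 2L == 0L) && is.matrix(grid)) {
      stop("invalid kernel spec: custom grid must have odd extents")
    }
    if (!is.matrix(grid) && length(grid) %% 2L == 0L) {
      stop("invalid kernel spec: custom grid must have odd extent")
    }
  }
  structure(list(kind = kind, size_px = size_px, sigma_px = sigma_px,
                 normalize = isTRUE(normalize), grid = grid),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  extras <- c(
    if (!is.null(x$size_px)) paste0("size ", x$size_px, " px"),
    if (!is.null(x$sigma_px)) paste0("sigma ", paste(x$sigma_px, collapse = "/"),
                                     " px"),
    if (!x$normalize) "unnormalized")
  cat("<kernel_spec ", x$kind,
      if (length(extras)) paste0(": ", paste(extras, collapse = ", ")),
      ">\n", sep = "")
  invisible(x)
}

# round an even requested extent up to the next odd integer
odd_extent <- function(size, warn = TRUE) {
  size <- as.integer(size)
  if (size %% 2L == 0L) {
    if (warn) {
      warning("even kernel extent ", size, " rounded up to ", size + 1L,
              " so the kernel can be centered", call. = FALSE)
    }
    size <- size + 1L
  }
  size
}

# 1D normalized gaussian, truncated at +-4 sigma
gaussian_taps <- function(sigma) {
  r <- as.integer(ceiling(4 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

#' Realize a kernel spec on a discrete grid
#'
#' Turns a [kernel_spec()] into a centered grid of odd extent: a numeric
#' vector for `ndim = 1` or a matrix for `ndim = 2`.  Gaussians are
#' truncated at four standard deviations and renormalized, so normalized
#' kernels sum to one up to floating-point rounding.  Realization is
#' deterministic: equal specs give bitwise-equal grids.
#'
#' @param spec A [kernel_spec()].
#' @param ndim Dimensionality of the signal the kernel will be applied
#'   to (1 or 2).
#' @param extent Signal extent used to resolve `constant_full` kernels
#'   whose `size_px` is `NULL`.
#' @return Numeric vector (1D) or matrix (2D) of kernel weights.
#' @export
#' @examples
#' realize_kernel(kernel_spec("box", size_px = 85), 1)[1]  # 1/85
#' sum(realize_kernel(kernel_spec("gaussian", sigma_px = 3), 2))  # 1
realize_kernel <- function(spec, ndim = 1, extent = NULL) {
  stopifnot(inherits(spec, "kernel_spec"), ndim %in% c(1L, 2L))
  taps1 <- function() {
    switch(spec$kind,
      delta = 1.0,
      box = {
        s <- odd_extent(spec$size_px)
        rep(if (spec$normalize) 1 / s else 1, s)
      },
      gaussian = {
        k <- gaussian_taps(spec$sigma_px)
        if (spec$normalize) k else k * sum(k) # already normalized
      },
      constant_full = {
        size <- spec$size_px
        if (is.null(size)) {
          if (is.null(extent)) {
            stop("constant_full kernel needs 'extent' (or an explicit size_px)")
          }
          # auto-resolution silently picks the next odd extent
          size <- if (extent %% 2L == 0L) extent + 1L else extent
        } else {
          size <- odd_extent(size)
        }
        rep(if (spec$normalize) 1 / size else 1, size)
      },
      stop("kernel kind '", spec$kind, "' has no 1D tap form"))
  }
  if (spec$kind == "custom") {
    g <- spec$grid
    if (ndim == 1L) {
      if (is.matrix(g)) stop("custom 2D grid used where a 1D kernel is required")
      return(as.numeric(g))
    }
    if (!is.matrix(g)) stop("custom 1D grid used where a 2D kernel is required")
    return(g)
  }
  if (spec$kind == "dog") {
    kn <- gaussian_taps(spec$sigma_px[1])
    kw <- gaussian_taps(spec$sigma_px[2])
    r <- (length(kw) - 1L) / 2L
    pad <- function(k) {
      d <- r - (length(k) - 1L) / 2L
      c(rep(0, d), k, rep(0, d))
    }
    if (ndim == 1L) return(pad(kn) - kw)
    return(outer(pad(kn), pad(kn)) - outer(kw, kw))
  }
  k1 <- taps1()
  if (ndim == 1L) k1 else outer(k1, k1)
}

# 1D taps + metadata for the separable fast path; NULL if not separable
separable_taps <- function(spec, extent = NULL) {
  if (!inherits(spec, "kernel_spec")) stop("expected a kernel_spec")
  if (spec$kind %in% c("delta", "box", "gaussian", "constant_full")) {
    realize_kernel(spec, 1L, extent = extent)
  } else {
    NULL
  }
}

#' Serialize and deserialize specs as structured text
#'
#' Kernel and nonlinearity specs round-trip through a YAML `key: value`
#' block, so model configurations can be stored alongside experiment
#' outputs.
#'
#' @param spec A [kernel_spec()] or [sigma_spec()].
#' @param text A character scalar produced by `spec_to_text()`.
#' @return `spec_to_text()` returns a character scalar;
#'   `spec_from_text()` returns the reconstructed spec object.
#' @export
spec_to_text <- function(spec) {
  stopifnot(inherits(spec, c("kernel_spec", "sigma_spec")))
  fields <- spec[!vapply(spec, is.null, logical(1))]
  if (!is.null(fields$grid)) fields$grid <- as.numeric(fields$grid)
  fields$.class <- class(spec)[1]
  yaml::as.yaml(fields)
}

#' @rdname spec_to_text
#' @export
spec_from_text <- function(text) {
  fields <- yaml::yaml.load(text)
  cls <- fields$.class
  fields$.class <- NULL
  if (identical(cls, "kernel_spec")) {
    do.call(kernel_spec, c(fields["kind"],
                           fields[setdiff(names(fields), "kind")]))
  } else if (identical(cls, "sigma_spec")) {
    do.call(sigma_spec, fields)
  } else {
    stop("unrecognized spec text (missing or unknown .class field)")
  }
}
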