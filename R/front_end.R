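#' Naka-Rushton photoreceptor response
#'
#' Saturating response `L^n / (L^n + S^n)` mapping nonnegative
#' luminances into `[0, 1)`.  `L = S` gives 0.5 for any exponent.
#'
#' @param L A [raster()] or numeric of nonnegative luminances.
#' @param S Positive semisaturation constant (same units as `L`).
#' @param n Positive exponent.
#' @return Responses in `[0, 1)`, same shape/class as the input.
#' @export
#' @examples
#' naka_rushton(0.18, S = 0.18, n = 1)  # 0.5
naka_rushton <- function(L, S, n = 1) {
  if (!is.numeric(S) || length(S) != 1L || S <= 0) {
    stop("'S' must be a positive scalar")
  }
  v <- raster_values(as_raster(L))
  if (any(v < 0)) stop("luminances must be nonnegative")
  out <- v^n / (v^n + S^n)
  raster_like(out, L, value_range = c(0, 1))
}

#' Semisaturation constant for the brightness-scaling experiment
#'
#' Luminance-adaptation rule mapping the mean luminance `b_k` of a
#' display (cd/m^2) to the Naka-Rushton semisaturation used when
#' modelling perceptual linearisation:
#' `S = 0.5 * 18 + 0.5 * 10^(0.63 * log10(b_k) + 1)`.
#'
#' @param b_k Positive mean luminance(s) in cd/m^2.
#' @return Semisaturation constant(s) `S` in cd/m^2.
#' @export
#' @examples
#' crispening_semisaturation(1)  # 14
crispening_semisaturation <- function(b_k) {
  if (any(b_k <= 0)) stop("'b_k' must be positive")
  0.5 * 18 + 0.5 * 10^(0.63 * log10(b_k) + 1)
}

#' CIELAB lightness from an sRGB image
#'
#' Standard colorimetric path: sRGB display values are linearized
#' (IEC 61966-2-1), luminance Y is taken against the D65 white of the
#' sRGB standard, and lightness is `L* = 116 f(Y/Yn) - 16`.  This plays
#' the role of the photoreceptor nonlinearity when the model is applied
#' to natural images.
#'
#' @param img `H x W x 3` array of sRGB display values in `[0, 1]`
#'   (as returned by [read_srgb()]), or integer values in `[0, 255]`.
#' @return A [raster()] of `L*` in `[0, 100]`.
#' @export
srgb_to_lightness <- function(img) {
  if (length(dim(img)) != 3L || dim(img)[3] != 3L) {
    stop("'img' must be an H x W x 3 sRGB array")
  }
  if (max(img) > 1) img <- img / 255
  lin <- ifelse(img <= 0.04045, img / 12.92, ((img + 0.055) / 1.055)^2.4)
  # luminance row of the sRGB -> XYZ (D65) matrix
  Y <- 0.2126729 * lin[, , 1] + 0.7151522 * lin[, , 2] +
       0.0721750 * lin[, , 3]
  f <- ifelse(Y > (6 / 29)^3, Y^(1 / 3), Y / (3 * (6 / 29)^2) + 4 / 29)
  raster(116 * f - 16, value_range = c(0, 100))
}

#' Power-law intensity transform
#'
#' Elementwise `v^gamma` for nonnegative signals; used to linearize
#' gamma-corrected stimulus values before the model.
#'
#' @param v A [raster()] or numeric, nonnegative.
#' @param gamma Positive exponent (default 2.2, the usual display
#'   gamma; the experiments that use it expose it as a config value).
#' @return Transformed values, same shape/class as the input.
#' @export
power_law <- function(v, gamma = 2.2) {
  if (gamma <= 0) stop("'gamma' must be positive")
  x <- raster_values(as_raster(v))
  if (any(x < 0)) stop("power-law input must be nonnegative")
  raster_like(x^gamma, v, value_range = range(x^gamma))
}

#' Gaussian retinal blur
#'
#' Convolution with a normalized Gaussian of standard deviation
#' `sigma_px` pixels (mirror boundary); `sigma_px = 0` is the identity.
#'
#' @param I A [raster()] or numeric vector/matrix.
#' @param sigma_px Nonnegative standard deviation in pixels.
#' @param boundary Boundary policy.
#' @return Blurred signal, same shape/class as the input.
#' @export
retinal_blur <- function(I, sigma_px, boundary = "mirror") {
  if (sigma_px < 0) stop("'sigma_px' must be nonnegative")
  if (sigma_px == 0) return(I)
  lrf_apply(I, kernel_spec("gaussian", sigma_px = sigma_px), boundary)
}
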