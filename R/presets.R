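#' Parameter presets for the vision-science experiments
#'
#' Ready-made [inrf_params()] / [lnl_params()] objects for the four
#' experiment pipelines.  Except for the ON/OFF cell simulation, all
#' INRF instances share one parameter set: Gaussian `m` (0.81 degrees of
#' visual angle), Gaussian `w` (2.77 degrees), delta `g`,
#' `lambda = 3.875`, and the asymmetric power nonlinearity with
#' exponents 0.625 (positive branch) and 0.775 (negative branch).  The
#' presets differ only in the pixel scale of the display they model.
#'
#' * `onoff_inrf_params()`: box `m` and `g` of width 85 (value 1/85),
#'   full-signal constant `w` (width equal to the 512-sample stimulus),
#'   `lambda = 1000` and the piecewise sinusoid nonlinearity.
#' * `inrf_b_params()`: the brightness model (INRF-B) at the
#'   brightness-scaling display resolution of 64 px/deg: `m` sigma 52 px,
#'   `w` sigma 178 px.  Also used by the image-quality metric.
#' * `white_inrf_params(ppd)`: the same model in degrees, realized at
#'   `ppd` pixels per degree (sigmas 0.81 and 2.745 degrees, the pixel
#'   values 54 and 183 at the source display's 66.7 px/deg).
#' * `irradiation_inrf_params()`: `m` sigma 100, `w` sigma 342 (pixel
#'   units of the 1024-sample step signal).
#' * `lnl_uniform_params()` / `lnl_saltpepper_params()`: the L+NL
#'   baseline fitted separately to the uniform-background and
#'   salt-and-pepper brightness data (DoG sigmas 30/60 px, lambda 2,
#'   exponents 0.5/0.7; and DoG 40/50 px, lambda 10, exponents 0.9/0.9).
#'
#' @param ppd Pixels per degree at which to realize the kernels.
#' @return An [inrf_params()] or [lnl_params()] object.
#' @name presets
NULL

#' @rdname presets
#' @export
onoff_inrf_params <- function() {
  inrf_params(
    m = kernel_spec("box", size_px = 85),
    w = kernel_spec("constant_full"),
    g = kernel_spec("box", size_px = 85),
    lambda = 1000,
    sigma = sigma_spec("piecewise_sinusoid"),
    boundary = "mirror")
}

#' @rdname presets
#' @export
inrf_b_params <- function() {
  inrf_params(
    m = kernel_spec("gaussian", sigma_px = 52),
    w = kernel_spec("gaussian", sigma_px = 178),
    g = kernel_spec("delta"),
    lambda = 3.875,
    sigma = sigma_spec("asymmetric_power", p = 0.625, q = 0.775),
    boundary = "mirror")
}

#' @rdname presets
#' @export
white_inrf_params <- function(ppd = 24) {
  inrf_params(
    m = kernel_spec("gaussian", sigma_px = 0.81 * ppd),
    w = kernel_spec("gaussian", sigma_px = 2.745 * ppd),
    g = kernel_spec("delta"),
    lambda = 3.875,
    sigma = sigma_spec("asymmetric_power", p = 0.625, q = 0.775),
    boundary = "mirror")
}

#' @rdname presets
#' @export
irradiation_inrf_params <- function() {
  inrf_params(
    m = kernel_spec("gaussian", sigma_px = 100),
    w = kernel_spec("gaussian", sigma_px = 342),
    g = kernel_spec("delta"),
    lambda = 3.875,
    sigma = sigma_spec("asymmetric_power", p = 0.625, q = 0.775),
    boundary = "mirror")
}

#' @rdname presets
#' @export
lnl_uniform_params <- function() {
  lnl_params(
    m = kernel_spec("gaussian", sigma_px = 52),
    dog = kernel_spec("dog", sigma_px = c(30, 60)),
    lambda = 2,
    sigma = sigma_spec("asymmetric_power", p = 0.5, q = 0.7),
    boundary = "mirror")
}

#' @rdname presets
#' @export
lnl_saltpepper_params <- function() {
  lnl_params(
    m = kernel_spec("gaussian", sigma_px = 52),
    dog = kernel_spec("dog", sigma_px = c(40, 50)),
    lambda = 10,
    sigma = sigma_spec("asymmetric_power", p = 0.9, q = 0.9),
    boundary = "mirror")
}
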