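# Display black and white of the calibrated monitor the brightness
# experiments model (cd/m^2).
DISPLAY_BLACK <- 0.65
DISPLAY_WHITE <- 75

#' 1D ON/OFF bar stimulus
#'
#' A 512-sample signal in `[0, 1]`: an alternating black/white
#' square-wave background of bar width `b` (a white bar starts at the
#' first sample) whose central `center_width` samples are replaced by a
#' test segment of value `u`.  No retinal blur is applied here.
#'
#' @param b Bar width in samples; must be below half the signal width.
#' @param u Test-segment value in `[0, 1]`.
#' @param total_width,center_width Signal and test-segment extents.
#' @return A [raster()] holding the 1D signal.
#' @export
make_onoff_stimulus <- function(b, u, total_width = 512, center_width = 64) {
  if (b >= total_width / 2) {
    stop("bar width ", b, " leaves no alternation in a ", total_width,
         "-sample signal")
  }
  if (u < 0 || u > 1) stop("'u' must be in [0, 1]")
  if (center_width >= total_width) {
    stop("center segment must be narrower than the signal")
  }
  phase <- ((seq_len(total_width) - 1L) %/% b) %% 2L
  sig <- ifelse(phase == 0L, 1, 0) # white bar first
  off <- (total_width - center_width) %/% 2L
  sig[(off + 1L):(off + center_width)] <- u
  raster(sig, value_range = c(0, 1))
}

#' Brightness-scaling display
#'
#' The stimulus of the perceptual linearisation experiment: eleven
#' uniform circles of 1 degree diameter on the horizontal meridian of a
#' 1280 x 960 monitor (64 px/deg), over either a uniform background of
#' a given luminance or a salt-and-pepper background in which every
#' pixel is independently display black (0.65 cd/m^2) with the given
#' fraction, otherwise display white (75 cd/m^2).
#'
#' Eleven 64 px circles with full 1-degree gaps would span 1344 px and
#' cannot fit the 1280 px monitor; the circle centers are therefore
#' placed evenly across the canvas with a 32 px margin (center spacing
#' about 1.8 degrees), which keeps each probe isolated well beyond the
#' `m` kernel radius.
#'
#' @param background `"uniform"` or `"salt_pepper"`.
#' @param background_level Uniform luminance in cd/m^2, or the black
#'   pixel fraction in `[0, 1]` for salt-and-pepper.
#' @param circle_luminances Eleven circle luminances in cd/m^2;
#'   defaults to a linear probe scale from display black to white.
#' @param circle_diameter_px,canvas Geometry (pixels; canvas is
#'   `c(height, width)`).
#' @param seed Integer seed for the salt-and-pepper draw.
#' @return A list of class `"brightness_display"`: `image` ([raster()]),
#'   `centers` (11 x 2 matrix of row/col), `circle_luminances`,
#'   `background`, `background_level`.
#' @export
make_brightness_display <- function(background = c("uniform", "salt_pepper"),
                                    background_level,
                                    circle_luminances =
                                      seq(DISPLAY_BLACK, DISPLAY_WHITE,
                                          length.out = 11),
                                    circle_diameter_px = 64,
                                    canvas = c(960, 1280),
                                    seed = 1L) {
  background <- match.arg(background)
  if (length(circle_luminances) != 11L) {
    stop("the display carries exactly eleven circles")
  }
  if (any(circle_luminances < DISPLAY_BLACK - 1e-9) ||
      any(circle_luminances > DISPLAY_WHITE + 1e-9)) {
    stop("circle luminances must lie within the display range [",
         DISPLAY_BLACK, ", ", DISPLAY_WHITE, "] cd/m^2")
  }
  h <- canvas[1]; wdt <- canvas[2]
  r <- circle_diameter_px / 2
  bg <- if (background == "uniform") {
    if (background_level < DISPLAY_BLACK - 1e-9 ||
        background_level > DISPLAY_WHITE + 1e-9) {
      stop("uniform background level outside the display range")
    }
    matrix(background_level, h, wdt)
  } else {
    f <- background_level
    if (f < 0 || f > 1) stop("salt-and-pepper black fraction must be in [0, 1]")
    with_local_seed(seed, {
      matrix(ifelse(stats::runif(h * wdt) < f, DISPLAY_BLACK, DISPLAY_WHITE),
             h, wdt)
    })
  }
  margin <- 32
  cx <- round(seq(margin + r, wdt - margin - r, length.out = 11))
  cy <- rep(round(h / 2), 11)
  if (any(cx - r < 1) || any(cx + r > wdt)) stop("circle layout exceeds canvas")
  if (any(diff(cx) < circle_diameter_px)) stop("circles overlap")
  col_idx <- matrix(rep(seq_len(wdt), each = h), h, wdt)
  row_idx <- matrix(rep(seq_len(h), wdt), h, wdt)
  img <- bg
  for (k in seq_len(11)) {
    disk <- (row_idx - cy[k])^2 + (col_idx - cx[k])^2 <= r^2
    img[disk] <- circle_luminances[k]
  }
  structure(list(
    image = raster(img, value_range = c(DISPLAY_BLACK, DISPLAY_WHITE),
                   ppd = 64),
    centers = cbind(row = cy, col = cx),
    circle_luminances = circle_luminances,
    background = background,
    background_level = background_level), class = "brightness_display")
}

#' White's illusion stimulus
#'
#' A vertical square-wave grating with two identical gray test patches,
#' one riding on a dark bar and one on a light bar (each one bar wide
#' and two bars tall, vertically centered).  Optional isotropic
#' bandpass noise is added with [add_bandpass_noise()].  The grating
#' geometry is a declared convention of this package: `n_bars` bars of
#' `bar_width_px` pixels at `ppd` pixels per degree.
#'
#' @param bar_width_px Bar width in pixels.
#' @param n_bars Number of bars (the canvas is square with side
#'   `n_bars * bar_width_px`).
#' @param test_gray Gray value of both test patches (same units as the
#'   bars, which are 0 and 1).
#' @param ppd Pixels per degree of visual angle.
#' @param noise_freq_cpd Center frequency of the added noise band in
#'   cycles per degree, or `NULL` for the noise-free stimulus.
#' @param noise_rms Root-mean-square contrast of the added noise.
#' @param seed Integer seed for the noise draw.
#' @return A list of class `"white_stimulus"`: `image` ([raster()]),
#'   logical patch masks `patch_dark` / `patch_light` (the patch on the
#'   dark and on the light bar), and the configuration fields.
#' @export
make_white_stimulus <- function(bar_width_px = 24, n_bars = 8,
                                test_gray = 0.5, ppd = 24,
                                noise_freq_cpd = NULL, noise_rms = 0.2,
                                seed = 1L) {
  side <- bar_width_px * n_bars
  bar_of_col <- ((seq_len(side) - 1L) %/% bar_width_px) %% 2L
  img <- matrix(rep(ifelse(bar_of_col == 0L, 0, 1), each = side), side, side)
  # patches on the two central bars of opposite polarity
  dark_bar <- which(bar_of_col == 0L)
  light_bar <- which(bar_of_col == 1L)
  mid_bar <- function(cols) {
    bars <- unique((cols - 1L) %/% bar_width_px)
    b <- bars[ceiling(length(bars) / 2)]
    (b * bar_width_px + 1L):((b + 1L) * bar_width_px)
  }
  pc_dark <- mid_bar(dark_bar)
  pc_light <- mid_bar(light_bar)
  ph <- 2L * bar_width_px
  pr <- (round(side / 2) - ph %/% 2L + 1L):(round(side / 2) + ph %/% 2L)
  if (max(pr) > side || min(pr) < 1) stop("test patch outside canvas")
  mask <- function(rows, cols) {
    m <- matrix(FALSE, side, side)
    m[rows, cols] <- TRUE
    m
  }
  patch_dark <- mask(pr, pc_dark)
  patch_light <- mask(pr, pc_light)
  img[patch_dark] <- test_gray
  img[patch_light] <- test_gray
  out <- raster(img, value_range = c(0, 1), ppd = ppd)
  if (!is.null(noise_freq_cpd)) {
    out <- add_bandpass_noise(out, noise_freq_cpd, noise_rms, seed = seed)
  }
  structure(list(image = out, patch_dark = patch_dark,
                 patch_light = patch_light, bar_width_px = bar_width_px,
                 n_bars = n_bars, test_gray = test_gray, ppd = ppd,
                 noise_freq_cpd = noise_freq_cpd, noise_rms = noise_rms,
                 seed = seed), class = "white_stimulus")
}

#' Add isotropic bandpass noise to an image
#'
#' Draws white Gaussian noise, keeps an annular frequency band of one
#' octave full width centered at `center_freq_cpd` (cycles per degree),
#' rescales the result to the requested root-mean-square value with
#' exactly zero mean, and adds it to the image.
#'
#' @param I A 2D [raster()] with `ppd` set.
#' @param center_freq_cpd Band center in cycles/degree (must be below
#'   the Nyquist frequency `ppd / 2`).
#' @param rms Noise root-mean-square; 0 returns the input unchanged.
#' @param seed Integer seed.
#' @return A [raster()] with the noisy image.
#' @export
add_bandpass_noise <- function(I, center_freq_cpd, rms, seed = 1L) {
  x <- as_raster(I)
  if (is.null(x$ppd)) stop("bandpass noise needs 'ppd' on the raster")
  if (rms == 0) return(x)
  v <- raster_values(x)
  if (!is.matrix(v)) stop("bandpass noise is defined for 2D rasters")
  if (center_freq_cpd >= x$ppd / 2) {
    stop("band center ", center_freq_cpd, " c/deg is at or above Nyquist (",
         x$ppd / 2, " c/deg)")
  }
  h <- nrow(v); wdt <- ncol(v)
  n <- with_local_seed(seed, matrix(stats::rnorm(h * wdt), h, wdt))
  freq_axis <- function(n) {
    f <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1) / n
    f[seq_len(n)]
  }
  fr <- freq_axis(h) * x$ppd  # cycles per degree
  fc <- freq_axis(wdt) * x$ppd
  rad <- sqrt(outer(fr^2, fc^2, `+`))
  band <- rad >= center_freq_cpd / sqrt(2) & rad <= center_freq_cpd * sqrt(2)
  if (!any(band)) stop("noise band is empty at this resolution")
  NF <- stats::fft(n) * band
  nb <- Re(stats::fft(NF, inverse = TRUE)) / (h * wdt)
  nb <- nb - mean(nb)
  nb <- nb * (rms / sqrt(mean(nb^2)))
  raster(v + nb, value_range = x$value_range, ppd = x$ppd)
}

#' 1D irradiation step stimulus
#'
#' A 1024-sample binary signal with a central step of width 400: a
#' white step on black ground, or its complement.
#'
#' @param polarity `"white_on_black"` or `"black_on_white"`.
#' @param total_width,step_width Signal and step extents in samples.
#' @return A [raster()] holding the 1D signal.
#' @export
make_irradiation_signal <- function(polarity = c("white_on_black",
                                                 "black_on_white"),
                                    total_width = 1024, step_width = 400) {
  polarity <- match.arg(polarity)
  sig <- numeric(total_width)
  off <- (total_width - step_width) %/% 2L
  sig[(off + 1L):(off + step_width)] <- 1
  if (polarity == "black_on_white") sig <- 1 - sig
  raster(sig, value_range = c(0, 1))
}
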