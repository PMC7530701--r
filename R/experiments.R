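#' ON/OFF polarity-reversal experiment
#'
#' Simulates a cell whose receptive field stays fixed while the
#' stimulus spatial frequency changes.  For each test value `u` the 1D
#' bar stimulus is built ([make_onoff_stimulus()]), blurred with a
#' Gaussian of standard deviation `blur_sigma` to emulate retinal
#' optics, the INRF is evaluated at the center sample, and the result
#' is half-wave rectified, giving the cell response `v`.  At low
#' spatial frequency (large `b`) the fixed model responds only to test
#' values below the 0.5 background average (OFF behaviour); at high
#' spatial frequency the same model responds only above it (ON).
#'
#' @param b Background bar width in samples.
#' @param u_grid Test values to sweep.
#' @param blur_sigma Retinal blur standard deviation in samples.
#' @param params The INRF to apply; defaults to [onoff_inrf_params()].
#' @return A data frame of class `"response_curve"` with columns `u`
#'   and `v` (rectified center response), and attribute `b`.
#' @export
run_onoff <- function(b, u_grid = seq(0, 1, by = 0.01), blur_sigma = 4,
                      params = onoff_inrf_params()) {
  v <- vapply(u_grid, function(u) {
    stim <- make_onoff_stimulus(b, u)
    blurred <- retinal_blur(stim, blur_sigma, boundary = params$boundary)
    n <- length(raster_values(stim))
    # even signal and segment widths leave no single centered sample;
    # the center-region response averages the two central outputs
    max(0, mean(inrf_points(blurred, params, c(n %/% 2L, n %/% 2L + 1L))))
  }, numeric(1))
  structure(data.frame(u = u_grid, v = v), b = b, class = c("response_curve",
                                                            "data.frame"))
}

#' Locate the response transition of an ON/OFF curve
#'
#' Finds where the rectified response of a [run_onoff()] curve switches
#' between positive and zero, reporting the midpoint of the bracketing
#' grid step.  The cell polarity is detected from which end of the
#' sweep responds: OFF cells respond at low `u`, ON cells at high `u`.
#'
#' @param curve A `"response_curve"` from [run_onoff()].
#' @param zero_tol Responses at or below this value count as zero.
#' @return List with `transition` (test value) and `polarity`
#'   (`"off"` or `"on"`).
#' @export
onoff_transition <- function(curve, zero_tol = 1e-9) {
  act <- curve$v > zero_tol
  if (!any(act) || all(act)) {
    stop("response curve shows no transition over the sweep")
  }
  if (act[1]) {
    i <- max(which(act)) # OFF: last responsive u
    if (i == nrow(curve)) stop("no zero segment after the responsive range")
    list(transition = mean(curve$u[c(i, i + 1L)]), polarity = "off")
  } else {
    i <- min(which(act)) # ON: first responsive u
    list(transition = mean(curve$u[c(i - 1L, i)]), polarity = "on")
  }
}

# mean photoreceptor response of the surround pixels
surround_response_mean <- function(display, S, n = 0.74) {
  nr <- function(L) as.numeric(naka_rushton(L, S = S, n = n))
  if (display$background == "uniform") {
    nr(display$background_level)
  } else {
    f <- display$background_level
    f * nr(DISPLAY_BLACK) + (1 - f) * nr(DISPLAY_WHITE)
  }
}

#' Brightness-scaling (crispening) experiment
#'
#' For each background, builds the eleven-circle display
#' ([make_brightness_display()]), applies the Naka-Rushton front end
#' (exponent 0.74, semisaturation from the display mean via
#' [crispening_semisaturation()]), runs the selected model, and reads
#' the output at the eleven circle centers.  Because only those eleven
#' values enter the brightness curve, the models are evaluated at the
#' probe centers with the literal summation ([inrf_points()]).
#'
#' @param model `"inrf_b"` (the INRF brightness model),
#'   `"lnl_uniform_fit"` or `"lnl_saltpepper_fit"` (the L+NL baseline
#'   with the parameters fitted to either background condition).
#' @param backgrounds A list; each element is `list(kind, level)` with
#'   `kind` `"uniform"` (level in cd/m^2) or `"salt_pepper"` (level =
#'   black pixel fraction).  Defaults to the five uniform levels of the
#'   psychophysical experiment.
#' @param seed Seed for salt-and-pepper draws.
#' @return A list of `"brightness_curve"` objects: data frames with
#'   columns `L` (circle luminance, cd/m^2) and `O` (model output at
#'   the circle center), with background metadata attributes.
#' @export
run_crispening <- function(model = c("inrf_b", "lnl_uniform_fit",
                                     "lnl_saltpepper_fit"),
                           backgrounds = uniform_backgrounds(),
                           seed = 1L) {
  model <- match.arg(model)
  lapply(seq_along(backgrounds), function(i) {
    bgr <- backgrounds[[i]]
    disp <- make_brightness_display(background = bgr$kind,
                                    background_level = bgr$level,
                                    seed = derive_seed(seed, i))
    L <- raster_values(disp$image)
    S <- crispening_semisaturation(mean(L))
    Ik <- naka_rushton(raster(L, ppd = disp$image$ppd), S = S, n = 0.74)
    O <- switch(model,
      inrf_b = inrf_points(Ik, inrf_b_params(), disp$centers),
      lnl_uniform_fit = lnl_points(Ik, lnl_uniform_params(), disp$centers),
      lnl_saltpepper_fit = lnl_points(Ik, lnl_saltpepper_params(),
                                      disp$centers))
    v <- as.numeric(naka_rushton(disp$circle_luminances, S = S, n = 0.74))
    structure(data.frame(L = disp$circle_luminances, v = v, O = O),
              background = bgr$kind, background_level = bgr$level,
              background_mean = mean(L), front_S = S, front_n = 0.74,
              surround_response = surround_response_mean(disp, S),
              class = c("brightness_curve", "data.frame"))
  })
}

#' Adaptation level of a brightness curve's surround
#'
#' The luminance at which the photoreceptor response equals the mean
#' response of the surround pixels.  For a uniform background this is
#' exactly the background luminance; for a salt-and-pepper background
#' it is the luminance equivalent of the mixed black/white response
#' (below the mean luminance, because the photoreceptor response is
#' concave).  Crispening, where present, is anchored at this level.
#'
#' @param curve A `"brightness_curve"` from [run_crispening()].
#' @return Adaptation luminance in cd/m^2.
#' @export
adaptation_level <- function(curve) {
  v <- attr(curve, "surround_response")
  S <- attr(curve, "front_S"); n <- attr(curve, "front_n")
  if (is.null(v) || is.null(S)) {
    stop("curve carries no front-end metadata")
  }
  S * (v / (1 - v))^(1 / n)
}

#' Background sets for the crispening experiment
#'
#' `uniform_backgrounds()` returns the five uniform luminance levels of
#' the psychophysical experiment; `saltpepper_backgrounds()` the
#' salt-and-pepper black fractions.  The fractions 0.75, 0.5 and 0.25
#' have mean luminances matching the middle three uniform levels
#' (19.24, 37.83, 56.41 cd/m^2); fractions 0 and 1 are degenerate
#' (they *are* uniform displays at 75 and 0.65 cd/m^2).
#'
#' @param include_degenerate Include the all-white (0) and all-black
#'   (1) fractions.
#' @return A list of `list(kind, level)` background descriptors.
#' @export
uniform_backgrounds <- function() {
  lapply(c(0.65, 19.24, 37.83, 56.41, 75.00),
         function(l) list(kind = "uniform", level = l))
}

#' @rdname uniform_backgrounds
#' @export
saltpepper_backgrounds <- function(include_degenerate = FALSE) {
  f <- if (include_degenerate) c(0, 0.25, 0.5, 0.75, 1) else c(0.25, 0.5, 0.75)
  lapply(f, function(l) list(kind = "salt_pepper", level = l))
}

#' Slope-peak statistic of a brightness curve
#'
#' Quantifies crispening: computes finite-difference slopes of the
#' curve (centered differences at interior probes, one-sided at the
#' ends), and reports where the slope peaks and how pronounced the peak
#' is relative to the median slope.
#'
#' When the curve carries a photoreceptor-response column `v` (as
#' curves from [run_crispening()] do), slopes are taken with respect to
#' that axis: the front end is shared by all models and backgrounds,
#' and the physical luminance axis is so compressive at the dark end
#' that its discretized slopes are dominated by the photoreceptor
#' nonlinearity rather than by the retinal model under study.  Peak
#' locations are always reported in luminance.
#'
#' @param curve A `"brightness_curve"` (or any data frame with columns
#'   `L` and `O`, optionally `v`) with at least three points.
#' @param background_level Optional luminance (cd/m^2); when given, the
#'   statistic also reports `aligned_ratio`, the slope at the probe
#'   nearest this level relative to the median slope — a measure of
#'   background-anchored crispening.
#' @return List with `peak_location` (the `L` of maximum slope),
#'   `peak_ratio` (max slope / median slope), `aligned_ratio` (or `NA`)
#'   and the `slopes` vector.
#' @export
slope_peak_statistic <- function(curve, background_level = NULL) {
  L <- curve$L
  x <- if (!is.null(curve$v)) curve$v else L
  O <- curve$O
  n <- length(x)
  if (n < 3L) stop("need at least three points to estimate slopes")
  slopes <- numeric(n)
  slopes[1] <- (O[2] - O[1]) / (x[2] - x[1])
  slopes[n] <- (O[n] - O[n - 1]) / (x[n] - x[n - 1])
  inner <- 2:(n - 1)
  slopes[inner] <- (O[inner + 1] - O[inner - 1]) / (x[inner + 1] - x[inner - 1])
  a <- abs(slopes)
  aligned <- NA_real_
  if (!is.null(background_level)) {
    aligned <- a[which.min(abs(L - background_level))] / stats::median(a)
  }
  list(peak_location = L[which.max(a)],
       peak_ratio = max(a) / stats::median(a),
       aligned_ratio = aligned,
       slopes = slopes)
}

#' White's illusion under bandpass noise
#'
#' For each noise center frequency, generates `n_real` seeded noisy
#' stimuli ([make_white_stimulus()]), passes each through a power-law
#' front end (display linearization; no Naka-Rushton stage here) and
#' the INRF, averages the model outputs, and takes the difference of
#' the mean output over the two test-patch regions.  The sign is fixed
#' to the polarity of the noise-free illusion, so positive strengths
#' mean the illusion survives and negative ones mean it reverses.
#'
#' @param noise_freqs Noise band centers in cycles/degree; the default
#'   is six log-spaced bands between 0.5 and 9 c/deg.
#' @param n_real Number of noise realizations per band.
#' @param seed Top-level seed; per-realization streams are derived by
#'   fixed offsets.
#' @param ppd,bar_width_px,n_bars,test_gray,noise_rms Stimulus
#'   geometry, passed to [make_white_stimulus()].
#' @param gamma Power-law exponent of the front end.
#' @param params INRF to apply; defaults to [white_inrf_params()] at
#'   `ppd`.
#' @param levels Level count for the fast evaluator [inrf_apply()].
#' @return A data frame of class `"illusion_strength"` with one row per
#'   frequency: `freq_cpd`, `strength` (mean over realizations), `sd`
#'   (between-realization standard deviation), `sd_mean` (standard
#'   error of the mean strength), `n_real`.  The noise-free strength is
#'   stored in attribute `strength0`.
#' @export
run_white <- function(noise_freqs = exp(seq(log(0.5), log(9),
                                            length.out = 6)),
                      n_real = 25, seed = 1L, ppd = 24, bar_width_px = 24,
                      n_bars = 8, test_gray = 0.5, noise_rms = 0.2,
                      gamma = 2.2, params = white_inrf_params(ppd),
                      levels = 16) {
  if (n_real < 1) stop("'n_real' must be at least 1")
  strength_of <- function(stim) {
    # noisy values are clipped to the displayable range before the
    # power-law linearization
    disp <- raster(pmin(pmax(raster_values(stim$image), 0), 1),
                   value_range = c(0, 1), ppd = stim$ppd)
    lin <- power_law(disp, gamma)
    out <- raster_values(inrf_apply(lin, params, levels = levels))
    mean(out[stim$patch_dark]) - mean(out[stim$patch_light])
  }
  base <- make_white_stimulus(bar_width_px, n_bars, test_gray, ppd,
                              noise_freq_cpd = NULL)
  s0 <- strength_of(base)
  pol <- sign(s0)
  if (pol == 0) pol <- 1
  rows <- lapply(seq_along(noise_freqs), function(i) {
    # the noise stream is derived from the band frequency itself, so a
    # run on a subset of bands reproduces the same per-band strengths
    band_off <- round(noise_freqs[i] * 1009) * 1000
    s <- vapply(seq_len(n_real), function(r) {
      stim <- make_white_stimulus(bar_width_px, n_bars, test_gray, ppd,
                                  noise_freq_cpd = noise_freqs[i],
                                  noise_rms = noise_rms,
                                  seed = derive_seed(seed, band_off + r))
      pol * strength_of(stim)
    }, numeric(1))
    data.frame(freq_cpd = noise_freqs[i], strength = mean(s),
               sd = stats::sd(s), sd_mean = stats::sd(s) / sqrt(n_real),
               n_real = n_real)
  })
  structure(do.call(rbind, rows), strength0 = pol * s0,
            class = c("illusion_strength", "data.frame"))
}

#' Irradiation illusion experiment
#'
#' Runs both polarities of the 1D step stimulus through the full
#' pipeline: Gaussian retinal blur (sd 20 samples), Naka-Rushton
#' photoreceptor response `v / (v + 0.18)`, the INRF, and clipping to
#' `[0, 1]`.  The apparent width of the figure is the number of samples
#' on the figure's side of the mid-threshold (the midpoint between the
#' central and outer plateau levels of the clipped profile); the
#' white-on-black figure comes out wider than the equally sized
#' black-on-white one.
#'
#' @param params INRF to apply; defaults to [irradiation_inrf_params()].
#' @param blur_sigma Retinal blur standard deviation in samples.
#' @param front_end `"naka_rushton"` (the default pipeline) or
#'   `"identity"` (control).
#' @param levels Level count for [inrf_apply()].
#' @return A list of class `"irradiation_result"`: clipped `profiles`
#'   (list of two numeric vectors) and `apparent_width` (named numeric,
#'   samples) for both polarities, plus the physical `step_width`.
#' @export
run_irradiation <- function(params = irradiation_inrf_params(),
                            blur_sigma = 20,
                            front_end = c("naka_rushton", "identity"),
                            levels = 64) {
  front_end <- match.arg(front_end)
  one <- function(polarity) {
    stim <- make_irradiation_signal(polarity)
    x <- retinal_blur(stim, blur_sigma, boundary = params$boundary)
    if (front_end == "naka_rushton") x <- naka_rushton(x, S = 0.18, n = 1)
    out <- raster_values(inrf_apply(x, params, levels = levels))
    pmin(pmax(out, 0), 1)
  }
  profiles <- list(white_on_black = one("white_on_black"),
                   black_on_white = one("black_on_white"))
  widths <- vapply(names(profiles), function(nm) {
    p <- profiles[[nm]]
    n <- length(p)
    inner <- mean(p[(n %/% 2 - 50):(n %/% 2 + 50)])
    outer_lvl <- mean(c(p[1:100], p[(n - 99):n]))
    thr <- (inner + outer_lvl) / 2
    if (nm == "white_on_black") sum(p > thr) else sum(p < thr)
  }, numeric(1))
  structure(list(profiles = profiles, apparent_width = widths,
                 step_width = 400),
            class = "irradiation_result")
}
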