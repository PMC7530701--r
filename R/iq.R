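#' INRF-IQ: full-reference image quality metric
#'
#' Both images are reduced to their CIELAB lightness channel
#' ([srgb_to_lightness()]), passed through the brightness model
#' ([inrf_b_params()]; optionally a sequential stack of several such
#' stages), and the score is the root-mean-square error between the two
#' model outputs.  The score is nonnegative, symmetric, and zero when
#' the images share the same lightness channel; larger scores mean a
#' more visible distortion.
#'
#' @param ref,dist sRGB arrays (`H x W x 3`, values in `[0, 1]` or
#'   `[0, 255]`), file paths readable by [read_srgb()], or already-
#'   computed lightness [raster()]s.
#' @param params INRF parameters for the brightness stage.
#' @param stages Number of stacked model stages (1 by default).
#' @param levels Level count for [inrf_apply()].
#' @return List of class `"iq_result"` with element `score`.
#' @export
#' @examples
#' img <- array(stats::runif(48), dim = c(4, 4, 3))
#' inrf_iq(img, img)$score  # 0
inrf_iq <- function(ref, dist, params = inrf_b_params(), stages = 1,
                    levels = 64) {
  to_lightness <- function(x) {
    if (is.character(x)) x <- read_srgb(x)
    if (is.raster_grid(x)) return(x)
    srgb_to_lightness(x)
  }
  LR <- to_lightness(ref); LD <- to_lightness(dist)
  vr <- raster_values(LR); vd <- raster_values(LD)
  if (!identical(dim(vr), dim(vd))) {
    stop("reference and distorted images must have equal dimensions")
  }
  model <- function(L) {
    out <- L
    for (s in seq_len(stages)) out <- inrf_apply(out, params, levels = levels)
    raster_values(out)
  }
  OR <- model(LR); OD <- model(LD)
  structure(list(score = sqrt(mean((OR - OD)^2))), class = "iq_result")
}

#' @export
print.iq_result <- function(x, ...) {
  cat("INRF-IQ score:", format(x$score), "\n")
  invisible(x)
}

#' Correlate the IQ metric with mean opinion scores
#'
#' Computes [inrf_iq()] for every (reference, distorted) pair in the
#' table and returns the Pearson correlation of the *negated* score
#' with the mean opinion scores (larger distortion gives a larger
#' score, hence a lower MOS), together with its absolute value.
#' Unreadable pairs are skipped with a message.
#'
#' @param pair_table Data frame with columns `ref`, `dist` (image paths
#'   or in-memory images in list columns) and `mos`.
#' @param ... Passed on to [inrf_iq()].
#' @return List with `r` (signed Pearson correlation of -score with
#'   MOS), `abs_r`, `n_used`, `n_skipped` and the per-pair `scores`.
#' @export
evaluate_mos_correlation <- function(pair_table, ...) {
  stopifnot(all(c("ref", "dist", "mos") %in% names(pair_table)))
  n <- nrow(pair_table)
  scores <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    scores[i] <- tryCatch(
      inrf_iq(pair_table$ref[[i]], pair_table$dist[[i]], ...)$score,
      error = function(e) NA_real_)
  }
  ok <- is.finite(scores)
  if (sum(!ok) > 0) {
    message(sum(!ok), " image pair(s) could not be scored and were skipped")
  }
  if (sum(ok) < 3) stop("fewer than 3 valid image pairs")
  s <- scores[ok]; mos <- pair_table$mos[ok]
  if (stats::sd(s) == 0 || stats::sd(mos) == 0) {
    stop("correlation undefined: zero variance in scores or MOS")
  }
  r <- stats::cor(-s, mos)
  list(r = r, abs_r = abs(r), n_used = sum(ok), n_skipped = sum(!ok),
       scores = scores)
}

#' Build an IQ pair table from a TID2013-style layout
#'
#' Adapter for evaluating the metric on an externally downloaded
#' quality database laid out as `reference_images/`,
#' `distorted_images/` and an `mos.txt` / `mos_with_names.txt` file
#' whose rows are `MOS distorted_name`.  The reference image of a
#' distorted file `iXX_YY_Z.bmp`-style name is taken as the `iXX`
#' prefix.  The dataset itself is not bundled.
#'
#' @param root Database root directory.
#' @param mos_file MOS file name within `root`.
#' @return A data frame with columns `ref`, `dist`, `mos` suitable for
#'   [evaluate_mos_correlation()].
#' @export
tid2013_pair_table <- function(root, mos_file = "mos_with_names.txt") {
  mf <- file.path(root, mos_file)
  if (!file.exists(mf)) stop("MOS file not found: ", mf)
  lines <- utils::read.table(mf, header = FALSE,
                             col.names = c("mos", "name"),
                             stringsAsFactors = FALSE)
  refs <- toupper(sub("_.*$", "", lines$name))
  data.frame(
    ref = file.path(root, "reference_images", paste0(refs, ".BMP")),
    dist = file.path(root, "distorted_images", lines$name),
    mos = lines$mos, stringsAsFactors = FALSE)
}
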