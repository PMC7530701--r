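#' INRF operator parameters
#'
#' Bundles the three kernels, the balance weight and the nonlinearity of
#' the intrinsically nonlinear receptive field
#' \deqn{INRF(x) = \sum_i m_i I(y_i) - \lambda \sum_i w_i\,
#'       \sigma\big(I(y_i) - (g*I)(x)\big),}
#' where `m` weighs linear dendritic contributions, `w` weighs the
#' nonlinear ones, and `g` is the narrow kernel producing the local mean
#' that shifts the nonlinearity (feedback from the soma).
#'
#' @param m,w,g [kernel_spec()]s for the linear, nonlinear and shift
#'   kernels.
#' @param lambda Finite scalar balancing the nonlinear term.
#' @param sigma A [sigma_spec()].
#' @param boundary Out-of-grid policy: `"mirror"` (default),
#'   `"replicate"`, `"periodic"` or `"zero"`.
#' @return An object of class `"inrf_params"`.
#' @seealso [inrf_apply()], [inrf_oracle()], [inrf_b_params()]
#' @export
inrf_params <- function(m, w, g = kernel_spec("delta"), lambda = 1,
                        sigma = sigma_spec("scaled_identity", alpha = 1),
                        boundary = c("mirror", "replicate", "periodic",
                                     "zero")) {
  stopifnot(inherits(m, "kernel_spec"), inherits(w, "kernel_spec"),
            inherits(g, "kernel_spec"), inherits(sigma, "sigma_spec"),
            is.finite(lambda))
  boundary <- match.arg(boundary)
  structure(list(m = m, w = w, g = g, lambda = lambda, sigma = sigma,
                 boundary = boundary),
            class = "inrf_params")
}

#' @export
print.inrf_params <- function(x, ...) {
  cat("<inrf_params lambda=", x$lambda, ", boundary=", x$boundary, ">\n",
      sep = "")
  for (nm in c("m", "w", "g")) {
    cat("  ", nm, ": ", sep = ""); print(x[[nm]])
  }
  cat("  sigma: "); print(x$sigma)
  invisible(x)
}

#' Linear + nonlinear (L+NL) baseline parameters
#'
#' The classical comparison model
#' \deqn{LN(x) = \sum_i m_i I(y_i) - \lambda\,
#'       \sigma\big((DoG * I)(x)\big):}
#' a linear term plus a pointwise nonlinearity applied *after* a
#' difference-of-Gaussians filtering (note the contrast with the INRF,
#' where the nonlinearity sits inside the summation).
#'
#' @param m Linear [kernel_spec()].
#' @param dog A [kernel_spec()] of kind `"dog"`.
#' @param lambda Finite scalar.
#' @param sigma A [sigma_spec()].
#' @param boundary Boundary policy, as in [inrf_params()].
#' @return An object of class `"lnl_params"`.
#' @export
lnl_params <- function(m, dog, lambda = 1,
                       sigma = sigma_spec("scaled_identity", alpha = 1),
                       boundary = c("mirror", "replicate", "periodic",
                                    "zero")) {
  stopifnot(inherits(m, "kernel_spec"), inherits(dog, "kernel_spec"),
            inherits(sigma, "sigma_spec"), is.finite(lambda))
  if (dog$kind != "dog") stop("lnl_params needs a kernel of kind 'dog'")
  boundary <- match.arg(boundary)
  structure(list(m = m, dog = dog, lambda = lambda, sigma = sigma,
                 boundary = boundary),
            class = "lnl_params")
}

# normalize user points to a 0-based index matrix (n x ndim)
as_point_matrix <- function(points, ndim) {
  if (ndim == 1L) {
    matrix(as.integer(points) - 1L, ncol = 1L)
  } else {
    p <- if (is.matrix(points)) points else matrix(points, ncol = 2L,
                                                   byrow = TRUE)
    matrix(as.integer(p) - 1L, ncol = 2L)
  }
}

#' Literal INRF evaluation at selected points
#'
#' Evaluates the model sum directly, term by term, at the requested
#' points: for each point the boundary-folded windows of the realized
#' `m`, `w` and `g` kernels are extracted and the double summation is
#' computed as written.  This is the reference semantics for the
#' operator and is exact up to floating-point rounding, but makes no
#' speed promise; [inrf_apply()] is the fast route for whole images.
#'
#' @param I A [raster()] or bare numeric vector/matrix.
#' @param params An [inrf_params()].
#' @param points 1-based indices: a vector for 1D signals, or an
#'   `n x 2` matrix of (row, col) for images.
#' @return Numeric vector of model outputs at the points.
#' @export
inrf_points <- function(I, params, points) {
  v <- raster_values(as_raster(I))
  nd <- if (is.matrix(v)) 2L else 1L
  ext <- if (nd == 1L) length(v) else max(dim(v))
  w_global <- params$w$kind == "constant_full" && is.null(params$w$size_px)
  mk <- realize_kernel(params$m, nd, extent = ext)
  wk <- if (w_global) NULL else realize_kernel(params$w, nd, extent = ext)
  gk <- realize_kernel(params$g, nd, extent = ext)
  rm_ <- kernel_radius(mk); rg <- kernel_radius(gk)
  rw <- if (w_global) NULL else kernel_radius(wk)
  pts <- as_point_matrix(points, nd)
  out <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    at <- pts[i, ]
    cg <- sum(gk * extract_window(v, rg, at, params$boundary))
    lin <- sum(mk * extract_window(v, rm_, at, params$boundary))
    nl <- if (w_global) {
      # full-signal w: exact global mean, each sample weighted once
      mean(eval_sigma(params$sigma, v - cg))
    } else {
      ww <- extract_window(v, rw, at, params$boundary)
      sum(wk * eval_sigma(params$sigma, ww - cg))
    }
    out[i] <- lin - params$lambda * nl
  }
  out
}

#' Brute-force INRF over a whole grid
#'
#' Runs the literal point evaluator [inrf_points()] at every grid
#' location.  Intended as the correctness oracle for [inrf_apply()] on
#' small inputs; cost grows with (pixels x kernel support).
#'
#' @inheritParams inrf_points
#' @return A [raster()] (or bare grid, matching the input) of model
#'   outputs.
#' @export
inrf_oracle <- function(I, params) {
  v <- raster_values(as_raster(I))
  if (is.matrix(v)) {
    pts <- as.matrix(expand.grid(row = seq_len(nrow(v)),
                                 col = seq_len(ncol(v))))
    out <- matrix(inrf_points(I, params, pts), nrow(v), ncol(v))
  } else {
    out <- inrf_points(I, params, seq_along(v))
  }
  raster_like(out, I)
}

#' Fast INRF evaluation by intensity-level decomposition
#'
#' Same mathematical contract as [inrf_oracle()].  The nonlinear term
#' \eqn{T(x) = \sum_i w_i \sigma(I(y_i) - c(x))} with
#' \eqn{c = g * I} depends on `x` only through the scalar `c(x)`, so it
#' can be evaluated by ordinary convolution per intensity level: for a
#' set of level values `c_l`, `T_l = w * sigma(I - c_l)`, and `T(x)` is
#' read at the level matching `c(x)`.  When `c` takes at most `levels`
#' distinct values the decomposition uses exactly those values and the
#' result is exact; otherwise `levels` values are placed uniformly over
#' `[min c, max c]` and `T(x)` is linearly interpolated between the two
#' bracketing levels.
#'
#' @inheritParams inrf_points
#' @param levels Positive integer (at least 2) or `"auto"` (64).
#' @return A [raster()] (or bare grid) of model outputs.
#' @export
inrf_apply <- function(I, params, levels = "auto") {
  if (identical(levels, "auto")) levels <- 64L
  levels <- as.integer(levels)
  if (is.na(levels) || levels < 2L) {
    stop("'levels' must be an integer >= 2 or \"auto\"")
  }
  v <- raster_values(as_raster(I))
  b <- params$boundary
  cx <- convolve_spec(v, params$g, b)
  lin <- convolve_spec(v, params$m, b)
  vals <- sort(unique(as.numeric(cx)))
  sig <- params$sigma
  if (length(vals) <= levels) {
    # exact decomposition on the observed local-mean values
    Tx <- v * 0
    idx <- match(as.numeric(cx), vals)
    for (l in seq_along(vals)) {
      sel <- idx == l
      if (!any(sel)) next
      Tl <- convolve_spec(eval_sigma(sig, v - vals[l]), params$w, b)
      Tx[sel] <- Tl[sel]
    }
  } else {
    grid <- seq(vals[1], vals[length(vals)], length.out = levels)
    step <- grid[2] - grid[1]
    lo <- pmin(pmax(findInterval(as.numeric(cx), grid), 1L), levels - 1L)
    tfrac <- (as.numeric(cx) - grid[lo]) / step
    Tx <- v * 0
    Tprev <- NULL
    for (l in seq_len(levels)) {
      Tl <- convolve_spec(eval_sigma(sig, v - grid[l]), params$w, b)
      if (l > 1L) {
        sel <- lo == (l - 1L)
        if (any(sel)) {
          Tx[sel] <- (1 - tfrac[sel]) * Tprev[sel] + tfrac[sel] * Tl[sel]
        }
      }
      Tprev <- Tl
    }
  }
  raster_like(lin - params$lambda * Tx, I)
}

#' Linear receptive-field response (plain convolution)
#'
#' @inheritParams inrf_points
#' @param kernel A [kernel_spec()].
#' @param boundary Boundary policy.
#' @return A [raster()] (or bare grid): `kernel * I`.
#' @export
lrf_apply <- function(I, kernel, boundary = "mirror") {
  v <- raster_values(as_raster(I))
  raster_like(convolve_spec(v, kernel, boundary), I)
}

#' Nonlinear-dendrite summation (fixed nonlinearity)
#'
#' \eqn{LNRF(x) = \sum_i w_i \sigma(I(y_i))}: each input sample is
#' passed through the same pointwise nonlinearity before the weighted
#' sum, so this is an ordinary convolution of `sigma(I)`.
#'
#' @inheritParams lrf_apply
#' @param sigma A [sigma_spec()].
#' @return A [raster()] (or bare grid).
#' @export
lnrf_apply <- function(I, kernel, sigma, boundary = "mirror") {
  v <- raster_values(as_raster(I))
  raster_like(convolve_spec(eval_sigma(sigma, v), kernel, boundary), I)
}

#' Apply the L+NL baseline model
#'
#' @inheritParams inrf_points
#' @param params An [lnl_params()].
#' @return A [raster()] (or bare grid).
#' @export
lnl_apply <- function(I, params) {
  v <- raster_values(as_raster(I))
  lin <- convolve_spec(v, params$m, params$boundary)
  dg <- convolve_spec(v, params$dog, params$boundary)
  raster_like(lin - params$lambda * eval_sigma(params$sigma, dg), I)
}

# literal L+NL at selected points (same windowed-sum semantics as
# inrf_points); used by the crispening pipeline, which only needs the
# model at the eleven probe centers
lnl_points <- function(I, params, points) {
  v <- raster_values(as_raster(I))
  nd <- if (is.matrix(v)) 2L else 1L
  mk <- realize_kernel(params$m, nd)
  dk <- realize_kernel(params$dog, nd)
  rm_ <- kernel_radius(mk); rd <- kernel_radius(dk)
  pts <- as_point_matrix(points, nd)
  out <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    at <- pts[i, ]
    lin <- sum(mk * extract_window(v, rm_, at, params$boundary))
    dg <- sum(dk * extract_window(v, rd, at, params$boundary))
    out[i] <- lin - params$lambda * eval_sigma(params$sigma, dg)
  }
  out
}

#' Collapse the INRF to a single linear kernel
#'
#' With a linear nonlinearity `sigma(z) = alpha z` the model reduces to
#' one convolution with
#' \deqn{k = m - \lambda\alpha\, w + \lambda\alpha \big(\sum_i w_i\big) g,}
#' the kernels being zero-padded to a common extent.  With Gaussian `m`
#' and `g` and a wider Gaussian `w` the combined kernel has
#' center-surround (difference-of-Gaussians-like) sign structure.
#'
#' @param params An [inrf_params()].
#' @param alpha Slope of the linear nonlinearity.
#' @param ndim Dimensionality of the target kernel (1 or 2).
#' @param extent Signal extent for resolving `constant_full` kernels.
#' @return The realized combined kernel grid (vector or matrix).
#' @export
reduce_to_linear <- function(params, alpha, ndim = 1, extent = NULL) {
  mk <- realize_kernel(params$m, ndim, extent = extent)
  wk <- realize_kernel(params$w, ndim, extent = extent)
  gk <- realize_kernel(params$g, ndim, extent = extent)
  rads <- vapply(list(mk, wk, gk), function(k) max(kernel_radius(k)),
                 numeric(1))
  r <- as.integer(max(rads))
  embed <- function(k) {
    if (ndim == 1L) {
      out <- numeric(2L * r + 1L)
      kr <- kernel_radius(k)
      out[(r - kr + 1L):(r + kr + 1L)] <- k
      out
    } else {
      out <- matrix(0, 2L * r + 1L, 2L * r + 1L)
      kr <- kernel_radius(k)
      out[(r - kr[1] + 1L):(r + kr[1] + 1L),
          (r - kr[2] + 1L):(r + kr[2] + 1L)] <- k
      out
    }
  }
  la <- params$lambda * alpha
  embed(mk) - la * embed(wk) + la * sum(wk) * embed(gk)
}

#' How many linear filters an L+NL expansion of the INRF needs
#'
#' Expressing the nonlinear term of the model in linear-filter form
#' requires one difference filter per pixel plus the final `w`
#' convolution plus the `m` convolution: `n_pixels + 2` in total for a
#' single output point, versus one convolution for a whole image under
#' a linear receptive field.
#'
#' @param n_pixels Number of discrete signal locations (>= 1).
#' @return Integer-valued count `n_pixels + 2`.
#' @export
#' @examples
#' count_lnl_filters(1e6)  # over a million
count_lnl_filters <- function(n_pixels) {
  if (any(n_pixels < 1)) stop("'n_pixels' must be >= 1")
  n_pixels + 2
}
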