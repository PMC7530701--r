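#' @useDynLib inrf, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

BOUNDARY_CODES <- c(mirror = 0L, replicate = 1L, periodic = 2L, zero = 3L)

boundary_code <- function(boundary) {
  boundary <- match.arg(boundary, names(BOUNDARY_CODES))
  BOUNDARY_CODES[[boundary]]
}

# Fold an out-of-range 0-based index vector into [0, n); mirror is
# half-sample symmetric (edge repeated), applied with period 2n so the
# excursion may exceed the grid.  Returns NA for the zero boundary.
fold_index_r <- function(i, n, boundary) {
  switch(boundary,
    mirror = {
      j <- i %% (2L * n)
      ifelse(j >= n, 2L * n - 1L - j, j)
    },
    replicate = pmin(pmax(i, 0L), n - 1L),
    periodic = i %% n,
    zero = ifelse(i >= 0L & i < n, i, NA_integer_),
    stop("unknown boundary '", boundary, "'"))
}

# Same-size convolution of a 1D/2D grid with a kernel spec, exploiting
# separability where the kind allows it.
convolve_spec <- function(values, spec, boundary = "mirror") {
  code <- boundary_code(boundary)
  if (spec$kind == "delta") return(values)
  if (spec$kind == "constant_full" && is.null(spec$size_px)) {
    # kernel spanning the whole signal: exact global mean, each sample
    # weighted once (no boundary folding)
    out <- values * 0 + mean(values)
    return(out)
  }
  if (spec$kind == "dog") {
    kn <- kernel_spec("gaussian", sigma_px = spec$sigma_px[1])
    kw <- kernel_spec("gaussian", sigma_px = spec$sigma_px[2])
    return(convolve_spec(values, kn, boundary) -
             convolve_spec(values, kw, boundary))
  }
  if (is.matrix(values)) {
    if (spec$kind == "custom") {
      k <- realize_kernel(spec, 2L)
      return(.conv2d_full_fold(values, k, code))
    }
    k1 <- separable_taps(spec, extent = max(dim(values)))
    out <- .conv2d_sep_fold(values, k1, k1, code)
    dimnames(out) <- NULL
    return(out)
  }
  k1 <- if (spec$kind == "custom") realize_kernel(spec, 1L)
        else separable_taps(spec, extent = length(values))
  .conv1d_fold(values, k1, code)
}

# Direct windowed sum at one 0-based point, used by the literal
# reference evaluators: returns the boundary-folded window of `values`
# matching a realized kernel grid centered at `at`.
extract_window <- function(values, radius, at, boundary) {
  if (is.matrix(values)) {
    rows <- fold_index_r(at[1] + (-radius[1]:radius[1]), nrow(values), boundary)
    cols <- fold_index_r(at[2] + (-radius[2]:radius[2]), ncol(values), boundary)
    if (boundary == "zero") {
      w <- matrix(0, 2 * radius[1] + 1, 2 * radius[2] + 1)
      ok_r <- !is.na(rows); ok_c <- !is.na(cols)
      w[ok_r, ok_c] <- values[rows[ok_r] + 1L, cols[ok_c] + 1L]
      return(w)
    }
    values[rows + 1L, cols + 1L]
  } else {
    idx <- fold_index_r(at + (-radius:radius), length(values), boundary)
    if (boundary == "zero") {
      w <- numeric(2 * radius + 1)
      ok <- !is.na(idx)
      w[ok] <- values[idx[ok] + 1L]
      return(w)
    }
    values[idx + 1L]
  }
}

kernel_radius <- function(grid) {
  if (is.matrix(grid)) (dim(grid) - 1L) %/% 2L else (length(grid) - 1L) %/% 2L
}
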