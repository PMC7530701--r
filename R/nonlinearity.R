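#' Pointwise dendritic nonlinearity specification
#'
#' Describes the sigmoid-like nonlinearity `sigma` applied to shifted
#' intensity differences inside the receptive-field models.  All kinds
#' satisfy `sigma(0) = 0`.
#'
#' \describe{
#'   \item{`asymmetric_power`}{`z^p` for `z >= 0`, `-|z|^q` for `z < 0`.
#'     The negative branch is written with the absolute value so the
#'     result is real for any exponent.  With `p`, `q < 1` the slope at
#'     zero is unbounded, which is what produces the sharp response
#'     changes around the adaptation level.}
#'   \item{`piecewise_sinusoid`}{`sin(pi z)` for `|z| < 0.5`,
#'     `sign(z) * sin(pi z)^2` otherwise; odd and continuous at
#'     `|z| = 0.5`, non-monotonic beyond it.}
#'   \item{`scaled_identity`}{`alpha * z`; in this regime the full model
#'     collapses to a single linear receptive field
#'     (see [reduce_to_linear()]).}
#'   \item{`sign`}{`sign(z)`, the unregularized limit used by
#'     histogram-equalization flows.}
#' }
#'
#' @param kind One of `"asymmetric_power"`, `"piecewise_sinusoid"`,
#'   `"scaled_identity"`, `"sign"`.
#' @param p,q Positive- and negative-branch exponents for
#'   `asymmetric_power`.
#' @param alpha Scale for `scaled_identity`.
#' @return An object of class `"sigma_spec"`.
#' @export
#' @examples
#' sg <- sigma_spec("asymmetric_power", p = 0.625, q = 0.775)
#' eval_sigma(sg, c(-1, 0, 1))
sigma_spec <- function(kind = c("asymmetric_power", "piecewise_sinusoid",
                                "scaled_identity", "sign"),
                       p = NULL, q = NULL, alpha = NULL) {
  kind <- match.arg(kind)
  if (kind == "asymmetric_power") {
    if (is.null(p) || is.null(q) || p <= 0 || q <= 0) {
      stop("invalid sigma spec: asymmetric_power needs positive exponents p, q")
    }
  }
  if (kind == "scaled_identity" && is.null(alpha)) {
    stop("invalid sigma spec: scaled_identity needs 'alpha'")
  }
  structure(list(kind = kind, p = p, q = q, alpha = alpha),
            class = "sigma_spec")
}

#' @export
print.sigma_spec <- function(x, ...) {
  extras <- c(if (!is.null(x$p)) paste0("p=", x$p),
              if (!is.null(x$q)) paste0("q=", x$q),
              if (!is.null(x$alpha)) paste0("alpha=", x$alpha))
  cat("<sigma_spec ", x$kind,
      if (length(extras)) paste0(" (", paste(extras, collapse = ", "), ")"),
      ">\n", sep = "")
  invisible(x)
}

#' Evaluate a nonlinearity elementwise
#'
#' @param spec A [sigma_spec()].
#' @param z Numeric vector, matrix or array of finite values.
#' @return `z`-shaped numeric with the branch formulas applied.
#' @export
eval_sigma <- function(spec, z) {
  stopifnot(inherits(spec, "sigma_spec"))
  out <- switch(spec$kind,
    asymmetric_power = {
      r <- z
      pos <- z >= 0
      r[pos] <- z[pos]^spec$p
      r[!pos] <- -(abs(z[!pos])^spec$q)
      r
    },
    piecewise_sinusoid = {
      inner <- abs(z) < 0.5
      r <- sign(z) * sin(pi * z)^2
      r[inner] <- sin(pi * z[inner])
      r
    },
    scaled_identity = spec$alpha * z,
    sign = sign(z),
    stop("unknown sigma kind '", spec$kind, "'"))
  if (is.array(z)) dim(out) <- dim(z)
  out
}
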