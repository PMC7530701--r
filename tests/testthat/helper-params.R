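# Small-kernel model parameters used throughout the unit tests; the
# printed experiment parameters live in the presets and are exercised
# in the acceptance suite.
small_inrf_params <- function(lambda = 2, boundary = "mirror",
                              sigma = sigma_spec("asymmetric_power",
                                                 p = 0.625, q = 0.775)) {
  inrf_params(
    m = kernel_spec("gaussian", sigma_px = 1.5),
    w = kernel_spec("gaussian", sigma_px = 3),
    g = kernel_spec("delta"),
    lambda = lambda, sigma = sigma, boundary = boundary)
}

# odd-signed power nonlinearity z^3 (z >= 0: z^3; z < 0: -|z|^3)
cube_sigma <- function() sigma_spec("asymmetric_power", p = 3, q = 3)

rand_matrix <- function(nr, nc, seed) {
  set.seed(seed)
  matrix(stats::runif(nr * nc), nr, nc)
}

# smooth random image in [0, 1]
smooth_image <- function(n, seed, blur = 2) {
  vals <- inrf:::raster_values(retinal_blur(rand_matrix(n, n, seed), blur))
  (vals - min(vals)) / (max(vals) - min(vals))
}

grid_values <- function(x) inrf:::raster_values(x)

# gray gradient test image as an sRGB array
gradient_srgb <- function(nr = 40, nc = 56) {
  base <- outer(seq(0.1, 0.9, length.out = nr),
                seq(0.1, 0.9, length.out = nc), function(a, b) (a + b) / 2)
  array(rep(base, 3), dim = c(nr, nc, 3))
}

add_image_noise <- function(img, sd_gray, seed) {
  set.seed(seed)
  noisy <- img + array(stats::rnorm(length(img), 0, sd_gray / 255),
                       dim = dim(img))
  pmin(pmax(noisy, 0), 1)
}
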