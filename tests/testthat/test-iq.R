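# small kernels make the metric cheap for unit tests; the printed
# brightness-model parameters are exercised in the acceptance suite
iq_test_params <- function() {
  inrf_params(m = kernel_spec("gaussian", sigma_px = 3),
              w = kernel_spec("gaussian", sigma_px = 8),
              g = kernel_spec("delta"), lambda = 3.875,
              sigma = sigma_spec("asymmetric_power", p = 0.625, q = 0.775))
}

test_that("the quality score is a pseudometric surrogate", {
  img <- gradient_srgb(24, 24)
  expect_equal(inrf_iq(img, img, params = iq_test_params())$score, 0)
  noisy <- add_image_noise(img, 12, seed = 1)
  s1 <- inrf_iq(img, noisy, params = iq_test_params())$score
  s2 <- inrf_iq(noisy, img, params = iq_test_params())$score
  expect_gt(s1, 0)
  expect_identical(s1, s2)
  # repeated evaluation is bitwise identical
  expect_identical(inrf_iq(img, noisy, params = iq_test_params())$score, s1)
  expect_error(inrf_iq(img, gradient_srgb(12, 12),
                       params = iq_test_params()),
               "equal dimensions")
})

test_that("scores grow with distortion amplitude", {
  img <- gradient_srgb(24, 24)
  scores <- vapply(c(2, 8, 32), function(s) {
    inrf_iq(img, add_image_noise(img, s, seed = 7),
            params = iq_test_params())$score
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
})

test_that("stacked stages change the score but keep it a metric surrogate", {
  img <- gradient_srgb(16, 16)
  noisy <- add_image_noise(img, 16, seed = 3)
  s2 <- inrf_iq(img, noisy, params = iq_test_params(), stages = 2)$score
  expect_gt(s2, 0)
  expect_equal(inrf_iq(img, img, params = iq_test_params(),
                       stages = 2)$score, 0)
})

test_that("MOS correlation harness matches its contracts", {
  img <- gradient_srgb(16, 16)
  n <- 50
  refs <- vector("list", n); dists <- vector("list", n)
  for (i in seq_len(n)) {
    refs[[i]] <- img
    dists[[i]] <- add_image_noise(img, 1 + i, seed = i)
  }
  tab <- data.frame(mos = rep(0, n))
  tab$ref <- refs
  tab$dist <- dists
  scores <- vapply(seq_len(n), function(i) {
    inrf_iq(refs[[i]], dists[[i]], params = iq_test_params())$score
  }, numeric(1))
  # MOS exactly affine in -score: perfect correlation
  tab$mos <- 5 - 0.3 * scores
  res <- evaluate_mos_correlation(tab, params = iq_test_params())
  expect_equal(res$r, 1, tolerance = 1e-10)
  expect_equal(res$abs_r, 1, tolerance = 1e-10)
  # MOS an independent permutation of the scores: null correlation
  set.seed(42)
  tab$mos <- sample(scores)
  res2 <- evaluate_mos_correlation(tab, params = iq_test_params())
  expect_lt(res2$abs_r, 0.4)
  # constant scores: undefined correlation signalled explicitly
  tab3 <- tab
  tab3$dist <- tab3$ref
  expect_error(evaluate_mos_correlation(tab3, params = iq_test_params()),
               "zero variance")
})

test_that("unreadable pairs are skipped and too-small tables error", {
  img <- gradient_srgb(16, 16)
  tab <- data.frame(mos = c(1, 2, 3, 4))
  tab$ref <- list(img, "no/such/file.png", img, img)
  tab$dist <- list(add_image_noise(img, 5, 1), "no/such/file.png",
                   add_image_noise(img, 15, 2), add_image_noise(img, 30, 3))
  expect_message(res <- evaluate_mos_correlation(tab,
                                                 params = iq_test_params()),
                 "skipped")
  expect_equal(res$n_used, 3)
  expect_equal(res$n_skipped, 1)
  tab2 <- tab[1:3, ]
  tab2$ref[[2]] <- "still/missing.png"
  expect_error(suppressMessages(
    evaluate_mos_correlation(tab2, params = iq_test_params())),
    "fewer than 3")
})

test_that("file round-trip feeds the metric through the PNG reader", {
  img <- gradient_srgb(16, 16)
  noisy <- add_image_noise(img, 20, seed = 5)
  fr <- tempfile(fileext = ".png"); fd <- tempfile(fileext = ".png")
  png::writePNG(img, fr)
  png::writePNG(noisy, fd)
  s_file <- inrf_iq(fr, fd, params = iq_test_params())$score
  expect_gt(s_file, 0)
  # 8-bit quantization: close to the in-memory score
  s_mem <- inrf_iq(img, noisy, params = iq_test_params())$score
  expect_lt(abs(s_file - s_mem) / s_mem, 0.1)
})
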