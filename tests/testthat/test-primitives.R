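test_that("realized kernels obey their structural invariants", {
  specs <- list(
    kernel_spec("delta"),
    kernel_spec("box", size_px = 3),
    kernel_spec("box", size_px = 85),
    kernel_spec("gaussian", sigma_px = 0.8),
    kernel_spec("gaussian", sigma_px = 4),
    kernel_spec("gaussian", sigma_px = 52),
    kernel_spec("constant_full", size_px = 511))
  for (spec in specs) {
    for (nd in 1:2) {
      k <- realize_kernel(spec, nd)
      expect_equal(sum(k), 1, tolerance = 1e-12)
      ext <- if (nd == 1) length(k) else dim(k)
      expect_true(all(ext %% 2 == 1))
    }
  }
  # delta: single central 1
  d <- realize_kernel(kernel_spec("delta"), 1)
  expect_identical(d, 1)
  d2 <- realize_kernel(kernel_spec("delta"), 2)
  expect_equal(sum(d2 != 0), 1)
  expect_equal(d2[(nrow(d2) + 1) / 2, (ncol(d2) + 1) / 2], 1)
  # box of size s: all entries equal to 1/s in 1D
  b <- realize_kernel(kernel_spec("box", size_px = 85), 1)
  expect_length(b, 85)
  expect_true(all(b == 1 / 85))
  # dog: narrow minus wide, each normalized before subtraction
  dg <- realize_kernel(kernel_spec("dog", sigma_px = c(2, 5)), 1)
  expect_equal(sum(dg), 0, tolerance = 1e-12)
  ctr <- (length(dg) + 1) / 2
  expect_gt(dg[ctr], 0)          # center excess
  expect_lt(min(dg), 0)          # inhibitory surround
  # determinism: equal specs realize bitwise-equal grids
  expect_identical(realize_kernel(kernel_spec("gaussian", sigma_px = 3), 2),
                   realize_kernel(kernel_spec("gaussian", sigma_px = 3), 2))
})

test_that("invalid kernel specs are rejected and even sizes rounded up", {
  expect_error(kernel_spec("box", size_px = 0), "invalid")
  expect_error(kernel_spec("gaussian", sigma_px = -1), "invalid")
  expect_error(kernel_spec("dog", sigma_px = c(5, 2)), "narrow")
  expect_error(kernel_spec("dog", sigma_px = c(3, 3)), "narrow")
  expect_warning(k <- realize_kernel(kernel_spec("box", size_px = 4), 1),
                 "rounded up")
  expect_length(k, 5)
})

test_that("nonlinearities follow their branch formulas", {
  ap <- sigma_spec("asymmetric_power", p = 0.625, q = 0.775)
  expect_equal(eval_sigma(ap, 0), 0)
  expect_equal(eval_sigma(ap, 1), 1)
  expect_equal(eval_sigma(ap, -1), -1)
  expect_equal(eval_sigma(ap, 0.5), 0.5^0.625)
  expect_equal(eval_sigma(ap, -0.5), -0.5^0.775)
  ps <- sigma_spec("piecewise_sinusoid")
  expect_equal(eval_sigma(ps, 0.25), sqrt(2) / 2, tolerance = 1e-12)
  expect_equal(eval_sigma(ps, 0.75), 0.5, tolerance = 1e-12)
  expect_equal(eval_sigma(ps, 0), 0)
  si <- sigma_spec("scaled_identity", alpha = 2.5)
  z <- seq(-2, 2, by = 0.25)
  expect_equal(eval_sigma(si, z), 2.5 * z)
  expect_equal(eval_sigma(sigma_spec("sign"), c(-3, 0, 2)), c(-1, 0, 1))
})

test_that("every nonlinearity vanishes at zero and the odd ones are odd", {
  specs <- list(sigma_spec("asymmetric_power", p = 0.625, q = 0.775),
                sigma_spec("piecewise_sinusoid"),
                sigma_spec("scaled_identity", alpha = 3),
                sigma_spec("sign"))
  z <- seq(-1.5, 1.5, by = 0.05)
  for (sg in specs) expect_equal(eval_sigma(sg, 0), 0)
  ps <- specs[[2]]
  expect_equal(eval_sigma(ps, -z), -eval_sigma(ps, z))
  # asymmetric power is odd-signed and strictly increasing on [-1, 1]
  ap <- specs[[1]]
  y <- eval_sigma(ap, z)
  expect_equal(sign(y), sign(z))
  inz <- z >= -1 & z <= 1
  expect_true(all(diff(y[inz]) > 0))
})

test_that("piecewise sinusoid is continuous at the branch boundary", {
  ps <- sigma_spec("piecewise_sinusoid")
  eps <- 1e-6
  expect_lt(abs(eval_sigma(ps, 0.5 - eps) - eval_sigma(ps, 0.5 + eps)), 1e-4)
  expect_lt(abs(eval_sigma(ps, -0.5 + eps) - eval_sigma(ps, -0.5 - eps)), 1e-4)
})

test_that("specs serialize to structured text and back", {
  for (spec in list(kernel_spec("gaussian", sigma_px = 52),
                    kernel_spec("dog", sigma_px = c(30, 60)),
                    kernel_spec("box", size_px = 85, normalize = FALSE),
                    sigma_spec("asymmetric_power", p = 0.625, q = 0.775),
                    sigma_spec("scaled_identity", alpha = 1.5))) {
    back <- spec_from_text(spec_to_text(spec))
    expect_equal(back, spec)
  }
  expect_error(spec_from_text("foo: 1\n"), "unrecognized")
})
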