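# The burial-decay model and its parameter fitting.

test_that("benthic and planktonic abundances match the stated constants", {
  p <- decay_params()
  expect_equal(benthic_abundance(0, p), 99)
  expect_equal(benthic_abundance(5, p), 50)     # linear midpoint
  expect_equal(benthic_abundance(10, p), 1)
  expect_equal(planktonic_abundance(0, p), 1)
  # closed form: decay coordinate 1 gives N0/e
  z1 <- 1 / (p$lambda_p * p$tau_scale)
  expect_equal(planktonic_abundance(z1, p), exp(-1))
  expect_error(benthic_abundance(-1, p), "non-negative")
  expect_error(planktonic_abundance(-0.5, p), "non-negative")
})

test_that("benthic abundance is continuous at the inhabited-zone boundary", {
  p <- decay_params()
  eps <- 1e-9
  expect_equal(benthic_abundance(p$z_inhabited - eps, p),
               benthic_abundance(p$z_inhabited + eps, p), tolerance = 1e-6)
  # degenerate limit: tau_scale -> 0 freezes the planktonic pool
  p0 <- decay_params(tau_scale = 1e-12)
  expect_equal(planktonic_abundance(c(0, 10, 30), p0), rep(1, 3),
               tolerance = 1e-9)
})

test_that("fraction profile peaks at the inhabited-zone bottom and decreases below", {
  p <- decay_params()
  expect_equal(fraction_profile(0, p)$fraction, 1 / (1 + 99))
  zs <- seq(0, 30, by = 0.01)
  fr <- fraction_profile(zs, p)$fraction
  expect_equal(zs[which.max(fr)], p$z_inhabited)
  below <- fr[zs > p$z_inhabited]
  expect_true(all(diff(below) < 0))
  # surface fraction identity holds for other parameterizations too
  p2 <- decay_params(N0 = 3, B_surface = 40, B_bottom = 2)
  expect_equal(fraction_profile(0, p2)$fraction, 3 / 43)
})

test_that("parameter invariants are enforced", {
  expect_error(decay_params(lambda_b = 1.5), "lambda_b")
  expect_error(decay_params(B_surface = 1, B_bottom = 2))
  expect_error(decay_params(z_inhabited = 0))
})

test_that("noiseless profiles are recovered to machine precision", {
  truth <- decay_params(lambda_p = 1.3, tau_scale = 0.03)
  z <- seq(0.5, 30, length.out = 25)
  f <- fraction_profile(z, truth)$fraction
  fit <- fit_decay_params(z, f, params = decay_params())
  expect_true(fit$converged)
  expect_lt(abs(fit$estimates["lambda_p"] - 1.3) / 1.3, 1e-6)
  expect_lt(abs(fit$estimates["tau_scale"] - 0.03) / 0.03, 1e-6)
  expect_lt(fit$rss, 1e-12)

  expect_error(fit_decay_params(1, 0.5), "at least")
  expect_error(fit_decay_params(c(1, 2), c(0, 0.5)), "strictly inside")
})

test_that("fitting tolerates noise and flags non-convergence instead of failing", {
  p <- decay_params()
  z <- seq(0.5, 30, length.out = 30)
  f <- fraction_profile(z, p)$fraction
  set.seed(20)
  y <- plogis(qlogis(f) + rnorm(30, 0, 0.05))
  fit <- fit_decay_params(z, y)
  expect_true(is.finite(fit$rss))
  expect_lt(abs(fit$estimates["lambda_p"] - 1), 0.5)
  expect_length(fit$residuals, 30)
})
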