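test_that("VE schedule is geometric with exact endpoints", {
  sch <- noise_schedule("VE", N = 3, sigma_min = 0.01, sigma_max = 0.6)
  # independent oracle: sigma_i = sigma_min * (sigma_max/sigma_min)^(i/N)
  expected <- 0.01 * (0.6 / 0.01)^((0:3) / 3)
  expect_equal(sch$sigmas, expected, tolerance = 1e-12)
  expect_identical(sch$sigmas[1], 0.01)
  expect_identical(sch$sigmas[4], 0.6)

  big <- noise_schedule("VE", N = 1500, sigma_max = 0.6)
  expect_length(big$sigmas, 1501L)
  expect_identical(big$sigmas[1501], 0.6)
  # log sigma affine in i
  ls <- log(big$sigmas)
  expect_lt(max(abs(diff(ls) - (ls[2] - ls[1]))), 1e-10)
  expect_true(all(diff(big$sigmas) > 0))
})

test_that("schedule construction rejects invalid parameters", {
  expect_error(noise_schedule("VE", N = 1), "N")
  expect_error(noise_schedule("VE", sigma_min = 0.5, sigma_max = 0.1), "sigma")
  expect_error(noise_schedule("VE", sigma_min = -1), "sigma")
  expect_error(noise_schedule("VP", beta_min = 5, beta_max = 1), "beta")
  expect_error(perturbation_kernel(noise_schedule("VE"), t = 1.5), "range")
  expect_error(perturbation_kernel(noise_schedule("VE"), i = 2000), "range")
})

test_that("perturbation kernel matches closed forms", {
  ve <- noise_schedule("VE", N = 10, sigma_min = 0.01, sigma_max = 2)
  kp <- perturbation_kernel(ve, i = 10)
  expect_equal(kp$mean_coeff, 1)
  expect_equal(kp$std, 2)

  vp <- noise_schedule("VP", N = 100, beta_min = 0.1, beta_max = 20)
  k0 <- perturbation_kernel(vp, t = 0)
  expect_equal(k0$mean_coeff, 1)
  expect_equal(k0$std, 0)
  # closed-form integral oracle at t = 1: the mean coefficient is
  # exp(-1/2 int_0^1 beta(s) ds) with int beta = 0.1 + (20 - 0.1)/2 = 10.05
  ib <- stats::integrate(function(s) 0.1 + s * (20 - 0.1), 0, 1)$value
  k1 <- perturbation_kernel(vp, t = 1)
  expect_equal(k1$mean_coeff, exp(-ib / 2), tolerance = 1e-9)
  expect_equal(k1$std, sqrt(1 - exp(-ib / 2)^2), tolerance = 1e-9)
  # mean coefficient decays monotonically and std grows
  tt <- seq(0, 1, by = 0.1)
  kk <- perturbation_kernel(vp, t = tt)
  expect_true(all(diff(kk$mean_coeff) < 0))
  expect_true(all(diff(kk$std) > 0))
})

test_that("perturb applies the kernel and respects shapes", {
  ve <- noise_schedule("VE", N = 10, sigma_min = 0.01, sigma_max = 2)
  x0 <- matrix(0, 4, 4)
  z <- matrix(1, 4, 4)
  expect_equal(perturb(x0, ve, i = 10, z = z), matrix(2, 4, 4))
  vp <- noise_schedule("VP", N = 10)
  x0 <- matrix(rnorm(16), 4, 4)
  expect_equal(perturb(x0, vp, t = 0, z = matrix(rnorm(16), 4)), x0)
  expect_error(perturb(x0, ve, i = 1, z = matrix(1, 2, 2)), "shape")
  # Monte-Carlo variance oracle at sigma = 0.5
  sch <- noise_schedule("VE", N = 2, sigma_min = 0.25, sigma_max = 1)
  withr::with_seed(1, {
    draws <- perturb(rep(0, 1e5), sch, i = 1)  # sigma_1 = 0.5
  })
  expect_equal(stats::var(draws), 0.25, tolerance = 0.02)
})

test_that("score_target equals the analytic Gaussian score", {
  sch <- noise_schedule("VE", N = 2, sigma_min = 0.3, sigma_max = 1.2)
  expect_equal(score_target(0, 2, sch, i = 2)[1], -2 / 1.2^2)
  x0 <- matrix(rnorm(25), 5, 5)
  expect_equal(score_target(x0, x0, sch, i = 0), matrix(0, 5, 5))
  # finite-difference oracle on log N(xt; x0, sigma^2), sigma = 0.3
  withr::with_seed(2, {
    x0 <- matrix(rnorm(9), 3, 3)
    xt <- matrix(rnorm(9), 3, 3)
  })
  st <- score_target(x0, xt, sch, i = 0)
  h <- 1e-6
  logp <- function(x) sum(dnorm(x, mean = x0, sd = 0.3, log = TRUE))
  fd <- matrix(0, 3, 3)
  for (k in seq_len(9)) {
    xp <- xt; xp[k] <- xp[k] + h
    xm <- xt; xm[k] <- xm[k] - h
    fd[k] <- (logp(xp) - logp(xm)) / (2 * h)
  }
  expect_lt(max(abs(st - fd)), 1e-4)
  # degenerate VP time
  vp <- noise_schedule("VP", N = 10)
  expect_error(score_target(x0, xt, vp, t = 0), "degenerate")
})

test_that("VE adds variance and VP preserves it (Monte Carlo)", {
  ve <- noise_schedule("VE", N = 4, sigma_min = 0.05, sigma_max = 0.8)
  n <- 4e4
  withr::with_seed(3, {
    for (i in c(1L, 4L)) {
      sig <- schedule_sigma(ve, i)
      draws <- perturb(rep(0.7, n), ve, i = i)
      se_var <- sig^2 * sqrt(2 / n)
      expect_lt(abs(stats::var(draws) - sig^2), 3 * se_var)
      expect_lt(abs(mean(draws) - 0.7), 3 * sig / sqrt(n))
    }
    vp <- noise_schedule("VP", N = 4)
    for (t in c(0.25, 1)) {
      x0 <- rnorm(n)  # unit-variance data
      draws <- perturb(x0, vp, t = t)
      expect_lt(abs(stats::var(draws) - 1), 3 * sqrt(2 / n))
    }
  })
})
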