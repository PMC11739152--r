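test_that("predictor step matches the discretized reverse-SDE update", {
  # geometric schedule holding sigma = (0.5, 1, 2)
  sch <- noise_schedule("VE", N = 2, sigma_min = 0.5, sigma_max = 2)
  x <- matrix(1, 2, 2)
  score <- matrix(-0.25, 2, 2)
  z0 <- matrix(0, 2, 2)
  # x + (sigma_{i+1}^2 - sigma_i^2) * score + sqrt(.) * z = 1 + 3 * (-0.25)
  expect_equal(predictor_step(x, 1L, score, sch, z = z0), matrix(0.25, 2, 2))
  expect_equal(predictor_step(x, 1L, matrix(0, 2, 2), sch, z = z0), x)
  expect_error(predictor_step(x, 2L, score, sch), "0..N-1")
  expect_error(predictor_step(x, 1L, matrix(0, 3, 3), sch), "shape|match")
})

test_that("corrector step and its step-size rule follow the Langevin form", {
  x <- matrix(0, 2, 2)
  sc <- matrix(2, 2, 2)
  z0 <- matrix(0, 2, 2)
  expect_equal(corrector_step(x, sc, 0.01, z = z0), matrix(0.02, 2, 2))
  expect_identical(corrector_step(x, sc, 0, z = z0), x)
  expect_error(corrector_step(x, sc, -1, z = z0), "eps")
  # ||z|| = ||score||, r = 0.5 -> eps = 2 * 0.25 = 0.5
  s <- matrix(1, 4, 4); z <- matrix(-1, 4, 4)
  expect_equal(corrector_step_size(s, z, 0.5), 0.5)
  expect_equal(corrector_step_size(s, z, 1.0), 4 * corrector_step_size(s, z, 0.5))
  withr::with_seed(51, {
    s <- matrix(rnorm(64), 8); z <- matrix(rnorm(64), 8)
  })
  direct <- 2 * (0.16 * sqrt(sum(z^2)) / sqrt(sum(s^2)))^2
  expect_equal(corrector_step_size(s, z, 0.16), direct, tolerance = 1e-12)
  expect_warning(
    eps <- corrector_step_size(matrix(0, 2, 2), z = matrix(1, 2, 2),
                               snr_r = 0.16, fallback_sigma = 0.5),
    "fallback|zero")
  expect_equal(eps, 0.5^2 * 1e-4)
})

test_that("corrector-only chain reaches the analytic stationary variance", {
  # target distribution N(0, sd_data^2) per pixel, fixed noise level sigma:
  # the Langevin chain should converge to variance sd_data^2 + sigma^2
  sd_data <- 0.1
  sigma <- 0.2
  v <- sd_data^2 + sigma^2
  score_fn <- function(x) -x / v
  withr::with_seed(52, {
    x <- matrix(rnorm(64 * 64), 64, 64)  # start far from stationarity
    for (it in seq_len(400)) {
      z <- matrix(rnorm(length(x)), nrow(x))
      s <- score_fn(x)
      eps <- corrector_step_size(s, z, 0.16)
      x <- corrector_step(x, s, eps, z)
    }
  })
  expect_equal(stats::var(as.vector(x)), v, tolerance = 0.05)
})

test_that("data consistency rewrites conditioning channels only, idempotently", {
  withr::with_seed(53, {
    stack <- array(rnorm(8 * 8 * 3 * 2), c(8, 8, 3, 2))
    cond <- array(rnorm(8 * 8 * 2 * 2), c(8, 8, 2, 2))
  })
  out <- apply_data_consistency(stack, cond)
  expect_identical(out[, , 2:3, ], cond)
  expect_identical(out[, , 1, ], stack[, , 1, ])
  expect_identical(apply_data_consistency(out, cond), out)
  expect_error(apply_data_consistency(stack, cond[, , 1, , drop = FALSE]),
               "shape")
  # unbatched variant
  s3 <- stack[, , , 1]
  c3 <- cond[, , , 1]
  o3 <- apply_data_consistency(s3, c3)
  expect_identical(o3[, , 2:3], c3)
})

test_that("sampler recovers a Gaussian target from its analytic score", {
  sd_data <- 0.1
  mu <- 0.3
  sch <- noise_schedule("VE", N = 100, sigma_min = 0.01, sigma_max = 0.6)
  oracle <- gaussian_oracle_score(mu, sd_data)
  cond <- array(0, c(16, 16, 1, 16))
  pc <- sample_dose(oracle, cond, sch,
                    sampler_config(N_steps = 100, M_corrector = 1, seed = 54,
                                   clip = FALSE))
  n <- length(pc)
  se <- sd_data / sqrt(n)  # pixels are independent draws
  expect_lt(abs(mean(pc) - mu), 3 * se)
  expect_equal(stats::var(as.vector(pc)), sd_data^2, tolerance = 0.15)
  # predictor-only also converges; corrector does not make things worse
  po <- sample_dose(oracle, cond, sch,
                    sampler_config(N_steps = 100, M_corrector = 0, seed = 54,
                                   clip = FALSE))
  expect_true(all(is.finite(po)))
  expect_lte(abs(mean(pc) - mu), abs(mean(po) - mu) + 3 * se)
})

test_that("sampling is seed-deterministic and annealing is monotone", {
  sigmas_seen <- c()
  cond_ok <- TRUE
  cond <- array(0.5, c(8, 8, 1, 2))
  probe <- function(x_stack, sigma) {
    sigmas_seen <<- c(sigmas_seen, sigma[1])
    cond_ok <<- cond_ok && identical(x_stack[, , 2, , drop = FALSE],
                                     array(cond, c(8, 8, 1, 2)))
    d <- dim(x_stack)
    -array(x_stack[, , 1, ], c(d[1], d[2], d[4])) / (0.01 + sigma[1]^2)
  }
  sch <- noise_schedule("VE", N = 20)
  cfgs <- sampler_config(N_steps = 20, M_corrector = 0, seed = 55)
  a <- sample_dose(probe, cond, sch, cfgs)
  expect_true(cond_ok)
  # predictor-only: the noise scale fed to the model strictly decreases
  # (final entry is the last-scale denoising pass)
  outer_sigmas <- sigmas_seen[seq_len(20)]
  expect_true(all(diff(outer_sigmas) < 0))
  b <- sample_dose(probe, cond, sch, cfgs)
  expect_identical(a, b)
  c2 <- sample_dose(probe, cond, sch,
                    sampler_config(N_steps = 20, M_corrector = 0, seed = 56))
  expect_false(identical(a, c2))
  # mismatched iteration count is a configuration error
  expect_error(sample_dose(probe, cond, sch,
                           sampler_config(N_steps = 10, seed = 1)),
               "discretization")
})

test_that("sampler output respects clipping and degenerate configs", {
  oracle <- gaussian_oracle_score(0.5, 0.05)
  sch <- noise_schedule("VE", N = 10)
  cond <- array(0, c(8, 8, 1))
  out <- sample_dose(oracle, cond, sch,
                     sampler_config(N_steps = 10, M_corrector = 0, seed = 57))
  expect_identical(dim(out), c(8L, 8L))
  expect_true(all(out >= 0 & out <= 1.2))
  out2 <- sample_dose(oracle, cond, sch,
                      sampler_config(N_steps = 10, M_corrector = 2, seed = 57,
                                     final_denoise = FALSE))
  expect_true(all(is.finite(out2)))
})
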