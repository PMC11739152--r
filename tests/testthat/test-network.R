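test_that("configuration contract is enforced", {
  expect_error(score_model_config(in_channels = 1), "in_channels")
  expect_error(score_model_config(kernel_size = 4), "odd")
  expect_error(score_model_config(base_width = 0), "positive")
  cfg <- score_model_config(base_width = 64, depth = 3)
  expect_identical(cfg$width_multipliers, c(1L, 2L, 2L))
})

test_that("parameter count grows with width and init is seed-deterministic", {
  small <- build_score_model(tiny_model_config(base_width = 4), seed = 1)
  wide <- build_score_model(tiny_model_config(base_width = 8), seed = 1)
  expect_gt(scoredose:::n_parameters(wide), scoredose:::n_parameters(small))
  again <- build_score_model(tiny_model_config(base_width = 4), seed = 1)
  expect_identical(small$params, again$params)
  other <- build_score_model(tiny_model_config(base_width = 4), seed = 2)
  expect_false(identical(small$params, other$params))
})

test_that("forward pass honours the shape contract and is reproducible", {
  m <- tiny_model()
  withr::with_seed(4, X <- array(rnorm(32 * 32 * 2), c(32, 32, 2, 1)))
  s1 <- score_forward(m, X, sigma = 0.3)
  expect_identical(dim(s1), c(32L, 32L, 1L))
  expect_true(all(is.finite(s1)))
  expect_identical(s1, score_forward(m, X, sigma = 0.3))
  # unbatched input -> unbatched output
  X2 <- X[, , , 1]
  s2 <- score_forward(m, X2, sigma = 0.3)
  expect_identical(dim(s2), c(32L, 32L))
  expect_equal(as.vector(s2), as.vector(s1))
  # any spatial size divisible by 2^depth works, and odd sizes are padded
  for (hw in list(c(16L, 24L), c(9L, 13L))) {
    Xs <- array(rnorm(prod(hw) * 2), c(hw, 2L, 1L))
    out <- score_forward(m, Xs, sigma = 0.1)
    expect_identical(dim(out), c(hw, 1L))
    expect_true(all(is.finite(out)))
  }
  expect_error(score_forward(m, array(0, c(16, 16, 3, 1)), sigma = 0.1),
               "channels")
})

test_that("time conditioning and conditioning channels are both live", {
  m <- live_tiny_model(seed = 3)
  withr::with_seed(5, X <- array(rnorm(16 * 16 * 2), c(16, 16, 2, 1)))
  a <- score_forward(m, X, sigma = 0.05)
  b <- score_forward(m, X, sigma = 0.5)
  expect_gt(max(abs(a * 0.05 - b * 0.5)), 0)  # compare raw eps outputs
  Xp <- X
  Xp[, , 2, ] <- X[rev(seq_len(16)), , 2, ]  # permute the conditioning channel
  cp <- score_forward(m, Xp, sigma = 0.05)
  expect_gt(max(abs(a - cp)), 0)
})

test_that("analytic gradients match finite differences on every tensor", {
  m <- tiny_model(seed = 11)
  withr::with_seed(12, {
    X <- array(rnorm(8 * 8 * 2 * 2), c(8, 8, 2, 2))
    z <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  })
  sigma <- c(0.1, 0.5)
  loss_fn <- function(params) {
    m2 <- m
    m2$params <- params
    mean((scoredose:::model_forward(m2, X, sigma)$eps - z)^2)
  }
  out <- scoredose:::model_forward(m, X, sigma, cache = TRUE)
  dl <- 2 * (out$eps - z) / length(z)
  grads <- scoredose:::model_backward(m, out$caches, dl)
  h <- 1e-6
  withr::with_seed(13, {
    for (nm in names(m$params)) {
      len <- length(m$params[[nm]])
      for (ix in sample(len, min(2L, len))) {
        pp <- m$params; pp[[nm]][ix] <- pp[[nm]][ix] + h
        pm <- m$params; pm[[nm]][ix] <- pm[[nm]][ix] - h
        fd <- (loss_fn(pp) - loss_fn(pm)) / (2 * h)
        expect_equal(grads[[nm]][ix], fd, tolerance = 1e-4,
                     label = sprintf("analytic grad of %s", nm))
      }
    }
  })
})

test_that("gradients reach every tensor after one optimizer step", {
  m <- tiny_model(seed = 21)
  withr::with_seed(22, {
    x0 <- array(rnorm(16 * 16 * 4), c(16, 16, 4))
    cond <- array(rnorm(16 * 16 * 1 * 4), c(16, 16, 1, 4))
  })
  sch <- noise_schedule("VE", N = 20)
  withr::with_seed(23, {
    st1 <- scoredose:::train_step_grads(m, x0, cond, sch, "sigma_sq")
    upd <- scoredose:::adam_step(m$params, st1$grads,
                                 scoredose:::adam_init(m$params), 1e-3)
    m$params <- upd$params
    st2 <- scoredose:::train_step_grads(m, x0, cond, sch, "sigma_sq")
  })
  nonzero <- vapply(st2$grads, function(g) any(g != 0), TRUE)
  expect_true(all(nonzero))
})

test_that("checkpoints restore exact forward behaviour", {
  m <- tiny_model(seed = 31)
  withr::with_seed(32, X <- array(rnorm(16 * 16 * 2), c(16, 16, 2, 1)))
  ref <- score_forward(m, X, sigma = 0.2)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  fit <- load_checkpoint(path)
  expect_identical(score_forward(fit$model, X, sigma = 0.2), ref)
  # corrupted archive -> clean error
  bad <- withr::local_tempfile(fileext = ".rds")
  writeLines("not a checkpoint", bad)
  expect_error(load_checkpoint(bad), "checkpoint")
})
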