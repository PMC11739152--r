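# Shared fixtures: tiny models, analytic-score oracles and miniature paired
# datasets, all generated in code under fixed seeds.

tiny_model_config <- function(in_channels = 2L, base_width = 4L, depth = 2L) {
  score_model_config(in_channels = in_channels, base_width = base_width,
                     depth = depth, time_embed_dim = 8L)
}

tiny_model <- function(seed = 1L, ...) {
  build_score_model(tiny_model_config(...), seed = seed)
}

# as tiny_model, but with a non-zero output convolution (the freshly built
# network zero-initializes its last layer, so its output is identically zero
# until trained; sensitivity checks need a live output path)
live_tiny_model <- function(seed = 1L, ...) {
  m <- tiny_model(seed = seed, ...)
  withr::with_seed(seed + 1000L, {
    m$params[["conv_out.W"]][] <- stats::rnorm(length(m$params[["conv_out.W"]]),
                                               sd = 0.3)
  })
  m
}

# Analytic score of an isotropic Gaussian data distribution N(mu, sd_data^2)
# per pixel, marginalized over the VE perturbation at scale sigma. Ignores
# the conditioning channels; the target channel is channel 1 of the stack.
gaussian_oracle_score <- function(mu, sd_data) {
  function(x_stack, sigma) {
    d <- dim(x_stack)
    batched <- length(d) == 4L
    if (!batched) dim(x_stack) <- c(d, 1L)
    xt <- x_stack[, , 1L, , drop = FALSE]
    dim(xt) <- dim(x_stack)[c(1, 2, 4)]
    B <- dim(xt)[3]
    sig <- if (length(sigma) == 1L) rep(sigma, B) else sigma
    v <- sd_data^2 + sig^2
    s <- -(xt - mu) / rep(v, each = dim(xt)[1] * dim(xt)[2])
    if (!batched) dim(s) <- dim(s)[1:2]
    s
  }
}

# A miniature paired cohort (constant-ish fields) for training smoke tests:
# the measured dose is a constant field with case-level Gaussian variation.
toy_constant_dataset <- function(n = 32L, H = 16L, seed = 7L,
                                 mu = 0.5, sd_case = 0.1) {
  withr::with_seed(seed, {
    cases <- lapply(seq_len(n), function(j) {
      level <- mu + sd_case * stats::rnorm(1)
      structure(list(case_id = sprintf("toy_%03d", j),
                     site = "chest",
                     ct = matrix(0, H, H),
                     rtdose = matrix(mu, H, H),
                     mdose = matrix(level, H, H),
                     spacing = c(1, 1)),
                class = "dose_case")
    })
    scoredose:::new_dose_dataset(cases)
  })
}

small_phantom_dataset <- function(n = 12L, seed = 5L, grid = 32L,
                                  error = error_model()) {
  make_dataset(n_cases = n, split_ratio = 0.75, spec = phantom_spec(grid),
               error = error, seed = seed)
}

# run config pointing all outputs into a temporary directory
tmp_run_config <- function(dir, n_cases = 6L, seed = 1L, grid = 32L) {
  cfg <- default_run_config(out_dir = dir)
  cfg$seed <- seed
  cfg$data$dir <- file.path(dir, "dataset")
  cfg$data$n_cases <- n_cases
  cfg$data$grid_size <- grid
  cfg$schedule$N <- 10L
  cfg$sampler$N_steps <- 10L
  cfg$model$base_width <- 4L
  cfg$model$depth <- 2L
  cfg$model$time_embed_dim <- 8L
  cfg$train$epochs <- 1L
  cfg$train$batch_size <- 2L
  cfg$train$val_fraction <- 0.25
  cfg
}
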