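#' Sampler configuration
#'
#' Settings for reverse-SDE predictor-corrector generation. `N_steps` is the
#' number of outer predictor iterations (the reverse-SDE discretization;
#' default 1500), `M_corrector` the annealed-Langevin refinements per outer
#' step, and `snr_r` the signal-to-noise ratio used to set the Langevin step
#' size.
#'
#' @param N_steps Outer iterations (`>= 1`).
#' @param M_corrector Corrector steps per outer iteration (`>= 0`).
#' @param snr_r Corrector signal-to-noise ratio (`> 0`).
#' @param final_denoise Apply the last-scale denoising move
#'   \eqn{x + \sigma_0^2 s} (no noise) after the loop.
#' @param clip Clip the returned field to `[0, 1.2]` of normalized dose
#'   (delivered dose is non-negative and may mildly exceed the planned
#'   maximum).
#' @param seed Integer seed for the sampling noise.
#' @param dc_mode Data-consistency mode; only `"reimpose_conditioning"` (the
#'   clean conditioning channels are rewritten into the stack at every
#'   iteration).
#' @return An object of class `sampler_config`.
#' @export
sampler_config <- function(N_steps = 1500L, M_corrector = 1L, snr_r = 0.16,
                           final_denoise = TRUE, clip = TRUE, seed = 1L,
                           dc_mode = "reimpose_conditioning") {
  dc_mode <- match.arg(dc_mode, "reimpose_conditioning")
  N_steps <- as.integer(N_steps)
  M_corrector <- as.integer(M_corrector)
  if (N_steps < 1L) stop("`N_steps` must be >= 1", call. = FALSE)
  if (M_corrector < 0L) stop("`M_corrector` must be >= 0", call. = FALSE)
  if (!is.finite(snr_r) || snr_r <= 0) stop("`snr_r` must be > 0", call. = FALSE)
  structure(list(N_steps = N_steps, M_corrector = M_corrector, snr_r = snr_r,
                 final_denoise = isTRUE(final_denoise), clip = isTRUE(clip),
                 seed = as.integer(seed), dc_mode = dc_mode),
            class = "sampler_config")
}

#' Reverse-SDE predictor update
#'
#' One step of the discretized reverse SDE from scale `i + 1` down to `i`.
#' In the variance-exploding form:
#' \deqn{\hat x_i = x_{i+1} + (\sigma_{i+1}^2 - \sigma_i^2)\, s
#'   + \sqrt{\sigma_{i+1}^2 - \sigma_i^2}\, z.}
#' For VP schedules the reparameterized (ancestral) form is used:
#' \eqn{\hat x_i = (x_{i+1} + \beta_{i+1} s)/\sqrt{1 - \beta_{i+1}}
#' + \sqrt{\beta_{i+1}} z} with discrete \eqn{\beta_{i+1} = \beta(t_{i+1})/N}.
#'
#' @param x Current field (any shape).
#' @param i Target scale index in `0..N-1`.
#' @param score Score estimate at the current scale `i + 1`, same shape as `x`.
#' @param schedule A [noise_schedule()].
#' @param z Standard-normal field (same shape); drawn from the current R
#'   random stream if omitted.
#' @return The updated field.
#' @export
predictor_step <- function(x, i, score, schedule, z = NULL) {
  stopifnot(inherits(schedule, "noise_schedule"))
  i <- as.integer(i)
  if (i < 0L || i > schedule$N - 1L) stop("`i` must be in 0..N-1", call. = FALSE)
  if (!identical(length(x), length(score))) {
    stop("`score` must match the shape of `x`", call. = FALSE)
  }
  if (is.null(z)) z <- array(stats::rnorm(length(x)), dim = dim(x) %||% length(x))
  if (schedule$kind == "VE") {
    s_hi <- schedule$sigmas[i + 2L]
    s_lo <- schedule$sigmas[i + 1L]
    d <- s_hi^2 - s_lo^2
    if (d <= 0) stop("schedule is not strictly increasing", call. = FALSE)
    x + d * score + sqrt(d) * z
  } else {
    t_hi <- (i + 1L) / schedule$N
    beta_d <- (schedule$beta_min + t_hi * (schedule$beta_max - schedule$beta_min)) /
      schedule$N
    (x + beta_d * score) / sqrt(1 - beta_d) + sqrt(beta_d) * z
  }
}

#' Annealed-Langevin corrector update
#'
#' One Langevin Monte Carlo refinement at a fixed noise scale:
#' \deqn{\tilde x = \hat x + \epsilon\, s + \sqrt{2 \epsilon}\, z.}
#'
#' @param x Current field.
#' @param score Score estimate at the current scale, same shape.
#' @param eps Step size(s), `>= 0`; a scalar, or one value per batch slice
#'   when `x` has a trailing batch dimension of matching length.
#' @param z Standard-normal field; drawn from the current R stream if omitted.
#' @return The updated field.
#' @export
corrector_step <- function(x, score, eps, z = NULL) {
  if (any(eps < 0)) stop("`eps` must be >= 0", call. = FALSE)
  if (!identical(length(x), length(score))) {
    stop("`score` must match the shape of `x`", call. = FALSE)
  }
  if (is.null(z)) z <- array(stats::rnorm(length(x)), dim = dim(x) %||% length(x))
  if (length(eps) > 1L) {
    per <- length(x) / length(eps)
    if (per != floor(per)) stop("`eps` length incompatible with `x`", call. = FALSE)
    eps <- rep(eps, each = per)
  }
  x + eps * score + sqrt(2 * eps) * z
}

#' Signal-to-noise corrector step size
#'
#' The Langevin step size is set from the ratio of the noise and score norms,
#' \eqn{\epsilon = 2 (r \|z\|_2 / \|s\|_2)^2}, so that the deterministic and
#' stochastic parts of the corrector move keep a fixed signal-to-noise ratio
#' `r`.
#'
#' @param score Score field.
#' @param z The noise field that will be used in the corrector move.
#' @param snr_r Target signal-to-noise ratio (`> 0`).
#' @param fallback_sigma Scale used for the fallback step size
#'   `sigma^2 * 1e-4` when the score norm is zero (with a warning).
#' @return Positive finite step size.
#' @export
corrector_step_size <- function(score, z, snr_r, fallback_sigma = NULL) {
  if (snr_r <= 0) stop("`snr_r` must be > 0", call. = FALSE)
  sn <- sqrt(sum(score^2))
  zn <- sqrt(sum(z^2))
  if (sn == 0) {
    if (is.null(fallback_sigma)) {
      stop("zero score norm and no `fallback_sigma` supplied", call. = FALSE)
    }
    warning("zero score norm; falling back to sigma^2 * 1e-4 step size",
            call. = FALSE)
    return(fallback_sigma^2 * 1e-4)
  }
  2 * (snr_r * zn / sn)^2
}

#' Re-impose conditioning channels (data consistency)
#'
#' Overwrites channels `2..C` of the sampling stack with the clean
#' conditioning fields, leaving the evolving target channel untouched. Applied
#' after every predictor and corrector move so that only the target channel
#' ever departs from the measured inputs.
#'
#' @param x_stack Array `(H, W, C)` or `(H, W, C, B)`.
#' @param conditioning Array `(H, W, C-1)` or `(H, W, C-1, B)`.
#' @return `x_stack` with conditioning channels replaced.
#' @export
apply_data_consistency <- function(x_stack, conditioning) {
  dx <- dim(x_stack)
  dc <- dim(conditioning)
  if (length(dc) == length(dx) - 1L) dc <- c(dc, 1L)
  if (length(dx) == 3L) {
    dim(x_stack) <- c(dx, 1L)
    dim(conditioning) <- dc
    out <- apply_data_consistency(x_stack, conditioning)
    dim(out) <- dx
    return(out)
  }
  if (!identical(dx[c(1, 2, 4)], dc[c(1, 2, 4)]) || dc[3] != dx[3] - 1L) {
    stop("conditioning shape must be (H, W, C-1[, B]) matching the stack",
         call. = FALSE)
  }
  x_stack[, , 1L + seq_len(dc[3]), ] <- conditioning
  x_stack
}

#' Predictor-corrector sampling of the delivered dose
#'
#' Generates the predicted delivered dose (PDose) from pure Gaussian noise
#' conditioned on the planned dose (and optional CT): channel 1 is initialized
#' as \eqn{N(0, \sigma_{max}^2)} and annealed through the reverse SDE, with
#' the conditioning channels re-imposed (data consistency) after every move.
#'
#' @param model A trained `score_model`, a [train_score_model()] fit, or a
#'   score function `(x_stack, sigma) -> field` (analytic oracles).
#' @param conditioning Array `(H, W, C-1)` or `(H, W, C-1, B)` of clean
#'   conditioning channels, normalized as in training.
#' @param schedule A [noise_schedule()] (taken from the fit if one is given).
#' @param config A [sampler_config()].
#' @return Field `(H, W)` or `(H, W, B)`: the predicted dose, clipped to
#'   `[0, 1.2]` when `config$clip` is set.
#' @export
sample_dose <- function(model, conditioning, schedule = NULL,
                        config = sampler_config()) {
  stopifnot(inherits(config, "sampler_config"))
  if (inherits(model, "scoredose_fit")) {
    if (is.null(schedule)) schedule <- model$schedule
    model <- model$model
  }
  if (is.null(schedule)) stop("supply a `schedule`", call. = FALSE)
  if (config$N_steps != schedule$N) {
    stop(sprintf(paste0("`N_steps` (%d) must equal the schedule's discretization",
                        " count N (%d): the outer iteration count is the number",
                        " of discrete reverse-SDE steps"),
                 config$N_steps, schedule$N), call. = FALSE)
  }
  dcnd <- dim(conditioning)
  batched <- length(dcnd) == 4L
  if (!batched) dim(conditioning) <- c(dcnd, 1L)
  d <- dim(conditioning)
  H <- d[1]; W <- d[2]; Ccond <- d[3]; B <- d[4]
  if (inherits(model, "score_model") && model$config$in_channels != Ccond + 1L) {
    stop(sprintf("model expects %d conditioning channel(s); got %d",
                 model$config$in_channels - 1L, Ccond), call. = FALSE)
  }
  nP <- H * W
  sig_at <- function(i) schedule_sigma(schedule, i)
  x <- withr::with_seed(config$seed, {
    sig_top <- if (schedule$kind == "VE") schedule$sigma_max else 1
    x <- array(stats::rnorm(nP * B, sd = sig_top), c(H, W, B))
    X <- array(0, c(H, W, Ccond + 1L, B))
    X <- apply_data_consistency(X, conditioning)
    for (step in seq_len(config$N_steps)) {
      i_hi <- schedule$N - step + 1L   # current scale
      i_lo <- i_hi - 1L                # target scale of the predictor
      X[, , 1L, ] <- x
      s <- score_forward(model, X, sigma = sig_at(i_hi))
      z <- array(stats::rnorm(nP * B), c(H, W, B))
      x <- predictor_step(x, i_lo, s, schedule, z)
      X[, , 1L, ] <- x
      X <- apply_data_consistency(X, conditioning)
      if (config$M_corrector > 0L) {
        for (mcr in seq_len(config$M_corrector)) {
          s <- score_forward(model, X, sigma = sig_at(i_lo))
          z <- array(stats::rnorm(nP * B), c(H, W, B))
          eps <- vapply(seq_len(B), function(b) {
            corrector_step_size(s[, , b], z[, , b], config$snr_r,
                                fallback_sigma = sig_at(i_lo))
          }, 0)
          x <- corrector_step(x, s, eps, z)
          X[, , 1L, ] <- x
          X <- apply_data_consistency(X, conditioning)
        }
      }
    }
    if (config$final_denoise) {
      sig0 <- sig_at(0L)
      if (sig0 > 0) {
        X[, , 1L, ] <- x
        s <- score_forward(model, X, sigma = sig0)
        x <- x + sig0^2 * s
      }
    }
    x
  })
  if (config$clip) x <- pmin(pmax(x, 0), 1.2)
  if (!batched) dim(x) <- c(H, W)
  x
}
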