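#' Construct a diffusion noise schedule
#'
#' Defines the noise parameterization of the forward stochastic differential
#' equation (SDE) used for both training and sampling. Two standard
#' parameterizations are supported:
#'
#' * **VE** (variance exploding): the perturbation kernel is
#'   \eqn{x_t = x_0 + \sigma(t) z}, with \eqn{N+1} discrete scales
#'   \eqn{\sigma_0 < \dots < \sigma_N} geometrically spaced between
#'   `sigma_min` and `sigma_max`.
#' * **VP** (variance preserving): drift \eqn{f = -\tfrac12\beta(t)x},
#'   diffusion \eqn{g = \sqrt{\beta(t)}} with a linear, strictly increasing
#'   \eqn{\beta(t)} on \eqn{(0,1)}; total variance of unit-variance data is
#'   held at 1 for all t.
#'
#' The VE form with `sigma_max = 0.6` is the package default: the
#' predictor-corrector updates used at sampling time are written in terms of
#' sigma-indexed noise scales, and the "initial noise scale" setting (0.6,
#' 6e2, 6e5) only has meaning on the VE scale axis.
#'
#' Time is handled discretely: index `i` in `0..N` maps to continuous time
#' `t = i/N` on the fixed horizon `T = 1`.
#'
#' @param kind `"VE"` or `"VP"`.
#' @param N Number of discretization steps (`N >= 2`); the schedule holds
#'   `N + 1` scales indexed `0..N`.
#' @param sigma_min,sigma_max VE bounds, `0 < sigma_min < sigma_max`.
#' @param beta_min,beta_max VP bounds on the (0,1) beta scale,
#'   `0 < beta_min < beta_max`.
#' @return An object of class `noise_schedule`.
#' @examples
#' sch <- noise_schedule("VE", N = 1500, sigma_min = 0.01, sigma_max = 0.6)
#' schedule_sigma(sch, i = 1500)  # 0.6
#' @export
noise_schedule <- function(kind = c("VE", "VP"), N = 1500L,
                           sigma_min = 0.01, sigma_max = 0.6,
                           beta_min = 0.1, beta_max = 20) {
  kind <- match.arg(kind)
  N <- as.integer(N)
  if (is.na(N) || N < 2L) {
    stop("`N` must be an integer >= 2", call. = FALSE)
  }
  if (kind == "VE") {
    if (!is.finite(sigma_min) || !is.finite(sigma_max) ||
        sigma_min <= 0 || sigma_max <= sigma_min) {
      stop("VE schedule requires 0 < sigma_min < sigma_max", call. = FALSE)
    }
    sigmas <- sigma_min * (sigma_max / sigma_min)^(seq(0L, N) / N)
    sigmas[N + 1L] <- sigma_max  # exact endpoint
    out <- list(kind = kind, N = N, T = 1,
                sigma_min = sigma_min, sigma_max = sigma_max,
                sigmas = sigmas)
  } else {
    if (!is.finite(beta_min) || !is.finite(beta_max) ||
        beta_min <= 0 || beta_max <= beta_min) {
      stop("VP schedule requires 0 < beta_min < beta_max", call. = FALSE)
    }
    out <- list(kind = kind, N = N, T = 1,
                beta_min = beta_min, beta_max = beta_max)
  }
  structure(out, class = "noise_schedule")
}

#' @export
print.noise_schedule <- function(x, ...) {
  if (x$kind == "VE") {
    cat(sprintf("<noise_schedule> VE, N = %d, sigma in [%g, %g] (geometric)\n",
                x$N, x$sigma_min, x$sigma_max))
  } else {
    cat(sprintf("<noise_schedule> VP, N = %d, beta(t) linear in [%g, %g]\n",
                x$N, x$beta_min, x$beta_max))
  }
  invisible(x)
}

# resolve (t, i) -> continuous time t in [0, T]; exactly one must be given
resolve_time <- function(schedule, t = NULL, i = NULL) {
  if (is.null(t) == is.null(i)) {
    stop("supply exactly one of `t` or `i`", call. = FALSE)
  }
  if (!is.null(i)) {
    if (any(i < 0 | i > schedule$N)) {
      stop("index `i` out of range 0..N", call. = FALSE)
    }
    t <- i / schedule$N
  }
  if (any(t < 0 | t > schedule$T)) {
    stop("time `t` out of range [0, T]", call. = FALSE)
  }
  t
}

#' Noise scale at a discrete index (VE)
#'
#' @param schedule A [noise_schedule()].
#' @param i Index (vectorized) in `0..N`.
#' @return `sigma_i` for VE schedules; for VP schedules the marginal standard
#'   deviation of the perturbation kernel at `t = i/N`.
#' @export
schedule_sigma <- function(schedule, i) {
  stopifnot(inherits(schedule, "noise_schedule"))
  if (any(i < 0 | i > schedule$N)) stop("index `i` out of range 0..N", call. = FALSE)
  if (schedule$kind == "VE") {
    schedule$sigmas[i + 1L]
  } else {
    perturbation_kernel(schedule, i = i)$std
  }
}

#' Closed-form perturbation kernel parameters
#'
#' The forward SDE admits a Gaussian transition kernel
#' \eqn{p_t(x_t | x_0) = N(x_t; m(t) x_0, s(t)^2 I)}. This returns the
#' mean coefficient \eqn{m(t)} and standard deviation \eqn{s(t)} in closed
#' form: VE has \eqn{m = 1, s = \sigma(t)}; VP with linear \eqn{\beta} has
#' \eqn{m = \exp(-\tfrac14 t^2 (\beta_{max}-\beta_{min}) - \tfrac12 t
#' \beta_{min})} and \eqn{s = \sqrt{1 - m^2}}.
#'
#' @inheritParams schedule_sigma
#' @param t Continuous time in `[0, 1]` (alternative to `i`); vectorized.
#' @param i Discrete index in `0..N`, mapped to `t = i/N`.
#' @return A list with vectors `mean_coeff` and `std`.
#' @export
perturbation_kernel <- function(schedule, t = NULL, i = NULL) {
  stopifnot(inherits(schedule, "noise_schedule"))
  tt <- resolve_time(schedule, t = t, i = i)
  if (schedule$kind == "VE") {
    if (!is.null(i)) {
      std <- schedule$sigmas[i + 1L]
    } else {
      std <- schedule$sigma_min * (schedule$sigma_max / schedule$sigma_min)^tt
    }
    list(mean_coeff = rep(1, length(tt)), std = std)
  } else {
    log_mean <- -0.25 * tt^2 * (schedule$beta_max - schedule$beta_min) -
      0.5 * tt * schedule$beta_min
    m <- exp(log_mean)
    list(mean_coeff = m, std = sqrt(pmax(1 - m^2, 0)))
  }
}

#' Sample from the forward perturbation kernel
#'
#' Returns \eqn{m(t) x_0 + s(t) z}. With `z` omitted, standard normal noise is
#' drawn from the current R random stream (all high-level entry points in the
#' package seed that stream explicitly).
#'
#' @param x0 Numeric array (any shape): the clean field.
#' @inheritParams perturbation_kernel
#' @param z Optional standard-normal array of the same shape as `x0`.
#' @return An array shaped like `x0`.
#' @export
perturb <- function(x0, schedule, t = NULL, i = NULL, z = NULL) {
  kp <- perturbation_kernel(schedule, t = t, i = i)
  if (length(kp$std) != 1L) stop("`perturb` takes a single time point", call. = FALSE)
  if (is.null(z)) {
    z <- array(stats::rnorm(length(x0)), dim = dim(x0) %||% length(x0))
  }
  if (!identical(length(z), length(x0)) ||
      !identical(dim(z) %||% length(z), dim(x0) %||% length(x0))) {
    stop("`z` must have the same shape as `x0`", call. = FALSE)
  }
  kp$mean_coeff * x0 + kp$std * z
}

#' Analytic score of the perturbation kernel
#'
#' The denoising-score-matching target: the gradient of the log Gaussian
#' perturbation kernel centred on `x0`,
#' \eqn{\nabla_{x_t} \log p_t(x_t | x_0) = -(x_t - m(t) x_0) / s(t)^2}.
#'
#' @param x0 Clean field.
#' @param xt Perturbed field, same shape as `x0`.
#' @inheritParams perturbation_kernel
#' @return An array shaped like `x0`.
#' @export
score_target <- function(x0, xt, schedule, t = NULL, i = NULL) {
  if (!identical(dim(x0) %||% length(x0), dim(xt) %||% length(xt))) {
    stop("`x0` and `xt` must have the same shape", call. = FALSE)
  }
  kp <- perturbation_kernel(schedule, t = t, i = i)
  if (length(kp$std) != 1L) stop("`score_target` takes a single time point", call. = FALSE)
  if (kp$std == 0) {
    stop("degenerate time: perturbation kernel has zero variance at t = 0 (VP)",
         call. = FALSE)
  }
  -(xt - kp$mean_coeff * x0) / kp$std^2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
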