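#' Training configuration
#'
#' Hyperparameters of the denoising score-matching loop. `lambda_weighting`
#' selects the per-scale weight \eqn{\lambda(\sigma)} of the objective:
#' `"sigma_sq"` (\eqn{\lambda = \sigma^2}, the standard choice that makes the
#' per-scale targets unit variance) or `"one"`.
#'
#' @param epochs Number of passes over the training cases.
#' @param batch_size Minibatch size (`>= 1`).
#' @param learning_rate Adam step size (`> 0`).
#' @param lambda_weighting `"sigma_sq"` or `"one"`.
#' @param ema_decay Exponential-moving-average decay for the returned weights
#'   in `[0, 1)`; `0` disables EMA.
#' @param seed Integer seed governing shuffling, scale sampling and noise.
#' @param time_sampling Only `"uniform_discrete"` (scale index drawn uniformly
#'   from `1..N` per sample).
#' @param val_fraction Fraction of the training cases held out for the
#'   per-epoch validation loss when no explicit validation set is given.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 10L, batch_size = 8L, learning_rate = 2e-4,
                         lambda_weighting = c("sigma_sq", "one"),
                         ema_decay = 0.999, seed = 1L,
                         time_sampling = "uniform_discrete",
                         val_fraction = 0.1) {
  lambda_weighting <- match.arg(lambda_weighting)
  time_sampling <- match.arg(time_sampling, "uniform_discrete")
  if (learning_rate <= 0) stop("`learning_rate` must be > 0", call. = FALSE)
  if (batch_size < 1L) stop("`batch_size` must be >= 1", call. = FALSE)
  if (ema_decay < 0 || ema_decay >= 1) stop("`ema_decay` must be in [0, 1)", call. = FALSE)
  if (epochs < 0L) stop("`epochs` must be >= 0", call. = FALSE)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, lambda_weighting = lambda_weighting,
                 ema_decay = ema_decay, seed = as.integer(seed),
                 time_sampling = time_sampling, val_fraction = val_fraction),
            class = "train_config")
}

# Stack a dataset into dense arrays: x0 (H, W, n) target (MDose) and
# cond (H, W, C-1, n) conditioning channels. `aux_channel` selects the third
# channel for 3-channel models: "ct" or "rtdose" (duplicated planned dose,
# the CT-free three-channel mode).
dataset_arrays <- function(data, in_channels, aux_channel = "ct") {
  cases <- dataset_cases(data)
  n <- length(cases)
  if (n == 0L) stop("dataset contains no cases", call. = FALSE)
  if (is.null(cases[[1]]$mdose)) stop("cases lack an MDose channel", call. = FALSE)
  d <- dim(cases[[1]]$mdose)
  x0 <- array(0, c(d[1], d[2], n))
  cond <- array(0, c(d[1], d[2], in_channels - 1L, n))
  for (j in seq_len(n)) {
    cs <- cases[[j]]
    x0[, , j] <- cs$mdose
    cond[, , 1L, j] <- cs$rtdose
    if (in_channels >= 3L) {
      cond[, , 2L, j] <- if (aux_channel == "ct") cs$ct else cs$rtdose
    }
  }
  list(x0 = x0, cond = cond,
       ids = vapply(cases, function(cs) cs$case_id, ""),
       sites = vapply(cases, function(cs) cs$site, ""))
}

# Draw (i, z, xt) for a batch and assemble the network input stack.
draw_perturbed_stack <- function(x0b, condb, schedule) {
  d <- dim(x0b)
  B <- d[3]
  idx <- sample.int(schedule$N, B, replace = TRUE)
  kp <- perturbation_kernel(schedule, i = idx)
  z <- array(stats::rnorm(prod(d)), d)
  nP <- d[1] * d[2]
  xt <- x0b * rep(kp$mean_coeff, each = nP) + z * rep(kp$std, each = nP)
  C <- dim(condb)[3] + 1L
  X <- array(0, c(d[1], d[2], C, B))
  X[, , 1L, ] <- xt
  X[, , 2:C, ] <- condb
  list(X = X, z = z, idx = idx, sigma = kp$std, mean_coeff = kp$mean_coeff)
}

#' Denoising score-matching loss
#'
#' The training objective: the score network is regressed onto the analytic
#' score of the Gaussian perturbation kernel,
#' \eqn{E_i E_{x_0} E_{x_t|x_0} \lambda(\sigma_i)
#' \| s_\Theta(x_t, i) - \nabla_{x_t} \log p_i(x_t|x_0) \|^2}
#' (per-pixel mean). With \eqn{\lambda = \sigma^2} this equals the mean of
#' \eqn{\|\sigma_i s_\Theta + z\|^2 / n_{pixels}}, so a perfect score gives 0
#' and the zero score gives 1 in expectation.
#'
#' Scale indices and noise are drawn from the current R random stream; seed it
#' (e.g. via [withr::with_seed()]) for reproducible evaluation.
#'
#' @param model A `score_model` or a score function `(x_stack, sigma) -> field`.
#' @param batch A `dose_dataset` or list of paired cases (each with `mdose`,
#'   `rtdose`, optionally `ct`).
#' @param schedule A [noise_schedule()].
#' @param lambda_weighting `"sigma_sq"` or `"one"`.
#' @param in_channels Channel count of the stack (defaults to the model's).
#' @param aux_channel `"ct"` or `"rtdose"`, third-channel content.
#' @return Scalar loss (non-negative).
#' @export
dsm_loss <- function(model, batch, schedule,
                     lambda_weighting = c("sigma_sq", "one"),
                     in_channels = NULL, aux_channel = "ct") {
  lambda_weighting <- match.arg(lambda_weighting)
  if (is.null(in_channels)) {
    in_channels <- if (inherits(model, "score_model")) model$config$in_channels else 2L
  }
  arr <- dataset_arrays(batch, in_channels, aux_channel)
  dr <- draw_perturbed_stack(arr$x0, arr$cond, schedule)
  s <- score_forward(model, dr$X, sigma = dr$sigma)
  d <- dim(arr$x0)
  nP <- d[1] * d[2]
  target <- -(dr$X[, , 1L, ] - arr$x0 * rep(dr$mean_coeff, each = nP)) /
    rep(dr$sigma^2, each = nP)
  lam <- if (lambda_weighting == "sigma_sq") dr$sigma^2 else rep(1, d[3])
  resid2 <- (s - target)^2
  per_case <- colMeans(matrix(resid2, nP, d[3]))
  mean(lam * per_case)
}

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

# One fused loss + gradient step on a batch (noise-prediction form).
train_step_grads <- function(model, x0b, condb, schedule, lambda_weighting) {
  dr <- draw_perturbed_stack(x0b, condb, schedule)
  out <- model_forward(model, dr$X, dr$sigma, cache = TRUE)
  d <- dim(x0b)
  nP <- d[1] * d[2]
  resid <- out$eps - dr$z
  if (lambda_weighting == "sigma_sq") {
    loss <- mean(resid^2)
    dl <- 2 * resid / length(resid)
  } else {
    w <- rep(1 / dr$sigma^2, each = nP)
    loss <- mean(resid^2 * w)
    dl <- 2 * resid * w / length(resid)
  }
  grads <- model_backward(model, out$caches, dl)
  list(loss = loss, grads = grads)
}

#' Train the score network
#'
#' Minimizes the denoising score-matching objective with Adam. Conditioning
#' channels are never perturbed: only the target (MDose) channel is noised.
#' The run is deterministic given `config$seed` on one platform.
#'
#' @param model A `score_model` from [build_score_model()].
#' @param data Training cases (`dose_dataset` or list of paired cases).
#' @param config A [train_config()].
#' @param schedule A [noise_schedule()].
#' @param val_data Optional held-out cases for the per-epoch validation loss;
#'   if `NULL`, `config$val_fraction` of `data` is split off.
#' @param aux_channel Third-channel content for 3-channel models
#'   (`"ct"` or `"rtdose"`).
#' @param verbose Print per-epoch losses.
#' @return An object of class `scoredose_fit`: the trained model (EMA weights
#'   when enabled), the per-epoch loss trace as a tibble, and the configs.
#' @export
train_score_model <- function(model, data, config = train_config(),
                              schedule = noise_schedule(), val_data = NULL,
                              aux_channel = "ct", verbose = FALSE) {
  stopifnot(inherits(model, "score_model"), inherits(config, "train_config"))
  arr <- dataset_arrays(data, model$config$in_channels, aux_channel)
  n <- dim(arr$x0)[3]
  withr::with_seed(config$seed, {
    if (is.null(val_data)) {
      n_val <- max(1L, floor(config$val_fraction * n))
      if (n_val >= n) stop("dataset too small to split off validation cases",
                           call. = FALSE)
      vidx <- sample.int(n, n_val)
      varr <- list(x0 = arr$x0[, , vidx, drop = FALSE],
                   cond = arr$cond[, , , vidx, drop = FALSE])
      tidx <- setdiff(seq_len(n), vidx)
      arr <- list(x0 = arr$x0[, , tidx, drop = FALSE],
                  cond = arr$cond[, , , tidx, drop = FALSE])
      n <- length(tidx)
    } else {
      varr <- dataset_arrays(val_data, model$config$in_channels, aux_channel)
    }
    state <- adam_init(model$params)
    ema <- if (config$ema_decay > 0) model$params else NULL
    trace <- vector("list", config$epochs)
    val_loss_of <- function(params) {
      m2 <- model
      m2$params <- params
      nv <- dim(varr$x0)[3]
      tot <- 0
      bs <- config$batch_size
      for (s0 in seq(1L, nv, by = bs)) {
        sel <- s0:min(s0 + bs - 1L, nv)
        st <- train_step_grads_loss_only(
          m2, varr$x0[, , sel, drop = FALSE], varr$cond[, , , sel, drop = FALSE],
          schedule, config$lambda_weighting)
        tot <- tot + st * length(sel)
      }
      tot / nv
    }
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      nb <- 0L
      for (s0 in seq(1L, n, by = config$batch_size)) {
        sel <- ord[s0:min(s0 + config$batch_size - 1L, n)]
        st <- train_step_grads(model,
                               arr$x0[, , sel, drop = FALSE],
                               arr$cond[, , , sel, drop = FALSE],
                               schedule, config$lambda_weighting)
        if (!is.finite(st$loss)) {
          stop(sprintf("training diverged: non-finite loss at epoch %d", ep),
               call. = FALSE)
        }
        upd <- adam_step(model$params, st$grads, state, config$learning_rate)
        model$params <- upd$params
        state <- upd$state
        if (!is.null(ema)) {
          dcy <- config$ema_decay
          for (nm in names(ema)) {
            ema[[nm]] <- dcy * ema[[nm]] + (1 - dcy) * model$params[[nm]]
          }
        }
        ep_loss <- ep_loss + st$loss
        nb <- nb + 1L
      }
      vl <- val_loss_of(if (!is.null(ema)) ema else model$params)
      trace[[ep]] <- tibble::tibble(epoch = ep, train_loss = ep_loss / nb,
                                    val_loss = vl)
      if (verbose) {
        message(sprintf("epoch %d/%d  train %.4f  val %.4f",
                        ep, config$epochs, ep_loss / nb, vl))
      }
    }
    if (!is.null(ema) && config$epochs > 0L) model$params <- ema
  })
  trace_tbl <- if (config$epochs > 0L) dplyr::bind_rows(trace) else
    tibble::tibble(epoch = integer(), train_loss = double(), val_loss = double())
  structure(list(model = model, trace = trace_tbl, config = config,
                 schedule = schedule, aux_channel = aux_channel),
            class = "scoredose_fit")
}

# Validation loss via the same noise-prediction parametrization (no grads).
train_step_grads_loss_only <- function(model, x0b, condb, schedule, lambda_weighting) {
  dr <- draw_perturbed_stack(x0b, condb, schedule)
  out <- model_forward(model, dr$X, dr$sigma)
  resid <- out$eps - dr$z
  if (lambda_weighting == "sigma_sq") {
    mean(resid^2)
  } else {
    nP <- dim(x0b)[1] * dim(x0b)[2]
    mean(resid^2 * rep(1 / dr$sigma^2, each = nP))
  }
}

#' @export
print.scoredose_fit <- function(x, ...) {
  cat(sprintf("<scoredose_fit> %d epoch(s), %s parameters\n",
              nrow(x$trace), format(n_parameters(x$model), big.mark = ",")))
  if (nrow(x$trace) > 0) {
    last <- x$trace[nrow(x$trace), ]
    cat(sprintf("  final train loss %.4f, validation loss %.4f\n",
                last$train_loss, last$val_loss))
  }
  invisible(x)
}
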