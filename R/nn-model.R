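#' Configuration of the time-conditioned score network
#'
#' Describes the convolutional encoder-decoder (U-Net) that estimates the
#' score of the noised target channel given the conditioning channels. The
#' network input is a channel stack `[noised MDose, RTDose, (CT or auxiliary)]`
#' and the output is a single-channel field of the same spatial shape.
#'
#' The noise level enters through a sinusoidal embedding of `log(sigma)`
#' passed through a two-layer MLP and injected into every residual block as a
#' per-channel bias. Internally the network predicts the standard-normal
#' noise component; [score_forward()] divides by `-sigma` so the public
#' surface always speaks in scores.
#'
#' @param in_channels Total input channels (target + conditioning), `>= 2`.
#' @param base_width Feature maps of the first convolution (the usual
#'   ablation axis compares 64 vs 128; any positive integer is accepted).
#' @param depth Number of resolution levels; the encoder downsamples
#'   `depth - 1` times, so spatial sizes divisible by `2^depth` are always
#'   safe (other sizes are reflection-padded and cropped).
#' @param width_multipliers Per-level width multipliers, length `depth`.
#'   Default `c(1, 2, 2, 4)` truncated/extended to `depth`.
#' @param kernel_size Odd convolution kernel size (default 3).
#' @param time_embed_dim Dimension of the noise-level embedding.
#' @param normalization `"none"` (default). Kept as an explicit knob so the
#'   forward contract records it.
#' @param activation `"silu"` (default) or `"relu"`.
#' @param use_coords Append two fixed coordinate channels (meshgrid in
#'   `[-1, 1]`) before the first convolution, letting the otherwise
#'   translation-equivariant network represent spatially fixed calibration
#'   structure. Default `TRUE`.
#' @return An object of class `score_model_config`.
#' @export
score_model_config <- function(in_channels = 2L, base_width = 128L, depth = 4L,
                               width_multipliers = NULL, kernel_size = 3L,
                               time_embed_dim = 128L,
                               normalization = "none",
                               activation = c("silu", "relu"),
                               use_coords = TRUE) {
  activation <- match.arg(activation)
  in_channels <- as.integer(in_channels)
  base_width <- as.integer(base_width)
  depth <- as.integer(depth)
  kernel_size <- as.integer(kernel_size)
  time_embed_dim <- as.integer(time_embed_dim)
  if (in_channels < 2L) {
    stop("`in_channels` must be >= 2 (target channel + conditioning)", call. = FALSE)
  }
  if (kernel_size %% 2L == 0L) stop("`kernel_size` must be odd", call. = FALSE)
  if (base_width < 1L || depth < 1L || time_embed_dim < 2L) {
    stop("`base_width`, `depth` must be positive; `time_embed_dim` >= 2", call. = FALSE)
  }
  if (is.null(width_multipliers)) {
    wm <- c(1L, 2L, 2L, 4L)
    width_multipliers <- if (depth <= 4L) wm[seq_len(depth)] else c(wm, rep(4L, depth - 4L))
  }
  width_multipliers <- as.integer(width_multipliers)
  if (length(width_multipliers) != depth || any(width_multipliers < 1L)) {
    stop("`width_multipliers` must be `depth` positive integers", call. = FALSE)
  }
  normalization <- match.arg(normalization, "none")
  structure(list(in_channels = in_channels, base_width = base_width,
                 depth = depth, width_multipliers = width_multipliers,
                 kernel_size = kernel_size, time_embed_dim = time_embed_dim,
                 normalization = normalization, activation = activation,
                 use_coords = use_coords),
            class = "score_model_config")
}

init_mat <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

init_res_params <- function(p, prefix, cin, cout, k2, D) {
  p[[paste0(prefix, ".conv1.W")]] <- init_mat(k2 * cin, cout, k2 * cin)
  p[[paste0(prefix, ".conv1.b")]] <- numeric(cout)
  p[[paste0(prefix, ".t.W")]] <- init_mat(D, cout, D)
  p[[paste0(prefix, ".t.b")]] <- numeric(cout)
  p[[paste0(prefix, ".conv2.W")]] <- init_mat(k2 * cout, cout, k2 * cout) / sqrt(2)
  p[[paste0(prefix, ".conv2.b")]] <- numeric(cout)
  if (cin != cout) {
    p[[paste0(prefix, ".skip.W")]] <- init_mat(cin, cout, cin)
    p[[paste0(prefix, ".skip.b")]] <- numeric(cout)
  }
  p
}

#' Build a score network
#'
#' Initializes all parameters from a seeded random stream; the same
#' `(config, seed)` pair always yields bit-identical weights.
#'
#' @param config A [score_model_config()].
#' @param seed Integer seed for parameter initialization.
#' @return An object of class `score_model`.
#' @examples
#' m <- build_score_model(score_model_config(base_width = 8, depth = 2,
#'                                           time_embed_dim = 8), seed = 1)
#' @export
build_score_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "score_model_config"))
  k2 <- config$kernel_size^2
  D <- config$time_embed_dim
  widths <- config$base_width * config$width_multipliers
  cin_eff <- config$in_channels + if (config$use_coords) 2L else 0L
  p <- withr::with_seed(seed, {
    p <- list()
    p[["time.W1"]] <- init_mat(D, D, D)
    p[["time.b1"]] <- numeric(D)
    p[["time.W2"]] <- init_mat(D, D, D)
    p[["time.b2"]] <- numeric(D)
    p[["conv_in.W"]] <- init_mat(k2 * cin_eff, widths[1], k2 * cin_eff)
    p[["conv_in.b"]] <- numeric(widths[1])
    for (l in seq_len(config$depth)) {
      p <- init_res_params(p, paste0("down", l), widths[l], widths[l], k2, D)
      if (l < config$depth) {
        p[[paste0("downconv", l, ".W")]] <- init_mat(k2 * widths[l], widths[l + 1],
                                                     k2 * widths[l])
        p[[paste0("downconv", l, ".b")]] <- numeric(widths[l + 1])
      }
    }
    p <- init_res_params(p, "mid", widths[config$depth], widths[config$depth], k2, D)
    for (l in rev(seq_len(config$depth))) {
      p <- init_res_params(p, paste0("up", l), 2L * widths[l], widths[l], k2, D)
      if (l > 1L) {
        p[[paste0("upconv", l, ".W")]] <- init_mat(k2 * widths[l], widths[l - 1],
                                                   k2 * widths[l])
        p[[paste0("upconv", l, ".b")]] <- numeric(widths[l - 1])
      }
    }
    p[["conv_out.W"]] <- matrix(0, k2 * widths[1], 1L)
    p[["conv_out.b"]] <- 0
    p
  })
  half <- D %/% 2L
  freqs <- exp(seq(0, log(100), length.out = half))
  structure(list(config = config, params = p, seed = as.integer(seed),
                 const = list(freqs = freqs, widths = widths, cin_eff = cin_eff),
                 ctx_env = new.env(parent = emptyenv())),
            class = "score_model")
}

#' @export
print.score_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 1L))
  cat(sprintf(
    "<score_model> in_channels = %d, base_width = %d, depth = %d, %s parameters\n",
    x$config$in_channels, x$config$base_width, x$config$depth,
    format(np, big.mark = ",")))
  invisible(x)
}

n_parameters <- function(model) sum(vapply(model$params, length, 1L))

get_ctx <- function(model, key, maker) {
  env <- model$ctx_env
  if (is.null(env[[key]])) env[[key]] <- maker()
  env[[key]]
}

time_embedding_fwd <- function(model, sigma, B) {
  p <- model$params
  u <- log(sigma)
  if (length(u) == 1L) u <- rep(u, B)
  ang <- outer(u, model$const$freqs)
  ff <- cbind(sin(ang), cos(ang))
  h1 <- ff %*% p[["time.W1"]] + rep(p[["time.b1"]], each = B)
  a1 <- act_fwd(h1, model$config$activation)
  temb <- a1 %*% p[["time.W2"]] + rep(p[["time.b2"]], each = B)
  list(temb = temb, ff = ff, h1 = h1, a1 = a1)
}

res_fwd <- function(model, x, temb, prefix, ctx, cache = FALSE) {
  p <- model$params
  act <- model$config$activation
  a0 <- act_fwd(x, act)
  c1 <- conv_fwd(a0, p[[paste0(prefix, ".conv1.W")]],
                 p[[paste0(prefix, ".conv1.b")]], ctx, keep_cols = cache)
  tp <- temb %*% p[[paste0(prefix, ".t.W")]] +
    rep(p[[paste0(prefix, ".t.b")]], each = nrow(temb))
  h <- c1$out + tp[ctx$brep, , drop = FALSE]
  a1 <- act_fwd(h, act)
  c2 <- conv_fwd(a1, p[[paste0(prefix, ".conv2.W")]],
                 p[[paste0(prefix, ".conv2.b")]], ctx, keep_cols = cache)
  has_skip <- !is.null(p[[paste0(prefix, ".skip.W")]])
  skip <- if (has_skip) {
    conv1x1_fwd(x, p[[paste0(prefix, ".skip.W")]],
                p[[paste0(prefix, ".skip.b")]], nrow(x))
  } else x
  out <- skip + c2$out
  if (!cache) return(list(out = out))
  list(out = out,
       cache = list(x = x, cols1 = c1$cols, h = h, cols2 = c2$cols,
                    has_skip = has_skip, ctx = ctx))
}

res_bwd <- function(model, dout, cache, prefix, grads, dtemb) {
  p <- model$params
  act <- model$config$activation
  ctx <- cache$ctx
  # skip branch
  if (cache$has_skip) {
    grads[[paste0(prefix, ".skip.W")]] <- crossprod(cache$x, dout)
    grads[[paste0(prefix, ".skip.b")]] <- colSums(dout)
    dx <- tcrossprod(dout, p[[paste0(prefix, ".skip.W")]])
  } else {
    dx <- dout
  }
  # conv2
  b2 <- conv_bwd(dout, p[[paste0(prefix, ".conv2.W")]], cache$cols2, ctx)
  grads[[paste0(prefix, ".conv2.W")]] <- b2$dW
  grads[[paste0(prefix, ".conv2.b")]] <- b2$db
  dh <- b2$dX * act_grad(cache$h, act)
  # time projection
  dtp <- rowsum(dh, ctx$brep)
  grads[[paste0(prefix, ".t.W")]] <- crossprod(dtemb$temb_in, dtp)
  grads[[paste0(prefix, ".t.b")]] <- colSums(dtp)
  dtemb$acc <- dtemb$acc + tcrossprod(dtp, p[[paste0(prefix, ".t.W")]])
  # conv1
  b1 <- conv_bwd(dh, p[[paste0(prefix, ".conv1.W")]], cache$cols1, ctx)
  grads[[paste0(prefix, ".conv1.W")]] <- b1$dW
  grads[[paste0(prefix, ".conv1.b")]] <- b1$db
  dx <- dx + b1$dX * act_grad(cache$x, act)
  list(dx = dx, grads = grads, dtemb = dtemb)
}

# Forward pass. X: array (H, W, C, B); sigma: scalar or length-B vector of
# noise scales. Returns the predicted noise component eps_hat as an
# (H, W, B) array (cropped to the input size), plus caches when requested.
model_forward <- function(model, X, sigma, cache = FALSE) {
  cfg <- model$config
  d <- dim(X)
  if (length(d) == 3L) {
    dim(X) <- c(d, 1L)
    d <- dim(X)
  }
  if (d[3] != cfg$in_channels) {
    stop(sprintf("input stack has %d channels; model expects %d",
                 d[3], cfg$in_channels), call. = FALSE)
  }
  H0 <- d[1]; W0 <- d[2]; B <- d[4]
  mult <- 2L^(cfg$depth - 1L)
  H <- as.integer(ceiling(H0 / mult) * mult)
  W <- as.integer(ceiling(W0 / mult) * mult)
  if (H != H0 || W != W0) X <- pad_reflect_hw(X, H, W)
  nP <- H * W
  # (H*W*B) x C feature matrix
  F0 <- matrix(aperm(X, c(1, 2, 4, 3)), nP * B, cfg$in_channels)
  if (cfg$use_coords) {
    key <- sprintf("coords_%d_%d_%d", H, W, B)
    coords <- get_ctx(model, key, function() {
      xx <- rep(seq(-1, 1, length.out = W), each = H)
      yy <- rep(seq(-1, 1, length.out = H), times = W)
      cbind(rep(yy, B), rep(xx, B))
    })
    F0 <- cbind(F0, coords)
  }
  te <- time_embedding_fwd(model, sigma, B)
  widths <- model$const$widths
  k <- cfg$kernel_size
  ctxs <- lapply(seq_len(cfg$depth), function(l) {
    hl <- H %/% (2L^(l - 1L)); wl <- W %/% (2L^(l - 1L))
    get_ctx(model, sprintf("c_%d_%d_%d_1", hl, wl, B),
            function() make_conv_ctx(hl, wl, k, 1L, B))
  })
  caches <- if (cache) list(te = te, F0 = F0) else NULL
  p <- model$params
  cin <- conv_fwd(F0, p[["conv_in.W"]], p[["conv_in.b"]], ctxs[[1]], keep_cols = cache)
  h <- cin$out
  if (cache) caches$conv_in_cols <- cin$cols
  skips <- vector("list", cfg$depth)
  for (l in seq_len(cfg$depth)) {
    r <- res_fwd(model, h, te$temb, paste0("down", l), ctxs[[l]], cache)
    h <- r$out
    if (cache) caches[[paste0("down", l)]] <- r$cache
    skips[[l]] <- h
    if (l < cfg$depth) {
      hl <- H %/% (2L^(l - 1L)); wl <- W %/% (2L^(l - 1L))
      dctx <- get_ctx(model, sprintf("c_%d_%d_%d_2", hl, wl, B),
                      function() make_conv_ctx(hl, wl, k, 2L, B))
      dc <- conv_fwd(h, p[[paste0("downconv", l, ".W")]],
                     p[[paste0("downconv", l, ".b")]], dctx, keep_cols = cache)
      h <- dc$out
      if (cache) caches[[paste0("downconv", l)]] <- list(cols = dc$cols, ctx = dctx)
    }
  }
  r <- res_fwd(model, h, te$temb, "mid", ctxs[[cfg$depth]], cache)
  h <- r$out
  if (cache) caches$mid <- r$cache
  for (l in rev(seq_len(cfg$depth))) {
    h <- cbind(h, skips[[l]])
    r <- res_fwd(model, h, te$temb, paste0("up", l), ctxs[[l]], cache)
    h <- r$out
    if (cache) caches[[paste0("up", l)]] <- r$cache
    if (l > 1L) {
      hl <- H %/% (2L^(l - 1L)); wl <- W %/% (2L^(l - 1L))
      uctx <- get_ctx(model, sprintf("u_%d_%d_%d", hl, wl, B),
                      function() make_up_ctx(hl, wl, B))
      h <- up_fwd(h, uctx)
      uc <- conv_fwd(h, p[[paste0("upconv", l, ".W")]],
                     p[[paste0("upconv", l, ".b")]], ctxs[[l - 1L]], keep_cols = cache)
      if (cache) caches[[paste0("upconv", l)]] <- list(cols = uc$cols, uctx = uctx,
                                                       ctx = ctxs[[l - 1L]])
      h <- uc$out
    }
  }
  co <- conv_fwd(h, p[["conv_out.W"]], p[["conv_out.b"]], ctxs[[1]], keep_cols = cache)
  if (cache) caches$conv_out_cols <- co$cols
  eps <- array(co$out, dim = c(H, W, B))
  if (H != H0 || W != W0) eps <- eps[seq_len(H0), seq_len(W0), , drop = FALSE]
  if (cache) {
    caches$ctxs <- ctxs
    caches$geom <- list(H = H, W = W, H0 = H0, W0 = W0, B = B)
    list(eps = eps, caches = caches)
  } else {
    list(eps = eps)
  }
}

# Backward pass: d_eps is (H0, W0, B) gradient of the loss w.r.t. eps_hat.
# Returns a flat named list of parameter gradients.
model_backward <- function(model, caches, d_eps) {
  cfg <- model$config
  g <- caches$geom
  p <- model$params
  ctxs <- caches$ctxs
  if (g$H != g$H0 || g$W != g$W0) {
    full <- array(0, dim = c(g$H, g$W, g$B))
    full[seq_len(g$H0), seq_len(g$W0), ] <- d_eps
    d_eps <- full
  }
  dY <- matrix(as.vector(d_eps), g$H * g$W * g$B, 1L)
  grads <- list()
  dtemb <- list(acc = matrix(0, g$B, cfg$time_embed_dim), temb_in = caches$te$temb)
  bo <- conv_bwd(dY, p[["conv_out.W"]], caches$conv_out_cols, ctxs[[1]])
  grads[["conv_out.W"]] <- bo$dW
  grads[["conv_out.b"]] <- bo$db
  dh <- bo$dX
  widths <- model$const$widths
  dskips <- vector("list", cfg$depth)
  for (l in seq_len(cfg$depth)) {
    if (l > 1L) {
      uc <- caches[[paste0("upconv", l)]]
      bu <- conv_bwd(dh, p[[paste0("upconv", l, ".W")]], uc$cols, uc$ctx)
      grads[[paste0("upconv", l, ".W")]] <- bu$dW
      grads[[paste0("upconv", l, ".b")]] <- bu$db
      dh <- up_bwd(bu$dX, uc$uctx)
    }
    rb <- res_bwd(model, dh, caches[[paste0("up", l)]], paste0("up", l), grads, dtemb)
    grads <- rb$grads; dtemb <- rb$dtemb
    wl <- widths[l]
    dh <- rb$dx[, seq_len(wl), drop = FALSE]
    dskips[[l]] <- rb$dx[, wl + seq_len(wl), drop = FALSE]
  }
  rb <- res_bwd(model, dh, caches$mid, "mid", grads, dtemb)
  grads <- rb$grads; dtemb <- rb$dtemb
  dh <- rb$dx
  for (l in rev(seq_len(cfg$depth))) {
    if (l < cfg$depth) {
      dc <- caches[[paste0("downconv", l)]]
      bd <- conv_bwd(dh, p[[paste0("downconv", l, ".W")]], dc$cols, dc$ctx)
      grads[[paste0("downconv", l, ".W")]] <- bd$dW
      grads[[paste0("downconv", l, ".b")]] <- bd$db
      dh <- bd$dX
    }
    dh <- dh + dskips[[l]]
    rb <- res_bwd(model, dh, caches[[paste0("down", l)]], paste0("down", l), grads, dtemb)
    grads <- rb$grads; dtemb <- rb$dtemb
    dh <- rb$dx
  }
  bi <- conv_bwd(dh, p[["conv_in.W"]], caches$conv_in_cols, ctxs[[1]])
  grads[["conv_in.W"]] <- bi$dW
  grads[["conv_in.b"]] <- bi$db
  # time-embedding MLP
  te <- caches$te
  B <- g$B
  grads[["time.W2"]] <- crossprod(te$a1, dtemb$acc)
  grads[["time.b2"]] <- colSums(dtemb$acc)
  da1 <- tcrossprod(dtemb$acc, p[["time.W2"]])
  dh1 <- da1 * act_grad(te$h1, cfg$activation)
  grads[["time.W1"]] <- crossprod(te$ff, dh1)
  grads[["time.b1"]] <- colSums(dh1)
  grads
}

#' Evaluate the score network
#'
#' Returns the estimated score \eqn{s_\Theta(x, \sigma)} of the noised target
#' channel (channel 1 of `x_stack`) at the given noise level. `model` may also
#' be a plain function `f(x_stack, sigma)` returning a score field, which is
#' how analytic-score oracles are substituted for the network.
#'
#' @param model A `score_model` or a function `(x_stack, sigma) -> score`.
#' @param x_stack Array `(H, W, C)` or `(H, W, C, B)`: noised target plus
#'   conditioning channels.
#' @param sigma Noise scale(s); scalar or length-B. Alternatively give
#'   `i` with `schedule`.
#' @param i,schedule Discrete scale index resolved via [schedule_sigma()].
#' @return Score field `(H, W)` or `(H, W, B)`, matching the batchedness of
#'   the input.
#' @export
score_forward <- function(model, x_stack, sigma = NULL, i = NULL, schedule = NULL) {
  if (is.null(sigma)) {
    if (is.null(i) || is.null(schedule)) {
      stop("supply `sigma`, or `i` together with `schedule`", call. = FALSE)
    }
    sigma <- schedule_sigma(schedule, i)
  }
  if (is.function(model)) {
    return(model(x_stack, sigma))
  }
  stopifnot(inherits(model, "score_model"))
  batched <- length(dim(x_stack)) == 4L
  out <- model_forward(model, x_stack, sigma)
  eps <- out$eps
  B <- dim(eps)[3]
  sig <- if (length(sigma) == 1L) rep(sigma, B) else sigma
  score <- -eps / rep(sig, each = dim(eps)[1] * dim(eps)[2])
  if (!batched) dim(score) <- dim(score)[1:2]
  score
}
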