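# Low-level convolutional primitives for the score network.
#
# Feature maps are stored as dense matrices F of shape (H*W*B) x C: row index
# (b-1)*H*W + p where p is the column-major linear index of the (H, W) plane.
# Convolutions are im2col gathers followed by one BLAS GEMM; backward passes
# are the exact adjoints (scatter-add + GEMM). All gather/scatter index maps
# depend only on the geometry (H, W, kernel, stride, batch) and are cached.

# Geometry context for a 2-D convolution ("same" padding (k-1)/2).
make_conv_ctx <- function(H, W, k, stride, B) {
  p <- (k - 1L) %/% 2L
  Hp <- H + 2L * p
  Wp <- W + 2L * p
  Ho <- if (stride == 1L) H else H %/% stride
  Wo <- if (stride == 1L) W else W %/% stride
  if (stride > 1L && (H %% stride != 0L || W %% stride != 0L)) {
    stop("strided convolution requires spatial size divisible by the stride",
         call. = FALSE)
  }
  k2 <- k * k
  nO <- Ho * Wo
  oi <- rep(seq_len(Ho), times = Wo)
  oj <- rep(seq_len(Wo), each = Ho)
  IDX <- matrix(0L, nO, k2)
  for (dj in seq_len(k)) {
    for (di in seq_len(k)) {
      u <- (dj - 1L) * k + di
      ii <- (oi - 1L) * stride + di
      jj <- (oj - 1L) * stride + dj
      IDX[, u] <- (jj - 1L) * Hp + ii
    }
  }
  plane_off <- (seq_len(B) - 1L) * (Hp * Wp)
  IDXB <- IDX[rep(seq_len(nO), times = B), , drop = FALSE] +
    rep(plane_off, each = nO)
  # rows of the padded feature matrix holding real (unpadded) pixels
  i0 <- rep(seq_len(H), times = W)
  j0 <- rep(seq_len(W), each = H)
  lin0 <- (j0 + p - 1L) * Hp + (i0 + p)
  interior <- as.vector(outer(lin0, plane_off, "+"))
  list(H = H, W = W, B = B, k = k, k2 = k2, stride = stride,
       Ho = Ho, Wo = Wo, nO = nO, nOB = nO * B,
       HpWpB = Hp * Wp * B,
       IDXB = IDXB, idxvec = as.vector(IDXB), interior = interior,
       brep = rep(seq_len(B), each = nO))
}

conv_fwd <- function(F, Wm, b, ctx, keep_cols = FALSE) {
  Cin <- ncol(F)
  Fp <- matrix(0, ctx$HpWpB, Cin)
  Fp[ctx$interior, ] <- F
  cols <- Fp[ctx$idxvec, , drop = FALSE]
  dim(cols) <- c(ctx$nOB, ctx$k2 * Cin)
  Y <- cols %*% Wm
  Y <- Y + rep(b, each = ctx$nOB)
  if (keep_cols) list(out = Y, cols = cols) else list(out = Y)
}

conv_bwd <- function(dY, Wm, cols, ctx) {
  Cin <- ncol(cols) %/% ctx$k2
  dW <- crossprod(cols, dY)
  db <- colSums(dY)
  dcols <- tcrossprod(dY, Wm)                     # nOB x (k2*Cin)
  dFp <- matrix(0, ctx$HpWpB, Cin)
  for (u in seq_len(ctx$k2)) {
    sel <- seq.int(u, by = ctx$k2, length.out = Cin)
    rows <- ctx$IDXB[, u]
    dFp[rows, ] <- dFp[rows, ] + dcols[, sel, drop = FALSE]
  }
  list(dX = dFp[ctx$interior, , drop = FALSE], dW = dW, db = db)
}

# 1x1 convolution is a plain matrix product on the feature matrix.
conv1x1_fwd <- function(F, Wm, b, nrows) {
  F %*% Wm + rep(b, each = nrows)
}

# Nearest-neighbour 2x upsampling index maps.
make_up_ctx <- function(H, W, B) {
  H2 <- 2L * H
  i0 <- rep(seq_len(H), times = W)
  j0 <- rep(seq_len(W), each = H)
  child <- function(di, dj) {
    lin2 <- (2L * j0 - 2L + dj - 1L) * H2 + (2L * i0 - 2L + di)
    as.vector(outer(lin2, (seq_len(B) - 1L) * 4L * H * W, "+"))
  }
  ch <- list(child(1L, 1L), child(2L, 1L), child(1L, 2L), child(2L, 2L))
  upidx <- integer(4L * H * W * B)
  for (m in 1:4) upidx[ch[[m]]] <- seq_len(H * W * B)
  list(upidx = upidx, children = ch, n_in = H * W * B, n_out = 4L * H * W * B)
}

up_fwd <- function(F, uctx) F[uctx$upidx, , drop = FALSE]

up_bwd <- function(dY, uctx) {
  ch <- uctx$children
  dY[ch[[1]], , drop = FALSE] + dY[ch[[2]], , drop = FALSE] +
    dY[ch[[3]], , drop = FALSE] + dY[ch[[4]], , drop = FALSE]
}

act_fwd <- function(x, kind) {
  if (kind == "silu") {
    s <- 1 / (1 + exp(-x))
    x * s
  } else {
    pmax(x, 0)
  }
}

act_grad <- function(x, kind) {
  if (kind == "silu") {
    s <- 1 / (1 + exp(-x))
    s * (1 + x * (1 - s))
  } else {
    (x > 0) + 0
  }
}

# Reflection-pad a (H, W, C, B) array on the right/bottom to target size.
pad_reflect_hw <- function(X, Ht, Wt) {
  d <- dim(X)
  if (d[1] == Ht && d[2] == Wt) return(X)
  ri <- c(seq_len(d[1]), rev(seq_len(d[1])))[seq_len(Ht)]
  rj <- c(seq_len(d[2]), rev(seq_len(d[2])))[seq_len(Wt)]
  X[ri, rj, , , drop = FALSE]
}
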