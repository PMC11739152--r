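#' Phantom geometry specification
#'
#' Describes one synthetic 2-D slice: an elliptical body on a square grid,
#' internal structures of distinct CT intensity, and one or more dose target
#' centres. Site labels are stratification tags for the cohort (they mirror
#' the clinical H&N / chest / abdomen mix) and do not change the geometry.
#'
#' @param grid_size Integer pair `(H, W)` (a single value is squared).
#' @param body Ellipse as `list(cx, cy, rx, ry)` in pixel units; defaults to
#'   a centred ellipse filling ~85% of the grid. Must fit inside the grid.
#' @param n_structures Number of internal CT ellipses.
#' @param n_targets Number of dose target centres (`>= 1`).
#' @param target_centers Optional explicit `n_targets x 2` matrix of `(row,
#'   col)` centres; all must lie inside the body (else an error). If `NULL`,
#'   centres are drawn inside the body per case.
#' @param site_label One of `"H&N"`, `"chest"`, `"abdomen"`.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_size = c(32L, 32L), body = NULL,
                         n_structures = 3L, n_targets = 2L,
                         target_centers = NULL,
                         site_label = c("H&N", "chest", "abdomen")) {
  site_label <- match.arg(site_label)
  if (length(grid_size) == 1L) grid_size <- rep(grid_size, 2L)
  grid_size <- as.integer(grid_size)
  if (any(grid_size < 16L)) stop("`grid_size` must be >= 16", call. = FALSE)
  H <- grid_size[1]; W <- grid_size[2]
  if (is.null(body)) {
    body <- list(cx = (W + 1) / 2, cy = (H + 1) / 2,
                 rx = 0.42 * W, ry = 0.45 * H)
  }
  if (body$cx - body$rx < 0.5 || body$cx + body$rx > W + 0.5 ||
      body$cy - body$ry < 0.5 || body$cy + body$ry > H + 0.5) {
    stop("body ellipse must fit inside the grid", call. = FALSE)
  }
  n_targets <- as.integer(n_targets)
  if (n_targets < 1L) stop("`n_targets` must be >= 1", call. = FALSE)
  if (!is.null(target_centers)) {
    target_centers <- as.matrix(target_centers)
    if (nrow(target_centers) != n_targets || ncol(target_centers) != 2L) {
      stop("`target_centers` must be an n_targets x 2 matrix", call. = FALSE)
    }
    inside <- ((target_centers[, 2] - body$cx) / body$rx)^2 +
      ((target_centers[, 1] - body$cy) / body$ry)^2 <= 1
    if (!all(inside)) stop("target centre outside the body ellipse", call. = FALSE)
  }
  structure(list(grid_size = grid_size, body = body,
                 n_structures = as.integer(n_structures),
                 n_targets = n_targets, target_centers = target_centers,
                 site_label = site_label),
            class = "phantom_spec")
}

#' Planned-to-delivered error model
#'
#' The deterministic transform (plus small noise) that turns the planned dose
#' into the "measured" delivered dose of a synthetic case:
#' `MDose = clip(calib * shift(blur(RTDose)) + noise, 0, Inf)`. It emulates
#' the plan-versus-delivery discrepancies a measurement system records:
#' finite detector resolution (Gaussian blur), a small setup/registration
#' shift, a smooth multiplicative output-calibration field (systematic, fixed
#' across cases), and additive measurement noise.
#'
#' @param blur_sigma Gaussian blur standard deviation, pixels (`>= 0`).
#' @param shift Sub-pixel translation `(dy, dx)` in pixels (bilinear).
#' @param calib_amp Amplitude `a` of the multiplicative calibration field
#'   `1 + a sin(2 pi y / P) sin(2 pi x / P)`; `|a| < 0.2`.
#' @param calib_period Spatial period `P` of the calibration field, pixels.
#' @param noise_sd Additive Gaussian noise sd on the normalized dose scale.
#' @return An object of class `error_model`.
#' @export
error_model <- function(blur_sigma = 1.5, shift = c(0.5, 0.5),
                        calib_amp = 0.05, calib_period = 16, noise_sd = 0.01) {
  if (blur_sigma < 0) stop("`blur_sigma` must be >= 0", call. = FALSE)
  if (abs(calib_amp) >= 0.2) stop("`calib_amp` must satisfy |a| < 0.2", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (calib_period <= 0) stop("`calib_period` must be > 0", call. = FALSE)
  structure(list(blur_sigma = blur_sigma, shift = as.numeric(shift),
                 calib_amp = calib_amp, calib_period = calib_period,
                 noise_sd = noise_sd),
            class = "error_model")
}

# Separable Gaussian blur, reflect boundary, truncated at 4 sd (the same
# contract as the reference scientific-python filter, so the two agree to
# floating-point precision).
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- as.integer(round(4 * sigma))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k <- k / sum(k)
  blur_1d <- function(m) {
    n <- nrow(m)
    idx <- c(rev(seq_len(r)), seq_len(n), n + 1 - seq_len(r))  # reflect
    mp <- m[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_len(2L * r + 1L)) {
      out <- out + k[j] * mp[(j - 1L) + seq_len(n), , drop = FALSE]
    }
    out
  }
  t(blur_1d(t(blur_1d(x))))
}

# Bilinear sub-pixel shift: out(i, j) = in(i - dy, j - dx), zero outside.
shift_bilinear <- function(x, shift) {
  dy <- shift[1]; dx <- shift[2]
  if (dy == 0 && dx == 0) return(x)
  H <- nrow(x); W <- ncol(x)
  ii <- seq_len(H) - dy
  jj <- seq_len(W) - dx
  i0 <- floor(ii); j0 <- floor(jj)
  fi <- ii - i0; fj <- jj - j0
  m <- as.integer(ceiling(max(abs(c(dy, dx))))) + 1L  # zero margin width
  xp <- matrix(0, H + 2L * m, W + 2L * m)
  xp[m + seq_len(H), m + seq_len(W)] <- x
  gi <- function(i) pmin(pmax(i + m, 1L), H + 2L * m)
  gj <- function(j) pmin(pmax(j + m, 1L), W + 2L * m)
  A <- xp[gi(i0), gj(j0), drop = FALSE]
  Bm <- xp[gi(i0 + 1), gj(j0), drop = FALSE]
  Cm <- xp[gi(i0), gj(j0 + 1), drop = FALSE]
  Dm <- xp[gi(i0 + 1), gj(j0 + 1), drop = FALSE]
  wA <- outer(1 - fi, 1 - fj); wB <- outer(fi, 1 - fj)
  wC <- outer(1 - fi, fj);     wD <- outer(fi, fj)
  A * wA + Bm * wB + Cm * wC + Dm * wD
}

calibration_field <- function(H, W, error) {
  P <- error$calib_period
  sy <- sin(2 * pi * (seq_len(H) - 1) / P)
  sx <- sin(2 * pi * (seq_len(W) - 1) / P)
  1 + error$calib_amp * outer(sy, sx)
}

#' Apply the planned-to-delivered transform
#'
#' @param rtdose Planned dose field.
#' @param error An [error_model()].
#' @param noise Optional pre-drawn standard-normal field (same shape); drawn
#'   from the current R stream if omitted and `noise_sd > 0`.
#' @return The delivered (measured) dose field, clipped below at 0.
#' @export
planned_to_measured <- function(rtdose, error, noise = NULL) {
  stopifnot(inherits(error, "error_model"))
  m <- gaussian_blur(rtdose, error$blur_sigma)
  m <- shift_bilinear(m, error$shift)
  if (error$calib_amp != 0) {
    m <- m * calibration_field(nrow(m), ncol(m), error)
  }
  if (error$noise_sd > 0) {
    if (is.null(noise)) noise <- matrix(stats::rnorm(length(m)), nrow(m))
    m <- m + error$noise_sd * noise
    m <- pmax(m, 0)
  }
  m
}

#' Generate one paired phantom case
#'
#' Builds aligned (CT, RTDose, MDose) fields on one grid: CT is the body plus
#' internal ellipses with distinct intensities; RTDose is a normalized sum of
#' anisotropic Gaussian kernels centred on the targets, zeroed outside the
#' body, with maximum exactly 1; MDose is the [planned_to_measured()]
#' transform of RTDose. Fully reproducible given `seed`.
#'
#' @param spec A [phantom_spec()].
#' @param error An [error_model()].
#' @param seed Integer seed.
#' @param case_id Character id.
#' @return A `dose_case`: list with `case_id`, `site`, `ct`, `rtdose`,
#'   `mdose`, `spacing`.
#' @export
make_case <- function(spec, error = error_model(), seed = 1L,
                      case_id = sprintf("case_%04d", seed)) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(error, "error_model"))
  H <- spec$grid_size[1]; W <- spec$grid_size[2]
  b <- spec$body
  Y <- matrix(seq_len(H), H, W)
  X <- matrix(seq_len(W), H, W, byrow = TRUE)
  body_mask <- ((X - b$cx) / b$rx)^2 + ((Y - b$cy) / b$ry)^2 <= 1
  withr::with_seed(seed, {
    ct <- matrix(0, H, W)
    ct[body_mask] <- 0.3
    for (s in seq_len(spec$n_structures)) {
      th <- stats::runif(1, 0, 2 * pi)
      rr <- sqrt(stats::runif(1)) * 0.6
      cx <- b$cx + rr * b$rx * cos(th)
      cy <- b$cy + rr * b$ry * sin(th)
      rx <- stats::runif(1, 0.08, 0.2) * W
      ry <- stats::runif(1, 0.08, 0.2) * H
      val <- stats::runif(1, 0.4, 0.9)
      msk <- (((X - cx) / rx)^2 + ((Y - cy) / ry)^2 <= 1) & body_mask
      ct[msk] <- val
    }
    if (is.null(spec$target_centers)) {
      th <- stats::runif(spec$n_targets, 0, 2 * pi)
      rr <- sqrt(stats::runif(spec$n_targets)) * 0.55
      centers <- cbind(b$cy + rr * b$ry * sin(th),
                       b$cx + rr * b$rx * cos(th))
    } else {
      centers <- spec$target_centers
    }
    dose <- matrix(0, H, W)
    for (tgt in seq_len(nrow(centers))) {
      sx <- stats::runif(1, 0.09, 0.16) * W
      sy <- stats::runif(1, 0.09, 0.16) * H
      rot <- stats::runif(1, 0, pi)
      amp <- stats::runif(1, 0.6, 1)
      xr <- (X - centers[tgt, 2]) * cos(rot) + (Y - centers[tgt, 1]) * sin(rot)
      yr <- -(X - centers[tgt, 2]) * sin(rot) + (Y - centers[tgt, 1]) * cos(rot)
      dose <- dose + amp * exp(-0.5 * ((xr / sx)^2 + (yr / sy)^2))
    }
    dose[!body_mask] <- 0
    dose <- dose / max(dose)
    mdose <- planned_to_measured(dose, error)
    structure(list(case_id = case_id, site = spec$site_label,
                   ct = ct, rtdose = dose, mdose = mdose,
                   spacing = c(1, 1)),
              class = "dose_case")
  })
}

#' @export
print.dose_case <- function(x, ...) {
  cat(sprintf("<dose_case> %s (%s), %d x %d grid\n",
              x$case_id, x$site, nrow(x$rtdose), ncol(x$rtdose)))
  invisible(x)
}

dataset_cases <- function(data) {
  if (inherits(data, "dose_dataset")) return(data$cases)
  if (inherits(data, "dose_case")) return(list(data))
  if (is.list(data)) {
    if (length(data) > 0 && inherits(data[[1]], "dose_case")) return(data)
    if (!is.null(data$mdose)) return(list(data))
  }
  stop("expected a dose_dataset, a dose_case, or a list of cases", call. = FALSE)
}

new_dose_dataset <- function(cases, manifest = list()) {
  structure(list(cases = cases, manifest = manifest), class = "dose_dataset")
}

#' @export
print.dose_dataset <- function(x, ...) {
  sites <- table(vapply(x$cases, function(cs) cs$site, ""))
  cat(sprintf("<dose_dataset> %d case(s): %s\n", length(x$cases),
              paste(sprintf("%s=%d", names(sites), sites), collapse = ", ")))
  invisible(x)
}

#' @export
length.dose_dataset <- function(x) length(x$cases)

# default cohort mix mirrors the clinical site proportions (115/87/98 of 300)
default_site_probs <- c("H&N" = 115, "chest" = 87, "abdomen" = 98) / 300

#' Generate a paired synthetic cohort with a stratified split
#'
#' Builds `n_cases` phantom cases under one [error_model()], assigns site
#' labels at the default clinical cohort proportions, and splits them into
#' train/test at `split_ratio`, stratified by site (each site's train
#' fraction within one case of the global ratio; no case in both splits).
#' `n_cases = 300` at the default 4:1 ratio yields exactly 240 training and
#' 60 test cases.
#'
#' @param n_cases Total cases (`>= 2`).
#' @param split_ratio Train fraction in `(0, 1)`; default `0.8` (4:1).
#' @param spec A [phantom_spec()] used for every case (site label overridden
#'   per case).
#' @param error An [error_model()].
#' @param seed Integer seed controlling geometry, noise, labels and split.
#' @param site_probs Named site proportions.
#' @return An object of class `dose_dataset_split` with elements `train`,
#'   `test` (both `dose_dataset`) and `manifest`.
#' @export
make_dataset <- function(n_cases = 600L, split_ratio = 0.8,
                         spec = phantom_spec(), error = error_model(),
                         seed = 1L, site_probs = default_site_probs) {
  n_cases <- as.integer(n_cases)
  if (n_cases < 2L) stop("`n_cases` must be >= 2", call. = FALSE)
  if (split_ratio <= 0 || split_ratio >= 1) {
    stop("`split_ratio` must be in (0, 1)", call. = FALSE)
  }
  n_train_total <- round(split_ratio * n_cases)
  if (n_train_total < 1L || n_train_total > n_cases - 1L) {
    stop("`split_ratio` produces an empty split", call. = FALSE)
  }
  sites <- names(site_probs)
  counts <- floor(n_cases * site_probs)
  rem <- n_cases - sum(counts)
  if (rem > 0) {
    frac <- n_cases * site_probs - counts
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[add] <- counts[add] + 1L
  }
  labels <- rep(sites, counts)
  withr::with_seed(seed, {
    labels <- sample(labels)
    case_seeds <- sample.int(.Machine$integer.max - 1L, n_cases)
    cases <- vector("list", n_cases)
    for (j in seq_len(n_cases)) {
      sp <- spec
      sp$site_label <- labels[j]
      cases[[j]] <- make_case(sp, error, seed = case_seeds[j],
                              case_id = sprintf("case_%04d", j))
    }
    train_idx <- integer(0)
    for (st in sites) {
      idx <- which(labels == st)
      n_tr <- round(split_ratio * length(idx))
      n_tr <- min(max(n_tr, 0L), length(idx))
      train_idx <- c(train_idx, sample(idx, n_tr))
    }
    # reconcile rounding so the global split is exact
    while (length(train_idx) > n_train_total) {
      train_idx <- train_idx[-sample.int(length(train_idx), 1L)]
    }
    while (length(train_idx) < n_train_total) {
      pool <- setdiff(seq_len(n_cases), train_idx)
      train_idx <- c(train_idx, pool[sample.int(length(pool), 1L)])
    }
    train_idx <- sort(train_idx)
    test_idx <- setdiff(seq_len(n_cases), train_idx)
    manifest <- list(
      n_cases = n_cases, split_ratio = split_ratio, seed = as.integer(seed),
      site_counts = as.list(counts),
      n_train = length(train_idx), n_test = length(test_idx),
      grid_size = spec$grid_size,
      spec = unclass(spec[c("grid_size", "n_structures", "n_targets")]),
      error_model = unclass(error),
      normalization = "per-case planned-dose maximum (RTDose max = 1)",
      channel_order = c("mdose", "rtdose", "ct"),
      train_ids = sprintf("case_%04d", train_idx),
      test_ids = sprintf("case_%04d", test_idx))
    structure(list(train = new_dose_dataset(cases[train_idx], manifest),
                   test = new_dose_dataset(cases[test_idx], manifest),
                   manifest = manifest),
              class = "dose_dataset_split")
  })
}

#' @export
print.dose_dataset_split <- function(x, ...) {
  cat(sprintf("<dose_dataset_split> %d train / %d test (ratio %.2f)\n",
              length(x$train$cases), length(x$test$cases),
              x$manifest$split_ratio))
  invisible(x)
}
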