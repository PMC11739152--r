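# broom-style accessors for fitted objects and schedules.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a trained score model
#'
#' One row per parameter tensor: name, shape and element count.
#'
#' @param x A `scoredose_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.scoredose_fit <- function(x, ...) {
  p <- x$model$params
  tibble::tibble(
    tensor = names(p),
    shape = vapply(p, function(w) paste(dim(w) %||% length(w), collapse = "x"), ""),
    n_parameters = vapply(p, length, 1L))
}

#' Glance at a trained score model
#'
#' @param x A `scoredose_fit`.
#' @param ... Unused.
#' @return A one-row tibble: parameter count, epochs, final losses.
#' @export
glance.scoredose_fit <- function(x, ...) {
  tr <- x$trace
  tibble::tibble(
    n_parameters = n_parameters(x$model),
    epochs = nrow(tr),
    final_train_loss = if (nrow(tr)) tr$train_loss[nrow(tr)] else NA_real_,
    final_val_loss = if (nrow(tr)) tr$val_loss[nrow(tr)] else NA_real_,
    ema = !is.null(x$config) && x$config$ema_decay > 0)
}

#' Tidy a noise schedule
#'
#' @param x A `noise_schedule`.
#' @param ... Unused.
#' @return A tibble with one row per discrete scale: index, time, the
#'   perturbation-kernel mean coefficient and standard deviation.
#' @export
tidy.noise_schedule <- function(x, ...) {
  i <- 0:x$N
  kp <- perturbation_kernel(x, i = i)
  tibble::tibble(i = i, t = i / x$N,
                 mean_coeff = kp$mean_coeff, std = kp$std)
}
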