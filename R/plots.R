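# ggplot2 display helpers for dose fields, cases, profiles, training traces
# and per-site summaries.

field_to_tbl <- function(field, name = "dose") {
  tibble::tibble(row = rep(seq_len(nrow(field)), times = ncol(field)),
                 col = rep(seq_len(ncol(field)), each = nrow(field)),
                 value = as.vector(field), channel = name)
}

#' Plot a dose (or CT) field
#'
#' @param field Numeric matrix.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_dose_field <- function(field, title = NULL) {
  df <- field_to_tbl(field)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "dose") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dose_case <- function(object, pdose = NULL, ...) {
  chans <- list(CT = object$ct, RTDose = object$rtdose, MDose = object$mdose)
  if (!is.null(pdose)) chans$PDose <- pdose
  df <- dplyr::bind_rows(purrr::imap(chans, function(f, nm) field_to_tbl(f, nm)))
  df$channel <- factor(df$channel, levels = names(chans))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~channel, nrow = 1) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = NULL) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = object$case_id, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Overlayed horizontal dose profiles
#'
#' Line profiles of measured, planned and (optionally) predicted dose along
#' one row of a case — the standard way to inspect where a prediction departs
#' from the measurement.
#'
#' @param case A `dose_case`.
#' @param row Row index.
#' @param pdose Optional predicted dose field.
#' @return A ggplot object.
#' @export
plot_line_profiles <- function(case, row, pdose = NULL) {
  series <- list(MDose = case$mdose, RTDose = case$rtdose)
  if (!is.null(pdose)) series$PDose <- pdose
  df <- dplyr::bind_rows(purrr::imap(series, function(f, nm) {
    dplyr::mutate(line_profile(f, row), series = nm)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$dose,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = sprintf("%s, row %d", case$case_id, row),
                  x = "position (px)", y = "normalized dose",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.scoredose_fit <- function(object, ...) {
  if (nrow(object$trace) == 0) stop("empty loss trace", call. = FALSE)
  df <- tidyr::pivot_longer(object$trace, c("train_loss", "val_loss"),
                            names_to = "split", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "epoch", y = "denoising score-matching loss",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.site_summary <- function(object, ...) {
  out_df <- tidyr::unnest(
    dplyr::select(object, "site", "metric", value = "outliers"), "value")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$site)) +
    ggplot2::geom_crossbar(ggplot2::aes(y = .data$median, ymin = .data$q1,
                                        ymax = .data$q3),
                           width = 0.5, fill = "grey90") +
    ggplot2::geom_point(data = out_df,
                        ggplot2::aes(y = .data$value), shape = 3) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
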