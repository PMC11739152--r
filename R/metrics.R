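#' Structural similarity index between two dose fields
#'
#' Gaussian-weighted SSIM (luminance/contrast/structure) with the standard
#' constants \eqn{C_1 = (k_1 L)^2}, \eqn{C_2 = (k_2 L)^2}, averaged over all
#' window positions whose support lies fully inside the image (a border of
#' `(window - 1) / 2` pixels is cropped before averaging, so the boundary
#' handling of the filter cannot influence the value).
#'
#' @param a,b Numeric matrices of equal shape, at least `window` pixels in
#'   each dimension.
#' @param window Odd window size (default 11).
#' @param sigma Gaussian window standard deviation (default 1.5).
#' @param k1,k2 Stability constants (defaults 0.01, 0.03).
#' @param data_range Value range `L` of the data (1 for normalized dose).
#' @param mask Optional logical matrix; when given, the mean is restricted to
#'   cropped window centres where `mask` is `TRUE` (body-mask variant).
#' @return Scalar SSIM in `[-1, 1]`.
#' @export
dose_ssim <- function(a, b, window = 11L, sigma = 1.5, k1 = 0.01, k2 = 0.03,
                      data_range = 1, mask = NULL) {
  if (!identical(dim(a), dim(b))) stop("`a` and `b` must have equal shape", call. = FALSE)
  if (data_range <= 0) stop("`data_range` must be > 0", call. = FALSE)
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("`window` must be odd", call. = FALSE)
  if (any(dim(a) < window)) stop("fields smaller than the SSIM window", call. = FALSE)
  r <- (window - 1L) %/% 2L
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k <- k / sum(k)
  filt1 <- function(m) {
    n <- nrow(m)
    idx <- c(rev(seq_len(r)), seq_len(n), n + 1 - seq_len(r))
    mp <- m[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_len(2L * r + 1L)) {
      out <- out + k[j] * mp[(j - 1L) + seq_len(n), , drop = FALSE]
    }
    out
  }
  filt <- function(m) t(filt1(t(filt1(m))))
  ux <- filt(a); uy <- filt(b)
  uxx <- filt(a * a); uyy <- filt(b * b); uxy <- filt(a * b)
  vx <- uxx - ux * ux
  vy <- uyy - uy * uy
  vxy <- uxy - ux * uy
  C1 <- (k1 * data_range)^2
  C2 <- (k2 * data_range)^2
  S <- ((2 * ux * uy + C1) * (2 * vxy + C2)) /
    ((ux^2 + uy^2 + C1) * (vx + vy + C2))
  ri <- (r + 1L):(nrow(a) - r)
  rj <- (r + 1L):(ncol(a) - r)
  Sc <- S[ri, rj]
  if (!is.null(mask)) {
    mc <- mask[ri, rj]
    if (!any(mc)) stop("mask excludes every interior window centre", call. = FALSE)
    mean(Sc[mc])
  } else {
    mean(Sc)
  }
}

#' Root-mean-square and mean-absolute error in percent
#'
#' Errors between two fields on the normalized `[0, 1]` dose scale, reported
#' in percent: `rmse_pct = 100 sqrt(mean((a - b)^2))`,
#' `mae_pct = 100 mean(|a - b|)`.
#'
#' @param a,b Numeric arrays of equal shape.
#' @param mask Optional logical array restricting the mean.
#' @return Scalar error in percent.
#' @export
rmse_pct <- function(a, b, mask = NULL) {
  check_same_shape(a, b)
  d <- (a - b)^2
  100 * sqrt(mean(if (is.null(mask)) d else d[mask]))
}

#' @rdname rmse_pct
#' @export
mae_pct <- function(a, b, mask = NULL) {
  check_same_shape(a, b)
  d <- abs(a - b)
  100 * mean(if (is.null(mask)) d else d[mask])
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a) %||% length(a), dim(b) %||% length(b))) {
    stop("fields must have equal shape", call. = FALSE)
  }
  invisible(TRUE)
}

#' Horizontal line profile of a dose field
#'
#' Ordered samples along one row, for overlaying measured / planned /
#' predicted dose in profile plots.
#'
#' @param field Numeric matrix.
#' @param row Row index (1-based).
#' @param spacing Pixel spacing along the row (position units).
#' @return A tibble with columns `position` and `dose`.
#' @export
line_profile <- function(field, row, spacing = 1) {
  if (row < 1L || row > nrow(field)) stop("`row` out of range", call. = FALSE)
  tibble::tibble(position = (seq_len(ncol(field)) - 1) * spacing,
                 dose = field[row, ])
}

#' Per-case metrics between predictions and measured dose
#'
#' Computes SSIM, RMSE(%) and MAE(%) of each predicted field against the
#' case's measured dose (whole grid by default, matching full-image metric
#' reporting; pass `mask_body = TRUE` for the body-restricted variant).
#'
#' @param pred Named list of predicted fields, or array `(H, W, n)` in the
#'   order of the dataset's cases, or a single matrix for a single case.
#' @param data A `dose_dataset` (or list of cases) holding the references.
#' @param reference Channel compared against: `"mdose"` (default) or
#'   `"rtdose"`.
#' @param mask_body Restrict metrics to the body (`ct > 0`) region.
#' @param ssim_args List of overrides for [dose_ssim()] parameters.
#' @return A tibble (one row per case): `case_id`, `site`, `ssim`,
#'   `rmse_pct`, `mae_pct`.
#' @export
evaluate_cases <- function(pred, data, reference = c("mdose", "rtdose"),
                           mask_body = FALSE, ssim_args = list()) {
  reference <- match.arg(reference)
  cases <- dataset_cases(data)
  if (is.matrix(pred)) pred <- list(pred)
  if (is.array(pred) && length(dim(pred)) == 3L) {
    pred <- lapply(seq_len(dim(pred)[3]), function(j) pred[, , j])
  }
  if (length(pred) != length(cases)) {
    stop("number of predictions does not match number of cases", call. = FALSE)
  }
  if (!is.null(names(pred)) && all(nzchar(names(pred)))) {
    ids <- vapply(cases, function(cs) cs$case_id, "")
    if (!setequal(names(pred), ids)) {
      stop("prediction names do not match dataset case ids", call. = FALSE)
    }
    pred <- pred[ids]
  }
  rows <- purrr::map2(pred, cases, function(p, cs) {
    ref <- cs[[reference]]
    msk <- if (mask_body) cs$ct > 0 else NULL
    sa <- utils::modifyList(list(a = p, b = ref, mask = msk), ssim_args)
    tibble::tibble(case_id = cs$case_id, site = cs$site,
                   ssim = do.call(dose_ssim, sa),
                   rmse_pct = rmse_pct(p, ref, msk),
                   mae_pct = mae_pct(p, ref, msk))
  })
  dplyr::bind_rows(rows)
}

#' Baseline discrepancy of the plan itself
#'
#' Metrics of the planned dose against the measured dose for every case —
#' the "no model" reference any useful predictor must beat.
#'
#' @param data A `dose_dataset` or list of cases.
#' @inheritParams evaluate_cases
#' @return A tibble like [evaluate_cases()].
#' @export
planned_vs_measured <- function(data, mask_body = FALSE, ssim_args = list()) {
  cases <- dataset_cases(data)
  evaluate_cases(lapply(cases, function(cs) cs$rtdose), cases,
                 reference = "mdose", mask_body = mask_body,
                 ssim_args = ssim_args)
}

#' Per-site quartile summary of case metrics
#'
#' Median, quartiles (linear interpolation), IQR and Tukey-fence outliers
#' (beyond `Q1 - 1.5 IQR` / `Q3 + 1.5 IQR`) of each metric, per anatomical
#' site — the numbers a per-site box plot displays.
#'
#' @param records A tibble from [evaluate_cases()] (columns `site` plus one
#'   or more numeric metric columns).
#' @param metrics Character vector of metric columns to summarize.
#' @return A tibble with class `site_summary`: one row per site x metric with
#'   `median`, `q1`, `q3`, `iqr`, `n_outliers` and a list-column `outliers`.
#' @export
summarize_by_site <- function(records,
                              metrics = intersect(c("ssim", "rmse_pct", "mae_pct"),
                                                  names(records))) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("`records` must be a nonempty data frame", call. = FALSE)
  }
  if (length(metrics) == 0L) stop("no metric columns found", call. = FALSE)
  long <- tidyr::pivot_longer(records[, c("site", metrics)],
                              dplyr::all_of(metrics),
                              names_to = "metric", values_to = "value")
  out <- long |>
    dplyr::group_by(.data$site, .data$metric) |>
    dplyr::summarize(
      n = dplyr::n(),
      median = stats::median(.data$value),
      q1 = stats::quantile(.data$value, 0.25, names = FALSE),
      q3 = stats::quantile(.data$value, 0.75, names = FALSE),
      iqr = .data$q3 - .data$q1,
      outliers = list(.data$value[.data$value < .data$q1 - 1.5 * .data$iqr |
                                    .data$value > .data$q3 + 1.5 * .data$iqr]),
      .groups = "drop") |>
    dplyr::mutate(n_outliers = lengths(.data$outliers))
  class(out) <- c("site_summary", class(out))
  out
}
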