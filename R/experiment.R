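#' Run the end-to-end synthetic dose-prediction experiment
#'
#' The package's reference experiment at desk scale: generate a paired
#' phantom cohort under the standard delivery-error model, train the
#' conditional score network on the training split, predict the delivered
#' dose for held-out cases by predictor-corrector sampling, and score the
#' predictions (and the planned-dose baseline) against the measured dose.
#'
#' The defaults are the experiment's study conditions: 600 cases on 32x32
#' grids split 4:1, delivery errors of a 1.5-pixel blur, a (0.5, 0.5)-pixel
#' shift, a 5% calibration field and 1% measurement noise, a VE schedule with
#' 300 scales on 0.01..0.6, and a compact score network (base width 16,
#' depth 2) sized for single-CPU training.
#'
#' @param seed Master seed; all stage seeds are derived from it.
#' @param n_cases Cohort size.
#' @param grid_size Grid edge length in pixels.
#' @param error Delivery [error_model()].
#' @param n_eval Number of held-out cases to sample and score.
#' @param epochs,batch_size,learning_rate,ema_decay Training settings.
#' @param base_width,depth,time_embed_dim Network size.
#' @param schedule_N Scales in the noise schedule (= sampler iterations).
#' @param M_corrector Langevin corrector steps per iteration.
#' @param verbose Print per-epoch losses.
#' @return A list of class `synthetic_experiment`: `fit`, `pdose`
#'   (H x W x n_eval), `metrics` and `baseline` tibbles, `summary` (one-row
#'   tibble of the headline numbers), and the `datasets`.
#' @export
run_synthetic_experiment <- function(seed = 1L,
                                     n_cases = 600L,
                                     grid_size = 32L,
                                     error = error_model(),
                                     n_eval = 20L,
                                     epochs = 16L,
                                     batch_size = 8L,
                                     learning_rate = 1.5e-3,
                                     ema_decay = 0.995,
                                     base_width = 16L,
                                     depth = 2L,
                                     time_embed_dim = 32L,
                                     schedule_N = 300L,
                                     M_corrector = 1L,
                                     verbose = FALSE) {
  seed <- as.integer(seed)
  ds <- make_dataset(n_cases, 0.8, phantom_spec(grid_size), error,
                     seed = seed)
  schedule <- noise_schedule("VE", N = schedule_N,
                             sigma_min = 0.01, sigma_max = 0.6)
  model <- build_score_model(
    score_model_config(in_channels = 2L, base_width = base_width,
                       depth = depth, time_embed_dim = time_embed_dim),
    seed = seed + 1L)
  fit <- train_score_model(
    model, ds$train,
    train_config(epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, ema_decay = ema_decay,
                 seed = seed + 2L),
    schedule, verbose = verbose)
  eval_cases <- ds$test$cases[seq_len(min(n_eval, length(ds$test$cases)))]
  arr <- dataset_arrays(new_dose_dataset(eval_cases), 2L)
  pdose <- sample_dose(fit, arr$cond, schedule,
                       sampler_config(N_steps = schedule_N,
                                      M_corrector = M_corrector,
                                      seed = seed + 3L))
  metrics <- evaluate_cases(pdose, eval_cases)
  baseline <- planned_vs_measured(eval_cases)
  summary <- tibble::tibble(
    n_train = length(ds$train$cases),
    n_test = length(ds$test$cases),
    n_eval = length(eval_cases),
    ssim_mean = mean(metrics$ssim),
    ssim_sd = stats::sd(metrics$ssim),
    rmse_pct_mean = mean(metrics$rmse_pct),
    mae_pct_mean = mean(metrics$mae_pct),
    baseline_ssim_mean = mean(baseline$ssim),
    baseline_rmse_pct_mean = mean(baseline$rmse_pct),
    baseline_mae_pct_mean = mean(baseline$mae_pct))
  structure(list(fit = fit, pdose = pdose, metrics = metrics,
                 baseline = baseline, summary = summary, datasets = ds),
            class = "synthetic_experiment")
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<synthetic_experiment> %d train / %d test, %d evaluated\n",
              s$n_train, s$n_test, s$n_eval))
  cat(sprintf("  predicted vs measured: SSIM %.4f, RMSE %.3f%%, MAE %.3f%%\n",
              s$ssim_mean, s$rmse_pct_mean, s$mae_pct_mean))
  cat(sprintf("  planned  vs measured: SSIM %.4f, RMSE %.3f%%, MAE %.3f%%\n",
              s$baseline_ssim_mean, s$baseline_rmse_pct_mean,
              s$baseline_mae_pct_mean))
  invisible(x)
}
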