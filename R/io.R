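# Persistence: datasets as per-case NIfTI volumes + a JSON manifest,
# checkpoints as RDS archives. All writers are deterministic (no timestamps)
# so identical seeds yield byte-identical files.

#' Write a paired dataset to disk
#'
#' Lays out `dir/manifest.json` plus one uncompressed NIfTI file per case and
#' channel (`<id>_mdose.nii`, `<id>_rtdose.nii`, `<id>_ct.nii`). Uncompressed
#' NIfTI is used so that re-running with the same seed produces byte-identical
#' files.
#'
#' @param data A `dose_dataset_split` from [make_dataset()] or a single
#'   `dose_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dose_dataset <- function(data, dir) {
  if (inherits(data, "dose_dataset_split")) {
    cases <- c(data$train$cases, data$test$cases)
    manifest <- data$manifest
  } else if (inherits(data, "dose_dataset")) {
    cases <- data$cases
    manifest <- data$manifest
    if (is.null(manifest$train_ids)) {
      manifest$train_ids <- vapply(cases, function(cs) cs$case_id, "")
      manifest$test_ids <- character(0)
    }
  } else {
    stop("`data` must be a dose_dataset or dose_dataset_split", call. = FALSE)
  }
  dir.create(file.path(dir, "cases"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory", call. = FALSE)
  manifest$sites <- lapply(cases, function(cs) cs$site)
  names(manifest$sites) <- vapply(cases, function(cs) cs$case_id, "")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  for (cs in cases) {
    for (ch in c("mdose", "rtdose", "ct")) {
      f <- file.path(dir, "cases", sprintf("%s_%s.nii", cs$case_id, ch))
      RNifti::writeNifti(RNifti::asNifti(cs[[ch]]), f)
    }
  }
  invisible(dir)
}

#' Read a dataset written by [write_dose_dataset()]
#'
#' @param dir Dataset directory.
#' @return A `dose_dataset_split` (with empty test split if none recorded).
#' @export
read_dose_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", dir, call. = FALSE)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  read_case <- function(id) {
    chans <- lapply(c("mdose", "rtdose", "ct"), function(ch) {
      f <- file.path(dir, "cases", sprintf("%s_%s.nii", id, ch))
      if (!file.exists(f)) stop("missing channel file: ", f, call. = FALSE)
      m <- as.array(RNifti::readNifti(f))
      matrix(m, dim(m)[1], dim(m)[2])
    })
    structure(list(case_id = id, site = manifest$sites[[id]],
                   ct = chans[[3]], rtdose = chans[[2]], mdose = chans[[1]],
                   spacing = c(1, 1)),
              class = "dose_case")
  }
  train <- lapply(manifest$train_ids, read_case)
  test <- lapply(as.character(manifest$test_ids %||% character(0)), read_case)
  structure(list(train = new_dose_dataset(train, manifest),
                 test = new_dose_dataset(test, manifest),
                 manifest = manifest),
            class = "dose_dataset_split")
}

#' Save / load a model checkpoint
#'
#' The checkpoint archives everything needed to restore exact forward
#' behaviour: weights, architecture config, schedule, initialization seed,
#' plus (optionally) the loss trace and training epoch for resuming.
#'
#' @param fit A `scoredose_fit` or bare `score_model`.
#' @param path Output `.rds` path.
#' @param extra Named list merged into the archive.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(fit, path, extra = list()) {
  if (inherits(fit, "score_model")) {
    fit <- list(model = fit, trace = NULL, config = NULL, schedule = NULL)
  }
  stopifnot(!is.null(fit$model))
  model <- fit$model
  obj <- c(list(kind = "scoredose_checkpoint",
                package_version = as.character(utils::packageVersion("scoredose")),
                model_config = model$config, params = model$params,
                model_seed = model$seed,
                schedule = fit$schedule, train_config = fit$config,
                trace = fit$trace, aux_channel = fit$aux_channel),
           extra)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return For `load_checkpoint`: a `scoredose_fit` with restored weights.
#' @export
load_checkpoint <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("corrupted or unreadable checkpoint: ", path, call. = FALSE)
  })
  if (!is.list(obj) || !identical(obj$kind, "scoredose_checkpoint")) {
    stop("not a scoredose checkpoint: ", path, call. = FALSE)
  }
  model <- build_score_model(obj$model_config, seed = obj$model_seed %||% 1L)
  model$params <- obj$params
  structure(list(model = model, trace = obj$trace, config = obj$train_config,
                 schedule = obj$schedule, aux_channel = obj$aux_channel %||% "ct",
                 extra = obj[setdiff(names(obj),
                                     c("kind", "package_version", "model_config",
                                       "params", "model_seed", "schedule",
                                       "train_config", "trace", "aux_channel"))]),
            class = "scoredose_fit")
}

#' Export a predicted dose field as NIfTI
#'
#' @param field Numeric matrix.
#' @param path Output `.nii` path.
#' @return `path`, invisibly.
#' @export
write_dose_nifti <- function(field, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(RNifti::asNifti(field), path)
  invisible(path)
}

#' @rdname write_dose_nifti
#' @export
read_dose_nifti <- function(path) {
  m <- as.array(RNifti::readNifti(path))
  matrix(m, dim(m)[1], dim(m)[2])
}
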