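# Cross-validation schemes and model comparison: effort-split averaging
# (fit on low effort, test on high, and vice versa; combined BIC) and
# seeded k-fold cross-validation over individual trials.

# element-wise average of a list of trials -> one averaged trial
average_trials <- function(trials) {
  n <- length(trials[[1]]$force)
  traces <- lapply(setNames(BAND_NAMES, BAND_NAMES), function(b)
    rowMeans(vapply(trials, function(tr) tr$band_trace[[b]], numeric(n))))
  list(band_trace = traces,
       force = rowMeans(vapply(trials, function(tr) tr$force, numeric(n))),
       times = trials[[1]]$times,
       fs = trials[[1]]$fs,
       sre = mean(vapply(trials, function(tr) as.numeric(tr$sre), numeric(1))))
}

prediction_metrics <- function(pred, meas, times) {
  list(within_r = within_trial_r(pred, meas),
       nrmse_pct = nrmse(pred, meas),
       stable_pred = stable_force(pred, times),
       stable_meas = stable_force(meas, times),
       dif_rt_s = dif_rt(pred, meas, times))
}

#' Effort-split cross-validation with combined BIC model comparison
#'
#' Trials are split at the self-rated effort threshold: low effort is
#' SRE <= 5 (inclusive), high effort SRE > 5. Band traces and force are
#' averaged within each half; each model is fitted on one half's averages
#' and tested on the other's, in both directions. The BIC per model is
#' computed on the concatenated test-set time points of both directions
#' (`n = 2 x` window length), penalised by the model's free-parameter count.
#'
#' @param trials list of trials (`band_trace`, `force`, `times`, `fs`,
#'   `sre`).
#' @param model_ids models to compare (default 1:8).
#' @param fs_feature feature rate in Hz (default taken from the trials).
#' @return list of class `stn_effort_split`: `per_model` (per model:
#'   fits, per-direction predictions and metrics, `bic`, `sigma2`, `n`,
#'   `k`), `comparison` (data.frame: model_id, k, sigma2, bic, within_r per
#'   direction), `split` (trial indices per half), `best_model`.
#' @export
effort_split_cv <- function(trials, model_ids = 1:8, fs_feature = NULL) {
  sre <- vapply(trials, function(tr) as.numeric(tr$sre), numeric(1))
  low <- which(sre <= 5)
  high <- which(sre > 5)
  if (!length(low) || !length(high))
    stopf("effort split needs both halves non-empty; SRE distribution: %s",
          paste(sort(sre), collapse = ", "))
  if (is.null(fs_feature)) fs_feature <- trials[[1]]$fs
  avg_low <- average_trials(trials[low])
  avg_high <- average_trials(trials[high])
  times <- avg_low$times

  per_model <- lapply(model_ids, function(id) {
    fit_low <- fit_model(id, avg_low, fs_feature)
    fit_high <- fit_model(id, avg_high, fs_feature)
    pred_high <- predict(fit_low, avg_high$band_trace, fs_feature)
    pred_low <- predict(fit_high, avg_low$band_trace, fs_feature)
    res <- c(pred_high - avg_high$force, pred_low - avg_low$force)
    n <- length(res)
    k <- count_free_parameters(id)
    sigma2 <- mean(res^2)
    list(model_id = id, k = k,
         fit_on_low = fit_low, fit_on_high = fit_high,
         metrics_high = prediction_metrics(pred_high, avg_high$force, times),
         metrics_low = prediction_metrics(pred_low, avg_low$force, times),
         pred_high = pred_high, pred_low = pred_low,
         sigma2 = sigma2, n = n, bic = bic(NULL, n, k, sigma2 = sigma2))
  })
  names(per_model) <- as.character(model_ids)
  comparison <- do.call(rbind, lapply(per_model, function(m)
    data.frame(model_id = m$model_id, k = m$k, sigma2 = m$sigma2, n = m$n,
               bic = m$bic,
               within_r_high = m$metrics_high$within_r,
               within_r_low = m$metrics_low$within_r,
               nrmse_high = m$metrics_high$nrmse_pct,
               nrmse_low = m$metrics_low$nrmse_pct)))
  rownames(comparison) <- NULL
  best <- comparison$model_id[which.min(comparison$bic)]
  structure(list(per_model = per_model, comparison = comparison,
                 split = list(low = low, high = high),
                 averages = list(low = avg_low, high = avg_high),
                 best_model = best),
            class = "stn_effort_split")
}

#' @export
print.stn_effort_split <- function(x, ...) {
  cat(sprintf("Effort-split CV (%d low / %d high trials); best model by BIC: %d\n",
              length(x$split$low), length(x$split$high), x$best_model))
  print(x$comparison[, c("model_id", "k", "bic", "within_r_high",
                         "within_r_low")])
  invisible(x)
}

#' Seeded k-fold partition
#'
#' @param n_trials number of trials.
#' @param n_folds number of folds (<= n_trials).
#' @param seed RNG seed for the permutation.
#' @return integer fold assignment per trial; fold sizes differ by at most 1
#'   and every trial is tested exactly once.
#' @export
kfold_assign <- function(n_trials, n_folds, seed = 1L) {
  if (n_trials < n_folds)
    stopf("need at least as many trials (%d) as folds (%d)", n_trials, n_folds)
  with_seed(seed, {
    fold <- rep(seq_len(n_folds), length.out = n_trials)
    fold[sample.int(n_trials)]
  })
}

#' k-fold cross-validated force prediction on individual trials
#'
#' Partitions the trials into `n_folds` folds (seeded random permutation,
#' sizes differing by at most one). In each iteration one fold is retained
#' for testing and the model is fitted on the concatenated trials of the
#' remaining folds; over all iterations every trial is predicted exactly
#' once. 5 folds for the main scheme; 4 folds (15 train / 5 test of 20
#' trials) for the validation-cohort scheme.
#'
#' @param trials list of trials.
#' @param model_id model to evaluate.
#' @param n_folds number of folds (default 5).
#' @param seed partition seed.
#' @param fs_feature feature rate (default from the trials).
#' @return list of class `stn_kfold`: `predictions` (one per trial:
#'   `pred`, `meas`, `sre`, `fold`, per-trial metrics), `fold` assignment,
#'   `fits` per fold, `metrics` (data.frame of per-trial metrics),
#'   `stable_r` ([stable_force_r()] across trials), `bic` over all tested
#'   points, `median_within_r`, `n_excluded` (trials with undefined
#'   metrics).
#' @export
kfold_cv <- function(trials, model_id, n_folds = 5L, seed = 1L,
                     fs_feature = NULL) {
  if (is.null(fs_feature)) fs_feature <- trials[[1]]$fs
  fold <- kfold_assign(length(trials), n_folds, seed)
  fits <- vector("list", n_folds)
  predictions <- vector("list", length(trials))
  for (f in seq_len(n_folds)) {
    train <- trials[fold != f]
    fits[[f]] <- fit_model(model_id, train, fs_feature)
    for (i in which(fold == f)) {
      pred <- predict(fits[[f]], trials[[i]]$band_trace, fs_feature)
      predictions[[i]] <- c(
        list(pred = pred, meas = trials[[i]]$force, sre = trials[[i]]$sre,
             fold = f),
        prediction_metrics(pred, trials[[i]]$force, trials[[i]]$times))
    }
  }
  metrics <- do.call(rbind, lapply(seq_along(predictions), function(i) {
    p <- predictions[[i]]
    data.frame(trial = i, sre = p$sre, fold = p$fold, within_r = p$within_r,
               nrmse_pct = p$nrmse_pct, stable_meas = p$stable_meas,
               stable_pred = p$stable_pred, dif_rt_s = p$dif_rt_s)
  }))
  res <- unlist(lapply(predictions, function(p) p$pred - p$meas))
  k <- count_free_parameters(model_id)
  stab <- stable_force_r(metrics$stable_pred, metrics$stable_meas)
  structure(list(predictions = predictions, fold = fold, fits = fits,
                 metrics = metrics, stable_r = stab,
                 bic = bic(sum(res^2), length(res), k),
                 median_within_r = median(metrics$within_r, na.rm = TRUE),
                 n_excluded = sum(is.na(metrics$within_r) |
                                    is.na(metrics$dif_rt_s)),
                 model_id = model_id, n_folds = n_folds, seed = seed),
            class = "stn_kfold")
}

#' @export
print.stn_kfold <- function(x, ...) {
  cat(sprintf(
    "%d-fold CV of model %d: median WithinR %.3f, StableFrcR %.3f, BIC %.1f\n",
    x$n_folds, x$model_id, x$median_within_r, x$stable_r$r, x$bic))
  invisible(x)
}
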