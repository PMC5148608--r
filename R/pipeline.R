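# Pipeline orchestration: simulate -> features -> fit -> evaluate as one
# reproducible run with a manifest, plus input validation and a CLI.

#' Validate a session's inputs against the pipeline's contract
#'
#' Report-only: checks channel count (4 monopolar + force), sampling rate,
#' monotone cue times, SRE range and decode-window feasibility.
#'
#' @param recording a recording-like list (`monopolar`, `force`, `fs`,
#'   `cue_times`, `sre`).
#' @return data.frame of violations (`field`, `message`); zero rows when the
#'   session is well-formed.
#' @export
validate_inputs <- function(recording) {
  v <- list()
  add <- function(field, msg) v[[length(v) + 1L]] <<- data.frame(
    field = field, message = msg, stringsAsFactors = FALSE)
  mono <- recording$monopolar
  if (!is.matrix(mono) || nrow(mono) != 4L)
    add("monopolar", sprintf("expected 4 monopolar contacts, got %s",
                             if (is.matrix(mono)) nrow(mono) else "none"))
  if (is.null(recording$force) || !length(recording$force))
    add("force", "force channel missing")
  else if (is.matrix(mono) && ncol(mono) != length(recording$force))
    add("force", "force length does not match the LFP channels")
  fs <- recording$fs
  if (is.null(fs) || !is.finite(fs) || fs <= 180)
    add("fs", sprintf("sampling rate must exceed 180 Hz (got %s)",
                      if (is.null(fs)) "none" else fs))
  ct <- recording$cue_times
  if (is.null(ct) || !length(ct)) add("cue_times", "no cue events")
  else {
    if (any(diff(ct) <= 0)) add("cue_times", "cue times must be strictly increasing")
    if (!is.null(fs) && is.finite(fs) && length(recording$force)) {
      dur <- length(recording$force) / fs
      bad <- which(ct + 2.8 > dur | ct - 1 < 0)
      if (length(bad))
        add("cue_times", sprintf("decode window [-1, 2.8] s infeasible for trial(s) %s",
                                 paste(bad, collapse = ", ")))
    }
  }
  sre <- recording$sre
  if (is.null(sre)) add("sre", "per-trial SRE labels missing")
  else {
    if (!is.null(ct) && length(sre) != length(ct))
      add("sre", "number of SRE labels differs from number of cues")
    if (any(sre < 0 | sre > 10, na.rm = TRUE))
      add("sre", sprintf("SRE out of range [0, 10]: %s",
                         paste(sre[sre < 0 | sre > 10], collapse = ", ")))
  }
  if (!length(v)) return(data.frame(field = character(),
                                    message = character()))
  do.call(rbind, v)
}

default_run_config <- function() {
  list(
    simulate = list(n_trials = 30L, fs = 512, true_model_id = 2L,
                    true_params = c(Kp1 = 2, Kp2 = -1, Tp = 0.2, Td = 0.2),
                    noise_sd = 0.05),
    session_dir = NULL,
    pair = "auto",
    fs_feature = 100,
    window = c(-1, 2.8),
    bands = list(alpha = c(4, 12), beta = c(13, 30), gamma = c(55, 90)),
    n_cycles = 7,
    model_ids = 1:8,
    cv = list(scheme = "effort_split", n_folds = 5L),
    seed = 1L,
    write_session_copy = FALSE
  )
}

normalize_run_config <- function(config) {
  cfg <- modifyList(default_run_config(), config)
  cfg$model_ids <- as.integer(unlist(cfg$model_ids))
  cfg$fs_feature <- as.numeric(cfg$fs_feature)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Run the full decoding pipeline
#'
#' Orchestrates simulate (or load) -> feature extraction -> model fitting ->
#' evaluation, writing features, per-trial/per-direction metrics, a model
#' comparison table, fitted parameters and a manifest (config hash, seed,
#' package versions). Re-running with the same config and seed reproduces
#' the numeric outputs bit-for-bit.
#'
#' @param config named list (see `default_run_config()` internals):
#'   either `simulate` (arguments to [synthetic_config()]) or `session_dir`;
#'   plus `pair`, `fs_feature`, `model_ids`, `cv` (`scheme` =
#'   "effort_split"/"kfold", `n_folds`), `seed`.
#' @param out_dir output directory.
#' @return list of class `stn_run`: `features`, `evaluation`, `paths`,
#'   `config`.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  cfg <- normalize_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = cfg$seed, stage = "init",
                   versions = list(
                     stnforce = as.character(utils::packageVersion("stnforce")),
                     R = paste(R.version$major, R.version$minor, sep = ".")),
                   complete = FALSE)
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  stage <- function(name, expr) {
    manifest$stage <<- name
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  session <- NULL
  recording <- stage("input", {
    if (!is.null(cfg$session_dir)) {
      x <- read_session(cfg$session_dir)
      if (inherits(x, "stn_session")) { session <- x; x$recording } else x
    } else {
      sim_args <- cfg$simulate
      if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
      if (!is.null(sim_args$true_params))
        sim_args$true_params <- unlist(sim_args$true_params)
      session <- do.call(synthetic_config, sim_args)
      session <- generate_session(session)
      session$recording
    }
  })
  bad <- validate_inputs(recording)
  if (nrow(bad))
    stopf("invalid session input:\n%s",
          paste(sprintf("- %s: %s", bad$field, bad$message), collapse = "\n"))

  features <- stage("features", extract_features(
    recording, pair = cfg$pair, fs_feature = cfg$fs_feature,
    n_cycles = cfg$n_cycles, window = as.numeric(unlist(cfg$window))))
  paths <- list(features = file.path(out_dir, "features.csv"))
  write_features(features, paths$features)

  evaluation <- stage("evaluate", {
    if (identical(cfg$cv$scheme, "kfold")) {
      runs <- lapply(cfg$model_ids, function(id)
        kfold_cv(features$trials, id, n_folds = cfg$cv$n_folds,
                 seed = cfg$seed, fs_feature = cfg$fs_feature))
      names(runs) <- as.character(cfg$model_ids)
      comparison <- do.call(rbind, lapply(runs, function(r)
        data.frame(model_id = r$model_id,
                   k = count_free_parameters(r$model_id), bic = r$bic,
                   median_within_r = r$median_within_r,
                   stable_r = r$stable_r$r)))
      metrics <- do.call(rbind, lapply(runs, function(r)
        cbind(model_id = r$model_id, r$metrics)))
      list(scheme = "kfold", runs = runs, comparison = comparison,
           metrics = metrics,
           best_model = comparison$model_id[which.min(comparison$bic)])
    } else {
      es <- effort_split_cv(features$trials, cfg$model_ids, cfg$fs_feature)
      metrics <- do.call(rbind, lapply(es$per_model, function(m) rbind(
        data.frame(model_id = m$model_id, direction = "fit_low_test_high",
                   as.data.frame(m$metrics_high)),
        data.frame(model_id = m$model_id, direction = "fit_high_test_low",
                   as.data.frame(m$metrics_low)))))
      rownames(metrics) <- NULL
      list(scheme = "effort_split", effort_split = es,
           comparison = es$comparison, metrics = metrics,
           best_model = es$best_model)
    }
  })
  paths$metrics <- file.path(out_dir, "metrics.csv")
  write.csv(evaluation$metrics, paths$metrics, row.names = FALSE)
  paths$comparison <- file.path(out_dir, "model_comparison.csv")
  write.csv(evaluation$comparison, paths$comparison, row.names = FALSE)

  paths$params <- file.path(out_dir, "fitted_params.json")
  best_fit <- if (evaluation$scheme == "effort_split")
    evaluation$effort_split$per_model[[as.character(evaluation$best_model)]]$fit_on_low
  else evaluation$runs[[as.character(evaluation$best_model)]]$fits[[1L]]
  fit_to_json(best_fit, paths$params)

  if (isTRUE(cfg$write_session_copy) && !is.null(session)) {
    paths$session <- file.path(out_dir, "session")
    write_session(session, paths$session)
  }

  cfg_path <- file.path(out_dir, "config.json")
  cfg_json <- cfg
  cfg_json$simulate$true_params <- as.list(cfg_json$simulate$true_params)
  jsonlite::write_json(cfg_json, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest$stage <- "done"
  manifest$complete <- TRUE
  manifest$config_md5 <- unname(tools::md5sum(cfg_path))
  manifest$selected_pair <- features$pair
  manifest$n_trials <- length(features$trials)
  manifest$n_dropped <- length(features$dropped)
  manifest$best_model <- evaluation$best_model
  manifest$outputs <- lapply(paths, identity)
  write_manifest()
  paths$manifest <- file.path(out_dir, "manifest.json")

  structure(list(features = features, evaluation = evaluation,
                 paths = paths, config = cfg, session = session),
            class = "stn_run")
}

#' @export
print.stn_run <- function(x, ...) {
  cat(sprintf("Pipeline run (%s CV): %d trials, pair %s, best model %d\n",
              x$evaluation$scheme, length(x$features$trials),
              x$features$pair, x$evaluation$best_model))
  invisible(x)
}

cli_args_to_list <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stopf("unexpected argument: %s", a)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      out[[key]] <- TRUE
      i <- i + 1L
    } else {
      out[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  out
}

#' Command-line entry point
#'
#' Subcommands: `simulate --config cfg.yaml --out dir [--seed N]`,
#' `features --in session_dir --out features.csv [--pair auto] [--feature-rate 100]`,
#' `fit --features features.csv --model 2 --out fit.json`,
#' `evaluate --features features.csv [--models 1,...,8] [--cv kfold:5 | effort_split] [--seed N] --out dir`,
#' `run --config run.yaml --out dir [--seed N]`, and
#' `validate --in session_dir`.
#' Exit codes: 0 ok, 1 input error, 2 internal error. Install a thin wrapper
#' with `Rscript -e 'stnforce::stn_cli()'` or use
#' `system.file("cli", "stnforce.R", package = "stnforce")`.
#'
#' @param args character vector (default `commandArgs(trailingOnly = TRUE)`).
#' @return exit status, invisibly (also used with `quit(status = )` by the
#'   installed wrapper).
#' @export
stn_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: stnforce <simulate|features|fit|evaluate|run|validate> [--key value ...]"
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1L]
  opt <- tryCatch(cli_args_to_list(args[-1L]), error = function(e) e)
  if (inherits(opt, "error")) { message(conditionMessage(opt)); return(invisible(1L)) }
  run <- function() {
    switch(cmd,
      simulate = {
        sim <- if (!is.null(opt$config)) read_config(opt$config) else list()
        if (!is.null(opt$seed)) sim$seed <- as.integer(opt$seed)
        if (!is.null(sim$true_params)) sim$true_params <- unlist(sim$true_params)
        ses <- generate_session(do.call(synthetic_config, sim))
        write_session(ses, opt$out)
        message("session written to ", opt$out)
      },
      features = {
        rec <- read_session(opt$`in`)
        if (inherits(rec, "stn_session")) rec <- rec$recording
        fr <- if (!is.null(opt$`feature-rate`)) as.numeric(opt$`feature-rate`) else 100
        feats <- extract_features(rec, pair = if (is.null(opt$pair)) "auto" else opt$pair,
                                  fs_feature = fr)
        write_features(feats, opt$out)
        message("features written to ", opt$out, " (pair ", feats$pair, ")")
      },
      fit = {
        trials <- read_features(opt$features)
        fit <- fit_model(as.integer(opt$model), trials,
                         fs_feature = trials[[1]]$fs)
        fit_to_json(fit, opt$out)
        message("fit written to ", opt$out)
      },
      evaluate = {
        trials <- read_features(opt$features)
        models <- if (is.null(opt$models)) 1:8
                  else as.integer(strsplit(opt$models, ",")[[1L]])
        cv <- if (is.null(opt$cv)) "effort_split" else opt$cv
        seed <- if (is.null(opt$seed)) 1L else as.integer(opt$seed)
        dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
        if (startsWith(cv, "kfold")) {
          nf <- if (grepl(":", cv)) as.integer(sub(".*:", "", cv)) else 5L
          runs <- lapply(models, function(id)
            kfold_cv(trials, id, n_folds = nf, seed = seed,
                     fs_feature = trials[[1]]$fs))
          comparison <- do.call(rbind, lapply(runs, function(r)
            data.frame(model_id = r$model_id, bic = r$bic,
                       median_within_r = r$median_within_r,
                       stable_r = r$stable_r$r)))
          metrics <- do.call(rbind, lapply(runs, function(r)
            cbind(model_id = r$model_id, r$metrics)))
        } else {
          es <- effort_split_cv(trials, models, trials[[1]]$fs)
          comparison <- es$comparison
          metrics <- comparison
        }
        write.csv(comparison, file.path(opt$out, "model_comparison.csv"),
                  row.names = FALSE)
        write.csv(metrics, file.path(opt$out, "metrics.csv"),
                  row.names = FALSE)
        message("evaluation written to ", opt$out)
      },
      run = {
        cfg <- if (!is.null(opt$config)) read_config(opt$config) else list()
        if (!is.null(opt$seed)) cfg$seed <- as.integer(opt$seed)
        run_pipeline(cfg, opt$out)
        message("pipeline outputs written to ", opt$out)
      },
      validate = {
        rec <- read_session(opt$`in`)
        if (inherits(rec, "stn_session")) rec <- rec$recording
        rep <- validate_inputs(rec)
        if (!nrow(rep)) message("session is well-formed")
        else {
          print(rep)
          return(1L)
        }
      },
      { message(usage); return(1L) }
    )
    0L
  }
  status <- tryCatch(run(), error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("not found|missing|unknown|must|expected|unexpected",
              conditionMessage(e))) 1L else 2L
  })
  if (is.null(status)) status <- 0L
  invisible(status)
}
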