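# Session and feature-table I/O. Sessions live in a delimited-text container:
# signals.tsv (time + 4 monopolar contacts + force), events.csv sidecar
# (cue_time_s, sre) and meta.json; synthetic ground truth goes to truth.json.

#' Write a recording or synthetic session to a directory
#'
#' @param x an `stn_recording` or `stn_session`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(x, dir) {
  rec <- if (inherits(x, "stn_session")) x$recording else x
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(rec$force)
  sig <- data.frame(time_s = (seq_len(n) - 1) / rec$fs,
                    t(rec$monopolar), force = rec$force)
  names(sig)[2:5] <- paste0("contact", 0:3)
  write.table(format(sig, digits = 10, trim = TRUE, scientific = FALSE),
              file.path(dir, "signals.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.csv(data.frame(cue_time_s = rec$cue_times, sre = rec$sre),
            file.path(dir, "events.csv"), row.names = FALSE)
  jsonlite::write_json(list(fs = rec$fs, meta = rec$meta),
                       file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  if (inherits(x, "stn_session")) {
    cfg <- x$config
    cfg_out <- lapply(unclass(cfg), function(v)
      if (is.numeric(v) || is.integer(v)) unclass(v) else v)
    jsonlite::write_json(
      list(true_model_id = x$true_model_id,
           true_params = as.list(x$true_params),
           config = cfg_out),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a recording (and ground truth, if present) from a directory
#'
#' @param dir directory written by [write_session()] (or assembled by hand
#'   in the same layout).
#' @return an `stn_recording`; when `truth.json` is present, an
#'   `stn_session` wrapping it (without regenerated envelopes).
#' @export
read_session <- function(dir) {
  sig <- read.delim(file.path(dir, "signals.tsv"))
  ev <- read.csv(file.path(dir, "events.csv"))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  mono <- t(as.matrix(sig[, paste0("contact", 0:3)]))
  rownames(mono) <- paste0("contact", 0:3)
  rec <- structure(list(monopolar = mono, force = sig$force, fs = meta$fs,
                        cue_times = ev$cue_time_s, sre = as.integer(ev$sre),
                        meta = meta$meta),
                   class = "stn_recording")
  truth_path <- file.path(dir, "truth.json")
  if (!file.exists(truth_path)) return(rec)
  truth <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
  structure(list(recording = rec, true_envelopes = NULL,
                 true_params = unlist(truth$true_params),
                 true_model_id = truth$true_model_id,
                 config = truth$config),
            class = "stn_session")
}

#' Write extracted features to a tidy CSV
#'
#' Long format: one row per trial x time point with the three band traces,
#' the normalised force, effort label and onset time.
#'
#' @param features an `stn_features` from [extract_features()], or a bare
#'   list of trials.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  trials <- if (inherits(features, "stn_features")) features$trials
            else features
  rows <- lapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    data.frame(trial = i, sre = tr$sre, time_s = tr$times,
               alpha = tr$band_trace$alpha, beta = tr$band_trace$beta,
               gamma = tr$band_trace$gamma, force = tr$force,
               onset_s = if (is.null(tr$onset_time)) NA_real_
                         else tr$onset_time)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a feature CSV back into a trial list
#'
#' @param path CSV written by [write_features()].
#' @return list of trials (`band_trace`, `force`, `times`, `fs`, `sre`,
#'   `onset_time`).
#' @export
read_features <- function(path) {
  df <- read.csv(path)
  lapply(split(df, df$trial), function(d) {
    d <- d[order(d$time_s), ]
    fs <- 1 / median(diff(d$time_s))
    list(band_trace = list(alpha = d$alpha, beta = d$beta, gamma = d$gamma),
         force = d$force, times = d$time_s, fs = round(fs, 6),
         sre = d$sre[1],
         onset_time = if (all(is.na(d$onset_s))) NA_real_ else d$onset_s[1])
  })
}

#' Read a run/simulation configuration (YAML or JSON)
#'
#' @param path configuration file; format by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a configuration list (YAML or JSON by extension)
#'
#' `read_config(write_config(x, p))` round-trips the configuration.
#'
#' @param config named list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(config, path)
  else jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE)
  invisible(path)
}
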