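#' Read and validate a run configuration
#'
#' Run configurations are YAML key-value files. Unknown keys are errors, not
#' warnings, so a typo cannot silently fall back to a default. Every known
#' key is optional; defaults are those of the underlying functions.
#'
#' @param path YAML file path.
#' @return named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("ibi_csv", "steps_csv", "panel_csv", "outdir", "seed",
             "night_window_h", "segment_len_s", "completeness_min",
             "range_ms", "rel_dev", "med_k", "rate", "bands",
             "lag", "estimator", "covariates", "log_metrics",
             "hrv_metric", "health_vars", "binary_vars",
             "n_persons", "n_obs_per_person", "true_between_r",
             "true_within_r", "icc_x", "icc_y", "alpha", "n_reps",
             "test_level", "duration", "target_rmssd", "mean_ibi")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown run_config key(s): ", paste(unknown, collapse = ", "))
  structure(cfg, class = "run_config")
}

cfg_get <- function(cfg, key, default) {
  if (is.null(cfg[[key]])) default else cfg[[key]]
}

ensure_outdir <- function(cfg) {
  outdir <- cfg_get(cfg, "outdir", ".")
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  outdir
}

#' Simulate an IBI recording and a panel to disk
#'
#' Writes the IBI CSV, steps CSV, panel CSV and truth sidecars for a
#' synthetic person-night plus a two-level panel, all derived from the
#' single configured seed (a missing seed is drawn, logged and echoed).
#'
#' @param cfg a `run_config` (or path to one).
#' @return invisible character vector of the files written.
#' @export
run_simulate <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  outdir <- ensure_outdir(cfg)
  seed <- cfg_get(cfg, "seed", NULL)
  if (is.null(seed)) {
    seed <- sample.int(.Machine$integer.max, 1)
    message("run_simulate: no seed configured; generated seed ", seed)
  }
  isim <- simulate_ibi(ibi_config(
    mean_ibi = cfg_get(cfg, "mean_ibi", 900),
    target_rmssd = cfg_get(cfg, "target_rmssd", 40),
    duration = cfg_get(cfg, "duration", 18000), seed = seed))
  psim <- simulate_panel(panel_config(
    cfg_get(cfg, "n_persons", 100), cfg_get(cfg, "n_obs_per_person", 9),
    seed = seed + 1L))
  files <- file.path(outdir, c("ibi.csv", "steps.csv", "ibi_truth.yaml",
                               "panel.csv", "panel_truth.yaml"))
  write_ibi_csv(isim$series, files[1], seed = seed)
  write_steps_csv(isim$steps, files[2], seed = seed)
  write_truth(isim$truth[setdiff(names(isim$truth), "movement_minutes")],
              files[3])
  write_panel_csv(psim$panel, files[4], seed = seed + 1L)
  write_truth(list(seed = seed + 1L,
                   icc = psim$truth$config$icc,
                   between_corr = as.vector(psim$truth$config$between_corr),
                   within_corr = as.vector(psim$truth$config$within_corr)),
              files[5])
  invisible(files)
}

#' Preprocess IBI recordings into HRV records
#'
#' Reads the configured IBI and steps CSVs, runs [process_night()] per
#' recording, and writes the segment table, rejection log and HRV record
#' CSV. A summary of segments kept and dropped by reason is printed.
#'
#' @param cfg a `run_config` (or path to one).
#' @return invisible character vector of the files written.
#' @export
run_preprocess <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  outdir <- ensure_outdir(cfg)
  series <- read_ibi_csv(cfg$ibi_csv)
  if (inherits(series, "beat_series")) series <- list(series)
  steps <- if (!is.null(cfg$steps_csv)) read_steps_csv(cfg$steps_csv) else NULL
  records <- list(); segs <- list(); rejs <- list()
  for (i in seq_along(series)) {
    s <- series[[i]]
    st <- if (is.null(steps)) NULL else steps[steps$person_id == s$person_id, ]
    night <- process_night(
      s, st, day_index = i,
      window_h = cfg_get(cfg, "night_window_h", c(0, 5)),
      seg_len_s = cfg_get(cfg, "segment_len_s", 300),
      completeness_min = cfg_get(cfg, "completeness_min", 0.70),
      range_ms = cfg_get(cfg, "range_ms", c(300, 2000)),
      rel_dev = cfg_get(cfg, "rel_dev", 0.25),
      med_k = cfg_get(cfg, "med_k", 5),
      rate = cfg_get(cfg, "rate", 4))
    if (!is.null(night$record)) records[[length(records) + 1L]] <- night$record
    sm <- night$segments
    if (nrow(sm)) { sm$person_id <- s$person_id; sm$recording <- i }
    segs[[i]] <- sm
    if (nrow(night$rejections)) rejs[[length(rejs) + 1L]] <- night$rejections
  }
  seg_tab <- do.call(rbind, segs)
  message("segments by status: ",
          paste(names(table(seg_tab$status)), table(seg_tab$status),
                sep = "=", collapse = ", "))
  rec_tab <- if (length(records)) do.call(rbind, records) else
    stop("no person-night yielded a valid HRV record")
  rec_tab <- log_transform(rec_tab, cfg_get(cfg, "log_metrics", "rmssd"))
  files <- file.path(outdir, c("segments.csv", "rejections.csv",
                               "hrv_records.csv"))
  utils::write.csv(seg_tab, files[1], row.names = FALSE)
  utils::write.csv(if (length(rejs)) do.call(rbind, rejs) else
    data.frame(beat_index = integer(0), ibi_ms = numeric(0),
               rule = character(0), segment = integer(0)),
    files[2], row.names = FALSE)
  utils::write.csv(rec_tab, files[3], row.names = FALSE)
  invisible(files)
}

#' Correlate HRV with health measures and write reports
#'
#' Reads a panel CSV, estimates the within/between-person correlation of the
#' configured HRV metric with each health variable (Pearson via the
#' two-level estimator; biserial for binary person-level variables), and the
#' HRV metric's variance components, and writes the correlation report and
#' ICC CSVs.
#'
#' @param cfg a `run_config` (or path to one).
#' @return invisible character vector of the files written.
#' @export
run_associate <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  outdir <- ensure_outdir(cfg)
  panel <- read_panel_csv(cfg$panel_csv)
  hrv <- cfg_get(cfg, "hrv_metric", "rmssd")
  health <- cfg_get(cfg, "health_vars",
                    setdiff(names(panel), c("person_id", "day_index", "age",
                                            "gender", hrv)))
  absent <- setdiff(c(hrv, health), names(panel))
  if (length(absent))
    stop("variable(s) not in panel: ", paste(absent, collapse = ", "),
         "; available: ",
         paste(setdiff(names(panel), c("person_id", "day_index")),
               collapse = ", "))
  binary <- cfg_get(cfg, "binary_vars",
                    health[vapply(health, function(v)
                      all(stats::na.omit(panel[[v]]) %in% c(0, 1)), TRUE)])
  covars <- cfg_get(cfg, "covariates", intersect(c("age", "gender"),
                                                 names(panel)))
  lag <- cfg_get(cfg, "lag", "same_day")
  estimates <- lapply(health, function(v) {
    if (v %in% binary) {
      per <- stats::aggregate(panel[[hrv]],
                              by = list(person_id = panel$person_id),
                              FUN = mean, na.rm = TRUE)
      bin <- panel[[v]][match(per$person_id, panel$person_id)]
      est <- biserial_corr(per$x, bin)
      est$pair <- c(x = v, y = hrv)
      est
    } else {
      paired <- align_lag(panel, v, hrv, lag)
      paired <- merge(paired,
                      panel[!duplicated(panel$person_id),
                            c("person_id", intersect(covars, names(panel)))],
                      by = "person_id")
      multilevel_corr(paired, v, hrv, covariates = covars,
                      estimator = cfg_get(cfg, "estimator", "ml"))
    }
  })
  report <- correlation_report(estimates)
  vc <- variance_components(panel, hrv)
  files <- file.path(outdir, c("correlations.csv", "icc.csv"))
  utils::write.csv(report, files[1], row.names = FALSE)
  utils::write.csv(data.frame(variable = vc$variable, var_bp = vc$var_bp,
                              var_wp = vc$var_wp, icc = vc$icc,
                              n_persons = vc$n_persons, n_obs = vc$n_obs),
                   files[2], row.names = FALSE)
  invisible(files)
}

#' Run a Monte Carlo power analysis to disk
#'
#' @param cfg a `run_config` (or path to one).
#' @return invisible path of the power CSV written.
#' @export
run_power <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  outdir <- ensure_outdir(cfg)
  pc <- power_config(
    n_persons = cfg_get(cfg, "n_persons", 100),
    n_obs_per_person = cfg_get(cfg, "n_obs_per_person", 9),
    true_between_r = cfg_get(cfg, "true_between_r", 0),
    true_within_r = cfg_get(cfg, "true_within_r", 0),
    icc_x = cfg_get(cfg, "icc_x", 0.5), icc_y = cfg_get(cfg, "icc_y", 0.5),
    alpha = cfg_get(cfg, "alpha", 0.05),
    n_reps = cfg_get(cfg, "n_reps", 1000),
    test_level = cfg_get(cfg, "test_level", "between"),
    seed = cfg_get(cfg, "seed", NULL))
  out <- power_curve(list(pc))
  path <- file.path(outdir, "power.csv")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
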