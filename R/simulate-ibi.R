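#' Configuration for the synthetic IBI generator
#'
#' Defines one synthetic recording. The generative model is a sinusoidal
#' respiratory-sinus-arrhythmia component (which controls high-frequency
#' power) plus AR(1) Gaussian noise, mean-shifted to `mean_ibi`:
#' \deqn{IBI_k = \mu + A \sin(2\pi f k \Delta) + e_k, \quad
#'       e_k = \phi e_{k-1} + \varepsilon_k.}
#' The innovation variance is solved so that the expected RMSSD of the series
#' equals `target_rmssd`: the mean squared successive difference contributed
#' by the sinusoid is \eqn{2 A^2 \sin^2(\pi f \Delta)} and by the AR(1) term
#' \eqn{2\sigma_e^2(1-\phi)}, with \eqn{\Delta} the mean beat spacing.
#'
#' @param mean_ibi mean interbeat interval, ms (> 0).
#' @param target_rmssd desired expected RMSSD, ms (>= 0).
#' @param resp_freq respiratory frequency, Hz; default 0.25 sits mid-HF-band.
#' @param resp_amp respiratory modulation amplitude, ms.
#' @param ar_coef AR(1) coefficient of the residual noise, in (-1, 1).
#' @param duration recording length, seconds (> 0).
#' @param gap_fraction proportion of true beats removed in contiguous
#'   missing-data gaps, in [0, 1).
#' @param spurious_rate spurious beats injected per 100 true beats; each
#'   artifact either splits one true interval into two short intervals
#'   (false detection) or doubles one interval (missed beat).
#' @param movement_minutes integer minute indices (0-based from recording
#'   start) given positive step counts in the paired step table.
#' @param start_clock_h clock hour of the first beat relative to local
#'   midnight (may be negative, e.g. -0.5 for 23:30).
#' @param person_id,recording_id identifiers copied into the outputs.
#' @param device_context device context tag for the series.
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return a list of class `ibi_config`.
#' @export
ibi_config <- function(mean_ibi = 900, target_rmssd = 40, resp_freq = 0.25,
                       resp_amp = 15, ar_coef = 0.3, duration = 18000,
                       gap_fraction = 0, spurious_rate = 0,
                       movement_minutes = integer(0), start_clock_h = 0,
                       person_id = "p1", recording_id = "r1",
                       device_context = "night_watch", seed = NULL) {
  cfg <- list(mean_ibi = mean_ibi, target_rmssd = target_rmssd,
              resp_freq = resp_freq, resp_amp = resp_amp, ar_coef = ar_coef,
              duration = duration, gap_fraction = gap_fraction,
              spurious_rate = spurious_rate,
              movement_minutes = as.integer(movement_minutes),
              start_clock_h = start_clock_h, person_id = person_id,
              recording_id = recording_id, device_context = device_context,
              seed = seed)
  class(cfg) <- "ibi_config"
  validate_ibi_config(cfg)
  cfg
}

validate_ibi_config <- function(cfg) {
  stopifnot(inherits(cfg, "ibi_config"))
  if (!(cfg$mean_ibi > 0)) stop("ibi_config: mean_ibi must be > 0")
  if (cfg$target_rmssd < 0) stop("ibi_config: target_rmssd must be >= 0")
  if (!(cfg$duration > 0)) stop("ibi_config: duration must be > 0")
  if (cfg$gap_fraction < 0 || cfg$gap_fraction >= 1)
    stop("ibi_config: gap_fraction must lie in [0, 1)")
  if (abs(cfg$ar_coef) >= 1) stop("ibi_config: ar_coef must lie in (-1, 1)")
  if (cfg$spurious_rate < 0) stop("ibi_config: spurious_rate must be >= 0")
  ## feasibility: the sinusoid alone must not exceed the RMSSD budget
  if (rsa_msd(cfg) > cfg$target_rmssd^2 + 1e-12)
    stop("ibi_config: resp_amp implies an RMSSD above target_rmssd; ",
         "lower resp_amp or raise target_rmssd")
  invisible(cfg)
}

## mean squared successive difference contributed by the respiratory sinusoid
rsa_msd <- function(cfg) {
  dt <- cfg$mean_ibi / 1000
  2 * cfg$resp_amp^2 * sin(pi * cfg$resp_freq * dt)^2
}

#' Simulate one wearable IBI recording
#'
#' Generates a beat series with known expected RMSSD, then degrades it:
#' contiguous gaps of missing beats, spurious beats (split or doubled
#' intervals), and a per-minute step table with positive counts in the
#' configured movement minutes. The returned truth object records every
#' parameter actually used, including the solved noise standard deviation and
#' exact artifact counts.
#'
#' @param cfg an [ibi_config()].
#' @return a list of class `ibi_sim` with elements `series` (a
#'   [beat_series()]), `steps` (data.frame `person_id`, `minute_start_ms`,
#'   `steps`), and `truth` (generating parameters and realized counts).
#' @export
#' @examples
#' sim <- simulate_ibi(ibi_config(duration = 600, seed = 1))
#' sim$series
simulate_ibi <- function(cfg) {
  validate_ibi_config(cfg)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  dt <- cfg$mean_ibi / 1000
  n <- ceiling(cfg$duration / dt) + 10L

  resid_msd <- cfg$target_rmssd^2 - rsa_msd(cfg)
  sigma_e <- sqrt(max(resid_msd, 0) / (2 * (1 - cfg$ar_coef)))
  eps_sd <- sigma_e * sqrt(1 - cfg$ar_coef^2)
  e <- if (sigma_e > 0) {
    as.numeric(stats::filter(stats::rnorm(n, 0, eps_sd), cfg$ar_coef,
                             method = "recursive"))
  } else numeric(n)
  rsa <- cfg$resp_amp * sin(2 * pi * cfg$resp_freq * (seq_len(n) - 1L) * dt)
  ibi <- pmax(cfg$mean_ibi + rsa + e, 200)  # guard against non-physiologic tails

  t0 <- cfg$start_clock_h * 3600 * 1000
  t_ms <- t0 + c(0, cumsum(ibi[-1]))
  keep <- t_ms - t0 <= cfg$duration * 1000
  t_ms <- t_ms[keep]
  n_true <- length(t_ms)
  ibi_out <- c(NA_real_, diff(t_ms))

  ## spurious beats: round(rate/100 * true beat count) artifacts
  n_spur <- round(cfg$spurious_rate / 100 * n_true)
  spur_split <- 0L; spur_miss <- 0L
  if (n_spur > 0) {
    cand <- sample(2:n_true, n_spur)
    split_sel <- stats::runif(n_spur) < 0.5
    extra_t <- numeric(0)
    drop_beat <- integer(0)
    for (j in seq_len(n_spur)) {
      k <- cand[j]
      if (split_sel[j]) {
        ## false detection: insert a beat inside interval k
        extra_t <- c(extra_t, t_ms[k - 1] + 0.45 * (t_ms[k] - t_ms[k - 1]))
        spur_split <- spur_split + 1L
      } else {
        ## missed beat: drop beat k, doubling the surrounding interval
        drop_beat <- c(drop_beat, k)
        spur_miss <- spur_miss + 1L
      }
    }
    t_ms <- sort(c(t_ms[setdiff(seq_len(n_true), drop_beat)], extra_t))
    ibi_out <- c(NA_real_, diff(t_ms))
  }

  ## contiguous gaps of missing beats
  n_gap_target <- round(cfg$gap_fraction * length(t_ms))
  removed <- logical(length(t_ms))
  n_removed <- 0L
  guard <- 0L
  while (n_removed < n_gap_target && guard < 1000L) {
    guard <- guard + 1L
    len <- min(stats::rpois(1, 20) + 5L, n_gap_target - n_removed)
    s <- sample.int(length(t_ms) - len + 1L, 1L)
    idx <- s:(s + len - 1L)
    idx <- idx[!removed[idx]]
    removed[idx] <- TRUE
    n_removed <- n_removed + length(idx)
  }
  if (any(removed)) {
    keep_idx <- which(!removed)
    t_ms <- t_ms[keep_idx]
    ibi_out <- ibi_out[keep_idx]
    pred_gone <- c(TRUE, diff(keep_idx) != 1L)
    ibi_out[pred_gone] <- NA_real_
  }

  series <- beat_series(cfg$person_id, cfg$recording_id, t_ms, ibi_out,
                        cfg$device_context)

  minutes <- seq(0L, floor((cfg$duration - 1) / 60))
  steps <- data.frame(
    person_id = cfg$person_id,
    minute_start_ms = t0 + minutes * 60000,
    steps = ifelse(minutes %in% cfg$movement_minutes,
                   10L + stats::rpois(length(minutes), 20L), 0L))

  truth <- c(unclass(cfg),
             list(sigma_e = sigma_e, n_true_beats = n_true,
                  n_spurious = n_spur, n_spurious_split = spur_split,
                  n_spurious_missed = spur_miss, n_gap_removed = n_removed))
  structure(list(series = series, steps = steps, truth = truth),
            class = "ibi_sim")
}
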