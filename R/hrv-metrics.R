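#' Root mean square of successive differences
#'
#' The primary time-domain HRV index, sensitive to beat-to-beat
#' (parasympathetically mediated) variability:
#' \deqn{RMSSD = \sqrt{\mathrm{mean}\big((IBI_{k+1} - IBI_k)^2\big)}.}
#' `NA` intervals break the series: a difference is only formed between two
#' consecutive valid IBIs.
#'
#' @param ibis numeric vector of interbeat intervals, ms; may contain `NA`.
#' @return RMSSD in ms.
#' @export
#' @examples
#' rmssd(c(800, 810, 790, 805))
rmssd <- function(ibis) {
  x <- successive_diffs(ibis)
  if (length(x) < 1) stop("rmssd undefined: fewer than 2 consecutive valid IBIs")
  sqrt(mean(x^2))
}

## differences between consecutive valid IBIs only; an NA severs the chain
successive_diffs <- function(ibis) {
  d <- diff(ibis)
  d[!is.na(d)]
}

#' Standard deviation of normal-to-normal intervals
#'
#' Sample standard deviation (n - 1 denominator) of the valid IBIs; an index
#' of overall HRV magnitude.
#'
#' @inheritParams rmssd
#' @return SDNN in ms.
#' @export
sdnn <- function(ibis) {
  x <- ibis[!is.na(ibis)]
  if (length(x) < 2) stop("sdnn undefined: fewer than 2 valid IBIs")
  stats::sd(x)
}

#' Standard HRV frequency bands
#'
#' Very-low, low and high frequency bands (Hz, half-open `[low, high)`)
#' following the conventional short-term HRV limits. Override by passing a
#' modified data.frame to [band_powers()].
#'
#' @return data.frame with columns `name`, `low`, `high`.
#' @export
hrv_bands <- function() {
  data.frame(name = c("vlf", "lf", "hf"),
             low = c(0.0033, 0.04, 0.15),
             high = c(0.04, 0.15, 0.40),
             stringsAsFactors = FALSE)
}

#' Frequency-domain HRV band powers
#'
#' Integrates the Welch-averaged periodogram (see [welch_psd()]) of the
#' mean-removed tachogram over each band. VLF power is suppressed (returned
#' as `NA` with a warning) for recordings shorter than `min_vlf_s` seconds,
#' because very-low-frequency oscillations are not resolvable below the
#' conventional five-minute minimum.
#'
#' @param tachogram evenly sampled IBI values, ms (>= 64 samples).
#' @param rate sampling rate of the tachogram, Hz.
#' @param bands band definition data.frame, default [hrv_bands()].
#' @param min_vlf_s minimum recording length for VLF, seconds.
#' @param ... passed to [welch_psd()].
#' @return named numeric vector of band powers in ms^2.
#' @export
band_powers <- function(tachogram, rate = 4, bands = hrv_bands(),
                        min_vlf_s = 300, ...) {
  stopifnot(length(tachogram) >= 64)
  ps <- welch_psd(tachogram - mean(tachogram), fs = rate, ...)
  pw <- vapply(seq_len(nrow(bands)), function(i) {
    sel <- ps$freq >= bands$low[i] & ps$freq < bands$high[i]
    sum(ps$psd[sel]) * ps$df
  }, 0)
  names(pw) <- bands$name
  dur <- length(tachogram) / rate
  if ("vlf" %in% names(pw) && dur < min_vlf_s) {
    warning("recording shorter than ", min_vlf_s,
            " s: VLF power suppressed", call. = FALSE)
    pw[["vlf"]] <- NA_real_
  }
  pw
}

#' Ratio of low- to high-frequency power
#'
#' @param lf,hf band powers, ms^2.
#' @return `lf / hf`.
#' @export
lf_hf_ratio <- function(lf, hf) {
  if (is.na(hf) || hf <= 0) stop("lf/hf undefined: hf power is zero or missing")
  lf / hf
}

#' Per-segment HRV metrics
#'
#' Computes the full metric set on one kept segment: time-domain metrics on
#' the valid IBIs and frequency-domain metrics on the interpolated tachogram.
#'
#' @param seg an `ibi_segment` with status `"kept"`.
#' @param rate tachogram sampling rate, Hz.
#' @param bands band definitions.
#' @return one-row data.frame of metrics (`rmssd`, `sdnn`, `hf`, `lf`, `vlf`,
#'   `lf_hf`).
#' @export
segment_metrics <- function(seg, rate = 4, bands = hrv_bands()) {
  tach <- interp_tachogram(seg, rate = rate)
  dur_s <- (seg$end_ms - seg$start_ms) / 1000
  pw <- suppressWarnings(
    band_powers(tach$ibi_ms, rate = rate, bands = bands,
                min_vlf_s = if (dur_s < 300) Inf else 300))
  data.frame(rmssd = rmssd(seg$ibi_ms), sdnn = sdnn(seg$ibi_ms),
             hf = unname(pw["hf"]), lf = unname(pw["lf"]),
             vlf = unname(pw["vlf"]),
             lf_hf = if (!is.na(pw["hf"]) && pw["hf"] > 0)
               unname(pw["lf"] / pw["hf"]) else NA_real_)
}

#' Aggregate segment metrics to a person-day record
#'
#' Unweighted mean of each metric across valid segments; the number of
#' contributing segments is recorded. Person-days without any valid segment
#' yield no record.
#'
#' @param seg_metrics data.frame of per-segment metrics (rows = kept
#'   segments of one person-day).
#' @param person_id,day_index identifiers for the record.
#' @param context `"night"` or `"morning"`.
#' @return one-row data.frame (an HRV record), or `NULL` when `seg_metrics`
#'   has no rows.
#' @export
aggregate_daily <- function(seg_metrics, person_id, day_index,
                            context = c("night", "morning")) {
  context <- match.arg(context)
  if (is.null(seg_metrics) || nrow(seg_metrics) == 0L) return(NULL)
  means <- colMeans(seg_metrics, na.rm = FALSE)
  out <- data.frame(person_id = person_id, day_index = day_index,
                    context = context, t(means),
                    n_valid_segments = nrow(seg_metrics),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Attach natural-log transforms of HRV metrics
#'
#' Adds `log_<metric>` columns alongside the raw values (HRV metrics are
#' right-skewed; log transformation is applied when distributions are
#' non-normal). Records with a non-positive metric keep an `NA` log value.
#'
#' @param records data.frame of HRV records.
#' @param metrics character vector of column names to transform.
#' @return the augmented data.frame.
#' @export
log_transform <- function(records, metrics = "rmssd") {
  for (m in metrics) {
    v <- records[[m]]
    lv <- ifelse(!is.na(v) & v > 0, log(v), NA_real_)
    if (any(!is.na(v) & v <= 0))
      warning("log transform skipped for ", sum(!is.na(v) & v <= 0),
              " non-positive ", m, " value(s)", call. = FALSE)
    records[[paste0("log_", m)]] <- lv
  }
  records
}
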