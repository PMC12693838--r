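#' Process one nocturnal recording end to end
#'
#' Runs the full preprocessing chain on a night recording: nocturnal
#' windowing, 5-minute segmentation, completeness screening (inclusive 70%
#' threshold), movement exclusion from the step table, spurious-IBI
#' filtering, and per-segment metric computation, aggregated to one
#' person-day HRV record. A kept segment in which the artifact filter
#' rejects more than half of the IBIs is invalidated with reason
#' `artifact_burst`. Segment statuses always account for every segment:
#' kept + low_completeness + movement + artifact_burst = total.
#'
#' @param series a [beat_series()] for one person-night.
#' @param steps step table for the same clock (data.frame `minute_start_ms`,
#'   `steps`); `NULL` skips movement screening.
#' @param day_index day index recorded on the output record.
#' @param window_h nocturnal clock window, hours since midnight.
#' @param seg_len_s segment length, seconds.
#' @param completeness_min minimum completeness kept (inclusive).
#' @param range_ms,rel_dev,med_k spurious-filter settings, see
#'   [filter_spurious()].
#' @param rate tachogram sampling rate, Hz.
#' @param bands spectral band definitions.
#' @param burst_max maximum tolerated fraction of filtered IBIs per segment.
#' @return list of class `hrv_night`: `record` (one-row HRV record or `NULL`
#'   when no segment survives), `segments` (summary data.frame),
#'   `rejections` (artifact log), `flags`.
#' @export
#' @examples
#' sim <- simulate_ibi(ibi_config(duration = 18000, seed = 2))
#' night <- process_night(sim$series, sim$steps)
#' night$record
process_night <- function(series, steps = NULL, day_index = 1L,
                          window_h = c(0, 5), seg_len_s = 300,
                          completeness_min = 0.70,
                          range_ms = c(300, 2000), rel_dev = 0.25, med_k = 5,
                          rate = 4, bands = hrv_bands(), burst_max = 0.5) {
  ws <- window_night(series, window_h)
  if (n_beats(ws) == 0L) {
    return(structure(list(record = NULL,
                          segments = segments_summary(list()),
                          rejections = data.frame(), flags = ws$flags),
                     class = "hrv_night"))
  }
  segs <- segment_series(ws, seg_len_s, window_h)
  segs <- screen_completeness(segs, completeness_min)
  if (!is.null(steps)) segs <- exclude_movement(segs, steps)

  rejections <- list()
  metrics <- list()
  for (i in seq_along(segs)) {
    if (segs[[i]]$status != "kept") next
    fl <- filter_spurious(segs[[i]], range_ms, rel_dev, med_k)
    n_valid_before <- sum(!is.na(segs[[i]]$ibi_ms))
    if (nrow(fl$log)) {
      fl$log$segment <- i
      rejections[[length(rejections) + 1L]] <- fl$log
    }
    if (n_valid_before > 0 && nrow(fl$log) / n_valid_before > burst_max) {
      segs[[i]]$status <- "artifact_burst"
      next
    }
    segs[[i]] <- fl$x
    m <- tryCatch(segment_metrics(segs[[i]], rate, bands),
                  error = function(e) NULL)
    if (is.null(m)) { segs[[i]]$status <- "artifact_burst"; next }
    metrics[[length(metrics) + 1L]] <- m
  }
  seg_metrics <- if (length(metrics)) do.call(rbind, metrics) else NULL
  record <- aggregate_daily(seg_metrics, series$person_id, day_index, "night")
  structure(list(record = record,
                 segments = segments_summary(segs),
                 rejections = if (length(rejections))
                   do.call(rbind, rejections) else data.frame(),
                 flags = ws$flags),
            class = "hrv_night")
}

#' Process one morning chest-strap recording
#'
#' Morning recordings (2 or 5 minutes, taken upon waking) bypass nocturnal
#' windowing and segmentation: the whole recording is one segment. VLF power
#' is suppressed for recordings shorter than five minutes.
#'
#' @param series a [beat_series()] with `device_context = "morning_strap"`.
#' @param day_index day index recorded on the output record.
#' @inheritParams process_night
#' @return list of class `hrv_night` (same shape as [process_night()]).
#' @export
process_morning <- function(series, day_index = 1L,
                            range_ms = c(300, 2000), rel_dev = 0.25,
                            med_k = 5, rate = 4, bands = hrv_bands(),
                            burst_max = 0.5) {
  validate_beat_series(series)
  if (n_beats(series) < 2)
    return(structure(list(record = NULL, segments = segments_summary(list()),
                          rejections = data.frame(),
                          flags = "no usable beats"), class = "hrv_night"))
  seg <- list(start_ms = series$t_ms[1],
              end_ms = series$t_ms[length(series$t_ms)] + 1,
              t_ms = series$t_ms, ibi_ms = series$ibi_ms,
              step_count = NA_integer_, status = "kept")
  class(seg) <- "ibi_segment"
  seg$completeness <- segment_completeness(seg)
  fl <- filter_spurious(seg, range_ms, rel_dev, med_k)
  n_valid <- sum(!is.na(seg$ibi_ms))
  if (n_valid > 0 && nrow(fl$log) / n_valid > burst_max) {
    seg$status <- "artifact_burst"
    return(structure(list(record = NULL, segments = segments_summary(list(seg)),
                          rejections = fl$log, flags = character(0)),
                     class = "hrv_night"))
  }
  seg <- fl$x
  m <- segment_metrics(seg, rate, bands)
  record <- aggregate_daily(m, series$person_id, day_index, "morning")
  structure(list(record = record, segments = segments_summary(list(seg)),
                 rejections = fl$log, flags = character(0)),
            class = "hrv_night")
}
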