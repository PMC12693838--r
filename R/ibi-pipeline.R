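#' Restrict a recording to the nocturnal window
#'
#' Keeps beats whose timestamps fall in the half-open clock window
#' (default midnight to 5 am, the nocturnal window used for smartwatch
#' recordings). The IBI of the first retained beat is dropped when its
#' predecessor lay outside the window, so no interval straddles the boundary.
#'
#' @param series a [beat_series()].
#' @param window_h numeric length-2 clock window in hours since local
#'   midnight, half-open `[start, end)`.
#' @return the windowed `beat_series`; when no beat falls in the window the
#'   returned series is empty and carries the flag `"no nocturnal data"`.
#' @export
window_night <- function(series, window_h = c(0, 5)) {
  validate_beat_series(series)
  lo <- window_h[1] * 3600 * 1000
  hi <- window_h[2] * 3600 * 1000
  inside <- which(series$t_ms >= lo & series$t_ms < hi)
  out <- subset_beats(series, inside)
  if (length(inside) == 0L) out$flags <- union(out$flags, "no nocturnal data")
  out
}

#' Divide a recording into fixed-length segments
#'
#' Tiles the window with contiguous half-open segments (default 300 s, the
#' five-minute convention for short-term HRV). A beat exactly on a boundary
#' belongs to the later segment.
#'
#' @param series a [beat_series()] (typically already windowed).
#' @param seg_len_s segment length in seconds.
#' @param window_h clock window in hours defining the tiling range; segments
#'   are anchored at `window_h[1]` so that empty leading segments are
#'   produced when the recording starts late.
#' @return a list of `ibi_segment` objects, each with `start_ms`, `end_ms`,
#'   the contained beats, `completeness`, a `step_count` placeholder and a
#'   `status` initialised according to the completeness threshold.
#' @export
segment_series <- function(series, seg_len_s = 300, window_h = c(0, 5)) {
  validate_beat_series(series)
  stopifnot(seg_len_s > 0)
  len_ms <- seg_len_s * 1000
  lo <- window_h[1] * 3600 * 1000
  hi <- window_h[2] * 3600 * 1000
  starts <- seq(lo, hi - 1, by = len_ms)
  lapply(starts, function(s0) {
    idx <- which(series$t_ms >= s0 & series$t_ms < s0 + len_ms)
    seg <- list(start_ms = s0, end_ms = s0 + len_ms,
                t_ms = series$t_ms[idx], ibi_ms = series$ibi_ms[idx],
                step_count = NA_integer_, status = "kept")
    ## the first contained beat's IBI reaches back before the segment start
    if (length(idx) && idx[1] > 1) seg$ibi_ms[1] <- NA_real_
    class(seg) <- "ibi_segment"
    seg$completeness <- segment_completeness(seg)
    seg
  })
}

#' Proportion of a segment covered by valid IBIs
#'
#' Completeness is defined as IBI coverage time: the sum of valid interbeat
#' intervals terminating inside the segment divided by the segment length,
#' capped at 1. This definition is robust to heart-rate differences (a slow
#' heart contributes fewer, longer intervals).
#'
#' @param seg an `ibi_segment`.
#' @return a proportion in [0, 1].
#' @export
segment_completeness <- function(seg) {
  len <- seg$end_ms - seg$start_ms
  min(sum(seg$ibi_ms, na.rm = TRUE) / len, 1)
}

#' Screen segments by completeness
#'
#' Marks segments with completeness below the threshold (inclusive keep at
#' the threshold itself) as `low_completeness`.
#'
#' @param segments list of `ibi_segment`.
#' @param threshold minimum completeness kept, default 0.70.
#' @return the annotated segment list.
#' @export
screen_completeness <- function(segments, threshold = 0.70) {
  lapply(segments, function(seg) {
    if (seg$status == "kept" && seg$completeness < threshold)
      seg$status <- "low_completeness"
    seg
  })
}

#' Remove segments overlapping movement
#'
#' Any segment overlapping a minute with a positive step count is invalidated
#' with reason `movement` — any steps at all disqualify the segment, since
#' motion corrupts wearable pulse detection. Minutes absent from the step
#' table follow `missing_policy`.
#'
#' @param segments list of `ibi_segment`.
#' @param steps data.frame with columns `minute_start_ms` and `steps`.
#' @param missing_policy `"keep"` (default; a warning is issued once when
#'   coverage is incomplete) or `"drop"`.
#' @return the annotated segment list.
#' @export
exclude_movement <- function(segments, steps, missing_policy = c("keep", "drop")) {
  missing_policy <- match.arg(missing_policy)
  warned <- FALSE
  lapply(segments, function(seg) {
    if (seg$status != "kept") return(seg)
    minute_lo <- floor(seg$start_ms / 60000) * 60000
    minutes <- seq(minute_lo, seg$end_ms - 1, by = 60000)
    m <- match(minutes, steps$minute_start_ms)
    if (anyNA(m)) {
      if (!warned) {
        warning("step table does not cover all segment minutes; policy = ",
                missing_policy, call. = FALSE)
        warned <<- TRUE
      }
      if (missing_policy == "drop") { seg$status <- "movement"; return(seg) }
    }
    sc <- sum(steps$steps[m[!is.na(m)]])
    seg$step_count <- sc
    if (sc > 0) seg$status <- "movement"
    seg
  })
}

#' Filter spurious interbeat intervals
#'
#' Applies two rules to the valid IBIs of a series or segment, in order:
#' an absolute physiological range (default 300–2000 ms), then a relative
#' rule rejecting IBIs deviating from a running 5-beat median by more than
#' `rel_dev` (default 25%). Rejected IBIs are set to `NA` — the beat grid is
#' never altered, so downstream interpolation treats rejections as gaps.
#'
#' @param x a `beat_series` or `ibi_segment`.
#' @param range_ms absolute acceptance range, ms.
#' @param rel_dev maximum relative deviation from the running median.
#' @param med_k running-median width (odd).
#' @return list with `x` (the filtered object) and `log`, a data.frame of
#'   rejections with columns `beat_index`, `ibi_ms`, `rule`.
#' @export
filter_spurious <- function(x, range_ms = c(300, 2000), rel_dev = 0.25,
                            med_k = 5) {
  ibi <- x$ibi_ms
  valid <- which(!is.na(ibi))
  rej_idx <- integer(0); rej_rule <- character(0)
  if (length(valid)) {
    v <- ibi[valid]
    out_range <- v < range_ms[1] | v > range_ms[2]
    if (length(v) >= med_k) {
      med <- stats::runmed(v, med_k, endrule = "median")
    } else med <- rep(stats::median(v), length(v))
    out_rel <- abs(v - med) / med > rel_dev
    rej <- out_range | out_rel
    rej_idx <- valid[rej]
    rej_rule <- ifelse(out_range[rej], "range", "relative_deviation")
  }
  x$ibi_ms[rej_idx] <- NA_real_
  list(x = x,
       log = data.frame(beat_index = rej_idx, ibi_ms = ibi[rej_idx],
                        rule = rej_rule, stringsAsFactors = FALSE))
}

#' Interpolate a segment to an evenly sampled tachogram
#'
#' Fits a natural cubic spline through the valid (timestamp, IBI) pairs and
#' evaluates it on a uniform grid, producing `seg_len * rate` samples across
#' the segment. Spectral metrics require this uniform resampling because the
#' IBI series is inherently irregularly sampled.
#'
#' @param seg an `ibi_segment` (or any list with `start_ms`, `end_ms`,
#'   `t_ms`, `ibi_ms`).
#' @param rate sampling rate, Hz.
#' @return list with `t_ms` (sample times) and `ibi_ms` (interpolated IBIs).
#' @export
interp_tachogram <- function(seg, rate = 4) {
  ok <- !is.na(seg$ibi_ms)
  if (sum(ok) < 2) stop("uninterpolatable segment: fewer than 2 valid beats")
  f <- stats::splinefun(seg$t_ms[ok], seg$ibi_ms[ok], method = "natural")
  n <- round((seg$end_ms - seg$start_ms) / 1000 * rate)
  t_out <- seg$start_ms + (seq_len(n) - 1) / rate * 1000
  list(t_ms = t_out, ibi_ms = f(t_out))
}

#' Summarise a segment list
#'
#' @param segments list of `ibi_segment`.
#' @return data.frame with one row per segment: bounds, beat counts,
#'   completeness, step count, status.
#' @export
segments_summary <- function(segments) {
  data.frame(
    segment = seq_along(segments),
    start_ms = vapply(segments, `[[`, 0, "start_ms"),
    end_ms = vapply(segments, `[[`, 0, "end_ms"),
    n_beats = vapply(segments, function(s) length(s$t_ms), 0L),
    n_valid_ibis = vapply(segments, function(s) sum(!is.na(s$ibi_ms)), 0L),
    completeness = vapply(segments, `[[`, 0, "completeness"),
    step_count = vapply(segments, `[[`, NA_integer_, "step_count"),
    status = vapply(segments, `[[`, "", "status"),
    stringsAsFactors = FALSE)
}
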