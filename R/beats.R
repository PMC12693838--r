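#' Beat series objects
#'
#' A `beat_series` holds one wearable recording: strictly increasing beat
#' timestamps (milliseconds on a local clock whose origin is midnight of the
#' recording night) and the interbeat interval (IBI) terminating at each beat.
#' The first beat, and any beat whose predecessor was lost to a gap or removed
#' by artifact filtering, carries an `NA` IBI: an IBI is only meaningful when
#' both of its bounding beats are present.
#'
#' @param person_id,recording_id identifiers.
#' @param t_ms numeric vector of beat timestamps in milliseconds, strictly
#'   increasing.
#' @param ibi_ms numeric vector, same length as `t_ms`; `ibi_ms[k]` is the
#'   interval `t_ms[k] - t_ms[k-1]` or `NA` when the predecessor beat is
#'   missing. `ibi_ms[1]` is always `NA`.
#' @param device_context one of `"night_watch"`, `"morning_strap"`,
#'   `"night_ring"`; morning chest-strap recordings bypass nocturnal windowing
#'   and are analysed as a single segment.
#' @return an object of class `beat_series`.
#' @export
beat_series <- function(person_id, recording_id, t_ms, ibi_ms,
                        device_context = c("night_watch", "morning_strap", "night_ring")) {
  device_context <- match.arg(device_context)
  x <- structure(
    list(person_id = as.character(person_id),
         recording_id = as.character(recording_id),
         t_ms = as.numeric(t_ms),
         ibi_ms = as.numeric(ibi_ms),
         device_context = device_context,
         flags = character(0)),
    class = "beat_series")
  validate_beat_series(x)
  x
}

#' Validate a beat series
#'
#' Checks the structural invariants: positive IBIs, strictly increasing
#' timestamps, and consistency `|t[k] - t[k-1] - ibi[k]| <= 1` ms for every
#' non-missing IBI.
#'
#' @param x a `beat_series`.
#' @return `x`, invisibly; errors describe the first violated invariant.
#' @export
validate_beat_series <- function(x) {
  stopifnot(inherits(x, "beat_series"))
  n <- length(x$t_ms)
  if (length(x$ibi_ms) != n)
    stop("beat_series: t_ms and ibi_ms must have equal length")
  if (n == 0L) return(invisible(x))
  if (!is.na(x$ibi_ms[1]))
    stop("beat_series: the first beat cannot carry an IBI")
  if (n > 1 && any(diff(x$t_ms) <= 0))
    stop("beat_series: timestamps must be strictly increasing")
  ok <- !is.na(x$ibi_ms)
  if (any(x$ibi_ms[ok] <= 0))
    stop("beat_series: IBIs must be positive")
  if (n > 1) {
    k <- which(ok)
    k <- k[k > 1]
    gap <- abs(x$t_ms[k] - x$t_ms[k - 1] - x$ibi_ms[k])
    if (any(gap > 1))
      stop("beat_series: IBI inconsistent with timestamps at beat ",
           k[which(gap > 1)[1]])
  }
  invisible(x)
}

#' @export
print.beat_series <- function(x, ...) {
  n <- length(x$t_ms)
  dur <- if (n) (x$t_ms[n] - x$t_ms[1]) / 1000 else 0
  cat(sprintf("<beat_series> %s / %s [%s]: %d beats over %.1f s, %d valid IBIs\n",
              x$person_id, x$recording_id, x$device_context, n, dur,
              sum(!is.na(x$ibi_ms))))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Number of beats in a series
#' @param x a `beat_series`.
#' @return integer beat count.
#' @export
n_beats <- function(x) length(x$t_ms)

## internal: subset beats by index, fixing up IBIs whose predecessor is dropped
subset_beats <- function(x, keep) {
  keep <- sort(unique(keep))
  t_ms <- x$t_ms[keep]
  ibi <- x$ibi_ms[keep]
  if (length(keep)) {
    ## an IBI survives only if the immediately preceding beat also survives
    pred_ok <- c(FALSE, keep[-1] - keep[-length(keep)] == 1L)
    ibi[!pred_ok] <- NA_real_
  }
  x$t_ms <- t_ms
  x$ibi_ms <- ibi
  x
}
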