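## Independent brute-force oracles, kept deliberately naive: plain loops over
## the defining formulas, no shared code with the package implementations.

brute_rmssd <- function(ibis) {
  acc <- 0; k <- 0
  for (i in seq_len(length(ibis) - 1)) {
    d <- ibis[i + 1] - ibis[i]
    acc <- acc + d * d
    k <- k + 1
  }
  sqrt(acc / k)
}

brute_sdnn <- function(ibis) {
  m <- 0
  for (v in ibis) m <- m + v / length(ibis)
  acc <- 0
  for (v in ibis) acc <- acc + (v - m)^2
  sqrt(acc / (length(ibis) - 1))
}

## a beat series with constant IBIs covering [t0, t1) ms
constant_series <- function(ibi = 800, t0 = 0, t1 = 18e6, person = "p1") {
  t_ms <- seq(t0, t1 - 1, by = ibi)
  beat_series(person, "r1", t_ms, c(NA, diff(t_ms)))
}

## empty step table covering a window, all zeros
zero_steps <- function(t0 = 0, t1 = 18e6, person = "p1") {
  mins <- seq(floor(t0 / 60000), ceiling(t1 / 60000) - 1)
  data.frame(person_id = person, minute_start_ms = mins * 60000, steps = 0L)
}

## one manually built 5-minute segment from explicit IBIs laid end to end
manual_segment <- function(ibis, start_ms = 0, len_ms = 300000) {
  t_ms <- start_ms + cumsum(c(0, ibis))
  ibi_ms <- c(NA, ibis)
  keep <- t_ms < start_ms + len_ms  # half-open: boundary beat excluded
  seg <- list(start_ms = start_ms, end_ms = start_ms + len_ms,
              t_ms = t_ms[keep], ibi_ms = ibi_ms[keep],
              step_count = 0L, status = "kept")
  class(seg) <- "ibi_segment"
  seg$completeness <- segment_completeness(seg)
  seg
}
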