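#' CSV readers and writers
#'
#' All tabular I/O is plain CSV with a single optional comment header line
#' (`# resthrv seed=<n>`) recording the seed that generated the file.
#' Schemas:
#' \itemize{
#'   \item IBI CSV: `person_id, recording_id, timestamp_ms, ibi_ms`
#'     (empty `ibi_ms` marks a missing-predecessor gap);
#'   \item steps CSV: `person_id, minute_start_ms, steps`;
#'   \item panel CSV (long): `person_id, day_index, variable, value`;
#'     person-level rows (covariates, baselines) carry an empty `day_index`.
#' }
#' Writers and readers round-trip with value equality.
#'
#' @param path file path.
#' @param x object to write.
#' @param seed optional integer recorded in the header comment.
#' @name resthrv-io
NULL

write_header <- function(path, seed) {
  if (!is.null(seed)) cat(sprintf("# resthrv seed=%d\n", seed), file = path)
}

read_csv_plain <- function(path, required) {
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(required, names(d))
  if (length(miss))
    stop("schema error in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  if (nrow(d) == 0L) stop("schema error in ", path, ": no data rows")
  d
}

#' @rdname resthrv-io
#' @export
write_ibi_csv <- function(x, path, seed = NULL) {
  stopifnot(inherits(x, "beat_series"))
  write_header(path, seed)
  d <- data.frame(person_id = x$person_id, recording_id = x$recording_id,
                  timestamp_ms = x$t_ms, ibi_ms = x$ibi_ms)
  suppressWarnings(utils::write.table(d, path, sep = ",", row.names = FALSE,
                                      append = !is.null(seed), quote = FALSE))
  invisible(path)
}

#' @rdname resthrv-io
#' @param device_context context assigned to the series read back.
#' @export
read_ibi_csv <- function(path, device_context = "night_watch") {
  d <- read_csv_plain(path, c("person_id", "recording_id", "timestamp_ms",
                              "ibi_ms"))
  split_d <- split(d, list(d$person_id, d$recording_id), drop = TRUE)
  out <- lapply(split_d, function(g) {
    g <- g[order(g$timestamp_ms), ]
    beat_series(g$person_id[1], g$recording_id[1], g$timestamp_ms,
                g$ibi_ms, device_context)
  })
  if (length(out) == 1L) out[[1]] else out
}

#' @rdname resthrv-io
#' @export
write_steps_csv <- function(x, path, seed = NULL) {
  write_header(path, seed)
  suppressWarnings(utils::write.table(
    x[c("person_id", "minute_start_ms", "steps")], path, sep = ",",
    row.names = FALSE, append = !is.null(seed), quote = FALSE))
  invisible(path)
}

#' @rdname resthrv-io
#' @export
read_steps_csv <- function(path) {
  read_csv_plain(path, c("person_id", "minute_start_ms", "steps"))
}

#' @rdname resthrv-io
#' @param covariates character vector of columns in `x` that are
#'   person-level (written with empty `day_index`).
#' @export
write_panel_csv <- function(x, path, covariates = c("age", "gender"),
                            seed = NULL) {
  id_cols <- c("person_id", "day_index")
  vars <- setdiff(names(x), c(id_cols, covariates))
  long_obs <- do.call(rbind, lapply(vars, function(v) {
    data.frame(person_id = x$person_id, day_index = x$day_index,
               variable = v, value = x[[v]], stringsAsFactors = FALSE)
  }))
  per <- x[!duplicated(x$person_id), c("person_id", covariates), drop = FALSE]
  long_cov <- do.call(rbind, lapply(intersect(covariates, names(x)),
    function(v) {
      data.frame(person_id = per$person_id, day_index = NA_integer_,
                 variable = v, value = per[[v]], stringsAsFactors = FALSE)
    }))
  long <- rbind(long_obs, long_cov)
  long <- long[!is.na(long$value), ]
  write_header(path, seed)
  suppressWarnings(utils::write.table(long, path, sep = ",",
                                      row.names = FALSE,
                                      append = !is.null(seed), quote = FALSE))
  invisible(path)
}

#' @rdname resthrv-io
#' @export
read_panel_csv <- function(path) {
  long <- read_csv_plain(path, c("person_id", "day_index", "variable",
                                 "value"))
  obs <- long[!is.na(long$day_index), ]
  per <- long[is.na(long$day_index), ]
  wide <- stats::reshape(obs, idvar = c("person_id", "day_index"),
                         timevar = "variable", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  for (v in unique(per$variable)) {
    m <- per[per$variable == v, ]
    wide[[v]] <- m$value[match(wide$person_id, m$person_id)]
  }
  rownames(wide) <- NULL
  wide[order(wide$person_id, wide$day_index), ]
}

#' Truth sidecar files
#'
#' The synthetic generators' ground truth (every generating parameter and
#' realized latent quantity) is written as YAML so that downstream recovery
#' checks can read back exactly what was generated.
#'
#' @param truth truth list from [simulate_ibi()] or [simulate_panel()].
#' @param path file path.
#' @return `path` (write) or the truth list (read).
#' @export
write_truth <- function(truth, path) {
  truth <- rapply(truth, unclass, how = "replace")
  yaml::write_yaml(truth, path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) yaml::read_yaml(path)
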