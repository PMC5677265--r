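#' Construct a gait recording
#'
#' A recording is a tibble with one row per sample: a 0-based sample index
#' `k`, three acceleration channels `ax`, `ay`, `az`, and (optionally, when a
#' pressure-insole reference is available) per-foot vertical ground reaction
#' forces `grf_left` and `grf_right` in newtons. The sampling rate is carried
#' as an attribute so piped calls do not need to repeat it.
#'
#' @param data data frame with columns `ax`, `ay`, `az` and optionally `k`,
#'   `grf_left`, `grf_right`.
#' @param sampling_rate sampling frequency in Hz.
#' @return a `grf_recording` tibble.
#' @export
grf_recording <- function(data, sampling_rate = 128) {
  if (!is.data.frame(data)) stop_structure("`data` must be a data frame.")
  need <- c("ax", "ay", "az")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    stop_structure(paste0("recording is missing channel(s): ",
                          paste(miss, collapse = ", ")))
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 || sampling_rate <= 0) {
    stop_param("`sampling_rate` must be a single positive number.")
  }
  out <- as_tibble(data)
  if (!"k" %in% names(out)) out <- dplyr::mutate(out, k = dplyr::row_number() - 1L)
  grf_cols <- intersect(c("grf_left", "grf_right"), names(out))
  for (col in grf_cols) {
    v <- out[[col]]
    if (any(v[!is.na(v)] < 0)) stop_domain(paste0("`", col, "` contains negative forces."))
  }
  lens <- vapply(out[c(need, grf_cols)], length, integer(1))
  stopifnot(length(unique(lens)) == 1)
  out <- dplyr::select(out, dplyr::all_of(c("k", need, grf_cols)))
  attr(out, "sampling_rate") <- as.numeric(sampling_rate)
  class(out) <- c("grf_recording", class(out))
  out
}

#' Sampling rate of a recording
#'
#' @param data a `grf_recording` (or any object carrying a `sampling_rate`
#'   attribute).
#' @param default value returned when no attribute is present.
#' @return sampling rate in Hz.
#' @export
sampling_rate <- function(data, default = 128) {
  attr(data, "sampling_rate") %||% default
}

has_reference <- function(data) {
  all(c("grf_left", "grf_right") %in% names(data))
}

#' Read / write recordings as CSV
#'
#' Plain-text interchange format: header row `k,ax,ay,az,grf_left,grf_right`
#' (force columns optional), one sample per line. Values round-trip at full
#' double precision.
#'
#' @param path file path.
#' @param sampling_rate sampling frequency in Hz attached to the result.
#' @return `read_recording()` returns a `grf_recording`;
#'   `write_recording()` invisibly returns its input.
#' @export
read_recording <- function(path, sampling_rate = 128) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    stop_structure(paste0("malformed recording CSV at line(s) ",
                          paste(unique(probs$row), collapse = ", "),
                          " of ", path))
  }
  known <- c("k", "ax", "ay", "az", "grf_left", "grf_right")
  unknown <- setdiff(names(df), known)
  if (length(unknown) > 0) {
    stop_structure(paste0("unknown channel column(s) in ", path, ": ",
                          paste(unknown, collapse = ", ")))
  }
  grf_recording(df, sampling_rate = sampling_rate)
}

#' @rdname read_recording
#' @param data a `grf_recording`.
#' @export
write_recording <- function(data, path) {
  readr::write_csv(as_tibble(data), path)
  invisible(data)
}

#' Read / write gait events as CSV
#'
#' Columns `foot` (`left`/`right`), `event` (`IC`/`FC`) and the 0-based
#' `sample_index`.
#'
#' @param path file path.
#' @return `read_gait_events()` returns a gait-events tibble with columns
#'   `foot`, `event`, `k`.
#' @export
read_gait_events <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("foot", "event_type", "sample_index") %in% names(df))) {
    stop_structure(paste0("events CSV ", path,
                          " must have columns foot, event_type, sample_index"))
  }
  ev <- tibble(foot = df$foot, event = df$event_type,
               k = as.integer(df$sample_index))
  validate_events(ev)
  ev
}

#' @rdname read_gait_events
#' @param events gait-events tibble (columns `foot`, `event`, `k`).
#' @export
write_gait_events <- function(events, path) {
  readr::write_csv(tibble(foot = events$foot, event_type = events$event,
                          sample_index = events$k), path)
  invisible(events)
}

#' @export
print.grf_recording <- function(x, ...) {
  cat(sprintf("# gait recording: %d samples at %g Hz%s\n", nrow(x),
              sampling_rate(x),
              if (has_reference(x)) " (with reference vGRF)" else ""))
  NextMethod()
}
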