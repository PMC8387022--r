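# Plain-text interchange formats. All numeric columns are written with
# "%.17g" so that a write/read round trip reproduces doubles bit-faithfully.

write_numeric_csv <- function(df, path) {
  out <- as.data.frame(lapply(df, function(col)
    if (is.numeric(col)) sprintf("%.17g", col) else as.character(col)),
    stringsAsFactors = FALSE)
  names(out) <- names(df)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Read and write track CSV files
#'
#' Columns `time_s, x_um, y_um[, hli]`, header required, '.' decimal
#' separator, full float precision.
#'
#' @param trk a [track()].
#' @param path file path.
#' @return `read_track` returns a [track()]; `write_track` returns `path`
#'   invisibly.
#' @export
write_track <- function(trk, path) {
  stopifnot(inherits(trk, "track"))
  df <- data.frame(time_s = trk$time, x_um = trk$x, y_um = trk$y)
  if (!is.null(trk$hli)) df$hli <- trk$hli
  write_numeric_csv(df, path)
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  df <- read.csv(path)
  need <- c("time_s", "x_um", "y_um")
  if (!all(need %in% names(df)))
    stop("track CSV must have columns time_s, x_um, y_um")
  track(df$time_s, df$x_um, df$y_um,
        hli = if ("hli" %in% names(df)) df$hli else NULL)
}

#' Read and write waveform CSV files
#'
#' Columns `time_s, deflection_um`.
#'
#' @param wf data.frame with `time_s`, `deflection_um` (as produced by
#'   [make_waveform()]).
#' @param path file path.
#' @export
write_waveform <- function(wf, path) {
  stopifnot(all(c("time_s", "deflection_um") %in% names(wf)))
  write_numeric_csv(wf[c("time_s", "deflection_um")], path)
  invisible(path)
}

#' @rdname write_waveform
#' @export
read_waveform <- function(path) {
  df <- read.csv(path)
  if (!all(c("time_s", "deflection_um") %in% names(df)))
    stop("waveform CSV must have columns time_s, deflection_um")
  df
}

#' Read and write rolling-event CSV files
#'
#' Single column `event_time_s`.
#'
#' @param process a [rolling_process()].
#' @param path file path.
#' @export
write_events <- function(process, path) {
  stopifnot(inherits(process, "rolling_process"))
  write_numeric_csv(data.frame(event_time_s = process$events), path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- read.csv(path)
  rolling_process(df$event_time_s)
}

#' Write a state history CSV
#'
#' Columns `time_s, state, d_um, s_um2` from [run_state_machine()].
#'
#' @param history a `state_history` data.frame.
#' @param path file path.
#' @export
write_state_history <- function(history, path) {
  write_numeric_csv(data.frame(time_s = history$time, state = history$state,
                               d_um = history$d, s_um2 = history$s), path)
  invisible(path)
}
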