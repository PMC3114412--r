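#' Epoched multichannel time series
#'
#' The universal input container of the package: a `channels x samples x
#' trials` numeric array together with its sampling rate and an
#' event-relative time axis in seconds (the time-locking event is at 0 s).
#' Trials are repeated realizations of the same epoch (e.g. event-locked
#' EEG segments); all estimators in the package pool across them.
#'
#' @param data Numeric matrix (`channels x samples`, treated as one trial)
#'   or 3-d array (`channels x samples x trials`). All values must be
#'   finite.
#' @param srate Sampling rate in Hz (> 0).
#' @param t_start Latency of the first sample in seconds relative to the
#'   time-locking event. Ignored when `times` is given.
#' @param times Optional explicit per-sample latency vector (seconds); must
#'   be uniformly spaced at `1/srate`.
#' @param channel_labels Optional character vector of unique channel names;
#'   defaults to `"ch1", "ch2", ...`.
#' @param condition Optional condition label (single string).
#'
#' @return An object of class `epoched_ts` with fields `data`, `srate`,
#'   `times`, `channel_labels`, `condition`.
#' @examples
#' x <- epoched_ts(matrix(rnorm(200), 2), srate = 100)
#' x
#' @export
epoched_ts <- function(data, srate, t_start = 0, times = NULL,
                       channel_labels = NULL, condition = NULL) {
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a channels x samples x trials array", call. = FALSE)
  storage.mode(data) <- "double"
  if (!all(is.finite(data)))
    stop("`data` contains non-finite values", call. = FALSE)
  if (!is.numeric(srate) || length(srate) != 1L || !is.finite(srate) || srate <= 0)
    stop("`srate` must be a single positive number (Hz)", call. = FALSE)
  d <- dim(data)
  if (d[1] < 1L || d[2] < 1L || d[3] < 1L)
    stop("need at least one channel, one sample and one trial", call. = FALSE)
  if (is.null(times)) {
    times <- t_start + (seq_len(d[2]) - 1) / srate
  } else {
    if (length(times) != d[2])
      stop("`times` must have one entry per sample", call. = FALSE)
    if (d[2] > 1L) {
      dt <- diff(times)
      if (any(dt <= 0) || any(abs(dt - 1 / srate) > 1e-9))
        stop("`times` must increase in constant steps of 1/srate", call. = FALSE)
    }
  }
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(d[1]))
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != d[1] || anyDuplicated(channel_labels))
    stop("`channel_labels` must be unique and one per channel", call. = FALSE)
  if (!is.null(condition)) condition <- as.character(condition)[1]
  structure(
    list(data = data, srate = srate, times = as.numeric(times),
         channel_labels = channel_labels, condition = condition),
    class = "epoched_ts")
}

#' @export
print.epoched_ts <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoched_ts> %d channel(s) x %d sample(s) x %d trial(s) @ %g Hz\n",
    d[1], d[2], d[3], x$srate))
  cat(sprintf("  time: %.4f .. %.4f s%s\n", x$times[1], x$times[length(x$times)],
              if (is.null(x$condition)) "" else paste0("  condition: ", x$condition)))
  invisible(x)
}

n_channels <- function(ts) dim(ts$data)[1]
n_samples  <- function(ts) dim(ts$data)[2]
n_trials   <- function(ts) dim(ts$data)[3]

assert_ets <- function(ts, arg = "ts") {
  if (!inherits(ts, "epoched_ts"))
    stop(sprintf("`%s` must be an epoched_ts object", arg), call. = FALSE)
  invisible(ts)
}

# Replace the data of an epoched_ts, keeping/refreshing metadata.
ets_replace <- function(ts, data, srate = ts$srate, times = ts$times) {
  epoched_ts(data, srate = srate, times = times,
             channel_labels = ts$channel_labels, condition = ts$condition)
}

#' Extract epochs from a continuous recording
#'
#' Slices a continuous (single-trial) `epoched_ts` into event-locked
#' epochs. Used after [read_edf()] to build the trials dimension.
#'
#' @param ts A single-trial `epoched_ts` (a continuous recording).
#' @param event_times Event latencies in seconds on the recording's time
#'   axis.
#' @param tmin,tmax Epoch limits in seconds relative to each event
#'   (`tmin < tmax`). Samples from `round(tmin*srate)` to
#'   `round(tmax*srate) - 1` relative to each event sample are taken, so
#'   each epoch has `round((tmax - tmin) * srate)` samples.
#' @return An `epoched_ts` with one trial per event and times relative to
#'   the event.
#' @export
epoch_recording <- function(ts, event_times, tmin, tmax) {
  assert_ets(ts)
  if (n_trials(ts) != 1L)
    stop("`ts` must be a continuous (single-trial) recording", call. = FALSE)
  if (!is.numeric(event_times) || length(event_times) < 1L)
    stop("need at least one event latency", call. = FALSE)
  if (tmin >= tmax) stop("`tmin` must be smaller than `tmax`", call. = FALSE)
  off0 <- round(tmin * ts$srate)
  nwin <- round((tmax - tmin) * ts$srate)
  if (nwin < 1L) stop("epoch window shorter than one sample", call. = FALSE)
  ev_idx <- round((event_times - ts$times[1]) * ts$srate) + 1L
  first <- ev_idx + off0
  last <- first + nwin - 1L
  bad <- first < 1L | last > n_samples(ts)
  if (any(bad))
    stop(sprintf("event(s) %s fall outside the recording",
                 paste(which(bad), collapse = ", ")), call. = FALSE)
  out <- array(0, c(n_channels(ts), nwin, length(ev_idx)))
  for (k in seq_along(ev_idx))
    out[, , k] <- ts$data[, first[k]:last[k], 1]
  epoched_ts(out, srate = ts$srate, t_start = off0 / ts$srate,
             channel_labels = ts$channel_labels, condition = ts$condition)
}
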