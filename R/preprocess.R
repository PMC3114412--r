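#' Remove per-trial constant or linear trends
#'
#' Subtracts, independently for every channel and trial, the least-squares
#' constant (`mode = "constant"`) or straight line (`mode = "linear"`)
#' fitted over samples. Slow drifts violate the (local) stationarity
#' assumption of autoregressive modeling, so detrending is the usual first
#' preprocessing step before windowed fits.
#'
#' @param ts An [epoched_ts()].
#' @param mode `"constant"` (mean removal) or `"linear"`.
#' @return An `epoched_ts` of identical shape.
#' @export
detrend <- function(ts, mode = c("linear", "constant")) {
  assert_ets(ts)
  mode <- match.arg(mode)
  d <- dim(ts$data)
  # samples x (channels*trials) view: each column is one channel/trial series
  m <- matrix(aperm(ts$data, c(2, 1, 3)), nrow = d[2])
  if (mode == "constant") {
    m <- sweep(m, 2, colMeans(m))
  } else {
    X <- cbind(1, seq_len(d[2]))
    m <- m - X %*% solve(crossprod(X), crossprod(X, m))
  }
  out <- aperm(array(m, c(d[2], d[1], d[3])), c(2, 1, 3))
  ets_replace(ts, out)
}

#' Normalize an epoched time series
#'
#' `"temporal"` z-scores every (channel, trial) series over samples.
#' `"ensemble"` normalizes across trials: at every (channel, sample) point
#' the mean over trials is subtracted and the across-trial standard
#' deviation (unbiased, n-1 denominator) is divided out, equalizing the
#' event-locked ensemble variance over the epoch.
#'
#' @param ts An [epoched_ts()].
#' @param mode `"temporal"` or `"ensemble"`.
#' @return An `epoched_ts` of identical shape.
#' @export
normalize_ensemble <- function(ts, mode = c("temporal", "ensemble")) {
  assert_ets(ts)
  mode <- match.arg(mode)
  d <- dim(ts$data)
  if (mode == "temporal") {
    if (d[2] < 2L)
      stop("temporal normalization needs at least 2 samples", call. = FALSE)
    m <- matrix(aperm(ts$data, c(2, 1, 3)), nrow = d[2])
    mu <- colMeans(m)
    sd_ <- sqrt(colSums(sweep(m, 2, mu)^2) / (d[2] - 1))
    if (any(sd_ == 0)) {
      k <- which(sd_ == 0)[1]
      stop(sprintf(
        "degenerate data: zero temporal standard deviation (channel %d, trial %d)",
        (k - 1L) %% d[1] + 1L, (k - 1L) %/% d[1] + 1L), call. = FALSE)
    }
    m <- sweep(sweep(m, 2, mu), 2, sd_, "/")
    out <- aperm(array(m, c(d[2], d[1], d[3])), c(2, 1, 3))
  } else {
    if (d[3] < 2L)
      stop("ensemble normalization needs at least 2 trials", call. = FALSE)
    mu <- apply(ts$data, c(1, 2), mean)
    sd_ <- sqrt(apply(ts$data, c(1, 2), stats::var))
    if (any(sd_ == 0)) {
      k <- which(sd_ == 0, arr.ind = TRUE)[1, ]
      stop(sprintf(
        "degenerate data: zero across-trial standard deviation (channel %d, sample %d)",
        k[1], k[2]), call. = FALSE)
    }
    out <- sweep(sweep(ts$data, c(1, 2), mu), c(1, 2), sd_, "/")
  }
  ets_replace(ts, out)
}

#' Anti-aliased downsampling
#'
#' Low-pass filters each channel/trial series with a zero-phase
#' (forward-backward) order-8 Chebyshev type-I filter whose cutoff sits at
#' 0.8 times the new Nyquist frequency, then keeps every `factor`-th
#' sample. `factor = 1` returns the input unchanged.
#'
#' @param ts An [epoched_ts()].
#' @param factor Integer decimation factor (>= 1).
#' @return An `epoched_ts` with `srate/factor` sampling rate; the time axis
#'   keeps the retained samples' original latencies.
#' @export
downsample <- function(ts, factor) {
  assert_ets(ts)
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
      factor < 1 || factor != round(factor))
    stop("`factor` must be a single integer >= 1", call. = FALSE)
  factor <- as.integer(factor)
  if (factor == 1L) return(ts)
  d <- dim(ts$data)
  keep <- seq(1L, d[2], by = factor)
  if (length(keep) < 2L)
    stop("decimated series would have fewer than 2 samples", call. = FALSE)
  flt <- signal::cheby1(8, 0.05, 0.8 / factor)  # W relative to Nyquist
  m <- matrix(aperm(ts$data, c(2, 1, 3)), nrow = d[2])
  for (j in seq_len(ncol(m)))
    m[, j] <- signal::filtfilt(flt, m[, j])
  m <- m[keep, , drop = FALSE]
  out <- aperm(array(m, c(length(keep), d[1], d[3])), c(2, 1, 3))
  ets_replace(ts, out, srate = ts$srate / factor, times = ts$times[keep])
}

#' Sliding analysis windows
#'
#' @param win_len Window length in seconds (> 0).
#' @param step Hop between window onsets in seconds (> 0).
#' @return A `window_spec` object.
#' @export
window_spec <- function(win_len, step) {
  if (!is.numeric(win_len) || length(win_len) != 1L || !is.finite(win_len) || win_len <= 0)
    stop("`win_len` must be a single positive number (s)", call. = FALSE)
  if (!is.numeric(step) || length(step) != 1L || !is.finite(step) || step <= 0)
    stop("`step` must be a single positive number (s)", call. = FALSE)
  structure(list(win_len = win_len, step = step), class = "window_spec")
}

#' Segment an epoch into sliding windows
#'
#' Windows are onset-anchored: the first starts at the first sample and
#' subsequent onsets advance by `round(step * srate)` samples while the
#' full window still fits; a trailing partial window is dropped, never
#' zero-padded. Each window keeps all trials. The window is identified by
#' the latency of its center.
#'
#' @param ts An [epoched_ts()].
#' @param spec A [window_spec()].
#' @return A list with one element per window: `list(center = <s>,
#'   data = <epoched_ts>)`.
#' @export
segment_windows <- function(ts, spec) {
  assert_ets(ts)
  if (!inherits(spec, "window_spec"))
    stop("`spec` must be a window_spec object", call. = FALSE)
  N <- n_samples(ts)
  wlen <- round(spec$win_len * ts$srate)
  stp <- max(1L, round(spec$step * ts$srate))
  if (wlen < 2L)
    stop("window must contain at least 2 samples", call. = FALSE)
  if (wlen > N)
    stop("`win_len` is longer than the epoch", call. = FALSE)
  onsets <- seq(1L, N - wlen + 1L, by = stp)
  lapply(onsets, function(o) {
    idx <- o:(o + wlen - 1L)
    list(center = ts$times[o] + (wlen - 1) / (2 * ts$srate),
         data = ets_replace(ts, ts$data[, idx, , drop = FALSE],
                            times = ts$times[idx]))
  })
}
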