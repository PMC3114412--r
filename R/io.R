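#' Read a continuous EDF/EDF+ recording
#'
#' Minimal reader for European Data Format files (16-bit, continuous
#' recordings). All retained signals must share one sampling rate;
#' annotation channels (`"EDF Annotations"`) are skipped. Digital values
#' are mapped to physical units with each signal's calibration fields.
#' Combine with [epoch_recording()] to build event-locked trials.
#'
#' @param path Path to an `.edf` file.
#' @return A single-trial [epoched_ts()] with `t_start = 0`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  rd_str <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  rd_num <- function(n) as.numeric(rd_str(n))
  ver <- rd_str(8)
  if (!identical(ver, "0"))
    stop(sprintf("not an EDF file (version field '%s'): %s", ver, path), call. = FALSE)
  invisible(rd_str(80)); invisible(rd_str(80))   # patient, recording id
  invisible(rd_str(8)); invisible(rd_str(8))     # start date, time
  invisible(rd_num(8))                           # header length
  invisible(rd_str(44))                          # reserved ("EDF+C" for continuous)
  n_rec <- rd_num(8)
  rec_dur <- rd_num(8)
  ns <- as.integer(rd_num(4))
  if (is.na(ns) || ns < 1L) stop("EDF header reports no signals", call. = FALSE)
  labels <- vapply(seq_len(ns), function(i) rd_str(16), "")
  invisible(vapply(seq_len(ns), function(i) rd_str(80), ""))  # transducer
  invisible(vapply(seq_len(ns), function(i) rd_str(8), ""))   # physical dimension
  pmin <- vapply(seq_len(ns), function(i) rd_num(8), 0)
  pmax <- vapply(seq_len(ns), function(i) rd_num(8), 0)
  dmin <- vapply(seq_len(ns), function(i) rd_num(8), 0)
  dmax <- vapply(seq_len(ns), function(i) rd_num(8), 0)
  invisible(vapply(seq_len(ns), function(i) rd_str(80), ""))  # prefiltering
  nr <- vapply(seq_len(ns), function(i) rd_num(8), 0)
  invisible(vapply(seq_len(ns), function(i) rd_str(32), ""))  # reserved
  keep <- labels != "EDF Annotations"
  if (!any(keep)) stop("EDF file contains only annotation channels", call. = FALSE)
  if (length(unique(nr[keep])) != 1L)
    stop("EDF signals have heterogeneous sampling rates; not supported", call. = FALSE)
  if (is.na(n_rec) || n_rec < 1 || is.na(rec_dur) || rec_dur <= 0)
    stop("EDF header has invalid record count/duration", call. = FALSE)
  nsamp <- as.integer(nr[keep][1])
  srate <- nsamp / rec_dur
  scale <- (pmax - pmin) / (dmax - dmin)
  out <- array(0, c(sum(keep), nsamp * n_rec))
  row_of <- cumsum(keep)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      v <- readBin(con, "integer", n = as.integer(nr[s]), size = 2,
                   signed = TRUE, endian = "little")
      if (keep[s])
        out[row_of[s], ((r - 1) * nsamp + 1):(r * nsamp)] <-
          (v - dmin[s]) * scale[s] + pmin[s]
    }
  }
  epoched_ts(out, srate = srate, t_start = 0, channel_labels = labels[keep])
}

#' Read/write epoched data as delimited text
#'
#' One file per trial; channels as columns with a header row of channel
#' labels, samples as rows.
#'
#' @param files Character vector of per-trial file paths (same channel
#'   layout in each).
#' @param srate Sampling rate in Hz.
#' @param t_start Latency of the first sample (s, event-relative).
#' @param sep Field separator (default tab).
#' @param condition Optional condition label.
#' @return [epoched_ts()] with `length(files)` trials.
#' @export
read_ets_txt <- function(files, srate, t_start = 0, sep = "\t", condition = NULL) {
  if (length(files) < 1L) stop("need at least one trial file", call. = FALSE)
  trs <- lapply(files, function(f) {
    as.matrix(utils::read.table(f, header = TRUE, sep = sep, check.names = FALSE))
  })
  dims <- vapply(trs, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("trial files disagree in shape", call. = FALSE)
  labs <- colnames(trs[[1]])
  dat <- array(0, c(dims[2, 1], dims[1, 1], length(trs)))
  for (k in seq_along(trs)) dat[, , k] <- t(trs[[k]])
  epoched_ts(dat, srate = srate, t_start = t_start,
             channel_labels = labs, condition = condition)
}

#' @rdname read_ets_txt
#' @param ts An [epoched_ts()] to write.
#' @param dir Output directory (created if missing); files are named
#'   `<prefix>_trial<k>.tsv`.
#' @param prefix File name prefix.
#' @return `write_ets_txt` returns the written paths invisibly.
#' @export
write_ets_txt <- function(ts, dir, prefix = "ets", sep = "\t") {
  assert_ets(ts)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(n_trials(ts))
  for (k in seq_len(n_trials(ts))) {
    paths[k] <- file.path(dir, sprintf("%s_trial%03d.tsv", prefix, k))
    m <- t(ts$data[, , k])
    colnames(m) <- ts$channel_labels
    utils::write.table(m, paths[k], sep = sep, row.names = FALSE, quote = FALSE)
  }
  invisible(paths)
}

# --- package container ------------------------------------------------------
# The on-disk container is R native serialization (RDS, version 3) of a
# tagged list: list(format = "varconn-container-v1", class = <class>,
# payload = <object>). Arrays, fitted models, connectivity results and
# statistics all travel through it between CLI stages.

CONTAINER_TAG <- "varconn-container-v1"

#' Read/write the package container
#'
#' Serializes any of the package's result objects (`epoched_ts`,
#' `var_model` or lists of them, `connectivity_result`, `stat_result`,
#' simulation output) to a tagged RDS container used for the CLI
#' `fit -> connect -> stats` handoff.
#'
#' @param x Object to store.
#' @param path File path (conventionally `.vc.rds`).
#' @return `vc_read` returns the stored object; `vc_write` returns `path`
#'   invisibly.
#' @export
vc_write <- function(x, path) {
  saveRDS(list(format = CONTAINER_TAG, class = class(x)[1], payload = x),
          path, version = 3)
  invisible(path)
}

#' @rdname vc_write
#' @export
vc_read <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, CONTAINER_TAG))
    stop(sprintf("%s is not a varconn container", path), call. = FALSE)
  obj$payload
}
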