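#' Spectral decomposition of a VAR model
#'
#' Fourier-transforms the coefficient matrices:
#' `Abar(f) = I - sum_k A_k exp(-i 2 pi f k / srate)`, the transfer matrix
#' `H(f) = Abar(f)^-1`, the spectral matrix `S(f) = H Sigma H^H` and, when
#' well conditioned, the inverse spectral matrix `P(f) = S(f)^-1`. Every
#' frequency-domain connectivity measure in the package is a function of
#' these four objects.
#'
#' @param model A `var_model` from [fit_var()].
#' @param freqs Frequency grid in Hz, strictly inside `(0, srate/2]`.
#'   Default: 1 Hz spacing from 1 to `srate/2 - 1` (DC excluded because
#'   `Abar(0)` is near-singular for near-unit-root models).
#' @return A `spectral_set`: complex arrays `A_f`, `H_f`, `S_f`, `P_f`
#'   (`M x M x n_freq`), plus `freqs`, `srate`, `noise_cov`, `order`.
#'   `P_f` is `NA`-filled (with `P_ok = FALSE`) when `S(f)` has condition
#'   number above 1e12 at some frequency.
#' @export
spectral_set <- function(model, freqs = default_freqs(model$srate)) {
  stopifnot(inherits(model, "var_model"))
  if (length(freqs) < 1L || is.unsorted(freqs, strictly = TRUE) ||
      any(freqs <= 0) || any(freqs > model$srate / 2 + 1e-9))
    stop("`freqs` must be ascending and within (0, srate/2]", call. = FALSE)
  if (companion_radius(model$coeffs) >= 1)
    warning("model is unstable (companion spectral radius >= 1); ",
            "spectral quantities are not interpretable as a stationary spectrum")
  M <- nrow(model$noise_cov)
  p <- model$order
  nf <- length(freqs)
  A_f <- array(0i, c(M, M, nf))
  H_f <- array(0i, c(M, M, nf))
  S_f <- array(0i, c(M, M, nf))
  P_f <- array(NA_complex_, c(M, M, nf))
  I <- diag(M)
  P_ok <- TRUE
  for (fi in seq_len(nf)) {
    z <- exp(-2i * pi * freqs[fi] * seq_len(p) / model$srate)
    Ab <- I + 0i
    for (k in seq_len(p)) Ab <- Ab - model$coeffs[, , k] * z[k]
    H <- tryCatch(solve(Ab), error = function(e)
      stop(sprintf("singular spectral coefficient matrix at f = %g Hz", freqs[fi]),
           call. = FALSE))
    S <- H %*% model$noise_cov %*% Conj(t(H))
    S <- (S + Conj(t(S))) / 2
    A_f[, , fi] <- Ab; H_f[, , fi] <- H; S_f[, , fi] <- S
    if (P_ok) {
      if (kappa(S, exact = TRUE) > 1e12) P_ok <- FALSE
      else {
        P <- solve(S)
        P_f[, , fi] <- (P + Conj(t(P))) / 2
      }
    }
  }
  structure(list(freqs = freqs, A_f = A_f, H_f = H_f, S_f = S_f, P_f = P_f,
                 P_ok = P_ok, srate = model$srate, noise_cov = model$noise_cov,
                 order = p, n_obs = model$n_obs,
                 channel_labels = model$channel_labels),
            class = "spectral_set")
}

default_freqs <- function(srate) {
  hi <- floor(srate / 2 - 1)
  if (hi < 1) stop("sampling rate too low for the default frequency grid", call. = FALSE)
  seq(1, hi, by = 1)
}

assert_ss <- function(ss) {
  if (!inherits(ss, "spectral_set"))
    stop("`ss` must be a spectral_set object", call. = FALSE)
  invisible(ss)
}

need_P <- function(ss) {
  if (!ss$P_ok)
    stop("conditioning error: spectral matrix is near-singular ",
         "(condition number > 1e12); inverse-spectral measures unavailable",
         call. = FALSE)
  invisible(ss)
}

# --- ConnectivityResult -----------------------------------------------------

#' @keywords internal
new_connectivity_result <- function(measure, values, freqs,
                                    window_centers = NA_real_,
                                    model_orders = NA_integer_,
                                    channel_labels = NULL) {
  if (length(dim(values)) == 3L) dim(values) <- c(dim(values), 1L)
  if (!is.null(channel_labels))
    dimnames(values) <- list(sink = channel_labels, source = channel_labels,
                             NULL, NULL)
  structure(list(measure = measure, values = values, freqs = freqs,
                 window_centers = window_centers, model_orders = model_orders,
                 channel_labels = channel_labels),
            class = "connectivity_result")
}

#' @export
print.connectivity_result <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<connectivity_result> %s: %d x %d channels, %d frequency(ies), %d window(s)\n",
              x$measure, d[1], d[2], d[3], d[4]))
  invisible(x)
}

# Evaluate one registry measure on a spectral_set -> M x M x nf real array.
eval_measure <- function(ss, name) {
  H2 <- Mod(ss$H_f)^2
  switch(name,
    power = {
      v <- Mod(ss$S_f)
      for (fi in seq_len(dim(v)[3])) diag(v[, , fi]) <- Re(diag(ss$S_f[, , fi]))
      v
    },
    cross_spectrum = Mod(ss$S_f),
    coherence = coh_core(ss, squared = TRUE),
    coherence_mag = coh_core(ss, squared = FALSE),
    imag_coherence = {
      d <- Re(diag3(ss$S_f))
      abs(Im(ss$S_f / sqrt(outer3(d, d))))
    },
    partial_coherence = pcoh_core(ss, squared = TRUE),
    partial_coherence_mag = pcoh_core(ss, squared = FALSE),
    multiple_coherence = mcoh_core(ss),
    dtf = sweep3(H2, rowSums3(H2)),
    dtf_mag = sqrt(sweep3(H2, rowSums3(H2))),
    dtf_unnorm = H2,
    ffdtf = {
      den <- apply(H2, 1, sum)  # per sink over sources and frequencies
      out <- H2
      for (i in seq_len(dim(H2)[1])) out[i, , ] <- H2[i, , ] / den[i]
      out
    },
    ddtf = eval_measure(ss, "ffdtf") * pcoh_core(ss, squared = TRUE),
    pdc = {
      A2 <- Mod(ss$A_f)^2
      sweep3(A2, colSums3(A2), margin = 2)
    },
    pdc_mag = sqrt(eval_measure(ss, "pdc")),
    pdc_factor = Mod(ss$A_f)^2,
    gpdc = {
      s2 <- diag(ss$noise_cov)
      if (any(s2 <= 0))
        stop("degenerate model: zero innovation variance", call. = FALSE)
      A2 <- Mod(ss$A_f)^2 / s2  # rows weighted by 1/sigma_ii^2
      sweep3(A2, colSums3(A2), margin = 2)
    },
    stop(sprintf("unknown connectivity measure '%s'", name), call. = FALSE)
  )
}

# small helpers on M x M x nf arrays
diag3 <- function(a) {
  M <- dim(a)[1]; nf <- dim(a)[3]
  out <- matrix(0i, M, nf)
  for (fi in seq_len(nf)) out[, fi] <- diag(a[, , fi])
  out
}
outer3 <- function(d1, d2) {
  M <- nrow(d1); nf <- ncol(d1)
  out <- array(0, c(M, M, nf))
  for (fi in seq_len(nf)) out[, , fi] <- outer(Re(d1[, fi]), Re(d2[, fi]))
  out
}
rowSums3 <- function(a) apply(a, c(1, 3), sum)
colSums3 <- function(a) apply(a, c(2, 3), sum)
sweep3 <- function(a, s, margin = 1) {
  out <- a
  nf <- dim(a)[3]
  for (fi in seq_len(nf)) {
    if (margin == 1) out[, , fi] <- a[, , fi] / s[, fi]
    else out[, , fi] <- sweep(a[, , fi], 2, s[, fi], "/")
  }
  out
}

coh_core <- function(ss, squared = TRUE) {
  d <- Re(diag3(ss$S_f))
  if (any(d <= 0)) stop("degenerate model: zero auto-spectrum", call. = FALSE)
  c2 <- Mod(ss$S_f)^2 / outer3(d, d)
  c2 <- pmin(c2, 1)
  if (squared) c2 else sqrt(c2)
}

pcoh_core <- function(ss, squared = TRUE) {
  need_P(ss)
  d <- Re(diag3(ss$P_f))
  c2 <- Mod(ss$P_f)^2 / outer3(d, d)
  c2 <- pmin(c2, 1)
  if (squared) c2 else sqrt(c2)
}

mcoh_core <- function(ss) {
  need_P(ss)
  ds <- Re(diag3(ss$S_f))
  dp <- Re(diag3(ss$P_f))
  M <- dim(ss$S_f)[1]; nf <- dim(ss$S_f)[3]
  out <- array(0, c(M, M, nf))
  g <- pmin(pmax(1 - 1 / (ds * dp), 0), 1)
  for (fi in seq_len(nf)) diag(out[, , fi]) <- g[, fi]
  out
}

cr_from_ss <- function(ss, name, center = NA_real_) {
  new_connectivity_result(name, eval_measure(ss, name), ss$freqs,
                          window_centers = center, model_orders = ss$order,
                          channel_labels = ss$channel_labels)
}

#' Individual connectivity measures of a spectral set
#'
#' Thin wrappers evaluating one measure on a [spectral_set()]:
#' * `power_spectrum`: diagonal = real auto-spectra `Re S_ii(f)`,
#'   off-diagonal slots carry the cross-spectrum magnitude `|S_ij|`.
#' * `coherence`: magnitude-squared coherence `|S_ij|^2 / (S_ii S_jj)`.
#' * `partial_coherence`: `|P_ij|^2 / (P_ii P_jj)` from the inverse
#'   spectral matrix -- coherence left after removing the linear influence
#'   of all other channels.
#' * `multiple_coherence`: diagonal `1 - 1/(S_ii P_ii)`, the coherence of
#'   channel i with all other channels jointly.
#' * `dtf`: directed transfer function `|H_ij|^2 / sum_m |H_im|^2`
#'   (sink-normalized: each row sums to 1 over sources).
#' * `ffdtf`: full-frequency DTF, `|H_ij(f)|^2` normalized by the sink's
#'   inflow summed over sources *and* frequencies.
#' * `ddtf`: direct DTF = ffDTF x partial coherence, suppressing indirect
#'   cascade pathways.
#' * `pdc`: partial directed coherence
#'   `|Abar_ij|^2 / sum_m |Abar_mj|^2` (source-normalized: each column
#'   sums to 1 over sinks).
#' * `gpdc`: generalized PDC with `1/sigma_ii^2` weighting, invariant to
#'   per-channel rescaling of the data.
#'
#' @param ss A [spectral_set()].
#' @return A `connectivity_result` (values indexed sink x source x
#'   frequency x window).
#' @name measures
NULL

#' @rdname measures
#' @export
power_spectrum <- function(ss) { assert_ss(ss); cr_from_ss(ss, "power") }

#' @rdname measures
#' @export
coherence <- function(ss) { assert_ss(ss); cr_from_ss(ss, "coherence") }

#' @rdname measures
#' @export
partial_coherence <- function(ss) { assert_ss(ss); cr_from_ss(ss, "partial_coherence") }

#' @rdname measures
#' @export
multiple_coherence <- function(ss) { assert_ss(ss); cr_from_ss(ss, "multiple_coherence") }

#' @rdname measures
#' @export
dtf <- function(ss) { assert_ss(ss); cr_from_ss(ss, "dtf") }

#' @rdname measures
#' @export
ffdtf <- function(ss) { assert_ss(ss); cr_from_ss(ss, "ffdtf") }

#' @rdname measures
#' @export
ddtf <- function(ss) { assert_ss(ss); cr_from_ss(ss, "ddtf") }

#' @rdname measures
#' @export
pdc <- function(ss) { assert_ss(ss); cr_from_ss(ss, "pdc") }

#' @rdname measures
#' @export
gpdc <- function(ss) { assert_ss(ss); cr_from_ss(ss, "gpdc") }

#' Registry of frequency-domain connectivity measures
#'
#' Names accepted by [connectivity()] and the CLI, all derivable from a
#' fitted MVAR model through its [spectral_set()]. Squared-magnitude forms
#' are the defaults (they carry the DTF/PDC normalization identities);
#' `_mag` are magnitude forms, `_unnorm`/`_factor` the unnormalized
#' numerators.
#'
#' @return Character vector of measure names.
#' @export
measure_registry <- function() {
  c("power", "cross_spectrum",
    "coherence", "coherence_mag", "imag_coherence",
    "partial_coherence", "partial_coherence_mag", "multiple_coherence",
    "dtf", "dtf_mag", "dtf_unnorm", "ffdtf", "ddtf",
    "pdc", "pdc_mag", "pdc_factor", "gpdc")
}

#' Sliding-window connectivity estimation
#'
#' The package's main driver: segments the epoch (optionally), fits one
#' MVAR model per window pooling trials, and evaluates the requested
#' registry measures on each window's spectral decomposition.
#'
#' @param ts An [epoched_ts()].
#' @param order Model order, or `NULL` to select with [select_order()]
#'   over `p_range`.
#' @param measures Character vector of [measure_registry()] names.
#' @param freqs Frequency grid (Hz); default [default_freqs()].
#' @param window A [window_spec()], or `NULL` to model the whole epoch as
#'   one window.
#' @param method Passed to [fit_var()].
#' @param p_range,criterion Used when `order = NULL`.
#' @return Named list of `connectivity_result` objects (one per measure),
#'   with the per-window fitted models in attribute `"models"`.
#' @examples
#' sim <- simulate_var(preset_scenarios()$chain3)
#' cr <- connectivity(sim$ts, order = 2, measures = "dtf", freqs = c(5, 10, 20))
#' cr$dtf
#' @export
connectivity <- function(ts, order = NULL, measures = "dtf",
                         freqs = default_freqs(ts$srate), window = NULL,
                         method = "ols", p_range = c(1, 10),
                         criterion = "bic") {
  assert_ets(ts)
  bad <- setdiff(measures, measure_registry())
  if (length(bad))
    stop(sprintf("unknown measure(s): %s", paste(bad, collapse = ", ")), call. = FALSE)
  wins <- if (is.null(window)) {
    list(list(center = mean(range(ts$times)), data = ts))
  } else segment_windows(ts, window)
  models <- lapply(wins, function(w) {
    p <- if (is.null(order)) select_order(w$data, p_range, criterion)$order else order
    m <- fit_var(w$data, p, method = method)
    m$window_center <- w$center
    m
  })
  centers <- vapply(wins, `[[`, 0, "center")
  orders <- vapply(models, `[[`, 0L, "order")
  sss <- lapply(models, spectral_set, freqs = freqs)
  out <- lapply(measures, function(nm) {
    vals <- array(0, c(n_channels(ts), n_channels(ts), length(freqs), length(wins)))
    for (wi in seq_along(sss)) vals[, , , wi] <- eval_measure(sss[[wi]], nm)
    new_connectivity_result(nm, vals, freqs, centers, orders,
                            channel_labels = ts$channel_labels)
  })
  names(out) <- measures
  attr(out, "models") <- models
  out
}

#' Node-level causal-flow summaries
#'
#' Averages a directed measure over a frequency band, then per window sums
#' directed flow out of and into each node: `outflow_j = sum_(i != j)
#' mean_band values[i, j]`, `inflow_j = sum_(i != j) mean_band
#' values[j, i]`, `asymmetry_ratio = (outflow - inflow) / (outflow +
#' inflow)` (+1 = pure causal source, -1 = pure causal sink, 0 when both
#' flows vanish), and the network's causal density (mean off-diagonal
#' band-averaged value).
#'
#' @param cr A `connectivity_result` of a directed measure.
#' @param band `c(f_lo, f_hi)` in Hz; must contain at least one grid
#'   frequency.
#' @return `list(nodes = data.frame(window_center, node, outflow, inflow,
#'   asymmetry_ratio), density = data.frame(window_center, causal_density))`.
#' @export
graph_measures <- function(cr, band) {
  stopifnot(inherits(cr, "connectivity_result"))
  if (length(band) != 2L || band[1] > band[2])
    stop("`band` must be c(f_lo, f_hi)", call. = FALSE)
  sel <- which(cr$freqs >= band[1] & cr$freqs <= band[2])
  if (!length(sel))
    stop("`band` contains no grid frequency", call. = FALSE)
  d <- dim(cr$values)
  M <- d[1]; nw <- d[4]
  labs <- cr$channel_labels %||% paste0("ch", seq_len(M))
  nodes <- NULL
  dens <- numeric(nw)
  for (wi in seq_len(nw)) {
    B <- apply(cr$values[, , sel, wi, drop = FALSE], c(1, 2), mean)
    diag(B) <- 0
    outflow <- colSums(B)  # column j: flow out of source j
    inflow <- rowSums(B)   # row j: flow into sink j
    tot <- outflow + inflow
    asym <- ifelse(tot > 0, (outflow - inflow) / tot, 0)
    nodes <- rbind(nodes, data.frame(
      window_center = cr$window_centers[wi], node = labs,
      outflow = outflow, inflow = inflow, asymmetry_ratio = asym,
      row.names = NULL))
    dens[wi] <- sum(B) / (M * (M - 1))
  }
  list(nodes = nodes,
       density = data.frame(window_center = cr$window_centers,
                            causal_density = dens))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
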