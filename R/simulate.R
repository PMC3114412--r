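#' Specify a ground-truth VAR simulation
#'
#' Defines a (possibly time-varying) order-`p` VAR process with a known
#' causal graph: a stable time-invariant base plus a list of directed
#' couplings, each optionally gated by an envelope over the epoch. This is
#' the package's test bed: every estimator can be checked against the
#' known generative graph.
#'
#' @param n_channels Number of channels `M`.
#' @param order Lag order `p` of the base coefficients.
#' @param base_coeffs `M x M x p` array (sink x source x lag), the
#'   time-invariant part. Must be stable (companion spectral radius < 1).
#' @param noise_cov Innovation covariance (symmetric PSD); default
#'   identity.
#' @param srate Sampling rate in Hz.
#' @param n_samples,n_trials Epoch length (samples) and trial count.
#' @param t_start Latency of the first sample (s, event-relative).
#' @param couplings List of couplings, each
#'   `coupling(sink, source, lag, amplitude, envelope, onset, offset)`.
#' @param burn_in Samples discarded before each trial's epoch (default
#'   1000, enough for transient decay at pole radii up to 0.98).
#' @param seed Default RNG seed used by [simulate_var()].
#' @return A `sim_spec` object.
#' @export
simulation_spec <- function(n_channels, order, base_coeffs,
                            noise_cov = diag(n_channels), srate,
                            n_samples, n_trials, t_start = 0,
                            couplings = list(), burn_in = 1000L, seed = 1L) {
  stopifnot(length(dim(base_coeffs)) == 3L,
            dim(base_coeffs)[1] == n_channels,
            dim(base_coeffs)[2] == n_channels,
            dim(base_coeffs)[3] == order)
  noise_cov <- (noise_cov + t(noise_cov)) / 2
  if (any(eigen(noise_cov, symmetric = TRUE, only.values = TRUE)$values < -1e-10))
    stop("`noise_cov` must be positive semidefinite", call. = FALSE)
  times <- t_start + (seq_len(n_samples) - 1) / srate
  for (cp in couplings) {
    stopifnot(inherits(cp, "vc_coupling"))
    if (cp$sink > n_channels || cp$source > n_channels)
      stop("coupling channel index out of range", call. = FALSE)
    if (cp$envelope != "none" &&
        (cp$onset < times[1] - 1e-9 || cp$offset > times[n_samples] + 1e-9))
      stop("coupling envelope extends outside the epoch", call. = FALSE)
  }
  max_lag <- max(c(order, vapply(couplings, `[[`, 0, "lag")))
  spec <- structure(
    list(n_channels = n_channels, order = as.integer(order),
         base_coeffs = base_coeffs, noise_cov = noise_cov, srate = srate,
         n_samples = as.integer(n_samples), n_trials = as.integer(n_trials),
         t_start = t_start, couplings = couplings,
         burn_in = as.integer(burn_in), seed = as.integer(seed),
         max_lag = as.integer(max_lag), times = times),
    class = "sim_spec")
  if (companion_radius(stationary_coeffs(spec)) >= 1)
    stop("time-invariant part of the model is unstable", call. = FALSE)
  spec
}

#' @rdname simulation_spec
#' @param sink,source Channel indices (`source -> sink`).
#' @param lag Lag (samples) at which the coupling acts.
#' @param amplitude Coefficient added to `A_lag[sink, source]`.
#' @param envelope `"none"` (always active), `"boxcar"` or `"hann"`; the
#'   latter two are supported on `[onset, offset]` seconds
#'   (event-relative).
#' @export
coupling <- function(sink, source, lag = 1L, amplitude,
                     envelope = c("none", "boxcar", "hann"),
                     onset = NA_real_, offset = NA_real_) {
  envelope <- match.arg(envelope)
  if (envelope != "none" && (!is.finite(onset) || !is.finite(offset) || onset >= offset))
    stop("windowed envelopes need onset < offset", call. = FALSE)
  structure(list(sink = as.integer(sink), source = as.integer(source),
                 lag = as.integer(lag), amplitude = amplitude,
                 envelope = envelope, onset = onset, offset = offset),
            class = "vc_coupling")
}

# base + always-on couplings, padded to max_lag: the process outside any
# envelope (also used during burn-in).
stationary_coeffs <- function(spec) {
  A <- array(0, c(spec$n_channels, spec$n_channels, spec$max_lag))
  if (spec$order > 0) A[, , seq_len(spec$order)] <- spec$base_coeffs
  for (cp in spec$couplings)
    if (cp$envelope == "none")
      A[cp$sink, cp$source, cp$lag] <- A[cp$sink, cp$source, cp$lag] + cp$amplitude
  A
}

# n_couplings x n_samples envelope gains within the epoch.
envelope_gains <- function(spec) {
  ncp <- length(spec$couplings)
  E <- matrix(0, ncp, spec$n_samples)
  for (ci in seq_len(ncp)) {
    cp <- spec$couplings[[ci]]
    if (cp$envelope == "none") { E[ci, ] <- 1; next }
    inside <- spec$times >= cp$onset - 1e-9 & spec$times <= cp$offset + 1e-9
    if (cp$envelope == "boxcar") E[ci, inside] <- 1
    else {
      u <- (spec$times[inside] - cp$onset) / (cp$offset - cp$onset)
      E[ci, inside] <- 0.5 - 0.5 * cos(2 * pi * u)
    }
  }
  E
}

#' Instantaneous stability of a simulation spec
#'
#' Companion-matrix spectral radius of the instantaneous coefficient
#' matrices at every epoch sample (envelopes make them time-varying).
#'
#' @param spec A [simulation_spec()].
#' @return `list(radius = per-sample numeric, max = max radius)`.
#' @export
check_stability <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  A0 <- stationary_coeffs(spec)
  E <- envelope_gains(spec)
  varying <- which(vapply(spec$couplings, function(cp) cp$envelope != "none", TRUE))
  radius <- rep(NA_real_, spec$n_samples)
  if (!length(varying)) {
    radius[] <- companion_radius(A0)
    return(list(radius = radius, max = radius[1]))
  }
  key_prev <- NULL
  r_prev <- NA_real_
  for (t in seq_len(spec$n_samples)) {
    key <- E[varying, t]
    if (!is.null(key_prev) && isTRUE(all.equal(key, key_prev, tolerance = 0))) {
      radius[t] <- r_prev
      next
    }
    A <- A0
    for (ci in varying) {
      cp <- spec$couplings[[ci]]
      A[cp$sink, cp$source, cp$lag] <-
        A[cp$sink, cp$source, cp$lag] + cp$amplitude * E[ci, t]
    }
    radius[t] <- companion_radius(A)
    key_prev <- key; r_prev <- radius[t]
  }
  list(radius = radius, max = max(radius))
}

# Stationary VAR recursion vectorized over trials (used by validate_model's
# consistency diagnostic). Returns M x n x n_trials.
simulate_var_core <- function(coeffs, noise_cov, n, n_trials, burn_in = 500L) {
  M <- dim(coeffs)[1]; p <- dim(coeffs)[3]
  L <- t(chol(noise_cov + diag(1e-12, M)))
  ntot <- n + burn_in + p
  x <- array(0, c(M, ntot, n_trials))
  innov <- array(stats::rnorm(M * ntot * n_trials), c(M, ntot, n_trials))
  for (t in (p + 1):ntot) {
    acc <- L %*% matrix(innov[, t, ], M)
    for (k in seq_len(p)) acc <- acc + coeffs[, , k] %*% matrix(x[, t - k, ], M)
    x[, t, ] <- acc
  }
  x[, (burn_in + p + 1):ntot, , drop = FALSE]
}

#' Simulate an epoched dataset with known causal graph
#'
#' Runs the (possibly time-varying) VAR recursion per trial with Gaussian
#' innovations: `burn_in` pre-epoch samples use the stationary part (base
#' plus always-on couplings) and are discarded; within the epoch each
#' windowed coupling's coefficient is scaled by its envelope. Reproducible
#' given the seed.
#'
#' @param spec A [simulation_spec()].
#' @param seed RNG seed (default `spec$seed`).
#' @return `list(ts = epoched_ts, truth = logical sink x source x sample
#'   array marking where each directed coupling is active, spec = spec)`.
#' @export
simulate_var <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "sim_spec"))
  st <- check_stability(spec)
  if (st$max >= 1)
    stop(sprintf(
      "unstable simulation: spectral radius %.3f at t = %.4f s",
      st$max, spec$times[which.max(st$radius)]), call. = FALSE)
  M <- spec$n_channels
  pL <- spec$max_lag
  A0 <- stationary_coeffs(spec)
  E <- envelope_gains(spec)
  varying <- which(vapply(spec$couplings, function(cp) cp$envelope != "none", TRUE))
  set.seed(seed)
  L <- t(chol(spec$noise_cov + diag(1e-12, M)))
  ntot <- spec$burn_in + spec$n_samples + pL
  x <- array(0, c(M, ntot, spec$n_trials))
  innov <- array(stats::rnorm(M * ntot * spec$n_trials), c(M, ntot, spec$n_trials))
  ep0 <- spec$burn_in + pL  # epoch sample s sits at column ep0 + s
  for (t in (pL + 1):ntot) {
    A <- A0
    s <- t - ep0
    if (s >= 1 && length(varying)) {
      for (ci in varying) {
        cp <- spec$couplings[[ci]]
        A[cp$sink, cp$source, cp$lag] <-
          A[cp$sink, cp$source, cp$lag] + cp$amplitude * E[ci, s]
      }
    }
    acc <- L %*% matrix(innov[, t, ], M)
    for (k in seq_len(pL)) acc <- acc + A[, , k] %*% matrix(x[, t - k, ], M)
    x[, t, ] <- acc
  }
  dat <- x[, (ep0 + 1):ntot, , drop = FALSE]
  truth <- array(FALSE, c(M, M, spec$n_samples))
  for (ci in seq_along(spec$couplings)) {
    cp <- spec$couplings[[ci]]
    act <- abs(cp$amplitude * E[ci, ]) > 0
    truth[cp$sink, cp$source, ] <- truth[cp$sink, cp$source, ] | act
  }
  list(ts = epoched_ts(dat, srate = spec$srate, t_start = spec$t_start),
       truth = truth, spec = spec)
}

# damped-oscillator AR(2) coefficients: pole radius r at frequency f0 Hz
ar2_osc <- function(f0, r, srate) c(2 * r * cos(2 * pi * f0 / srate), -r^2)

#' Bundled simulation scenarios
#'
#' Named ground-truth scenarios used throughout the tests and the
#' acceptance checks:
#' * `uncoupled3`: three independent damped oscillators (5, 10, 18 Hz) --
#'   the null scenario for type-I calibration.
#' * `chain3`: a causal chain `x1 -> x2 -> x3` (couplings 0.5 at lag 1,
#'   100 trials); the `1 -> 3` path is indirect, separating dDTF from DTF.
#' * `transient_theta`: two 5 Hz (theta-band) oscillators with an
#'   `x1 -> x2` coupling gated by a 300 ms Hann envelope at 0.1--0.4 s
#'   after the event, emulating a transient event-related information-flow
#'   burst.
#' * `bidirectional2`: two oscillators symmetrically coupled with equal
#'   strength (asymmetry ratios should vanish).
#'
#' @return Named list of [simulation_spec()] objects.
#' @export
preset_scenarios <- function() {
  osc3 <- function(fs, rs, srate) {
    A <- array(0, c(length(fs), length(fs), 2))
    for (i in seq_along(fs)) A[i, i, ] <- ar2_osc(fs[i], rs[i], srate)
    A
  }
  list(
    uncoupled3 = simulation_spec(
      3, 2, osc3(c(5, 10, 18), c(0.9, 0.9, 0.9), 128), srate = 128,
      n_samples = 128, n_trials = 20, seed = 101L),
    chain3 = simulation_spec(
      3, 2, osc3(c(10, 10, 10), c(0.95, 0.7, 0.7), 128), srate = 128,
      n_samples = 128, n_trials = 100,
      couplings = list(coupling(2, 1, 1, 0.5), coupling(3, 2, 1, 0.5)),
      seed = 102L),
    transient_theta = simulation_spec(
      2, 2, osc3(c(5, 5), c(0.9, 0.9), 128), srate = 128,
      n_samples = 192, n_trials = 50, t_start = -0.5,
      couplings = list(coupling(2, 1, 1, 1.0, "hann", onset = 0.1, offset = 0.4)),
      seed = 103L),
    bidirectional2 = simulation_spec(
      2, 2, osc3(c(10, 10), c(0.9, 0.9), 128), srate = 128,
      n_samples = 256, n_trials = 50,
      couplings = list(coupling(2, 1, 1, 0.15), coupling(1, 2, 1, 0.15)),
      seed = 104L)
  )
}
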