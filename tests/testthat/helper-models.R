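# Shared fixture builders (all generated in code at test time).

# Random stable VAR model with well-conditioned innovation covariance.
random_stable_model <- function(M, p, seed, srate = 100) {
  set.seed(seed)
  A <- array(rnorm(M * M * p, sd = 0.3 / sqrt(p * M)), c(M, M, p))
  r <- varconn:::companion_radius(A)
  if (r >= 0.9) for (k in seq_len(p)) A[, , k] <- A[, , k] * (0.85 / r)^k
  W <- matrix(rnorm(M * M), M)
  Sig <- crossprod(W) / M + diag(0.2, M)
  var_model(A, Sig, srate = srate)
}

# Direct model constructor for closed-form cases.
toy_model <- function(coeffs, sigma, srate = 100, n_obs = 1000L) {
  var_model(coeffs, sigma, srate = srate, n_obs = n_obs)
}

# White-noise epoched series.
white_ts <- function(M = 2, N = 200, Tt = 5, srate = 100, seed = 1, sd = 1) {
  set.seed(seed)
  epoched_ts(array(rnorm(M * N * Tt, sd = sd), c(M, N, Tt)), srate = srate)
}

# Stationary VAR dataset from explicit coefficients via the simulator.
var_ts <- function(coeffs, sigma = NULL, N, Tt, srate = 100, seed = 1,
                   couplings = list()) {
  M <- dim(coeffs)[1]
  if (is.null(sigma)) sigma <- diag(M)
  spec <- simulation_spec(M, dim(coeffs)[3], coeffs, noise_cov = sigma,
                          srate = srate, n_samples = N, n_trials = Tt,
                          couplings = couplings, seed = seed)
  simulate_var(spec)$ts
}
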