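# Independent oracles, deliberately written as straight loops / direct
# formulas sharing no code with the package internals.

# Transfer and spectral matrices by brute force.
oracle_spectral <- function(coeffs, sigma, freqs, srate) {
  M <- dim(coeffs)[1]; p <- dim(coeffs)[3]
  H <- array(0i, c(M, M, length(freqs)))
  S <- array(0i, c(M, M, length(freqs)))
  for (fi in seq_along(freqs)) {
    Ab <- matrix(0i, M, M)
    for (i in 1:M) for (j in 1:M) {
      Ab[i, j] <- (i == j) + 0i
      for (k in seq_len(p))
        Ab[i, j] <- Ab[i, j] - coeffs[i, j, k] * exp(-2i * pi * freqs[fi] * k / srate)
    }
    Hf <- solve(Ab)
    Sf <- matrix(0i, M, M)
    for (i in 1:M) for (j in 1:M)
      for (a in 1:M) for (b in 1:M)
        Sf[i, j] <- Sf[i, j] + Hf[i, a] * sigma[a, b] * Conj(Hf[j, b])
    H[, , fi] <- Hf
    S[, , fi] <- Sf
  }
  list(H = H, S = S)
}

# Benjamini-Hochberg / Benjamini-Yekutieli step-up by direct rule.
oracle_fdr <- function(p, q, by = FALSE) {
  m <- length(p)
  o <- order(p)
  crit <- q * seq_len(m) / m
  if (by) crit <- crit / sum(1 / seq_len(m))
  ok <- which(p[o] <= crit)
  reject <- rep(FALSE, m)
  if (length(ok)) reject[o[seq_len(max(ok))]] <- TRUE
  reject
}

# Welch one-sided PSD (units^2/Hz), Hann window, 50% overlap.
oracle_welch <- function(x, srate, nseg = 128) {
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nseg - 1)) / (nseg - 1))
  step <- nseg %/% 2
  starts <- seq(1, length(x) - nseg + 1, by = step)
  acc <- numeric(nseg)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)] * w
    acc <- acc + Mod(fft(seg))^2
  }
  psd <- acc / length(starts) / (srate * sum(w^2))
  nb <- nseg %/% 2
  list(freq = (1:nb) * srate / nseg, psd = 2 * psd[2:(nb + 1)])
}

# Multi-trial cross-spectral coherence: one Hann-tapered segment per trial.
oracle_trial_coherence <- function(ts, i, j) {
  N <- dim(ts$data)[2]
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(N - 1)) / (N - 1))
  sxx <- syy <- numeric(N)
  sxy <- complex(N)
  for (tr in seq_len(dim(ts$data)[3])) {
    X <- fft((ts$data[i, , tr] - mean(ts$data[i, , tr])) * w)
    Y <- fft((ts$data[j, , tr] - mean(ts$data[j, , tr])) * w)
    sxx <- sxx + Mod(X)^2
    syy <- syy + Mod(Y)^2
    sxy <- sxy + X * Conj(Y)
  }
  nb <- N %/% 2
  list(freq = (1:nb) * ts$srate / N,
       coh = (Mod(sxy)^2 / (sxx * syy))[2:(nb + 1)])
}

# Stationary process covariance via the companion-form Lyapunov equation.
oracle_var_variance <- function(coeffs, sigma) {
  M <- dim(coeffs)[1]; p <- dim(coeffs)[3]
  A <- matrix(0, M * p, M * p)
  for (k in seq_len(p)) A[1:M, ((k - 1) * M + 1):(k * M)] <- coeffs[, , k]
  if (p > 1) A[(M + 1):(M * p), 1:(M * (p - 1))] <- diag(M * (p - 1))
  Q <- matrix(0, M * p, M * p)
  Q[1:M, 1:M] <- sigma
  G <- solve(diag((M * p)^2) - kronecker(A, A), as.vector(Q))
  matrix(G, M * p)[1:M, 1:M]
}

# Minimal EDF writer (independent of the package reader).
write_edf_fixture <- function(path, dat, srate, phys = c(-200, 200)) {
  M <- nrow(dat); N <- ncol(dat)
  n_rec <- N %/% srate
  stopifnot(n_rec * srate == N)
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(s, n) writeChar(formatC(substr(s, 1, n), width = -n),
                                  con, n, eos = NULL)
  pad("0", 8); pad("X patient", 80); pad("X recording", 80)
  pad("01.01.20", 8); pad("12.00.00", 8)
  pad(as.character(256 * (1 + M)), 8); pad("", 44)
  pad(as.character(n_rec), 8); pad("1", 8); pad(as.character(M), 4)
  for (i in 1:M) pad(sprintf("sig%d", i), 16)
  for (i in 1:M) pad("synthetic", 80)
  for (i in 1:M) pad("uV", 8)
  for (i in 1:M) pad(as.character(phys[1]), 8)
  for (i in 1:M) pad(as.character(phys[2]), 8)
  for (i in 1:M) pad("-32768", 8)
  for (i in 1:M) pad("32767", 8)
  for (i in 1:M) pad("", 80)
  for (i in 1:M) pad(as.character(srate), 8)
  for (i in 1:M) pad("", 32)
  dig <- round((dat - phys[1]) / (phys[2] - phys[1]) * 65535 - 32768)
  for (r in 1:n_rec) for (s in 1:M)
    writeBin(as.integer(dig[s, ((r - 1) * srate + 1):(r * srate)]),
             con, size = 2, endian = "little")
  invisible(path)
}
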