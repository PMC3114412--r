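test_that("spectral_set has closed-form limits and internal identities", {
  # order 0, identity innovations: H = I, S = I at every frequency
  m0 <- toy_model(array(0, c(2, 2, 0)), diag(2))
  ss0 <- spectral_set(m0, c(10, 20, 40))
  for (fi in 1:3) {
    expect_equal(ss0$H_f[, , fi], diag(2) + 0i, tolerance = 1e-12)
    expect_equal(ss0$S_f[, , fi], diag(2) + 0i, tolerance = 1e-12)
  }
  # univariate AR(1), a = 0.5 at f -> 0: H -> 2, S -> 4
  m1 <- toy_model(array(0.5, c(1, 1, 1)), matrix(1), srate = 1000)
  ss1 <- spectral_set(m1, c(0.01, 100))
  expect_equal(Re(ss1$H_f[1, 1, 1]), 2, tolerance = 1e-3)
  expect_equal(Re(ss1$S_f[1, 1, 1]), 4, tolerance = 1e-2)
  # identities H A = I, S Hermitian with nonnegative diagonal
  m <- random_stable_model(3, 2, seed = 31)
  ss <- spectral_set(m, c(5, 17, 33))
  for (fi in 1:3) {
    expect_lt(max(Mod(ss$H_f[, , fi] %*% ss$A_f[, , fi] - diag(3))), 1e-8)
    expect_lt(max(Mod(ss$S_f[, , fi] - Conj(t(ss$S_f[, , fi])))), 1e-9)
    expect_true(all(Re(diag(ss$S_f[, , fi])) >= 0))
  }
  expect_error(spectral_set(m, c(0, 10)), "freqs")
  expect_error(spectral_set(m, c(10, 60)), "freqs")
})

test_that("transfer and spectral matrices match the brute-force oracle", {
  for (seed in 32:36) {
    m <- random_stable_model(3, 2, seed = seed)
    freqs <- c(3.5, 12, 27, 49)
    ss <- spectral_set(m, freqs)
    orc <- oracle_spectral(m$coeffs, m$noise_cov, freqs, m$srate)
    expect_lt(max(Mod(ss$H_f - orc$H)), 1e-10)
    expect_lt(max(Mod(ss$S_f - orc$S)), 1e-10)
  }
})

test_that("model spectrum matches the AR(1) closed form and a Welch estimate", {
  srate <- 128
  m <- toy_model(array(0.5, c(1, 1, 1)), matrix(1), srate = srate)
  freqs <- 1:63
  ss <- spectral_set(m, freqs)
  closed <- 1 / Mod(1 - 0.5 * exp(-2i * pi * freqs / srate))^2
  expect_equal(Re(ss$S_f[1, 1, ]), closed, tolerance = 1e-12)

  set.seed(37)
  x <- as.numeric(stats::arima.sim(list(ar = 0.5), 1e5))
  w <- oracle_welch(x, srate, nseg = 64)
  grid <- w$freq[w$freq < srate / 2]            # Welch bins below Nyquist
  model_psd <- 2 / Mod(1 - 0.5 * exp(-2i * pi * grid / srate))^2 / srate
  welch_at <- w$psd[match(grid, w$freq)]
  expect_lt(max(abs(welch_at / model_psd - 1)), 0.10)
})

test_that("white-noise power is flat and total power satisfies Parseval", {
  mw <- toy_model(array(0, c(2, 2, 0)), diag(c(2, 3)), srate = 100)
  pw <- power_spectrum(spectral_set(mw, c(5, 25, 45)))
  expect_equal(pw$values[1, 1, , 1], rep(2, 3))
  expect_equal(pw$values[2, 2, , 1], rep(3, 3))

  m <- random_stable_model(2, 2, seed = 38, srate = 100)
  freqs <- seq(0.25, 50, by = 0.25)
  ss <- spectral_set(m, freqs)
  diags <- vapply(seq_along(freqs), function(fi) Re(diag(ss$S_f[, , fi])),
                  numeric(2))
  var_spec <- rowSums(diags) * 0.25 * 2 / m$srate
  var_true <- diag(oracle_var_variance(m$coeffs, m$noise_cov))
  expect_lt(max(abs(var_spec / var_true - 1)), 0.05)
})

test_that("coherence has its closed forms and matches a Welch oracle", {
  mu <- toy_model(array(c(0.5, 0, 0, -0.3), c(2, 2, 1)), diag(2))
  cu <- coherence(spectral_set(mu, c(10, 30)))
  expect_lt(max(abs(cu$values[1, 2, , 1])), 1e-12)
  expect_equal(cu$values[1, 1, , 1], rep(1, 2))

  rho <- 0.6
  mc <- toy_model(array(0, c(2, 2, 0)),
                  matrix(c(1, rho, rho, 1), 2))
  cc <- coherence(spectral_set(mc, c(5, 20, 45)))
  expect_equal(cc$values[1, 2, , 1], rep(rho^2, 3), tolerance = 1e-12)

  # driven pair: model-based coherence vs nonparametric cross-spectral oracle
  A <- array(0, c(2, 2, 2))
  A[1, 1, ] <- c(2 * 0.95 * cos(2 * pi * 10 / 128), -0.95^2)
  A[2, 2, 1] <- 0.3
  ts <- var_ts(A, N = 128, Tt = 200, srate = 128, seed = 39,
               couplings = list(coupling(2, 1, 1, 0.8)))
  m <- fit_var(ts, 2)
  freqs <- (1:63)
  ch <- coherence(spectral_set(m, freqs))
  orc <- oracle_trial_coherence(ts, 1, 2)
  at10 <- which(freqs == 10)
  expect_gt(ch$values[1, 2, at10, 1], 0.5)
  expect_equal(ch$values[1, 2, at10, 1], orc$coh[orc$freq == 10],
               tolerance = 0.1)
})

test_that("partial coherence removes indirect links that coherence keeps", {
  # two channels: partial coherence equals ordinary coherence
  m2 <- random_stable_model(2, 2, seed = 40)
  ss2 <- spectral_set(m2, c(5, 15, 35))
  expect_equal(partial_coherence(ss2)$values[1, 2, , 1],
               coherence(ss2)$values[1, 2, , 1], tolerance = 1e-9)
  # uncoupled: all off-diagonal partial coherence vanishes
  mu <- toy_model(array(c(0.5, 0, 0, -0.3), c(2, 2, 1)), diag(2))
  expect_lt(max(abs(partial_coherence(spectral_set(mu, c(10, 30)))$values[1, 2, , 1])),
            1e-12)
  # chain x1 -> x2 -> x3: ordinary coherence(1,3) is inflated, partial is not
  A <- array(0, c(3, 3, 2))
  for (i in 1:3) A[i, i, ] <- c(2 * 0.9 * cos(2 * pi * 10 / 128), -0.81)
  A[2, 1, 1] <- 0.7
  A[3, 2, 1] <- 0.7
  m <- toy_model(A, diag(3), srate = 128)
  ss <- spectral_set(m, 10)
  expect_gt(coherence(ss)$values[1, 3, 1, 1], 0.3)
  expect_lt(partial_coherence(ss)$values[1, 3, 1, 1], 0.1)
})

test_that("multiple coherence reduces to pairwise coherence for two channels", {
  m2 <- random_stable_model(2, 3, seed = 41)
  ss2 <- spectral_set(m2, c(4, 22, 41))
  expect_equal(multiple_coherence(ss2)$values[1, 1, , 1],
               coherence(ss2)$values[1, 2, , 1], tolerance = 1e-9)
  mu <- toy_model(array(c(0.5, 0, 0, -0.3), c(2, 2, 1)), diag(2))
  expect_lt(max(multiple_coherence(spectral_set(mu, c(10, 30)))$values), 1e-12)
  # joint dependence dominates every pairwise coherence with that channel
  m3 <- random_stable_model(3, 2, seed = 42)
  ss3 <- spectral_set(m3, c(5, 18, 33))
  mc <- multiple_coherence(ss3)$values
  co <- coherence(ss3)$values
  for (i in 1:3) for (fi in 1:3) {
    others <- setdiff(1:3, i)
    expect_gte(mc[i, i, fi, 1] + 1e-9, max(co[i, others, fi, 1]))
  }
})
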