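test_that("DTF and PDC normalization identities hold on random stable models", {
  for (seed in 1:100) {
    M <- 2 + (seed %% 4)          # 2..5 channels
    p <- 1 + (seed %% 4)          # 1..4 lags
    m <- random_stable_model(M, p, seed = 1000 + seed)
    ss <- spectral_set(m, c(7, 21, 42))
    v_dtf <- dtf(ss)$values
    v_pdc <- pdc(ss)$values
    expect_lt(max(abs(apply(v_dtf, c(1, 3, 4), sum) - 1)), 1e-10)
    expect_lt(max(abs(apply(v_pdc, c(2, 3, 4), sum) - 1)), 1e-10)
    expect_true(all(v_dtf >= 0 & v_dtf <= 1 + 1e-9))
    expect_true(all(v_pdc >= 0 & v_pdc <= 1 + 1e-9))
  }
})

test_that("uncoupled models yield zero directed flow, identity diagonal", {
  mu <- toy_model(array(diag(c(0.5, -0.3)), c(2, 2, 1)), diag(2))
  ss <- spectral_set(mu, c(10, 30))
  for (meas in c("dtf", "ffdtf", "ddtf", "pdc", "gpdc")) {
    v <- varconn:::eval_measure(ss, meas)
    expect_lt(max(abs(v[1, 2, ])), 1e-12)
    expect_lt(max(abs(v[2, 1, ])), 1e-12)
  }
  expect_equal(dtf(ss)$values[1, 1, , 1], rep(1, 2))
})

test_that("unidirectional coupling produces strictly one-way DTF and PDC", {
  A <- array(c(0.5, 0.4, 0, 0.3), c(2, 2, 1))   # ch1 -> ch2 only
  m <- toy_model(A, diag(2), srate = 100)
  ss <- spectral_set(m, c(5, 20, 45))
  expect_true(all(dtf(ss)$values[2, 1, , 1] > 0))
  expect_lt(max(dtf(ss)$values[1, 2, , 1]), 1e-10)
  expect_true(all(pdc(ss)$values[2, 1, , 1] > 0))
  expect_lt(max(pdc(ss)$values[1, 2, , 1]), 1e-10)
})

test_that("ffDTF is the DTF numerator under a full-frequency normalization", {
  m <- random_stable_model(3, 2, seed = 50)
  freqs <- seq(2, 48, by = 2)
  ss <- spectral_set(m, freqs)
  v <- ffdtf(ss)$values
  # per sink, the grand sum over sources and frequencies is 1
  expect_lt(max(abs(apply(v, 1, sum) - 1)), 1e-10)
  # proportional to |H_ij|^2 at each frequency (oracle recomputation)
  H2 <- Mod(oracle_spectral(m$coeffs, m$noise_cov, freqs, m$srate)$H)^2
  for (i in 1:3) {
    den <- sum(H2[i, , ])
    expect_lt(max(abs(v[i, , , 1] - H2[i, , ] / den)), 1e-10)
  }
})

test_that("dDTF is ffDTF times partial coherence and suppresses cascades", {
  m <- random_stable_model(3, 2, seed = 51)
  ss <- spectral_set(m, c(5, 15, 30))
  expect_lt(max(abs(ddtf(ss)$values -
                    ffdtf(ss)$values * partial_coherence(ss)$values)), 1e-12)
  # chain x1 -> x2 -> x3: dDTF demotes the indirect 1 -> 3 path more than DTF
  A <- array(0, c(3, 3, 2))
  for (i in 1:3) A[i, i, ] <- c(2 * 0.9 * cos(2 * pi * 10 / 128), -0.81)
  A[2, 1, 1] <- 0.7
  A[3, 2, 1] <- 0.7
  ssc <- spectral_set(toy_model(A, diag(3), srate = 128), 10)
  vd <- dtf(ssc)$values; vdd <- ddtf(ssc)$values
  expect_lt(vdd[3, 1, 1, 1] / vdd[2, 1, 1, 1],
            vd[3, 1, 1, 1] / vd[2, 1, 1, 1])
})

test_that("GPDC equals PDC for white innovations and is scale-invariant", {
  m <- random_stable_model(3, 2, seed = 52)
  m$noise_cov <- diag(3) * 1.7
  ss <- spectral_set(m, c(5, 15, 30))
  expect_equal(gpdc(ss)$values, pdc(ss)$values, tolerance = 1e-12)
  expect_lt(max(abs(apply(gpdc(ss)$values, c(2, 3, 4), sum) - 1)), 1e-10)

  # rescale one channel's data by 10 and refit: GPDC unchanged, PDC not
  A <- array(c(0.5, 0.4, 0, 0.3), c(2, 2, 1))
  ts <- var_ts(A, N = 400, Tt = 50, seed = 53)
  scaled <- ts
  scaled$data[2, , ] <- scaled$data[2, , ] * 10
  f1 <- fit_var(ts, 1); f2 <- fit_var(scaled, 1)
  g1 <- gpdc(spectral_set(f1, c(10, 25)))$values
  g2 <- gpdc(spectral_set(f2, c(10, 25)))$values
  expect_lt(max(abs(g1 - g2)), 1e-8)
})

test_that("block-diagonal models show exact graph separation", {
  A <- array(0, c(4, 4, 2))
  A[1:2, 1:2, 1] <- c(0.5, 0.4, -0.2, 0.3)
  A[1:2, 1:2, 2] <- c(-0.2, 0.1, 0.05, -0.25)
  A[3:4, 3:4, 1] <- c(0.6, 0.3, 0.1, 0.2)
  Sig <- diag(4); Sig[1, 2] <- Sig[2, 1] <- 0.4
  m <- toy_model(A, Sig, srate = 100)
  ss <- spectral_set(m, c(5, 20, 45))
  cross <- rbind(cbind(matrix(FALSE, 2, 2), matrix(TRUE, 2, 2)),
                 cbind(matrix(TRUE, 2, 2), matrix(FALSE, 2, 2)))
  for (meas in c("dtf", "ffdtf", "ddtf", "pdc", "gpdc")) {
    v <- varconn:::eval_measure(ss, meas)
    for (fi in 1:3) expect_lt(max(v[, , fi][cross]), 1e-10)
  }
})

test_that("the measure registry is broad, unique and fully evaluable", {
  reg <- measure_registry()
  expect_gte(length(reg), 15)
  expect_equal(anyDuplicated(reg), 0)
  m <- random_stable_model(2, 2, seed = 54)
  ss <- spectral_set(m, c(10, 30))
  for (nm in reg) {
    v <- varconn:::eval_measure(ss, nm)
    expect_true(all(is.finite(v)), info = nm)
    expect_equal(dim(v), c(2, 2, 2), info = nm)
  }
  expect_error(varconn:::eval_measure(ss, "nope"), "unknown")
})

test_that("graph measures identify sources, sinks and symmetric flows", {
  A <- array(c(0.5, 0.4, 0, 0.3), c(2, 2, 1))   # pure source ch1, sink ch2
  ss <- spectral_set(toy_model(A, diag(2)), c(5, 20, 45))
  gm <- graph_measures(dtf(ss), band = c(1, 50))
  expect_equal(gm$nodes$asymmetry_ratio, c(1, -1), tolerance = 1e-12)

  # symmetric bidirectional coupling: asymmetry ratios vanish on long data
  sim <- simulate_var(preset_scenarios()$bidirectional2)
  crs <- connectivity(sim$ts, order = 2, measures = "dtf", freqs = c(8, 10, 12))
  gmb <- graph_measures(crs$dtf, band = c(8, 12))
  expect_lt(max(abs(gmb$nodes$asymmetry_ratio)), 0.1)

  # uncoupled: causal density near zero
  mu <- toy_model(array(diag(c(0.5, -0.3)), c(2, 2, 1)), diag(2))
  gmu <- graph_measures(dtf(spectral_set(mu, c(10, 30))), band = c(5, 35))
  expect_lt(gmu$density$causal_density, 1e-12)
  expect_error(graph_measures(gmu <- dtf(spectral_set(mu, c(10, 30))),
                              band = c(60, 70)), "band")
})

test_that("a transient theta coupling peaks in the overlapping windows", {
  sim <- simulate_var(preset_scenarios()$transient_theta)
  crs <- suppressWarnings(   # edge windows fit unstable local models by design
    connectivity(sim$ts, order = 2, measures = "ddtf",
                 freqs = 3:7, window = window_spec(0.3, 0.1)))
  v <- apply(crs$ddtf$values[2, 1, , ], 2, mean)   # band-averaged 1 -> 2
  centers <- crs$ddtf$window_centers
  best <- centers[which.max(v)]
  # envelope active on [0.1, 0.4] s; a 0.3 s window overlaps iff its center
  # lies in (-0.05, 0.55)
  expect_gt(best, -0.05)
  expect_lt(best, 0.55)
  on_env <- centers > -0.05 & centers < 0.55
  expect_gt(max(v[on_env]), max(v[!on_env]))
})
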