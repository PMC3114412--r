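test_that("phase surrogates preserve amplitude spectra and are seeded", {
  set.seed(71)
  ts <- epoched_ts(array(rnorm(3 * 100 * 4), c(3, 100, 4)), 100)
  sg <- phase_surrogate(ts, seed = 5)
  a0 <- apply(ts$data, c(1, 3), function(x) Mod(fft(x)))
  a1 <- apply(sg$data, c(1, 3), function(x) Mod(fft(x)))
  expect_lt(max(abs(a0 - a1)), 1e-9)
  # Parseval: per-series sample variance preserved
  expect_lt(max(abs(apply(ts$data, c(1, 3), var) - apply(sg$data, c(1, 3), var))),
            1e-9)
  expect_identical(phase_surrogate(ts, seed = 5)$data, sg$data)
  expect_false(identical(phase_surrogate(ts, seed = 6)$data, sg$data))
  expect_error(phase_surrogate(epoched_ts(matrix(0, 1, 3), 10)), "4 samples")
})

test_that("phase surrogates destroy cross-channel coupling", {
  A <- array(c(0.5, 0.8, 0, 0.3), c(2, 2, 1))
  ts <- var_ts(A, N = 128, Tt = 30, srate = 128, seed = 72)
  at10 <- function(x) {
    o <- oracle_trial_coherence(x, 1, 2)
    o$coh[o$freq == 10]
  }
  expect_gt(at10(ts), 0.3)
  set.seed(73)
  cohs <- vapply(1:200, function(s) at10(phase_surrogate(ts)), 0)
  expect_lt(mean(cohs), 0.15)
})

test_that("surrogate test p-values obey the +1 convention and find true edges", {
  A <- array(c(0.5, 0.6, 0, 0.3), c(2, 2, 1))
  ts <- var_ts(A, N = 256, Tt = 40, srate = 128, seed = 74)
  pl <- make_pipeline("dtf", order = 1, freqs = c(10, 30))
  st <- surrogate_test(pl, ts, n_surrogates = 99, seed = 75)
  expect_equal(st$pvalues[2, 1, 1, 1], 1 / 100)   # observed above all nulls
  expect_true(all(st$pvalues >= 1 / 100, na.rm = TRUE))
  expect_true(all(is.na(diag(st$pvalues[, , 1, 1]))))
  expect_true(st$mask[2, 1, 1, 1])
  expect_false(st$mask[1, 2, 1, 1])
  # reproducible given the seed
  st2 <- surrogate_test(pl, ts, n_surrogates = 99, seed = 75)
  expect_identical(st2$pvalues, st$pvalues)
  expect_error(surrogate_test(pl, ts, n_surrogates = 5), ">= 19")
})

test_that("bootstrap confidence bands bracket the estimate and the truth", {
  A <- array(c(0.5, 0.4, 0, 0.3), c(2, 2, 1))
  freqs <- c(10, 25)
  pl <- make_pipeline("dtf", order = 1, freqs = freqs)
  ts <- var_ts(A, N = 200, Tt = 30, seed = 76)
  cb <- bootstrap_ci(pl, ts, n_boot = 199, level = 0.95, seed = 77)
  expect_true(all(cb$lower <= cb$upper))
  inside <- cb$lower <= cb$estimate & cb$estimate <= cb$upper
  expect_gte(mean(inside), 0.95)
  cb2 <- bootstrap_ci(pl, ts, n_boot = 199, level = 0.95, seed = 77)
  expect_identical(cb2$lower, cb$lower)
  expect_error(bootstrap_ci(pl, var_ts(A, N = 200, Tt = 1, seed = 1), 100),
               "2 trials")

  # coverage of the generative DTF across simulated datasets
  truth <- dtf(spectral_set(toy_model(A, diag(2)), freqs))$values[2, 1, 1, 1]
  covered <- vapply(1:100, function(k) {
    tsk <- var_ts(A, N = 200, Tt = 30, seed = 7000 + k)
    ck <- bootstrap_ci(pl, tsk, n_boot = 100, level = 0.95, seed = k)
    ck$lower[2, 1, 1, 1] <= truth && truth <= ck$upper[2, 1, 1, 1]
  }, TRUE)
  expect_gte(mean(covered), 0.87)
  expect_lte(mean(covered), 0.99)
})

test_that("permutation test is antisymmetric, calibrated and powerful", {
  A0 <- array(diag(c(0.5, 0.3)), c(2, 2, 1))
  pl <- make_pipeline("dtf", order = 1, freqs = 10)
  a <- var_ts(A0, N = 128, Tt = 20, srate = 128, seed = 81)
  b <- var_ts(A0, N = 128, Tt = 20, srate = 128, seed = 82)
  sab <- permutation_test(pl, a, b, n_perm = 49, seed = 83)
  sba <- permutation_test(pl, b, a, n_perm = 49, seed = 83)
  expect_equal(sab$observed$values, -sba$observed$values)

  # identical generating process: p-values uniform over repetitions
  pvals <- vapply(1:60, function(k) {
    ak <- var_ts(A0, N = 128, Tt = 15, srate = 128, seed = 8000 + 2 * k)
    bk <- var_ts(A0, N = 128, Tt = 15, srate = 128, seed = 8001 + 2 * k)
    permutation_test(pl, ak, bk, n_perm = 49, seed = k)$pvalues[2, 1, 1, 1]
  }, 0)
  # p-values live on the lattice k/50: bin into equal-probability fifths and
  # test uniformity by chi-squared goodness of fit
  counts <- table(cut(pvals, breaks = seq(0, 1, by = 0.2)))
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)

  # injected difference (coupling present only in condition a) is detected
  Ac <- array(c(0.5, 0.5, 0, 0.3), c(2, 2, 1))
  hits <- vapply(1:20, function(k) {
    ak <- var_ts(Ac, N = 128, Tt = 25, srate = 128, seed = 8500 + 2 * k)
    bk <- var_ts(A0, N = 128, Tt = 25, srate = 128, seed = 8501 + 2 * k)
    permutation_test(pl, ak, bk, n_perm = 39, seed = k)$pvalues[2, 1, 1, 1] <= 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.9)
  expect_error(permutation_test(pl, a, white_ts(3, 128, 4), 19), "disagree")
})

test_that("analytic PDC/DTF thresholds scale with data and stay calibrated", {
  A <- array(c(0.5, 0.4, 0, 0.3), c(2, 2, 1))
  small <- var_ts(A, N = 150, Tt = 10, seed = 84)
  big <- var_ts(A, N = 150, Tt = 100, seed = 84)
  crs_s <- connectivity(small, order = 1, measures = "pdc", freqs = c(10, 25))
  crs_b <- connectivity(big, order = 1, measures = "pdc", freqs = c(10, 25))
  th_s <- analytic_test(crs_s$pdc, attr(crs_s, "models"), "pdc")$thresholds
  th_b <- analytic_test(crs_b$pdc, attr(crs_b, "models"), "pdc")$thresholds
  expect_true(all(th_b[!is.na(th_b)] < th_s[!is.na(th_s)]))

  # type-I calibration under an uncoupled model, both measures
  for (meas in c("pdc", "dtf")) {
    rej <- vapply(1:150, function(k) {
      ts <- var_ts(array(diag(c(0.5, -0.3)), c(2, 2, 1)), N = 200, Tt = 5,
                   seed = 9000 + k)
      crs <- connectivity(ts, order = 1, measures = meas, freqs = 15)
      at <- analytic_test(crs[[meas]], attr(crs, "models"), meas, alpha = 0.05)
      at$pvalues[2, 1, 1, 1] <= 0.05
    }, TRUE)
    expect_gte(mean(rej), 0.01)
    expect_lte(mean(rej), 0.12)
  }
})

test_that("analytic and surrogate decisions concur on a coupled system", {
  sim <- simulate_var(preset_scenarios()$chain3)
  freqs <- c(5, 10, 20)
  crs <- connectivity(sim$ts, order = 2, measures = "dtf", freqs = freqs)
  at <- analytic_test(crs$dtf, attr(crs, "models"), "dtf", alpha = 0.05)
  pl <- make_pipeline("dtf", order = 2, freqs = freqs)
  st <- surrogate_test(pl, sim$ts, n_surrogates = 99, seed = 85)
  off <- !is.na(st$pvalues)
  agree <- mean((at$qvalues[off] <= 0.05) == (st$qvalues[off] <= 0.05))
  expect_gte(agree, 0.8)
})

test_that("FDR correction matches the independent step-up oracle", {
  p15 <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212,
           0.216, 0.222, 0.251, 0.269, 0.275, 0.34)
  out <- fdr_correct(p15, q = 0.05, mode = "bh")
  expect_identical(out$mask, oracle_fdr(p15, 0.05))
  expect_identical(which(out$mask), 1L)  # only p = 0.001 survives step-up

  for (seed in 1:25) {
    set.seed(seed)
    p <- runif(40)^2
    expect_identical(fdr_correct(p, 0.05, "bh")$mask, oracle_fdr(p, 0.05))
    expect_identical(fdr_correct(p, 0.05, "by")$mask, oracle_fdr(p, 0.05, by = TRUE))
    # BH rejections are a superset of BY rejections
    expect_true(all(fdr_correct(p, 0.05, "bh")$mask |
                    !fdr_correct(p, 0.05, "by")$mask))
  }
  expect_true(all(!fdr_correct(rep(1, 20), 0.05)$mask))
  expect_error(fdr_correct(c(0.5, 1.2), 0.05), "\\[0, 1\\]")
  # array shape and NA cells are preserved
  pa <- array(runif(24), c(2, 2, 3, 2)); pa[1, 1, , ] <- NA
  fc <- fdr_correct(pa, 0.1)
  expect_equal(dim(fc$qvalues), dim(pa))
  expect_true(all(!fc$mask[1, 1, , ]))
})

test_that("BH controls the realized false discovery rate under the null", {
  set.seed(86)
  fdp <- vapply(1:500, function(k) {
    p <- runif(30)
    mean(oracle_fdr(p, 0.1) * 1)  # every rejection is false under the null
    m <- fdr_correct(p, q = 0.1, mode = "bh")$mask
    if (any(m)) 1 else 0          # FDP is 0/1 under a complete null
  }, 0)
  expect_lte(mean(fdp), 0.1 + 0.03)
})
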