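#' Time-domain conditional Granger causality
#'
#' For every directed pair `j -> i`, compares the innovation variance of
#' sink `i` under the full model with the variance under a reduced model
#' whose regressors omit every lag of source `j` (conditioning on all
#' remaining channels): `GC(j -> i) = ln(Sigma_r[i, i] / Sigma_f[i, i])`.
#' Positive values mean the source's past improves linear prediction of
#' the sink beyond the sink's own (and all other channels') past. Small
#' negative sampling fluctuations are clipped to 0 and counted in
#' attribute `"n_clipped"`. The diagonal is `NaN` (self-causality is
#' undefined).
#'
#' @param window An [epoched_ts()].
#' @param order Model order `p >= 1`.
#' @param method Passed to [fit_var()].
#' @return A frequency-free `connectivity_result` (`freqs = NA`, one
#'   window) in nats.
#' @export
gc_time <- function(window, order, method = "ols") {
  assert_ets(window, "window")
  if (order < 1) stop("`order` must be >= 1 for Granger causality", call. = FALSE)
  p <- as.integer(order)
  M <- n_channels(window)
  full <- fit_var(window, p, method = method)
  de <- build_design(window$data, p)
  vals <- matrix(NaN, M, M)
  n_clipped <- 0L
  for (j in seq_len(M)) {
    drop_cols <- (seq_len(p) - 1L) * M + j
    Xr <- de$X[, -drop_cols, drop = FALSE]
    qrX <- qr(Xr)
    resid <- qr.resid(qrX, de$Y)
    dfr <- nrow(Xr) - ncol(Xr)
    sr <- colSums(resid^2) / dfr
    for (i in seq_len(M)) {
      if (i == j) next
      g <- log(sr[i] / full$noise_cov[i, i])
      if (g < 0) { n_clipped <- n_clipped + 1L; g <- 0 }
      vals[i, j] <- g
    }
  }
  cr <- new_connectivity_result("gc_time", array(vals, c(M, M, 1, 1)),
                                NA_real_, model_orders = p,
                                channel_labels = window$channel_labels)
  attr(cr, "n_clipped") <- n_clipped
  cr
}

#' Geweke pairwise spectral Granger causality
#'
#' For each ordered channel pair a bivariate VAR is refit on that pair
#' alone and Geweke's frequency decomposition is evaluated:
#' `f(j -> i)(f) = ln( S_ii(f) / (S_ii(f) - (Sigma_jj - Sigma_ij^2 /
#' Sigma_ii) |H_ij(f)|^2) )`, the log-ratio of the sink's total spectrum
#' to its intrinsic part after removing the source's causal contribution
#' (the innovation-correlation rotation is absorbed in the conditional
#' variance term). Averaged over the full band, it approximates the
#' time-domain pairwise Granger causality. Tiny negative values are
#' clipped to 0; the diagonal is `NaN`.
#'
#' @param window An [epoched_ts()].
#' @param order Bivariate model order `p >= 1`.
#' @param freqs Frequency grid in Hz.
#' @param method Passed to [fit_var()].
#' @return A `connectivity_result` (nats) over the grid.
#' @export
ggc_spectral <- function(window, order, freqs = default_freqs(window$srate),
                         method = "ols") {
  assert_ets(window, "window")
  if (order < 1) stop("`order` must be >= 1 for Granger causality", call. = FALSE)
  M <- n_channels(window)
  nf <- length(freqs)
  vals <- array(NaN, c(M, M, nf))
  for (i in seq_len(M)) for (j in seq_len(M)) {
    if (j <= i) next
    sub <- epoched_ts(window$data[c(i, j), , , drop = FALSE],
                      srate = window$srate, times = window$times,
                      channel_labels = window$channel_labels[c(i, j)])
    fit <- fit_var(sub, order, method = method)
    ss <- spectral_set(fit, freqs)
    Sg <- fit$noise_cov
    # j -> i: pair index (1 <- 2); i -> j: (2 <- 1)
    s11 <- Re(diag3(ss$S_f)[1, ]); s22 <- Re(diag3(ss$S_f)[2, ])
    h12 <- Mod(ss$H_f[1, 2, ])^2; h21 <- Mod(ss$H_f[2, 1, ])^2
    v2 <- Sg[2, 2] - Sg[1, 2]^2 / Sg[1, 1]
    v1 <- Sg[1, 1] - Sg[1, 2]^2 / Sg[2, 2]
    vals[i, j, ] <- pmax(log(s11 / pmax(s11 - v2 * h12, .Machine$double.eps)), 0)
    vals[j, i, ] <- pmax(log(s22 / pmax(s22 - v1 * h21, .Machine$double.eps)), 0)
  }
  new_connectivity_result("ggc_spectral", array(vals, c(M, M, nf, 1)), freqs,
                          model_orders = as.integer(order),
                          channel_labels = window$channel_labels)
}
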