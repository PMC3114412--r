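#' @keywords internal
new_var_model <- function(order, coeffs, noise_cov, srate, n_obs,
                          method = "ols", xtx = NULL, channel_labels = NULL,
                          window_center = NA_real_) {
  M <- nrow(noise_cov)
  noise_cov <- (noise_cov + t(noise_cov)) / 2
  if (!all(is.finite(coeffs))) stop("non-finite VAR coefficients", call. = FALSE)
  ev <- eigen(noise_cov, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10))
    stop("innovation covariance is not positive semidefinite", call. = FALSE)
  structure(
    list(order = order, coeffs = coeffs, noise_cov = noise_cov, srate = srate,
         n_obs = n_obs, method = method, xtx = xtx,
         channel_labels = channel_labels, window_center = window_center),
    class = "var_model")
}

#' Construct a VAR model from explicit coefficients
#'
#' Builds a `var_model` directly from known coefficient matrices and an
#' innovation covariance -- for closed-form analyses, simulations with
#' known ground truth, or evaluating connectivity measures at exact
#' parameter values (rather than estimates from [fit_var()]).
#'
#' @param coeffs `M x M x p` array, `coeffs[i, j, k]`: influence of source
#'   channel `j` at lag `k` on sink channel `i`.
#' @param noise_cov `M x M` symmetric positive-semidefinite innovation
#'   covariance.
#' @param srate Sampling rate in Hz.
#' @param n_obs Nominal observation count recorded in the model (used only
#'   by asymptotic statistics; irrelevant for closed-form work).
#' @return A `var_model`.
#' @examples
#' m <- var_model(array(0.5, c(1, 1, 1)), matrix(1), srate = 100)
#' spectral_set(m, c(10, 25))
#' @export
var_model <- function(coeffs, noise_cov, srate, n_obs = 1000L) {
  if (length(dim(coeffs)) != 3L || dim(coeffs)[1] != dim(coeffs)[2] ||
      dim(coeffs)[1] != nrow(noise_cov))
    stop("`coeffs` must be an M x M x p array matching `noise_cov`", call. = FALSE)
  new_var_model(dim(coeffs)[3], coeffs, noise_cov, srate, as.integer(n_obs),
                method = "explicit")
}

#' @export
print.var_model <- function(x, ...) {
  cat(sprintf("<var_model> order %d, %d channel(s), %d observation(s), method %s\n",
              x$order, nrow(x$noise_cov), x$n_obs, x$method))
  cat(sprintf("  companion spectral radius: %.4f\n", companion_radius(x$coeffs)))
  invisible(x)
}

# Stacked lag design, pooled over trials; rows never cross trial
# boundaries. Column (k-1)*M + j holds channel j at lag k.
build_design <- function(x, p) {
  d <- dim(x)
  M <- d[1]; N <- d[2]; Tt <- d[3]
  rows <- N - p
  X <- matrix(0, rows * Tt, p * M)
  Y <- matrix(0, rows * Tt, M)
  for (tr in seq_len(Tt)) {
    E <- stats::embed(t(matrix(x[, , tr], M, N)), p + 1L)
    rr <- ((tr - 1L) * rows + 1L):(tr * rows)
    Y[rr, ] <- E[, seq_len(M), drop = FALSE]
    if (p > 0L) X[rr, ] <- E[, -seq_len(M), drop = FALSE]
  }
  list(X = X, Y = Y)
}

#' Fit a multivariate autoregressive model
#'
#' Fits `y_t = sum_k A_k y_(t-k) + e_t` on one analysis window, pooling
#' trials as independent realizations (no regression row straddles a trial
#' boundary). Coefficient orientation is `A_k[i, j]`: influence of source
#' channel `j` at lag `k` on sink channel `i`. The innovation covariance
#' uses the degrees-of-freedom corrected denominator `n_obs - p * M`.
#'
#' `method = "ols"` solves the pooled least-squares problem directly.
#' `method = "vieira_morf"` runs the multichannel Vieira-Morf lattice
#' (geometric-mean normalized reflection coefficients, pooled over trials)
#' and returns the same output contract; it is often better conditioned on
#' short windows. Data are assumed zero-mean; apply [detrend()] first.
#'
#' @param window An [epoched_ts()] (one analysis window).
#' @param order Model order `p >= 0` (lags).
#' @param method `"ols"` or `"vieira_morf"` (alias `"viera_morf"`).
#' @return A `var_model`: fields `order`, `coeffs` (`M x M x p` array),
#'   `noise_cov`, `srate`, `n_obs`, plus the pooled regressor
#'   cross-product `xtx` used by [analytic_test()].
#' @examples
#' ts <- simulate_var(preset_scenarios()$chain3)$ts
#' fit_var(ts, order = 2)
#' @export
fit_var <- function(window, order, method = c("ols", "vieira_morf", "viera_morf")) {
  assert_ets(window, "window")
  method <- match.arg(method)
  if (method == "viera_morf") method <- "vieira_morf"
  if (!is.numeric(order) || length(order) != 1L || order != round(order) || order < 0)
    stop("`order` must be a single integer >= 0", call. = FALSE)
  p <- as.integer(order)
  d <- dim(window$data)
  M <- d[1]
  if (d[2] <= p)
    stop(sprintf("underdetermined model: %d samples per trial cannot support order %d",
                 d[2], p), call. = FALSE)
  n_obs <- d[3] * (d[2] - p)
  if (p > 0L && n_obs < p * M + 1L)
    stop(sprintf(
      "underdetermined model: %d pooled rows < %d regressors + 1", n_obs, p * M),
      call. = FALSE)
  de <- build_design(window$data, p)
  if (p == 0L) {
    Sig <- crossprod(de$Y) / n_obs
    return(new_var_model(0L, array(0, c(M, M, 0L)), Sig, window$srate, n_obs,
                         method, xtx = matrix(0, 0, 0),
                         channel_labels = window$channel_labels))
  }
  xtx <- crossprod(de$X)
  if (method == "ols") {
    qrX <- qr(de$X)
    if (qrX$rank < p * M)
      stop("underdetermined model: rank-deficient regressor matrix", call. = FALSE)
    B <- qr.coef(qrX, de$Y)
    A <- aperm(array(t(B), c(M, M, p)), c(1, 2, 3))
  } else {
    A <- vieira_morf_coeffs(window$data, p)
    B <- matrix(aperm(A, c(2, 3, 1)), nrow = p * M)  # undo orientation for residuals
  }
  resid <- de$Y - de$X %*% B
  df <- n_obs - p * M
  Sig <- crossprod(resid) / df
  new_var_model(p, A, Sig, window$srate, n_obs, method, xtx = xtx,
                channel_labels = window$channel_labels)
}

# Multichannel Vieira-Morf lattice, pooled across trials.
# Returns the M x M x p forward coefficient array (A[i,j,k]: j -> i, lag k).
vieira_morf_coeffs <- function(x, p) {
  d <- dim(x)
  M <- d[1]; N <- d[2]; Tt <- d[3]
  f <- lapply(seq_len(Tt), function(tr) matrix(x[, , tr], M, N))
  b <- f
  A <- vector("list", p)   # forward predictors at current stage
  Bc <- vector("list", p)  # backward predictors
  for (m in 0:(p - 1L)) {
    Pf <- matrix(0, M, M); Pb <- matrix(0, M, M); Dl <- matrix(0, M, M)
    tt <- (m + 2L):N
    for (tr in seq_len(Tt)) {
      Fm <- f[[tr]][, tt, drop = FALSE]
      Bm <- b[[tr]][, tt - 1L, drop = FALSE]
      Pf <- Pf + tcrossprod(Fm)
      Pb <- Pb + tcrossprod(Bm)
      Dl <- Dl + tcrossprod(Fm, Bm)
    }
    Lf <- t(chol((Pf + t(Pf)) / 2))
    Lb <- t(chol((Pb + t(Pb)) / 2))
    rho <- forwardsolve(Lf, t(forwardsolve(Lb, t(Dl))))
    Kf <- Lf %*% rho %*% solve(Lb)
    Kb <- Lb %*% t(rho) %*% solve(Lf)
    newA <- vector("list", m + 1L)
    newB <- vector("list", m + 1L)
    if (m > 0L) for (k in seq_len(m)) {
      newA[[k]] <- A[[k]] - Kf %*% Bc[[m + 1L - k]]
      newB[[k]] <- Bc[[k]] - Kb %*% A[[m + 1L - k]]
    }
    newA[[m + 1L]] <- Kf
    newB[[m + 1L]] <- Kb
    A <- newA; Bc <- newB
    for (tr in seq_len(Tt)) {
      Fm <- f[[tr]][, tt, drop = FALSE]
      Bm <- b[[tr]][, tt - 1L, drop = FALSE]
      fn <- matrix(NA_real_, M, N); bn <- matrix(NA_real_, M, N)
      fn[, tt] <- Fm - Kf %*% Bm
      bn[, tt] <- Bm - Kb %*% Fm
      f[[tr]] <- fn; b[[tr]] <- bn
    }
  }
  out <- array(0, c(M, M, p))
  for (k in seq_len(p)) out[, , k] <- A[[k]]
  out
}

# Companion matrix of an M x M x p coefficient array.
companion_matrix <- function(coeffs) {
  M <- dim(coeffs)[1]; p <- dim(coeffs)[3]
  if (p == 0L) return(matrix(0, M, M))
  C <- matrix(0, M * p, M * p)
  for (k in seq_len(p)) C[1:M, ((k - 1) * M + 1):(k * M)] <- coeffs[, , k]
  if (p > 1L) C[(M + 1):(M * p), 1:(M * (p - 1))] <- diag(M * (p - 1))
  C
}

companion_radius <- function(coeffs) {
  if (dim(coeffs)[3] == 0L) return(0)
  max(Mod(eigen(companion_matrix(coeffs), only.values = TRUE)$values))
}

#' Select the VAR model order by information criterion
#'
#' Fits every order in `p_range` by OLS and evaluates
#' `log det(Sigma_ML) + penalty * p * M^2 / n`, with penalty 2 (`aic`),
#' `log n` (`bic`) or `2 log log n` (`hq`). Ties break toward the smaller
#' order.
#'
#' @param window An [epoched_ts()].
#' @param p_range Integer vector `c(p_min, p_max)`, `p_min >= 0`.
#' @param criterion `"aic"`, `"bic"` or `"hq"`.
#' @return `list(order = p_opt, curve = named numeric criterion values)`.
#' @export
select_order <- function(window, p_range, criterion = c("bic", "aic", "hq")) {
  assert_ets(window, "window")
  criterion <- match.arg(criterion)
  if (length(p_range) != 2L || any(p_range != round(p_range)) ||
      p_range[1] < 0 || p_range[2] < p_range[1])
    stop("`p_range` must be c(p_min, p_max) with 0 <= p_min <= p_max", call. = FALSE)
  ps <- seq.int(p_range[1], p_range[2])
  M <- n_channels(window)
  curve <- vapply(ps, function(p) {
    fit <- fit_var(window, p, method = "ols")
    n <- fit$n_obs
    # ML (undivided-df) innovation covariance for the criterion
    sig_ml <- fit$noise_cov * (n - p * M) / n
    pen <- switch(criterion, aic = 2, bic = log(n), hq = 2 * log(log(n)))
    ld <- determinant(sig_ml, logarithm = TRUE)
    if (ld$sign <= 0) return(Inf)
    as.numeric(ld$modulus) + pen * p * M^2 / n
  }, 0)
  names(curve) <- as.character(ps)
  list(order = ps[which.min(curve)], curve = curve)
}

#' Validate a fitted VAR model
#'
#' Computes (i) stability: the companion-matrix spectral radius (stable iff
#' < 1); (ii) residual whiteness: a multivariate portmanteau chi-squared
#' test on residual autocorrelations up to lag `min(20, n_samples/4)`;
#' (iii) percent consistency: how much of the data's correlation structure
#' (auto/cross covariances up to lag `p`) is reproduced by data simulated
#' from the fitted model.
#'
#' @param model A `var_model` from [fit_var()].
#' @param window The [epoched_ts()] the model was fitted on.
#' @param seed Seed for the consistency simulation (fixed default keeps the
#'   diagnostic deterministic).
#' @return `list(is_stable, spectral_radius, whiteness_pvalue, consistency_pct)`.
#' @export
validate_model <- function(model, window, seed = 1L) {
  stopifnot(inherits(model, "var_model"))
  assert_ets(window, "window")
  d <- dim(window$data)
  M <- d[1]
  if (M != nrow(model$noise_cov))
    stop("model and window disagree in channel count", call. = FALSE)
  radius <- companion_radius(model$coeffs)
  p <- model$order
  de <- build_design(window$data, p)
  B <- if (p > 0L) matrix(aperm(model$coeffs, c(2, 3, 1)), nrow = p * M) else NULL
  resid <- if (p > 0L) de$Y - de$X %*% B else de$Y
  # portmanteau: pooled residual autocovariances within trials
  rows <- d[2] - p
  h <- max(p + 1L, min(20L, floor(d[2] / 4)))
  n_tot <- nrow(resid)
  C0 <- crossprod(resid) / n_tot
  C0i <- solve(C0)
  Q <- 0
  for (k in seq_len(h)) {
    Ck <- matrix(0, M, M)
    for (tr in seq_len(d[3])) {
      rr <- ((tr - 1L) * rows + 1L):(tr * rows)
      E <- resid[rr, , drop = FALSE]
      if (rows > k) Ck <- Ck + crossprod(E[(k + 1):rows, , drop = FALSE],
                                         E[1:(rows - k), , drop = FALSE])
    }
    Ck <- Ck / n_tot
    Q <- Q + sum(diag(t(Ck) %*% C0i %*% Ck %*% C0i)) / (n_tot - k)
  }
  Q <- Q * n_tot^2
  df <- M^2 * (h - p)
  whiteness_p <- if (df > 0) stats::pchisq(Q, df, lower.tail = FALSE) else NA_real_
  # percent consistency (simulate same-shape data from the model)
  consistency <- local({
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    sim <- simulate_var_core(model$coeffs, model$noise_cov, d[2], d[3],
                             burn_in = 500L)
    rd <- stacked_autocov(window$data, p)
    rs <- stacked_autocov(sim, p)
    100 * (1 - sqrt(sum((rs - rd)^2)) / sqrt(sum(rd^2)))
  })
  list(is_stable = radius < 1, spectral_radius = radius,
       whiteness_pvalue = whiteness_p,
       consistency_pct = min(consistency, 100))
}

# Vector of pooled auto/cross-covariances at lags 0..p (consistency check).
stacked_autocov <- function(x, p) {
  d <- dim(x)
  out <- NULL
  for (k in 0:max(p, 1L)) {
    Ck <- matrix(0, d[1], d[1])
    for (tr in seq_len(d[3])) {
      A <- matrix(x[, , tr], d[1], d[2])
      n <- d[2]
      Ck <- Ck + tcrossprod(A[, (k + 1):n, drop = FALSE], A[, 1:(n - k), drop = FALSE]) / n
    }
    out <- c(out, as.vector(Ck / d[3]))
  }
  out
}
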