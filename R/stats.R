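#' Phase-randomization surrogate data
#'
#' For every channel and trial the series is Fourier transformed, the
#' amplitude spectrum is kept exactly, and the phases of all
#' non-DC/non-Nyquist bins are replaced by i.i.d. uniform(-pi, pi) draws,
#' independently across channels; Hermitian symmetry is enforced before
#' the inverse transform, so the output is real. Randomizing phases
#' independently per channel destroys all cross-channel dependence while
#' preserving each channel's autospectrum (and, by Parseval, its sample
#' power) -- the null hypothesis of the surrogate tests.
#'
#' @param ts An [epoched_ts()] with at least 4 samples.
#' @param seed Optional RNG seed (same seed, same surrogate).
#' @return An `epoched_ts` of identical shape.
#' @export
phase_surrogate <- function(ts, seed = NULL) {
  assert_ets(ts)
  N <- n_samples(ts)
  if (N < 4L) stop("phase randomization needs at least 4 samples", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  d <- dim(ts$data)
  m <- matrix(aperm(ts$data, c(2, 1, 3)), nrow = N)
  F <- stats::mvfft(m)
  idx <- 2:ceiling(N / 2)  # bins with a conjugate partner (DC/Nyquist excluded)
  ph <- matrix(stats::runif(length(idx) * ncol(m), -pi, pi), length(idx))
  F[idx, ] <- Mod(F[idx, ]) * exp(1i * ph)
  F[N + 2L - idx, ] <- Conj(F[idx, ])
  out <- Re(stats::mvfft(F, inverse = TRUE)) / N
  ets_replace(ts, aperm(array(out, c(N, d[1], d[3])), c(2, 1, 3)))
}

#' Build a fit-and-measure pipeline closure
#'
#' Packages the estimation settings into a function `ts -> connectivity
#' result` so resampling tests apply *identical* settings to observed and
#' null datasets.
#'
#' @inheritParams connectivity
#' @param measure One registry measure name, or `"gc_time"` /
#'   `"ggc_spectral"`.
#' @return A function of one `epoched_ts` argument returning a
#'   `connectivity_result`.
#' @export
make_pipeline <- function(measure, order, freqs = NULL, window = NULL,
                          method = "ols") {
  force(measure); force(order); force(freqs); force(window); force(method)
  if (measure == "gc_time")
    return(function(ts) gc_time(ts, order, method = method))
  if (measure == "ggc_spectral")
    return(function(ts) ggc_spectral(ts, order,
                                     freqs %||% default_freqs(ts$srate),
                                     method = method))
  function(ts)
    connectivity(ts, order = order, measures = measure,
                 freqs = freqs %||% default_freqs(ts$srate),
                 window = window, method = method)[[measure]]
}

#' @keywords internal
new_stat_result <- function(observed, pvalues, qvalues, mask, method,
                            null_samples = NULL, thresholds = NULL) {
  structure(list(observed = observed, pvalues = pvalues, qvalues = qvalues,
                 mask = mask, method = method, null_samples = null_samples,
                 thresholds = thresholds),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s: %d/%d cells significant at q <= %g\n",
              x$method$test, sum(x$mask, na.rm = TRUE), sum(!is.na(x$pvalues)),
              x$method$q))
  invisible(x)
}

#' Phase-randomization surrogate test
#'
#' Applies `pipeline` to the observed data and to `n_surrogates`
#' phase-randomized copies (see [phase_surrogate()]); the right-tail
#' p-value per (sink, source, frequency, window) cell uses the
#' finite-sample-valid `+1` convention `p = (1 + #{null >= observed}) /
#' (n_surrogates + 1)`, so it can never be 0. Diagonal cells are excluded.
#' FDR-adjusted q-values and the significance mask at `q` are attached.
#'
#' @param pipeline A function `epoched_ts -> connectivity_result`, e.g.
#'   from [make_pipeline()].
#' @param ts Observed [epoched_ts()].
#' @param n_surrogates Number of surrogates (>= 19).
#' @param seed RNG seed (the whole test is reproducible given it).
#' @param tail Only `"right"` is meaningful for nonnegative measures.
#' @param q FDR threshold for the mask.
#' @param mode FDR mode, see [fdr_correct()].
#' @param keep_null Keep the null samples array (memory-hungry).
#' @return A `stat_result`.
#' @export
surrogate_test <- function(pipeline, ts, n_surrogates = 199, seed = 1L,
                           tail = "right", q = 0.05, mode = "bh",
                           keep_null = FALSE) {
  assert_ets(ts)
  tail <- match.arg(tail, "right")
  if (n_surrogates < 19) stop("`n_surrogates` must be >= 19", call. = FALSE)
  obs <- pipeline(ts)
  set.seed(seed)
  exceed <- array(0L, dim(obs$values))
  null_samples <- if (keep_null)
    array(NA_real_, c(n_surrogates, dim(obs$values))) else NULL
  for (s in seq_len(n_surrogates)) {
    sv <- tryCatch(pipeline(phase_surrogate(ts))$values, error = function(e)
      stop(sprintf("pipeline failed on surrogate %d: %s", s, conditionMessage(e)),
           call. = FALSE))
    exceed <- exceed + (sv >= obs$values)
    if (keep_null) null_samples[s, , , , ] <- sv
  }
  p <- (1 + exceed) / (n_surrogates + 1)
  for (i in seq_len(dim(p)[1])) p[i, i, , ] <- NA_real_
  fc <- fdr_correct(p, q = q, mode = mode)
  new_stat_result(obs, p, fc$qvalues, fc$mask,
                  method = list(test = "surrogate", null = "independent per-channel phase randomization",
                                n_surrogates = n_surrogates, seed = seed,
                                tail = tail, q = q, mode = mode),
                  null_samples = null_samples)
}

#' Trial-bootstrap confidence bands
#'
#' Resamples trials with replacement, reapplies the pipeline, and returns
#' pointwise percentile intervals per cell.
#'
#' @inheritParams surrogate_test
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param level Interval level in (0, 1), e.g. 0.95.
#' @return A `confidence_bands` object: `lower`/`upper` arrays over the
#'   result index space, the point `estimate`, and `level`.
#' @export
bootstrap_ci <- function(pipeline, ts, n_boot = 199, level = 0.95, seed = 1L) {
  assert_ets(ts)
  if (n_trials(ts) < 2L)
    stop("bootstrap needs at least 2 trials", call. = FALSE)
  if (n_boot < 100) stop("`n_boot` must be >= 100", call. = FALSE)
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)", call. = FALSE)
  obs <- pipeline(ts)
  set.seed(seed)
  Tt <- n_trials(ts)
  boot <- array(NA_real_, c(n_boot, dim(obs$values)))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(Tt, Tt, replace = TRUE)
    tsb <- ets_replace(ts, ts$data[, , idx, drop = FALSE])
    boot[b, , , , ] <- pipeline(tsb)$values
  }
  a <- (1 - level) / 2
  qs <- apply(boot, c(2, 3, 4, 5), stats::quantile,
              probs = c(a, 1 - a), na.rm = TRUE, names = FALSE)
  structure(list(lower = array(qs[1, , , , ], dim(obs$values)),
                 upper = array(qs[2, , , , ], dim(obs$values)),
                 estimate = obs$values, level = level,
                 method = list(test = "bootstrap", n_boot = n_boot, seed = seed)),
            class = "confidence_bands")
}

#' Permutation test for a between-condition difference
#'
#' The statistic is `measure(a) - measure(b)` per cell; the null is built
#' by randomly reassigning trials to the two conditions (group sizes
#' preserved) and recomputing. Two-sided p-values use the `+1` convention.
#'
#' @inheritParams surrogate_test
#' @param ts_a,ts_b The two conditions (same channels and sampling rate).
#' @param n_perm Number of permutations (>= 19).
#' @return A `stat_result`; `observed` holds the difference.
#' @export
permutation_test <- function(pipeline, ts_a, ts_b, n_perm = 199, seed = 1L,
                             q = 0.05, mode = "bh") {
  assert_ets(ts_a, "ts_a"); assert_ets(ts_b, "ts_b")
  if (n_channels(ts_a) != n_channels(ts_b) ||
      n_samples(ts_a) != n_samples(ts_b) || ts_a$srate != ts_b$srate)
    stop("conditions disagree in channels, samples or sampling rate", call. = FALSE)
  if (n_perm < 19) stop("`n_perm` must be >= 19", call. = FALSE)
  stat_of <- function(a, b) pipeline(a)$values - pipeline(b)$values
  obs_cr <- pipeline(ts_a)
  obs <- obs_cr$values - pipeline(ts_b)$values
  na <- n_trials(ts_a)
  pool <- array(c(ts_a$data, ts_b$data),
                c(n_channels(ts_a), n_samples(ts_a), na + n_trials(ts_b)))
  set.seed(seed)
  exceed <- array(0L, dim(obs))
  for (s in seq_len(n_perm)) {
    lab <- sample.int(dim(pool)[3])
    pa <- ets_replace(ts_a, pool[, , lab[seq_len(na)], drop = FALSE])
    pb <- ets_replace(ts_b, pool[, , lab[-seq_len(na)], drop = FALSE])
    exceed <- exceed + (abs(stat_of(pa, pb)) >= abs(obs))
  }
  p <- (1 + exceed) / (n_perm + 1)
  fc <- fdr_correct(p, q = q, mode = mode)
  obs_cr$values <- obs
  obs_cr$measure <- paste0(obs_cr$measure, "_diff")
  new_stat_result(obs_cr, p, fc$qvalues, fc$mask,
                  method = list(test = "permutation", n_perm = n_perm,
                                seed = seed, tail = "two-sided", q = q,
                                mode = mode))
}

#' Asymptotic significance test for PDC and DTF
#'
#' Under the null of no connection `j -> i`, the real and imaginary parts
#' of the estimated spectral coefficient `Abar_ij(f)` (PDC) or transfer
#' entry `H_ij(f)` (DTF, via the delta method through `H = Abar^-1`) are
#' asymptotically zero-mean Gaussian with covariance obtained from the OLS
#' coefficient covariance `Sigma_ii (X'X)^-1`. The quadratic form of the
#' estimate against that covariance is chi-squared with degrees of freedom
#' equal to the covariance rank (2 in general, 1 where the two parts are
#' collinear, e.g. order-1 models). This is an asymptotic test: its
#' calibration is checked by simulation, not assumed.
#'
#' @param cr `connectivity_result` for the same measure/frequency grid
#'   (used for cell bookkeeping; may cover several windows).
#' @param model The fitted `var_model` (or list of per-window models, one
#'   per window of `cr`) with its `xtx` slot.
#' @param measure `"pdc"` or `"dtf"`.
#' @param alpha Test level used for the per-cell null thresholds.
#' @param q,mode FDR settings for the mask.
#' @return A `stat_result` with `thresholds` on the measure scale.
#' @export
analytic_test <- function(cr, model, measure = c("pdc", "dtf"), alpha = 0.05,
                          q = alpha, mode = "bh") {
  measure <- match.arg(measure)
  stopifnot(inherits(cr, "connectivity_result"))
  models <- if (inherits(model, "var_model")) list(model) else model
  stopifnot(all(vapply(models, inherits, TRUE, "var_model")))
  d <- dim(cr$values)
  if (length(models) != d[4])
    stop("need one fitted model per window of `cr`", call. = FALSE)
  p <- array(NA_real_, d)
  thr <- array(NA_real_, d)
  for (wi in seq_len(d[4])) {
    aw <- analytic_cells(models[[wi]], cr$freqs, measure, alpha)
    p[, , , wi] <- aw$p
    thr[, , , wi] <- aw$thr
  }
  fc <- fdr_correct(p, q = q, mode = mode)
  new_stat_result(cr, p, fc$qvalues, fc$mask,
                  method = list(test = "analytic", measure = measure,
                                alpha = alpha, q = q, mode = mode,
                                note = "asymptotic chi-squared on Re/Im quadratic form"),
                  thresholds = thr)
}

# Per-window analytic p-values and thresholds (M x M x nf).
analytic_cells <- function(model, freqs, measure, alpha) {
  if (is.null(model$xtx) || model$order < 1L)
    stop("analytic test needs a fitted model of order >= 1 with its `xtx`",
         call. = FALSE)
  M <- nrow(model$noise_cov); pord <- model$order
  G <- solve(model$xtx)
  ss <- spectral_set(model, freqs)
  nf <- length(freqs)
  pv <- array(NA_real_, c(M, M, nf))
  th <- array(NA_real_, c(M, M, nf))
  theta <- 2 * pi * freqs / model$srate
  for (fi in seq_len(nf)) {
    co <- cos(theta[fi] * seq_len(pord))
    si <- sin(theta[fi] * seq_len(pord))
    A2 <- Mod(ss$A_f[, , fi])^2
    H2 <- Mod(ss$H_f[, , fi])^2
    denom <- if (measure == "pdc") colSums(A2) else rowSums(H2)
    for (i in seq_len(M)) for (j in seq_len(M)) {
      if (i == j) next
      if (measure == "pdc") {
        idx <- (seq_len(pord) - 1L) * M + j
        W <- model$noise_cov[i, i] * G[idx, idx, drop = FALSE]
        # Abar_ij = -sum_k A_ij(k) e^{-i k theta}: Re = -a'co, Im = a'si
        C2 <- rbind(c(co %*% W %*% co, -co %*% W %*% si),
                    c(-si %*% W %*% co, si %*% W %*% si))
        x <- c(Re(ss$A_f[i, j, fi]), Im(ss$A_f[i, j, fi]))
        den <- denom[j]
      } else {
        # delta method: dH_ij = sum_{m,n,k} H_im H_nj e^{-i k theta} dA_mn(k)
        H <- ss$H_f[, , fi]
        Cc <- matrix(0i, pord * M, M)  # rows (k,n), cols m
        for (k in seq_len(pord)) {
          e <- exp(-1i * k * theta[fi])
          Cc[((k - 1) * M + 1):(k * M), ] <- e * outer(H[, j], H[i, ])
        }
        KA <- function(V) G %*% V %*% model$noise_cov  # (Sigma (x) G) action
        a <- Re(Cc); b <- Im(Cc)
        Ka <- KA(a); Kb <- KA(b)
        C2 <- rbind(c(sum(a * Ka), sum(a * Kb)),
                    c(sum(b * Ka), sum(b * Kb)))
        x <- c(Re(H[i, j]), Im(H[i, j]))
        den <- denom[i]
      }
      eg <- eigen((C2 + t(C2)) / 2, symmetric = TRUE)
      # directions carrying < 1% of the leading variance are dominated by
      # higher-order terms (Re/Im near-collinear, e.g. order-1 models):
      # folding them into the quadratic form makes the test conservative
      keep <- eg$values > max(eg$values) * 1e-2
      rk <- sum(keep)
      y <- crossprod(eg$vectors[, keep, drop = FALSE], x)
      qf <- sum(y^2 / eg$values[keep])
      pv[i, j, fi] <- stats::pchisq(qf, df = rk, lower.tail = FALSE)
      th[i, j, fi] <- stats::qchisq(1 - alpha, df = rk) * max(eg$values) / den
    }
  }
  list(p = pv, thr = th)
}

#' False discovery rate correction
#'
#' Benjamini-Hochberg (`"bh"`) or Benjamini-Yekutieli (`"by"`) step-up
#' adjustment of a p-value array (`NA` cells are passed through). The
#' default policy elsewhere in the package corrects across all (sink,
#' source, frequency, window) cells of a measure jointly.
#'
#' @param pvalues Numeric array/vector of p-values in `[0, 1]`.
#' @param q FDR threshold for the rejection mask.
#' @param mode `"bh"` or `"by"`.
#' @return `list(qvalues, mask)` with the input's shape.
#' @export
fdr_correct <- function(pvalues, q = 0.05, mode = c("bh", "by")) {
  mode <- match.arg(mode)
  pv <- as.vector(pvalues)
  if (any(pv < 0 | pv > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  qa <- stats::p.adjust(pv, method = toupper(mode))
  qvalues <- pvalues
  qvalues[] <- qa
  mask <- qvalues <= q
  mask[is.na(mask)] <- FALSE
  list(qvalues = qvalues, mask = mask)
}
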