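---
title: "Sliding-window MVAR effective connectivity: models, measures and statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sliding-window MVAR effective connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

varconn estimates *effective connectivity* — directed, frequency-resolved
influence between channels of a multichannel neural time series — from
sliding-window multivariate autoregressive (MVAR) models, and attaches
resampling and asymptotic significance statistics to every estimate. This
vignette is the package's methods account: the model and its assumptions,
the measures and their exact definitions, the statistical machinery, the
numerical choices, and what the bundled simulator does and does not
emulate.

## The model

An epoched dataset is a `channels x samples x trials` array with sampling
rate `srate` and an event-relative time axis (event at 0 s). Within one
analysis window the data are modeled as a stationary VAR(p) process

    y_t = A_1 y_(t-1) + ... + A_p y_(t-p) + e_t,   e_t ~ N(0, Sigma)

with the orientation convention `A_k[i, j]`: influence of *source* channel
`j` at lag `k` on *sink* channel `i`. This convention is used everywhere —
connectivity arrays are always indexed `[sink, source, frequency,
window]` — and is pinned by a unidirectional-simulation test, because a
silent transpose is the classic failure mode of connectivity code.

Estimation pools trials as independent realizations of the same process:
lagged regression rows are built per trial and stacked, so no row ever
straddles a trial boundary. Two estimators share one output contract:

* **OLS**: direct least squares on the pooled lag-stacked design.
* **Vieira–Morf lattice** (`method = "vieira_morf"`): the multichannel
  Levinson recursion with geometric-mean normalized reflection
  coefficients, pooled across trials; often better conditioned on short
  windows. Its coefficients feed the same residual computation, so
  `noise_cov` has an identical definition for both.

The innovation covariance uses the degrees-of-freedom corrected
denominator `n_obs - p*M` (`n_obs` pooled rows, `M` channels), which keeps
small-window estimates unbiased. No intercept is fitted: data are assumed
zero-mean per window, which is what `detrend()` is for.

Assumptions to keep in mind: linearity, Gaussian innovations, and *local*
stationarity — the sliding-window approach models transient dynamics by
assuming stationarity only within each window (0.3–1 s windows are
typical at EEG sampling rates). Order selection (`select_order()`) uses
`log det(Sigma_ML) + penalty * p * M^2 / n` with AIC/BIC/HQ penalties and
breaks ties toward the smaller order. Model quality is reported by
`validate_model()`: companion-matrix stability, a multivariate portmanteau
whiteness test on residual autocorrelations (lags up to `min(20,
n_samples/4)`), and percent consistency — how much of the data's
auto/cross-covariance structure (lags 0..p) is reproduced by data
simulated from the fitted model.

## From coefficients to connectivity

All frequency-domain measures derive from the Fourier transform of the
coefficient matrices,

    Abar(f) = I - sum_k A_k exp(-i 2 pi f k / srate)
    H(f)    = Abar(f)^-1                  (transfer matrix)
    S(f)    = H(f) Sigma H(f)^H           (spectral matrix)
    P(f)    = S(f)^-1                     (inverse spectral matrix)

computed by `spectral_set()` on a grid inside `(0, srate/2]`. DC is
excluded from the default grid (1 Hz steps from 1 Hz to Nyquist − 1)
because `Abar(0)` approaches singularity for near-unit-root processes.
`P(f)` is only formed while `S(f)` has condition number below 1e12;
beyond that the inverse-spectral measures raise a conditioning error
rather than returning noise.

The registry (`measure_registry()`, 17 names) uses the canonical
literature definitions, frozen here so tests are unambiguous:

| measure | definition | normalization |
|---|---|---|
| `power` | `Re S_ii(f)` on the diagonal, `abs(S_ij)` off it | — |
| `coherence` | `abs(S_ij)^2 / (S_ii S_jj)` | in [0, 1] |
| `partial_coherence` | `abs(P_ij)^2 / (P_ii P_jj)` | in [0, 1] |
| `multiple_coherence` | `1 - 1/(S_ii P_ii)` (diagonal) | in [0, 1] |
| `dtf` | `abs(H_ij)^2 / sum_m abs(H_im)^2` | sink rows sum to 1 |
| `ffdtf` | `abs(H_ij(f))^2 / sum_f sum_m abs(H_im)^2` | sink grand sum 1 |
| `ddtf` | `ffdtf * partial_coherence` | in [0, 1] |
| `pdc` | `abs(Abar_ij)^2 / sum_m abs(Abar_mj)^2` | source columns sum to 1 |
| `gpdc` | PDC with `1/sigma_ii^2` row weights | scale-invariant |

plus magnitude (`_mag`) and unnormalized (`_unnorm`, `pdc_factor`)
variants, the cross-spectrum and the imaginary coherence. Squared forms
are the defaults because they carry the normalization identities (tested
to 1e-10 over random stable models). DTF measures *inflow-normalized
total* influence (direct + cascaded); PDC measures *outflow-normalized
direct* influence; dDTF multiplies the full-frequency DTF by the partial
coherence specifically to suppress indirect cascade pathways (the
`chain3` scenario demonstrates this: the spurious `1 -> 3` path is
demoted relative to the true edges).

Granger causality is provided in both domains. `gc_time()` is
conditional: the reduced model omits only the source channel's lags and
keeps all others, `GC(j->i) = ln(Sigma_r[i,i] / Sigma_f[i,i])`.
`ggc_spectral()` is deliberately *pairwise* (a bivariate model is refit
per channel pair) and evaluates Geweke's decomposition

    f(j->i)(f) = ln[ S_ii(f) / (S_ii(f) - (Sigma_jj - Sigma_ij^2/Sigma_ii) |H_ij(f)|^2) ]

whose conditional-variance term absorbs the innovation-correlation
rotation; its band average approximates the pairwise time-domain GC
(tested to within 10% on long data). Tiny negative values arising from
sampling noise are clipped to zero and counted.

`graph_measures()` reduces a directed measure to node summaries per
window after band-averaging: outflow (column sums off the diagonal),
inflow (row sums), the asymmetry ratio `(out - in)/(out + in)` (+1 pure
source, −1 pure sink, defined as 0 when both flows vanish), and the
network's causal density.

## Statistics

**Phase-randomization surrogates.** `phase_surrogate()` Fourier-transforms
every channel/trial series, keeps amplitudes exactly, replaces the phases
of all conjugate-paired bins by i.i.d. uniform(−π, π) draws *independently
across channels* (DC and Nyquist stay real), and inverts. This destroys
all cross-channel dependence while preserving each channel's autospectrum
and, by Parseval, its sample power — the null of "no coupling". Published
descriptions of this family leave the exact multichannel variant open;
independent-per-channel randomization is this package's documented choice
and is recorded in `StatResult$method`. `surrogate_test()` applies the
*identical* fit-and-measure pipeline to the data and to `n` surrogates and
uses the finite-sample-valid p-value `(1 + #exceedances)/(n + 1)`, which
can never be zero; FDR-corrected q-values and a significance mask are
attached.

**Known calibration limit.** Circular phase randomization replaces linear
by circular autocorrelation. For short windows of strongly autocorrelated
signals (e.g. 1 s of an `r = 0.9` oscillator at 128 Hz) the circular
surrogate ensemble slightly under-disperses the cross-channel sampling
variability, so the test is mildly anti-conservative: in the package's
own null calibration (three independent oscillators, 20 trials, 99
surrogates, 200 runs) per-cell type-I rates at α = 0.05 ranged from 0.02
to 0.175 (mean 0.064), while the same experiment with 4 s trials put
every cell in 0.03–0.07. Treat surrogate p-values from windows much
shorter than ~10 cycles of the slowest rhythm as approximate, or use the
permutation/analytic routes. This behaviour is measured, not hidden: the
acceptance checks report it.

**Bootstrap and permutation.** `bootstrap_ci()` resamples trials with
replacement and returns pointwise percentile bands (coverage checked by
simulation: 0.87–0.99 at the 95% level in the bundled experiment).
`permutation_test()` compares two conditions by `measure(a) − measure(b)`
with trial labels reshuffled (group sizes preserved) and two-sided `+1`
p-values; the statistic is exactly antisymmetric under label swap.

**Analytic tests.** For PDC and DTF, the real and imaginary parts of the
estimated `Abar_ij(f)` (PDC; linear in the coefficients) or `H_ij(f)`
(DTF; delta method through `H = Abar^-1`) are asymptotically Gaussian
with covariance propagated from the OLS covariance `Sigma_ii (X'X)^-1`.
The test statistic is the quadratic form of the estimate against that 2×2
covariance, referred to chi-squared with df equal to the covariance rank.
Numerical choice: eigendirections carrying less than 1% of the leading
eigenvalue are dropped from the form (rank-adaptive df). The two parts
are near-collinear in low-order models (exactly collinear at p = 1), and
folding the collapsed direction — which is dominated by higher-order
noise — into a df = 2 form makes the test several-fold conservative;
with the 1% cut the measured null rejection rate at α = 0.05 is
0.037–0.07 across order-1/2 scenarios. The test is asymptotic; its
calibration is verified by simulation in the test suite, not assumed.

**FDR.** `fdr_correct()` wraps the standard Benjamini–Hochberg and
Benjamini–Yekutieli step-up adjustments (via `p.adjust`) and is checked
against an independently coded step-up oracle. The default policy
corrects across all (sink, source, frequency, window) cells of a measure
jointly.

## The simulator

`simulation_spec()`/`simulate_var()` generate ground-truth VAR data: a
stable time-invariant base (stability of the companion matrix is enforced
at every instant, checked by `check_stability()`), plus directed
couplings optionally gated by boxcar or Hann envelopes inside the epoch —
the locally-stationary regime the sliding-window estimator exists for.
Innovations are Gaussian, matching the linear-Gaussian assumptions of the
GC framework; burn-in (default 1000 samples, ample for pole radii up to
0.98) is discarded per trial. Every run returns the boolean ground-truth
graph aligned with the epoch.

The presets define the package's standing study conditions and were fixed
once, a priori: `uncoupled3` (independent 5/10/18 Hz damped oscillators,
1 s epochs, 20 trials — the null scenario), `chain3` (`x1 -> x2 -> x3`,
couplings 0.5 at lag 1, 100 trials — power and indirect-path scenario),
`transient_theta` (two 5 Hz oscillators, one coupling under a 300 ms Hann
envelope at 0.1–0.4 s — the event-related transient scenario; windows
straddling the envelope edges legitimately fit unstable local stationary
approximations and trigger the instability warning), and
`bidirectional2` (equal symmetric coupling — zero asymmetry scenario).

What the simulator does *not* emulate: volume conduction and mixing
(inputs are assumed source-separated upstream, e.g. by ICA), nonlinearity,
non-Gaussian innovations, measurement noise, and inter-subject
variability. Passing tests therefore demonstrate estimator correctness on
the model class the method assumes, not robustness to real-EEG model
violations.

## Numerical and design choices

* Windows are onset-anchored; a trailing partial window is dropped, never
  zero-padded (padding would corrupt the local model). Window identity is
  its center latency in seconds.
* Ensemble normalization uses the unbiased (n−1) standard deviation and
  names the offending channel/sample on zero-variance input. Temporal and
  ensemble modes are both provided; the pipeline default applies temporal
  then ensemble, a documented choice where practice varies.
* Anti-alias filtering for `downsample()` is a zero-phase
  forward–backward order-8 Chebyshev-I low-pass at 0.8 × the new Nyquist
  (≥ 40 dB effective stopband after the double pass); `factor = 1` is a
  bit-exact identity.
* `fit_var` refuses underdetermined problems (`n_obs < p*M + 1`, or
  rank-deficient designs) instead of silently regularizing.
* Spectral conditioning: inverse-spectral measures error beyond condition
  number 1e12; unstable models produce a warning (their "spectrum" is not
  a stationary spectrum) but not an error, since windowed fits near
  nonstationary transitions cross that line by design.
* Serialization: results travel between CLI stages in a tagged RDS
  container (`vc_write()`/`vc_read()`); exports for downstream tools are
  plain TSV (per-pair time × frequency grids, long format) plus a JSON
  manifest echoing config, seeds, package version and per-window
  diagnostics. Reruns with identical config and seeds are byte-identical.
* Problem sizes in the test suite are chosen to make each property
  decisive yet quick: oracle and identity checks run on toy/random models
  in milliseconds; parameter recovery uses 200 trials × 500 samples
  (100k pooled rows, sampling error ≈ 0.003 per coefficient against the
  ±0.03 assertion); Monte-Carlo calibrations use 60–200 seeded runs.

## Known limitations

Sliding-window MVAR assumes enough samples per window for `p*M^2`
parameters; very short windows need the lattice estimator and low orders.
The surrogate test's short-window anti-conservativeness is quantified
above. The analytic tests are asymptotic. Conditional *spectral* GC,
Kalman/state-space adaptive estimation, regularized VAR, transfer entropy
and phase-amplitude coupling are out of scope; the registry's enumeration
of measures is this package's own.
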