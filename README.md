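# varconn

Sliding-window MVAR effective connectivity for multichannel neural time
series.

`varconn` is for researchers who have epoched multichannel recordings —
EEG/MEG source or channel activities, ECoG, LFPs — and want to know *who
drives whom, at which frequency, and when*. Undirected ("functional")
measures like correlation and coherence cannot answer that; `varconn`
implements the Granger-causal toolchain: a process A Granger-causes B if
A's past improves the linear prediction of B beyond B's own past.

The pipeline is the standard four-stage flow:

1. **Preprocess** — detrending, temporal/ensemble normalization,
   anti-aliased downsampling, sliding-window segmentation.
2. **Model** — per-window multivariate autoregressive (MVAR) fits pooled
   over trials, `y_t = Σ_k A_k y_(t−k) + e_t`, by OLS or the Vieira–Morf
   lattice, with order selection (AIC/BIC/HQ) and validation (stability,
   residual whiteness, percent consistency). From the Fourier transform
   `Ā(f) = I − Σ_k A_k e^(−i2πfk/srate)` come the transfer matrix
   `H = Ā⁻¹`, the spectral matrix `S = H Σ Hᴴ` and its inverse.
3. **Connectivity** — a 17-measure registry: spectral power,
   ordinary/partial/multiple coherences, the DTF family
   (`|H_ij|²/Σ_m|H_im|²`, ffDTF, dDTF = ffDTF × partial coherence), the
   PDC family (`|Ā_ij|²/Σ_m|Ā_mj|²`, GPDC), plus time-domain conditional
   and Geweke spectral Granger causality. Everything is indexed
   `[sink, source, frequency, window]`.
4. **Statistics & export** — phase-randomization surrogates, trial
   bootstrap, permutation tests between conditions, asymptotic
   chi-squared tests for DTF/PDC, all with BH/BY false-discovery-rate
   control; node-level graph summaries (outflow, inflow, asymmetry
   ratio); TSV/JSON exports and a deterministic, manifest-carrying
   command-line pipeline.

A seeded VAR simulator with known causal graphs (stationary chains,
symmetric pairs, and transient Hann-windowed couplings) provides ground
truth for every estimator and drives the test suite.

## Worked example

Simulate the bundled causal chain `x1 → x2 → x3` (damped 10 Hz
oscillators, couplings 0.5 at lag 1, 100 trials), fit one MVAR model and
estimate directed flow:

```r
library(varconn)
sim <- simulate_var(preset_scenarios()$chain3, seed = 1)
m   <- fit_var(sim$ts, order = 2)
round(m$coeffs[, , 1], 3)
#        [,1]   [,2]   [,3]
# [1,]  1.669 -0.005 -0.006
# [2,]  0.495  1.228 -0.011
# [3,] -0.004  0.501  1.230
```

The lag-1 coefficients recover the generative structure: the diagonal
holds each oscillator's own dynamics, and the two couplings (truth 0.5)
appear at `[2,1]` and `[3,2]` — row = sink, column = source.

```r
crs <- connectivity(sim$ts, order = 2, measures = c("dtf", "ddtf"),
                    freqs = c(5, 10, 20))
round(crs$dtf$values[, , 2, 1], 3)   # DTF at 10 Hz
#      source
# sink    ch1   ch2   ch3
#   ch1 1.000 0.000 0.000
#   ch2 0.990 0.009 0.000
#   ch3 0.987 0.009 0.004
round(crs$ddtf$values[, , 2, 1], 3)  # dDTF at 10 Hz
#      source
# sink    ch1   ch2   ch3
#   ch1 0.929 0.000 0.000
#   ch2 0.191 0.009 0.000
#   ch3 0.000 0.007 0.003
```

DTF reports *total* (direct + cascaded) inflow, so `ch3` appears driven
by `ch1` (0.987) through the chain; dDTF multiplies by the partial
coherence and correctly zeroes the indirect `1 → 3` path while keeping
the true edges. Node summaries make the roles explicit:

```r
graph_measures(crs$dtf, band = c(5, 20))$nodes
#   window_center node outflow  inflow asymmetry_ratio
# 1           0.5  ch1 1.45268 0.00026            1.00
# 2           0.5  ch2 0.14678 0.75997           -0.68
# 3           0.5  ch3 0.00042 0.83967           -1.00
```

`ch1` is a pure causal source (+1), `ch3` a pure sink (−1). Significance
via phase-randomization surrogates (p-values use the never-zero `+1`
convention; q-values are BH-corrected):

```r
pl <- make_pipeline("dtf", order = 2, freqs = c(5, 10, 20))
st <- surrogate_test(pl, sim$ts, n_surrogates = 99, seed = 2)
round(st$pvalues[, , 2, 1], 3)       # at 10 Hz
#      source
# sink   ch1  ch2  ch3
#   ch1   NA 0.98 0.53
#   ch2 0.01   NA 0.82
#   ch3 0.01 0.66   NA
```

The chain's inflow from `ch1` is significant at the driving frequency;
reverse and absent connections are not.

The same flow runs from the shell:

```sh
Rscript inst/cli/varconn.R simulate --preset chain3 --seed 1 --out sim.vc.rds
Rscript inst/cli/varconn.R fit      --in sim.vc.rds --order 2 --out models.vc.rds
Rscript inst/cli/varconn.R connect  --in models.vc.rds --measures dtf,ddtf \
                                    --freqs 5,10,20 --out conn.vc.rds
Rscript inst/cli/varconn.R graph    --in conn.vc.rds --band 5,20 --out graph.tsv
```

or end-to-end from a JSON config with `run` (see
`Rscript inst/cli/varconn.R config` for the full default configuration).

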