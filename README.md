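# nedp — nearly exact discrepancy principle for Poisson image restoration

Restoring a blurred, photon-limited image means solving

    x̂(μ) = argmin_{x ≥ 0}  TV(x) + μ · KL(Hx + b; y)

where `y` are Poisson counts with mean `λ̄ = H x̄ + b`, `TV` is isotropic
total variation, and `KL(λ; y) = Σ_i F(λ_i; y_i)` with
`F(λ; y) = λ − y ln λ + y ln y − y` is the generalized Kullback–Leibler
fidelity (the Poisson negative log-likelihood up to constants). Everything
hinges on the regularization parameter `μ`. The classical *discrepancy
principle* chooses `μ` so that the fidelity at the restored image equals a
target `Δ`; the standard choice `Δ = m/2` (for `m` pixels) comes from a
series truncation of the expected fidelity `δ(E)(λ) = E[F(Y_λ)]` that is
valid only as `λ → ∞` — at low photon counts it is off by ~10% and the
restorations over- or under-smooth badly.

This package is for people restoring low-count Poisson images
(fluorescence microscopy, emission tomography, astronomy) who want `μ`
selected automatically and reliably across count regimes. It provides:

* **Exact series analysis** (`centralMoment`, `momentRatioPoly`,
  `seriesCoefficients`, `convergenceProbability`): Poisson central moments
  and the truncated expansion
  `δ(E)(λ) ≈ Σ γ_i^(N) λ^(−i)` in exact rational arithmetic, showing that
  the coefficient sequence grows and the series diverges for `λ ≤ 1` —
  the constant target cannot be fixed by taking more terms.
* **Monte Carlo calibration** (`simulateCalibration`, `fitCorrection`):
  sample means and variances of `F(Y_λ)` on a 1385-point grid
  `λ ∈ [0, 250]`, and a multistart inverse-variance-weighted
  Levenberg–Marquardt fit of the rational correction
  `δ(NE)(λ) = 1/2 + (λ² + c₁λ + c₂)/(12λ³ + c₃λ² + c₄λ − 2c₂)`,
  with the frozen reference vector `ĉ = (+2.5792, −1.5205, −5.6244,
  +17.9347)` available as `referenceFitParams()`.
* **DP-ADMM solver** (`dpRestore`): ADMM with closed-form subproblems
  (FFT solve, group shrinkage, projection, per-pixel fidelity formula)
  that re-selects `γ = μ/β_λ` at every iteration as the root of the
  discrepancy equation, under the approximate (`Δ = m/2`), theoretical
  (oracle) or nearly exact (`Δ(NE)(γ) = m/2 + Σ ε(λ_i(γ); ĉ)`) principle.
* **Synthetic data and metrics** (`makePhantom`, `degrade`, `isnr`,
  `ssim`) and an experiment driver (`runExperiment`), plus a thin CLI
  (`exec/nedp`) with `series`, `calibrate`, `simulate`, `restore`,
  `evaluate`, `experiment` subcommands.

## Worked example

```r
library(nedp)

## exact series table: the truncated expansion of E[F(Y_lambda)]
seriesCoefficients(4)
#> SeriesExpansion of order 4
#>   delta^(E)(lambda) ~ 1/2 + 1/12/lambda^1 + -29/12/lambda^2 + -1/4/lambda^3 + remainder

## low-count restoration benchmark
x   <- makePhantom("piecewise_constant", c(64, 64), seed = 1)
sim <- degrade(x, acquisitionSpec(kappa = 5, band = 5, sigma = 1, seed = 1))

res <- dpRestore(sim$y, sim$model, solverConfig("nearly_exact", maxIter = 400))
res
#> RestorationResult: 64x64 image, nearly_exact DP
#>   mu_hat = 2.037724 , iterations = 400 (max iterations)
isnr(restoredImage(res) / 5, x, 2e-3)   # 11.99566 dB
ssim(restoredImage(res) / 5, x)         # 0.7770189

resA <- dpRestore(sim$y, sim$model, solverConfig("approximate", maxIter = 400))
muHat(resA)                              # 0.09215875
isnr(restoredImage(resA) / 5, x, 2e-3)   # 3.671187 dB
```

At `κ = 5` (at most five expected photons per pixel) the nearly exact
principle selects `μ̂ ≈ 2.04` and gains about 12 dB over the degraded
input, while the classical constant target selects `μ̂ ≈ 0.09` — far too
much regularization — and gains only 3.7 dB. The per-iteration history of
`γ`, the discrepancy value and its target are in `solverTrace(res)`.

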