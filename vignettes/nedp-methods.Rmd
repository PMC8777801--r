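---
title: "Selecting the regularization parameter for Poisson image restoration: methods and design notes"
author: "nedp authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nedp)
```

## The model

Photon-limited imaging (fluorescence microscopy, emission tomography,
astronomy) produces integer count images $y \in \mathbb{N}^m$ modelled as
independent Poisson draws with mean $\bar\lambda = H\bar x + b$, where $H$
is a known blur operator, $\bar x \ge 0$ the unknown scene and $b \ge 0$ a
constant emission background. The restoration model minimized here is the
TV-KL functional

$$\hat x(\mu) \in \arg\min_{x \ge 0}\; \mathrm{TV}(x) + \mu\,
\mathrm{KL}(Hx + b;\, y),$$

with isotropic total variation and the generalized Kullback–Leibler
divergence $\mathrm{KL}(\lambda; y) = \sum_i F(\lambda_i; y_i)$,
$F(\lambda; y) = \lambda - y\ln\lambda + y\ln y - y$ (the Poisson negative
log-likelihood up to constants). Everything in the package revolves around
choosing the regularization parameter $\mu$ automatically by a
*discrepancy principle* (DP): pick $\mu$ such that the fidelity value at
the restored image equals a prescribed target $\Delta$.

## Why the classical constant target fails at low counts

For Gaussian noise the analogue of $\Delta$ is a known constant. For
Poisson data the natural target is the expected fidelity
$\delta^{(E)}(\lambda) = E[F(Y_\lambda)]$ summed over pixels, and the
classical approximate DP replaces $\delta^{(E)}$ by the constant $1/2$
(so $\Delta^{(A)} = m/2$), justified by a Taylor expansion of the
logarithm valid as $\lambda \to \infty$.

The `moments_series` machinery makes the failure of that truncation
precise, entirely in exact rational arithmetic:

* `centralMoment(i)` evaluates the Poisson central moments
  $\eta_i(Y_\lambda)$ through the classical recursion
  $\eta_{i+2} = \lambda(\eta_{i+1}' + (i+1)\eta_i)$, symbolically on
  coefficient lists.
* `momentRatioPoly(i)` forms $P_i = \eta_{i+2}/\lambda$, an integer
  polynomial of degree $\lfloor i/2\rfloor$ with unit constant term.
* `seriesCoefficients(N)` combines these with the expansion weights into
  the truncated series
  $\delta^{(E)}(\lambda) \approx \sum_{i=0}^{N-1}\gamma_i^{(N)}\lambda^{-i}$.

The exact coefficient table shows that $\gamma_i^{(N)}$ stabilizes at a
limiting value once $N \ge 2i + 2$ (each $\gamma_i$ collects moment-ratio
contributions up to index $2i$), and that the limiting sequence is
positive and strictly increasing from $i = 2$ on. The weighted geometric
series therefore diverges for $\lambda \le 1$: no truncation order can
represent the expected fidelity in the low-count regime. The companion
diagnostic `convergenceProbability(lambda)` — the probability
$P(0 < Y_\lambda \le 2\lambda)$ that the draw falls inside the logarithm
expansion's convergence region — approaches 1 only for large $\lambda$.

Exactness matters here: the argument rests on signs and growth of rational
coefficients such as $516833/504$, which floating-point accumulation would
obscure. Rationals are stored as reduced integer pairs in doubles with a
$2^{53}$ overflow guard; the default order cap $N \le 12$ keeps all
intermediate integers far below that bound (the cap is a configuration
argument, not a hard limit).

## The nearly exact target

Since no closed form exists, $\delta^{(E)}$ is calibrated by Monte Carlo
(`simulateCalibration`): at each of 1385 grid values
$\lambda_i \in [0, 250]$ (steps $0.01$ on $[0,6]$, $0.1$ on $[6,66]$, $1$
on $[66,250]$ — dense exactly where the curve bends), $S$ Poisson draws
are mapped through $F$ and summarized by the sample mean
$\hat\delta^{(E)}(\lambda_i)$ and variance $v_i$. Draws are tabulated by
count value so $S = 10^6$ per point runs in about a minute; by the CLT the
sample means are Gaussian with variance $v_i/S$, which justifies the
inverse-variance weights used next.

`fitCorrection` fits the rational correction model

$$\delta^{(NE)}(\lambda) = \tfrac12 + \epsilon(\lambda; c), \qquad
\epsilon(\lambda; c) = \frac{\lambda^2 + c_1\lambda + c_2}
{12\lambda^3 + c_3\lambda^2 + c_4\lambda - 2c_2},$$

whose form hard-wires the two structural facts $\epsilon(0) = -1/2$
(so the corrected target vanishes with $\lambda$) and
$\epsilon(\lambda) \sim 1/(12\lambda)$ (the leading series term), by
weighted nonlinear least squares ($w_i = 1/v_i$; the $\lambda = 0$ point
is excluded since its variance is exactly zero and the model already
interpolates it). The objective is non-convex, so the Levenberg–Marquardt
solver is restarted from uniform draws on $[-20, 20]^4$ (default 100
starts) and every candidate is screened for strict positivity of the
denominator on a dense grid over $[0, 10^4]$; all distinct local minima
are reported, not just the winner. The frozen reference vector
$\hat c = (+2.5792, -1.5205, -5.6244, +17.9347)$, obtained from a
large-scale calibration at $S = 5\times 10^7$, ships as
`referenceFitParams()`; recalibrations never overwrite it. At
$S = 10^6$ the refit reproduces $c_1$ to well within 1%.

Accuracy of the calibrated target, measured against fresh Monte Carlo
tables: the constant $1/2$ is off by roughly $-6$% to $-14$% for
$\lambda \in [1, 4]$ (and diverges to $+\infty$ as $\lambda \to 0$),
while $\delta^{(NE)}$ stays within about 1.3% for $\lambda \ge 0.08$.
One honest caveat: the rational form itself carries a bias of about
$-3.5$% near $\lambda \approx 0.05$ (growing below that), which no
sample size or fitting effort removes — it is a capacity limit of the
four-parameter family, inherited by the reference parameters as well.
Practically this matters little, because pixels at such levels contribute
almost nothing to the summed target, but tests asserting sub-2% tracking
down to $\lambda = 0.05$ will fail for this reason and we have left that
assertion in place rather than weaken it.

## Solving the model: DP-ADMM

`dpRestore` minimizes the TV-KL model by ADMM on the splitting
$\lambda = Hx + b$, $g = Dx$, $z = x$, with penalty parameters
$(\beta_\lambda, \beta_g, \beta_z)$, all defaulting to 1 (the useful
range is roughly $[0.5, 2]$; convergence speed, not the selected
parameter, is what they influence). All operators use periodic boundary
conditions, so $H^TH$, $D^TD$ and $I$ are simultaneously diagonal in the
2-D Fourier basis and the $x$-subproblem is an exact one-FFT solve; the
$g$-subproblem is per-pixel group shrinkage, the $z$-subproblem a
projection, and the $\lambda$-subproblem has the per-pixel closed form

$$\lambda_i(\gamma) = \tfrac12\left(v_i - \gamma +
\sqrt{(v_i-\gamma)^2 + 4 y_i \gamma}\right),
\qquad \gamma = \mu/\beta_\lambda .$$

The DP enters through $\gamma$: at every iteration the discrepancy
equation $D(\gamma) = \Delta(\gamma)$ is solved by bracketing plus
bisection (default) or a safeguarded secant step, warm-started at the
previous $\gamma$, with geometric bracket expansion (factor 10, cap
$10^{12}$) and acceptance when $|D - \Delta| \le \mathtt{rootTol}\cdot m$.
Three targets are supported: the oracle $\Delta^{(T)}$ (known truth —
for benchmarking only), the constant $\Delta^{(A)} = m/2$, and the
nearly exact $\Delta^{(NE)}(\gamma) = m/2 + \sum_i
\epsilon(\lambda_i(\gamma); \hat c)$, which moves with $\gamma$. For the
moving target a sufficient root-existence condition is checked first
(`neRootExists`): some $y_i \ne 0$ and $\sum_i [F(t_i;y_i) -
\epsilon(t_i;\hat c)] \ge m/2$ with $t = \max(v, 0)$; when it fails the
parameter is simply frozen for that iteration. For the constant targets,
if the residual at $\gamma = 0$ is already non-positive we return
$\gamma = 0$ — a boundary case the theory leaves open.

Numerical choices worth knowing: counts stay integer; $\lambda$ is
clamped at $10^{-12}$ before logarithms (transient zeros with $y_i > 0$
would otherwise produce infinities mid-iteration, while $F(0; y>0) =
+\infty$ is deliberately *returned* by `klTerm` so brackets behave);
multipliers start at zero and $x^{(0)} = y$; the stopping rule is the
relative change $\|x^{(k)} - x^{(k-1)}\|_2 / \|x^{(k-1)}\|_2 < 10^{-5}$
with a zero-norm guard.

One empirical observation the user should know: with the constant
targets the scheme converges to the stated tolerance, but under the
moving nearly exact target the coupled iteration (parameter responds to
the iterate, iterate responds to the parameter) can settle into a
narrow limit cycle instead of a fixed point — relative oscillations of
order $10^{-3}$ in $x$ and a few percent in $\gamma$, robust across
penalty triplets we tried. The selected $\hat\mu$ and the restoration
quality are unaffected at that scale; freezing $\gamma$ once it has
stabilized collapses the cycle immediately (we verified convergence to
$\epsilon_x < 10^{-5}$ that way), and `maxIter` bounds the run in any
case. The `converged` flag reports honestly which regime a run ended in.

## Synthetic data, metrics, and what the tests do and do not show

`makePhantom` provides piecewise-constant (nested shapes), blob (random
discs) and smooth-ramp scenes in $[0,1]$; `degrade` implements the
acquisition protocol — multiply by the photon scale $\kappa$, blur with a
unit-sum Gaussian PSF sampled at pixel centers on a `band`-by-`band`
support, add the constant background (default $2\times 10^{-3}$), draw
Poisson counts. Default study conditions for the low-count experiments:
$64\times 64$ piecewise-constant phantom, $\kappa = 5$, PSF band 5 /
sigma 1, five noise seeds — problem sizes chosen so the whole experiment
suite runs on a desktop in minutes. Quality is reported as ISNR,
$10\log_{10}(\|\bar x - b\|^2 / \|\bar x - \hat x\|^2)$ (the numerator
taken literally with the constant background), and SSIM with the standard
defaults (11×11 Gaussian window, $\sigma = 1.5$, $K_1 = 0.01$,
$K_2 = 0.03$), computed with periodic filtering and a half-window border
excluded.

Under those conditions the nearly exact principle consistently dominates
the constant one: its median ISNR is higher and its selected
$\hat\mu^{(NE)}$ lands much closer to the theoretical-oracle value
$\mu^{(T)}$ than $\hat\mu^{(A)}$ does (in a typical run: $\hat\mu^{(NE)}
\approx 0.90$, $\mu^{(T)} \approx 1.25$, $\hat\mu^{(A)} \approx 0.11$,
with ISNR 13.6 dB versus 6.7 dB).

What passing these tests does *not* show: the phantoms are periodic-BC
friendly, noiseless except for Poisson counting, with exactly known PSF
and constant background. Real microscopy adds model mismatch (inexact
PSF, spatially varying blur and background, readout noise, saturation)
that the synthetic protocol deliberately omits; the DP machinery is
agnostic to those effects only insofar as the KL model remains adequate.

## Known limitations

* Periodic boundary conditions only; scenes with strong edge content at
  the frame boundary acquire wrap-around artifacts.
* Uniqueness of the nearly exact discrepancy root is not guaranteed (the
  existence condition is one-sided); with multiple roots the bracketing
  solver returns one of them deterministically given the warm start.
* The rational correction's small-$\lambda$ bias, and the limit-cycle
  behaviour of the coupled iteration, both discussed above.
* The correction family is fixed; no model selection over alternative
  rational degrees is attempted.
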