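---
title: "Height distributions at a given diameter: models, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Height distributions at a given diameter: models, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdsde)
```

## The modelling problem

In inventory data a given breast-height diameter does not determine a tree's
height: stands differ in site quality, stocking and history, and trees
differ within a stand.  `hdsde` treats height at diameter $d$ as a random
variable $H(d)$ governed by a stochastic differential equation in $d$,

$$\mathrm{d}H(d) = a(d, H)\,\mathrm{d}d + b(d, H)\,\mathrm{d}W(d),
\qquad H(d_0) = 1.3\ \mathrm{m},$$

so that the whole conditional distribution of height — not only its mean —
is available in closed form at every diameter.  The initial condition is
structural: at the diameter origin a tree is exactly breast height
(1.3 m), where diameter measurement starts.  Between-stand variation enters
through a plot-level random effect $\phi_i \sim N(0, \sigma_\phi^2)$ added
to the growth-level parameter $\alpha$; within-stand variation enters
through the Brownian term scaled by $\sigma$.

Five drift/noise choices are implemented, drawn from the classical growth
laws.  Their transition laws conditional on the initial state are:

* **Vasicek** (`V`, Mitscherlich drift $\beta(\alpha + \phi - H)$, additive
  noise): $H(d) \sim N(\mu_V, \lambda_V^2)$ with
  $\mu_V = 1.3e^{-\beta d} + (\alpha+\phi)(1 - e^{-\beta d})$ and
  $\lambda_V^2 = \sigma^2 (1 - e^{-2\beta d}) / (2\beta)$.
* **Gompertz 3-parameter** (`G3`, multiplicative noise): $\log H(d)$ is an
  Ornstein–Uhlenbeck process,
  $\mu_{G3} = \log(1.3) e^{-\beta d} +
  (\alpha + \phi - \sigma^2/2)(1-e^{-\beta d})/\beta$, same
  $\lambda^2$ form as Vasicek.
* **Gompertz 4-parameter** (`G4`): as G3 on $\log(H - \gamma)$, a
  $\gamma$-shifted lognormal.  $\gamma$ is a threshold parameter; fitted
  values are typically strongly negative, which makes the law nearly
  normal (see *Limitations*).
* **Bertalanffy** (`B`): lognormal with
  $\mu_B = \log\!\big[1.3\,((1-\gamma e^{-\beta d})/(1-\gamma))^{\alpha+\phi}\big]
  - \sigma^2 d/2$ and $\lambda_B^2 = \sigma^2 d$.
* **Gamma** (`G`, regulated Malthus): lognormal with
  $\mu_G = \log 1.3 + (\alpha+\phi)\log(d/0.001) -
  (\beta + \sigma^2/2)(d - 0.001)$,
  $\lambda_G^2 = \sigma^2 (d - 0.001)$; its origin is $d_0 = 0.001$ cm and
  its $\beta$ may take either sign.

In every case the conditional mean $m(d)$ with $\sigma \to 0$ collapses
onto the deterministic growth trajectory with $\alpha$ replaced by
$\alpha + \phi$, and the Bertalanffy location includes the Itô correction
$-\sigma^2 d/2$ so that $m_B(d)$ equals the deterministic sigmoid exactly —
the form consistent with the family's moment expressions (the location is
defined from the moments, which are the internally consistent quantities).

## Parameters, units, defaults

| parameter | units | meaning | typical (Scots pine) |
|-----------|-------|---------|----------------------|
| $\alpha$  | m (V), 1/– otherwise | growth level / asymptote | 26.6 (V) |
| $\beta$   | 1/cm | reversion or deceleration rate | 0.067 (V) |
| $\gamma$  | m (G4), – (B) | threshold / shape | −150 (G4), 0.99 (B) |
| $\sigma$  | law-dependent | diffusion coefficient | 0.61 (V) |
| $\sigma_\phi$ | as $\alpha$ | between-plot SD of the level | 3.9 (V) |

Validation enforces $\sigma > 0$, $\beta > 0$ except for the Gamma family,
$0 < \gamma < 1$ for Bertalanffy (keeps $1 - \gamma e^{-\beta d}$ positive)
and $\gamma < 1.3$ for G4 (the initial height must lie in the support).
Diameters are cm, heights m, volumes m³ throughout; the stem volume
function defaults to $V = 5.8\times 10^{-5}\, d^{1.8801} h^{0.9723}$.

## What the simulator emulates

`hd_simulate()` reproduces the statistical structure the estimator assumes:
many small plots, a Gaussian plot effect on $\alpha$, conditionally
independent trees, and heights drawn *exactly* from the closed-form
transition law (a normal/lognormal draw at each tree's diameter — no Euler
discretization, so simulated data follow the model law to machine
precision).  Defaults mirror a national-inventory cross-section of Scots
pine: plot sizes 1–14 trees with the empirical frequency table
`hd_plot_size_freq()` (mode at 2–4 trees, sizes above 10 rare), and
diameters from a truncated normal with mean 27.33 cm, SD 8.69 cm on
[15.1, 66.1] cm.  The truncated normal is a modelling choice — inventories
report summary moments, not a distributional form — chosen once to match
those moments.  Each plot consumes its own random substream derived from
the root seed, so enlarging a simulation never changes earlier plots.

What the simulator deliberately omits: within-plot diameter correlation,
spatial structure, age covariates, and measurement error.  Tests passing
on these data therefore demonstrate correctness of the estimation and
prediction machinery *under the model's own assumptions*, not robustness
to the ways real inventories violate them.

## Estimation

The fixed-effects log-likelihood is the sum of log transition densities
with $\phi = 0$.  For mixed effects, each plot contributes the marginal
likelihood $\int e^{g_i(\phi)} \mathrm{d}\phi$ where $g_i$ collects the
plot's log-densities plus the $N(0, \sigma_\phi^2)$ log-prior, evaluated by
the Laplace approximation
$g_i(\hat\phi_i) + \tfrac12 \log 2\pi - \tfrac12 \log(-g_i''(\hat\phi_i))$.

A structural fact makes this exact rather than approximate: all five laws
are Gaussian on a transformed height scale $y$ ($y = h$, $\log h$ or
$\log(h-\gamma)$) with location *linear* in $\phi$.  Hence $g_i$ is exactly
quadratic, the mode is available in closed form,

$$\hat\phi_i = \frac{\sum_j b_j (y_j - c_j)/\lambda_j^2}
{\sum_j b_j^2/\lambda_j^2 + 1/\sigma_\phi^2},$$

and the Laplace value equals the exact marginal log-likelihood.  The test
suite verifies this against an exact multivariate-normal computation
(Vasicek) and adaptive/Gauss–Hermite quadrature (all families).  A plot
with no trees contributes zero (the prior integrates to one).

Numerical choices:

* Optimization runs on an unconstrained scale — $\log\beta$ (except the
  sign-free Gamma $\beta$), $\log\sigma$, $\log\sigma_\phi$, logit
  $\gamma$ for Bertalanffy, and $\gamma = \min(h) - e^{c}$ for G4, which
  keeps every observation inside the support during optimization.
  Estimates are reported back-transformed.
* Starting values come from least squares on the deterministic trajectory
  (`minpack.lm::nlsLM`; the Gamma trajectory is exactly log-linear, so a
  plain linear regression supplies its start), with $\sigma$ initialized
  from residual spread mapped through the variance function at the mean
  diameter and $\sigma_\phi$ from the spread of per-plot mean residuals.
* Three jittered starts guard against the flat $(\alpha, \gamma)$ ridge of
  the G4 family; `nlminb` runs to a relative tolerance of 1e-10.
* The convergence flag requires optimizer success *and* a small
  finite-difference gradient.  With log-likelihoods of magnitude $10^4$,
  central differences carry noise around $10^{-3}$, so the gradient
  criterion is scaled by $|\mathrm{LL}|$ with tolerance 1e-2 — a
  noise-aware restatement of "gradient numerically zero".
* Standard errors are $\sqrt{\mathrm{diag}(\tilde I^{-1})}$ with
  $\tilde I$ the negative numeric Hessian (central differences, step
  $10^{-5}\max(1,|\hat\theta|)$) on the natural scale.  A variant that
  additionally divides by $\sqrt{n}$ is available behind
  `control = list(se_scale_by_n = TRUE)` for comparison with sources that
  print that form; standard asymptotics are the default.
* AIC is $-2\,\mathrm{LL} + 2p$ with $p$ counting every estimated
  parameter, including $\sigma_\phi$ in mixed fits.

## Calibration and prediction

For a new stand with $m$ measured trees, `hd_calibrate()` inverts the
conditional mean function at each tree and averages:
$\hat\phi = \tfrac1m\sum_j \phi_j$ where, e.g. for Vasicek,
$\phi_j = (h_j - \alpha - (1.3-\alpha)e^{-\beta d_j})/(1 - e^{-\beta d_j})$.
For the G3/G4 laws the inversion carries the lognormal correction term
$\sigma^2(1 - e^{-\beta d_j})/4$, so a single-tree calibration makes the
conditional mean pass *exactly* through that tree — an identity the tests
assert at 1e-9 for all five families.  Two properties deserve emphasis:

* This is a mean inversion, not a posterior mode: it does **not** shrink
  toward zero when data are sparse or $\sigma_\phi$ is small, unlike the
  Laplace mode.  Both are available (`hd_calibrate()` vs
  `hd_laplace_plot()$phi_hat`).
* Bertalanffy trees at very small diameters make the inversion denominator
  vanish; trees with $|{\cdot}| < 10^{-8}$ are excluded with a warning.

Stochastic prediction draws $U \sim \mathrm{Unif}(0,1)$ and returns the
transition-law quantile at $U$ — the same code path as the quantile
function and the simulator, so there is no duplicated distributional math.

## Derived attributes

* Slenderness $E[H/d]$ integrates over heights in $(0, 50]$ m, the
  conventional upper bound for this index; when the mass above 50 m is
  negligible it reduces to $m(d)/d$.  Returned as m/cm, with the plotted
  $100\,h/d$ convention behind `percent = TRUE` (both conventions are in
  field use).
* Mean stem volume uses the exact lognormal fractional moment
  $b_1 d^{b_2} e^{b_3\mu + b_3^2\lambda^2/2}$ for G3/B/G, and adaptive
  quadrature (tolerance 1e-10) over $h > 0$ for V and G4; the Vasicek
  negative-height mass is excluded and reported as an attribute (it is
  ~0 at realistic parameters).
* CVs are returned in percent; the volume CV is independent of $b_1, b_2$
  (they cancel), and for lognormal families equals
  $100\sqrt{e^{b_3^2\lambda^2} - 1}$.

## Evaluation

`hd_klic()` is the sample mean log-density difference between two fitted
models, evaluated with each mixed model's own per-plot effect modes
(fixed-effects models use $\phi = 0$); out-of-support observations are
excluded with a warning.  `hd_fit_statistics()` implements the bias $B$,
bias variation $\xi$ (denominator $n-1$), accuracy
$\delta = \sqrt{B^2 + \xi}$, adjusted $R^2$, and the RSS form
$\mathrm{AICC} = n\log(\mathrm{RSS}) + 2p$.  That AICC is a ranking
statistic built from prediction residuals and carries no small-sample
correction despite the name; it ranks models identically to AIC when they
differ only through RSS at a common $n$ and $p$.

## Design decisions that were genuinely open

* **Degenerate law at $d_0$.** Density, CDF, quantile and sampling raise an
  informative error at $d = d_0$ (all mass at 1.3 m); mean and variance
  return (1.3, 0).
* **Upper diameter limit.** No finite upper bound is imposed on $d$; the
  empirically observed inventory range tops out near 74 cm, and all
  formulas remain valid beyond it.
* **Exact inner step.** The generic mode-finding loop the Laplace method
  usually needs is replaced by the closed-form mode, since linearity of
  the location in $\phi$ makes the inner problem exactly quadratic; a
  finite-difference check that $g'(\hat\phi) \approx 0$ is kept in the
  tests.
* **Problem sizes.** The shipped tests use 500 estimation plots for the
  headline recovery experiment (about 1,800 trees), 200 validation plots
  for calibration, 10 replicates of 200 plots for the family-ranking
  experiment, and $10^5$ draws for Monte Carlo oracles — sizes at which
  Monte Carlo error bands (3 SEs) are decisive for the properties tested.

## Limitations

* The G4 family's shifted lognormal approaches a normal law as
  $\gamma \to -\infty$.  Fitted to data generated by the Vasicek model, G4
  therefore reproduces the Vasicek density almost exactly (with one extra
  parameter), and in-sample KLIC between the two is dominated by
  overfitting noise of order $1/n$ with essentially random sign.  Distinguishing
  these two families requires data whose height laws are genuinely skewed.
  The same near-equivalence makes G4's $(\alpha, \gamma)$ pair weakly
  identified — its standard errors are large and the observed information
  occasionally near-singular; multi-start optimization mitigates the
  ridge but cannot remove it.
* Only $\alpha$ carries a random effect; site effects acting through
  $\beta$ or $\sigma$ are not modelled.
* Cross-sectional likelihood only: repeated measurements of the same tree
  would violate the independence assumption.
* The calibration estimator is unshrunken; with one unusual tree it will
  chase that tree.  Users wanting conservative localization should use the
  Laplace mode instead.
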