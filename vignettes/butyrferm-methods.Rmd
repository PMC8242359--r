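---
title: "Models and methods in butyrferm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in butyrferm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(butyrferm)
```

`butyrferm` models the three quantitative stages of improving a butyric
acid producer (*Clostridium tyrobutyricum*) by heavy-ion irradiation:
how irradiation dose kills colonies, how improved mutants are called
from productivity ratios, and how a selected mutant grows and acidifies
a batch fermenter. This vignette explains each model, the choices behind
the defaults, and what the accompanying tests do and do not establish.

## Dose–response: binomial counts under a logistic lethality curve

At each dose $x_j$ (Gy), $n_j$ colonies are irradiated and $y_j$ die;
$y_j$ is modeled as Binomial$(n_j, p_j)$ with

$$\operatorname{logit}(p_j) = \beta_0 + \beta_1 \log_{10} x_j .$$

The log10 covariate matches the reference experiment's design (seven
doses, 50–80 Gy, roughly 6{,}000 colonies each); a raw-dose covariate is
available via `fit_mle(..., covariate = "raw")`. The model describes
*lethality*; survival is $1 - p$ everywhere, and `survival_summary()`
reports proportions rounded half-up to four decimals, the convention of
the printed survival table.

`fit_mle()` maximizes the exact binomial likelihood (binomial
coefficients included, so reported $-2\log L$ values are comparable
across uses). The optimizer starts from ordinary least squares on
empirical logits with a 0.5 continuity correction — chosen because the
highest dose typically kills every colony, and the corrected logits keep
the start finite — then refines by Nelder–Mead and BFGS. Rows with 0% or
100% survival stay in the likelihood; the correction is used *only* to
initialize. Complete separation (a dose threshold below which everything
survives and above which everything dies) makes the MLE diverge; it is
detected, flagged and warned about rather than hidden.

A deviance-like diagnostic printed in the source narrative
($D = -40.28$) is not reproducible — a deviance cannot be negative and
the underlying data selection is unstated — so the package emits
$-2\log L$ as a diagnostic and verifies nothing against that figure.
Which of the three samples (or their pool) underlies the published
curve is equally unstated; `fit_mle()` fits samples separately and
`pool_survival_tables()` merges counts dose-by-dose when a pooled fit is
wanted.

### A documented transcription correction

In the printed survival table, sample H51-8 at 55 Gy lists 3,430 in the
lethal-count column while printing survival 0.6236. Since
$3430/5500 = 0.6236$ exactly, and the other two samples at 55 Gy show
survival near 0.60–0.62 (lethal fractions near 0.38–0.40), the printed
cell evidently holds the *survivor* count. The packaged fixture stores
the implied lethal count $5500 - 3430 = 2070$ and keeps the printed
proportion column verbatim; with this single correction every one of the
21 rows satisfies
`survival = (n_total − n_lethal)/n_total` at four decimals.

## Mutant screening

The screening statistic is $\delta = r_{\text{butyric}}/r_{\text{acetic}}$,
reported to two decimals (half-up). A strain is called **positive** iff
its reported $\delta$ *strictly* exceeds the wild-type baseline
(default 3.05) — ties are negative, so the wild type never calls itself
improved. Classification uses the reported (rounded) ratio so that calls
match what a reader of the productivity table would compute.

Several printed $\delta$ values disagree with their own row
productivities. `delta_mismatch_log()` recomputes every ratio and flags
rows differing by more than 0.03 (one reporting unit plus rounding
slack); on the packaged table exactly two rows are flagged (the first
mutant group's pair). Printed values are treated as data: logged, never
overwritten. Likewise the screening rates $R_{M/T} = 100\,M/T$ and
$R_{P/T} = 100\,P/T$ are computed from the table-footer counts
$(P, M, T) = (24, 81, 409)$ — the subtotal grouping cannot be
reconstructed from the per-row calls, so the counts are read as data.
$100 \cdot 24/409 = 5.87$, which rounds to 5.9; the source prints 5.8
(a truncation), so tests assert the arithmetic, not that printed digit.
The MTT viability model $2^{-T_{\text{delay}}/T_{\text{doubling}}}$ is
provided as `mtt_survival_fraction()`.

## Batch fermentation kinetics

The state is $(X, S, P_{Ba}, P_{Aa})$: biomass (g/L DCW), glucose and
the two acids (g/L). The model is

$$\frac{dX}{dt} = \left[\mu_m \frac{S}{S + K_S + S^2/K_I}
  \left(1 - \frac{P}{P_d}\right)^{i} - K_d\right] X, \qquad
  P = P_{Ba} + P_{Aa},$$

$$\frac{dP_j}{dt} = \alpha_j \left(\frac{dX}{dt}\right)^{\!+} + \beta_j X,
  \qquad j \in \{Ba, Aa\},$$

$$-\frac{dS}{dt} = \frac{1}{Y_X}\left(\frac{dX}{dt}\right)^{\!+}
  + \frac{1}{Y_{Ba}}\frac{dP_{Ba}}{dt}
  + \frac{1}{Y_{Aa}}\frac{dP_{Aa}}{dt} + m_S X .$$

Reference values (packaged as `load_fixture("table4")`): $\mu_m = 0.48$
1/h, $K_S = 1.71$ g/L, $K_I = 383$ g/L, $P_d = 53.8$ g/L, $i = 5.32$,
$K_d = 0.0027$ 1/h, $\alpha_{Ba} = 3.12$, $\alpha_{Aa} = 0.83$ g/g DCW,
$\beta_{Ba} = 0.049$ g/g DCW/h, $Y_X = 0.812$, $Y_{Ba} = 0.973$,
$Y_{Aa} = 0.997$ g/g, $m_S = 0.015$ 1/h.

Design decisions, several forced by ambiguities in the source text:

* **$P$ is the total acid.** The symbol glosses under the growth
  equation ("$P$ is butyric acid, $P_d$ is acetic acid") contradict the
  later, self-consistent statement that growth stops when *total* acids
  reach $P_d = 53.8$ g/L. The total-acids reading is the default; the
  literal butyrate-only reading is available via
  `inhibition_product = "butyrate"`.
* **Clamped inhibition base.** $i = 5.32$ is non-integer, so
  $(1 - P/P_d)$ is clamped to $[0, 1]$ before exponentiation: growth is
  zero beyond $P_d$, never complex or oscillatory.
* **Death acts subtractively at all times** ($\mu - K_d$), the simplest
  reading consistent with a small constant decline after the peak.
* **Only the positive part of $dX/dt$** drives growth-associated
  formation and the biomass term of the substrate balance, so decaying
  biomass neither makes product nor returns substrate.
* **$\beta_{Aa} = 0$ by default** (the reference table prints "–"),
  making acetate formation purely growth-associated; overridable.
* **$X_0 = 0.1$ g/L DCW** is the default inoculum — never printed in
  the source — and any simulation aiming to mimic a published run must
  set it explicitly. OD-to-DCW conversion uses 0.412 g/L per OD600 unit
  (`OD_TO_DCW`).
* **Growth optimum.** $\sqrt{K_S K_I} = 25.59$ g/L with the reference
  parameters, while the source narrative claims "approximately 50 g/L";
  `haldane_optimum()` returns the arithmetic value and its documentation
  surfaces the discrepancy without reconciling it.
* **Yield factors are model parameters, not stoichiometric bounds.**
  The pathway stoichiometry (glucose → butyrate + 2H₂ + 2CO₂; glucose +
  2H₂O → 2 acetate + 4H₂ + 2CO₂, with butyric acid C₄H₈O₂ — the printed
  formula is garbled) gives theoretical mass yields 0.489 and 0.667 g/g
  (`stoichiometric_yields()`). The substrate balance instead routes
  glucose at $Y_{Ba} = 0.973$ g/g, so simulated butyrate can exceed
  0.489 × glucose consumed; the bound the model *does* guarantee, and
  the tests assert, is $\Delta P_{Ba} \le Y_{Ba}\,\Delta S$.

### Numerics

Integration uses `deSolve::ode()` (lsoda) at `rtol = 1e-8`,
`atol = 1e-10` (both configurable). The substrate-exhaustion clamp is
applied continuously — production and consumption scale by
$S/(S + 10^{-6})$ — because a hard switch at $S = 0$ is a discontinuous
vector field on which adaptive steppers stall when glucose runs out
under active biomass; $10^{-6}$ g/L is at least three orders of
magnitude below any saturation constant of interest, so the
regularization is dynamically invisible. Outputs are clamped at zero.
The test suite checks the adaptive solution against an independently
hand-coded fixed-step RK4 oracle (h = 0.01) to 0.5% on the reference
scenario, and checks the substrate balance by trapezoid reconstruction
to 1%.

## Least-squares estimation

`fit_monod()` fits $y = \theta_1 x/(\theta_2 + x)$ by Nelder–Mead from
the double-reciprocal linearization start, mirroring the source's
`fminsearch` workflow. The source's sentence equating $\theta_1$ with
$K_S$ and $\theta_2$ with $K_I$ contradicts its own definitions
($\theta_1$ is a rate in 1/h); the definition reading is used. The pure
Monod form is appropriate for low-glucose growth data (5–25 g/L), where
inhibition terms are negligible; `fit_haldane()` fits the full
three-parameter law when the data span the optimum. Both fitters run a
deterministic five-point multi-start ladder (start × 1, ½, 2, ¼, 4) and
keep the best minimum; the suite checks `fit_monod()` against a
400 × 400 brute-force grid. $K_I$ (and to a lesser degree $K_S$) is
weakly identified when observations stop short of high substrate — the
recovery experiments therefore report means over seeded replicates, and
tolerance on $K_S$ is double that on $\mu_m$.

`fit_timecourse()` estimates any named subset of the kinetic parameters
from an observed trajectory by minimizing a weighted sum of squares over
all four state variables. Residuals are weighted by the inverse squared
observed range per variable by default, so glucose (order 100 g/L) does
not drown biomass (order 1 g/L). One free parameter uses Brent within
its bounds; several use Nelder–Mead with out-of-bound proposals rejected.
Default boxes: rate-like parameters in $[10^{-6}, 10]$, concentrations in
$[10^{-3}, 10^4]$. `fit_diagnostics()` reports $S_R$, $n$, $p$, the
residual mean square $S_R/(n-p)$ and curvature-based confidence
intervals ($\mathrm{cov} = 2 s^2 H^{-1}$ by central finite differences).
The growth-rate data behind the source's quoted $S_R = 3\times10^{-4}$
($n = 5$, $p = 2$) are not tabulated anywhere, so that figure serves
only as a format example for the diagnostics output.

## The DRAM sampler

Both Bayesian fits use an in-package delayed-rejection adaptive
Metropolis sampler (`dram_sample()`), matching the methodology cited by
the source. Specifics the source leaves unstated follow standard DRAM
practice:

* two proposal stages; the second shrinks the proposal scale by
  `dr_scale` (default 1/5) and uses the delayed-rejection acceptance
  ratio that preserves detailed balance;
* covariance adaptation from the accumulated history every 100 steps
  (after step 1,000 for dose–response-sized problems, step 200 for
  kinetics-sized ones), scaled by $2.38^2/d$ with a $10^{-10}$ diagonal
  regularizer;
* an observation-variance chain drawn each sweep from its scaled
  inverse-$\chi^2$ full conditional (weak prior: $n_0 = 1$, $s_0^2$ =
  initial residual mean square unless given);
* default chain lengths follow the published figures: 50,000 steps for
  the dose–response fit, 4,000 for the kinetics growth fit — both
  configurable, and the suite uses shorter chains on analytic targets
  where Monte-Carlo error is measurable;
* burn-in defaults to the first 20% of the chain;
* seeds are mandatory; identical configurations give bit-identical
  chains. With adaptation and delayed rejection disabled the sampler
  reduces exactly (same RNG stream) to plain Metropolis, which the suite
  regression-tests.

The source's "each dimension was required to repeat 500 times" is
ambiguous (replicate chains? adaptation cycles?); a replicate-run
harness (`dram_replicates()`) is provided but nothing runs it by
default. Correctness is established on conjugate targets where the
posterior is closed-form: the mean chain against the analytic Gaussian
posterior, the variance chain against its scaled inverse-$\chi^2$
marginal, and a discretized two-state target against its stationary
mass to 2%.

`predictive_envelope()` evaluates a model function over a random
subsample of post-burn-in rows and returns pointwise central quantile
bands (defaults 50/90/95/99%), optionally adding observation noise drawn
from the variance chain. Because all levels are quantiles of one common
sample, the bands are nested at every grid point by construction.

## Synthetic data: what it emulates, and what it does not

`generate_survival_table()` draws lethal counts binomially under the
logistic model at the reference dose design — exactly the sampling model
the dose–response analysis assumes, so recovery tests validate the
estimator, not the model. `generate_timecourse()` adds independent
multiplicative Gaussian noise (default $\sigma$ = 2%, typical of OD and
HPLC precision; the source states no noise model) to the simulated
trajectory, clamped at zero.

The recovery experiments run by `scripts/acceptance.R` use problem
sizes chosen to keep each experiment well-identified yet quick: 12
glucose levels log-spaced on $[1, 150]$ g/L (log spacing puts points
below $K_S$ and beyond the growth optimum, which is what identifies
$K_S$), 10 seeded replicates; and 13 sampling times over a 120-h batch
at $S_0 = 180$ g/L for the $P_d$ refit, again 10 replicates. Every seed
derives from the script's `--seed` argument.

Passing these tests shows the estimators recover parameters *from data
generated by the model itself under idealized noise*. Real
fermentations violate the model in known ways: the lag phase is not
represented (the source itself notes the maintenance formulation cannot
capture it), noise in practice is correlated over time and between
variables, pH and undissociated-acid speciation are ignored (the model
fixes pH 6.0 implicitly through its fitted constants), and gas-phase
effects are absent. Published end-point figures that depend on
unpublished experimental conditions (maximum butyrate titres, yield
ranges, the exact published trajectories) are therefore *not*
reproduction targets; the suite instead verifies the structural
properties the model guarantees and the qualitative behaviour the study
reports — butyrate as the dominant acid and total acids climbing into
the $P_d$ regime in a high-glucose batch.

## Known limitations

* Lag-phase dynamics and pH/undissociated-acid effects are out of model
  scope, as discussed above.
* $K_I$ is reported by `fit_haldane()` but should not be trusted from
  data that stop below ~2× the growth optimum.
* The ODE right-hand side is only piecewise smooth (positive-part and
  clamp operators); solutions are fine for lsoda/RK4 but high-order
  dense-output interpolation across the growth-arrest surface loses one
  order of accuracy.
* `fit_timecourse()` with many free parameters inherits Nelder–Mead's
  local character; the deterministic multi-start ladder mitigates but
  does not eliminate local minima. The MCMC route gives a posterior
  check on identifiability.
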