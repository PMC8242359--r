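# butyrferm

Modeling tools for strain improvement of butyric-acid-producing
*Clostridium tyrobutyricum* by heavy-ion irradiation mutagenesis. The
package covers the three quantitative stages of that pipeline:

1. **Dose–response** — colony lethality after irradiation is modeled as
   binomial with a logistic dependence on log10 dose,
   `logit(p) = β₀ + β₁·log₁₀(dose)`, fitted by maximum likelihood and,
   optionally, by Bayesian MCMC;
2. **Mutant screening** — strains are called *positive* (improved) when
   their butyrate:acetate specific-productivity ratio δ strictly exceeds
   the wild-type baseline (δ = 3.05), with screening-rate summaries
   (R_M/T, R_P/T) and the MTT survival fraction `2^(−T_delay/T_doubling)`;
3. **Batch fermentation kinetics** — an ODE model coupling
   substrate-inhibited growth with product inhibition and death,

   dX/dt = [ μ_m S / (S + K_S + S²/K_I) · (1 − P/P_d)^i − K_d ] X,

   two-product Luedeking–Piret acid formation
   `dP_j/dt = α_j (dX/dt)⁺ + β_j X` for butyrate and acetate, and a
   substrate balance
   `−dS/dt = (dX/dt)⁺/Y_X + (dP_Ba/dt)/Y_Ba + (dP_Aa/dt)/Y_Aa + m_S X`,
   with least-squares and MCMC parameter estimation.

A delayed-rejection adaptive Metropolis (DRAM) sampler with a conjugate
error-variance chain and posterior-predictive envelopes is implemented
in-package and drives both Bayesian fits. Seeded synthetic-data
generators and plain-text transcriptions of the study's reference tables
(survival counts, screening productivities, the kinetic parameter set)
make every stage testable with no external data.

## Worked example

```r
library(butyrferm)

## dose-response: fit the packaged survival table for sample Q36-8
tab <- load_fixture("table2")$`Q36-8`
fit_mle(tab)
#> Binomial-logistic dose-lethality fit (log10-dose covariate)
#>   beta0 = -39.0430, beta1 = 22.0140
#>   -2 log-likelihood = 1280.03; converged: TRUE
```

The positive slope (≈22 per log10 Gy) quantifies how steeply lethality
rises across the 50–80 Gy window; survival drops from 85% to 0 over that
range.

```r
## kinetics: where is growth fastest, and how does a 180 g/L batch run?
p <- load_fixture("table4")
haldane_optimum(p)
#> $S_opt
#> [1] 25.5916
#> $mu_opt
#> [1] 0.4234157

tc <- simulate_batch(p, fermentation_state(X = 0.1, S = 180), t_end = 120,
                     t_eval = seq(0, 120, 10))
tail(round(as.data.frame(tc), 3), 3)
#>      t     X       S   P_Ba  P_Aa
#> 11 100 5.152 120.775 39.801 4.592
#> 12 110 5.015 117.453 42.292 4.592
#> 13 120 4.882 114.219 44.716 4.592
```

Growth peaks at √(K_S·K_I) ≈ 25.6 g/L glucose at 0.423 1/h; in the
simulated 180 g/L batch, butyrate (44.7 g/L) dominates acetate
(4.6 g/L) and total acids approach the critical inhibition level
P_d = 53.8 g/L, at which growth stops.

```r
## screening: the wild-type ratio and the mutation rates
delta_ratio(34.32, 11.24)   # 3.05  (wild-type baseline)
screening_rates(P = 24, M = 81, T = 409)
#> Screening summary: T = 409, M = 81, P = 24
#>   R_M/T = 19.8%  R_P/T = 5.9%
```

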