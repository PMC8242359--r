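ref <- load_fixture("table4")

monod_mu <- function(S, th1, th2) th1 * S / (th2 + S)

test_that("noise-free Monod data are recovered to 4 decimals", {
  S <- c(1, 2, 5, 10, 25, 50, 100, 200)
  dat <- data.frame(S = S, mu_obs = monod_mu(S, 0.48, 25))
  fit <- fit_monod(dat)
  expect_equal(fit$theta1, 0.48, tolerance = 1e-4)
  expect_equal(fit$theta2, 25, tolerance = 1e-4)
  expect_lt(fit$ssq, 1e-10)
  # descent property: the optimum is no worse than the start
  expect_lte(fit$ssq, fit$objective(fit$start))
})

test_that("exact half-saturation and saturation points pin the two parameters", {
  # y(theta2) = theta1/2 and y(large S) ~ theta1 identify the pair
  dat <- data.frame(S = c(18, 5000, 18),
                    mu_obs = monod_mu(c(18, 5000, 18), 0.36, 18))
  fit <- fit_monod(dat)
  expect_equal(fit$theta1, 0.36, tolerance = 1e-3)
  expect_equal(fit$theta2, 18, tolerance = 1e-2)
})

test_that("Monod fit matches a brute-force grid search to one grid cell", {
  S <- c(5, 10, 15, 20, 25)
  set.seed(55)
  dat <- data.frame(S = S, mu_obs = monod_mu(S, 0.48, 1.71) *
                      (1 + 0.02 * rnorm(5)))
  fit <- fit_monod(dat)
  th1s <- seq(0.3, 0.7, length.out = 400)
  th2s <- seq(0.2, 6, length.out = 400)
  ssq_grid <- outer(th1s, th2s, Vectorize(function(a, b)
    sum((dat$mu_obs - monod_mu(dat$S, a, b))^2)))
  best <- arrayInd(which.min(ssq_grid), dim(ssq_grid))
  expect_lt(abs(fit$theta1 - th1s[best[1]]), diff(th1s[1:2]) * 1.5)
  expect_lt(abs(fit$theta2 - th2s[best[2]]), diff(th2s[1:2]) * 1.5)
  expect_lte(fit$ssq, min(ssq_grid))
})

test_that("degenerate growth-rate inputs are rejected", {
  expect_error(fit_monod(data.frame(S = c(1, 2, 3), mu_obs = c(0, 0, 0))),
               "zero")
  expect_error(fit_monod(data.frame(S = c(1, 1, 1), mu_obs = c(1, 1, 1))),
               "distinct")
  expect_error(fit_monod(data.frame(S = c(1, 2), mu_obs = c(0.1, 0.2))))
})

test_that("the substrate-inhibition growth law is recovered from clean data", {
  S <- exp(seq(log(1), log(150), length.out = 12))
  dat <- data.frame(S = S, mu_obs = specific_growth_rate(ref, S, 0))
  fit <- fit_haldane(dat)
  expect_equal(unname(fit$estimates["mu_m"]), ref$mu_m, tolerance = 1e-3)
  expect_equal(unname(fit$estimates["K_S"]), ref$K_S, tolerance = 1e-2)
  expect_equal(unname(fit$estimates["K_I"]), ref$K_I, tolerance = 0.05)
})

test_that("time-course SSQ is zero at truth, linear in weights, order-invariant", {
  init <- fermentation_state(X = 0.1, S = 60)
  tc <- generate_timecourse(ref, init, seq(0, 72, 6), sigma = 0)
  expect_equal(ssq_timecourse(ref, tc, initial = init), 0, tolerance = 1e-12)

  tc_noisy <- generate_timecourse(ref, init, seq(0, 72, 6), sigma = 0.02,
                                  seed = 5)
  w <- c(X = 1, S = 1, P_Ba = 1, P_Aa = 1)
  s1 <- ssq_timecourse(ref, tc_noisy, weights = w, initial = init)
  s2 <- ssq_timecourse(ref, tc_noisy, weights = 2 * w, initial = init)
  expect_equal(s2, 2 * s1)

  perm <- tc_noisy[sample(nrow(tc_noisy)), ]
  expect_equal(ssq_timecourse(ref, perm, weights = w, initial = init), s1)

  # local identifiability: perturbing mu_m by +10% strictly raises the SSQ
  bumped <- kinetic_params(mu_m = ref$mu_m * 1.1, K_S = ref$K_S,
                           K_I = ref$K_I, P_d = ref$P_d, i = ref$i,
                           K_d = ref$K_d, alpha_Ba = ref$alpha_Ba,
                           alpha_Aa = ref$alpha_Aa, beta_Ba = ref$beta_Ba,
                           beta_Aa = ref$beta_Aa, Y_X = ref$Y_X,
                           Y_Ba = ref$Y_Ba, Y_Aa = ref$Y_Aa, m_S = ref$m_S)
  expect_gt(ssq_timecourse(bumped, tc_noisy, weights = w, initial = init), s1)
})

test_that("an all-fixed fit spec returns the parameters unchanged", {
  init <- fermentation_state(X = 0.1, S = 60)
  tc <- generate_timecourse(ref, init, seq(0, 48, 8), sigma = 0)
  sp <- timecourse_fit_spec(free = setNames(numeric(0), character(0)),
                            fixed = ref, initial_state = init)
  fit <- fit_timecourse(tc, sp)
  expect_identical(fit$params, ref)
  expect_equal(fit$objective, 0, tolerance = 1e-12)
})

test_that("a single free parameter is recovered from a noisy time course", {
  init <- fermentation_state(X = 0.1, S = 180)
  tc <- generate_timecourse(ref, init, seq(0, 120, 10), sigma = 0.02,
                            seed = 77)
  sp <- timecourse_fit_spec(free = c(P_d = 40), fixed = ref,
                            lower = 20, upper = 100, initial_state = init)
  fit <- fit_timecourse(tc, sp)
  expect_true(fit$converged)
  expect_lt(abs(fit$estimates[["P_d"]] - ref$P_d) / ref$P_d, 0.1)
})

test_that("MCMC and simplex estimates agree on an identifiable 2-parameter problem", {
  init <- fermentation_state(X = 0.1, S = 60)
  tc <- generate_timecourse(ref, init, seq(0, 72, 8), sigma = 0.02, seed = 9)
  sp <- timecourse_fit_spec(free = c(mu_m = 0.3, P_d = 40), fixed = ref,
                            lower = c(0.05, 20), upper = c(2, 100),
                            initial_state = init)
  ls_fit <- fit_timecourse(tc, sp, method = "simplex")
  mc_fit <- fit_timecourse(tc, sp, method = "mcmc",
                           mcmc_config = mcmc_config(1200, seed = 10,
                                                     adapt_start = 200))
  post_sd <- mc_fit$diagnostics$sd
  expect_true(all(abs(mc_fit$estimates - ls_fit$estimates) <=
                    2 * post_sd + 1e-8))
  expect_s3_class(mc_fit$chain, "dram_chain")
})

test_that("fit diagnostics report the residual mean square and sane intervals", {
  # arithmetic forced by the definition: S_R/(n-p) with S_R=3e-4, n=5, p=2
  fake <- structure(list(estimates = c(theta1 = 0.5, theta2 = 2),
                         ssq = 3e-4, n_points = 5L, n_params = 2L,
                         objective = function(th)
                           3e-4 + sum((th - c(0.5, 2))^2)),
                    class = c("monod_fit", "growth_fit"))
  d <- fit_diagnostics(fake)
  expect_equal(d$residual_mean_square, 1e-4)
  expect_equal(d$n, 5L)
  expect_equal(d$p, 2L)

  # zero residuals collapse the intervals onto the estimate
  S <- c(2, 5, 10, 20, 40)
  exact <- fit_monod(data.frame(S = S, mu_obs = monod_mu(S, 0.4, 8)))
  exact$ssq <- 0
  dz <- fit_diagnostics(exact)
  expect_equal(unname(dz$ci[, "lower"]), unname(dz$estimates))
  expect_equal(unname(dz$ci[, "upper"]), unname(dz$estimates))

  # intervals shrink as n grows at fixed noise
  make_fit <- function(n, seed) {
    set.seed(seed)
    S <- rep(c(2, 5, 10, 20, 40), length.out = n)
    fit_monod(data.frame(S = S,
                         mu_obs = pmax(monod_mu(S, 0.4, 8) +
                                         rnorm(n, 0, 0.005), 0)))
  }
  se_small <- fit_diagnostics(make_fit(10, 1))$se
  se_large <- fit_diagnostics(make_fit(80, 1))$se
  expect_true(all(se_large < se_small))

  expect_error(fit_diagnostics(structure(list(estimates = 1, ssq = 1,
                                              n_points = 2L, n_params = 2L,
                                              objective = identity),
                                         class = c("monod_fit",
                                                   "growth_fit"))),
               "n > p")
})

test_that("fit specs validate bounds and parameter names", {
  init <- fermentation_state()
  expect_error(timecourse_fit_spec(free = c(bogus = 1), fixed = ref,
                                   initial_state = init), "unknown")
  expect_error(timecourse_fit_spec(free = c(mu_m = 0.5), fixed = ref,
                                   lower = 2, upper = 1,
                                   initial_state = init), "lower < upper")
  expect_error(timecourse_fit_spec(free = c(mu_m = 50), fixed = ref,
                                   lower = 0.1, upper = 10,
                                   initial_state = init), "within")
})
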