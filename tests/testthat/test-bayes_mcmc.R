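gauss_target <- function(n = 40, mean = 2, sd = 0.5, seed = 99) {
  set.seed(seed)
  rnorm(n, mean, sd)
}

test_that("DRAM recovers the closed-form posterior of a Gaussian mean", {
  y <- gauss_target()
  ch <- dram_sample(init = 0, config = mcmc_config(8000, seed = 3),
                    ssfun = function(th) sum((y - th)^2), n_obs = length(y),
                    sigma2_init = 0.25, update_sigma2 = FALSE)
  d <- chain_diagnostics(ch)
  # flat prior, known variance: posterior = N(ybar, sigma2/n)
  mc_se <- d$sd / sqrt(d$ess)
  expect_lt(abs(d$mean - mean(y)), 3 * mc_se)
  expect_equal(unname(d$sd), sqrt(0.25 / length(y)), tolerance = 0.15)
})

test_that("the error-variance chain matches its conjugate closed form", {
  y <- gauss_target()
  n <- length(y); n0 <- 1; s20 <- 0.3
  ch <- dram_sample(init = 0,
                    config = mcmc_config(8000, seed = 4, error_prior_n0 = n0,
                                         error_prior_s20 = s20),
                    ssfun = function(th) sum((y - th)^2), n_obs = n)
  keep <- ch$s2chain[-(1:1600)]
  # marginal posterior: Scaled-Inv-chi2(n0 + n - 1, .), mean below
  analytic <- (n0 * s20 + (n - 1) * var(y)) / (n0 + n - 3)
  mc_se <- sd(keep) / sqrt(butyrferm:::ess(keep))
  expect_lt(abs(mean(keep) - analytic), 3 * mc_se)
  expect_true(all(ch$s2chain > 0))
})

test_that("chains are bit-identical under a fixed seed", {
  y <- gauss_target()
  run <- function() dram_sample(init = 0, config = mcmc_config(1500, seed = 7),
                                ssfun = function(th) sum((y - th)^2),
                                n_obs = length(y))
  a <- run(); b <- run()
  expect_identical(a$samples, b$samples)
  expect_identical(a$s2chain, b$s2chain)
  expect_identical(a$accept_stage1, b$accept_stage1)
})

test_that("NaN log-likelihoods are treated as rejections, not errors", {
  ll <- function(th) if (th > 1) NaN else dnorm(th, log = TRUE)
  ch <- dram_sample(init = 0, config = mcmc_config(2000, seed = 11),
                    log_likelihood = ll)
  expect_true(all(is.finite(ch$samples)))
  expect_true(all(ch$samples <= 1))
})

test_that("with adaptation and delayed rejection off, DRAM is plain Metropolis", {
  y <- gauss_target(n = 25)
  ss <- function(th) sum((y - th)^2)
  sigma2 <- 0.25
  n_steps <- 400L
  cfg <- mcmc_config(n_steps, seed = 21, adapt_start = n_steps + 1L,
                     n_stages = 1, init_cov = matrix(0.04))
  ch <- dram_sample(init = 1, config = cfg, ssfun = ss, n_obs = length(y),
                    sigma2_init = sigma2, update_sigma2 = FALSE)
  # independent plain random-walk Metropolis with the same RNG call pattern
  lp <- function(th) -0.5 * ss(th) / sigma2 - 0.5 * length(y) * log(2 * pi * sigma2)
  set.seed(21)
  x <- 1; cur <- lp(x); trace <- numeric(n_steps)
  for (k in seq_len(n_steps)) {
    cand <- x + rnorm(1) * 0.2
    lpc <- lp(cand)
    if (runif(1) < min(1, exp(lpc - cur))) { x <- cand; cur <- lpc }
    trace[k] <- x
  }
  expect_identical(drop(ch$samples), trace)
})

test_that("the sampler reproduces a discretized two-state target within 2%", {
  # piecewise-constant density: mass 0.3 on [0,1), 0.7 on [1,2)
  lt <- function(x) {
    if (x < 0 || x >= 2) return(-Inf)
    log(if (x < 1) 0.3 else 0.7)
  }
  ch <- dram_sample(init = 0.5,
                    config = mcmc_config(1e5, seed = 5, adapt_start = 500),
                    log_likelihood = lt)
  s <- ch$samples[-(1:20000), 1]
  expect_lt(abs(mean(s >= 1) - 0.7), 0.02)
})

test_that("predictive envelopes collapse for constant models and nest otherwise", {
  chain <- pseudo_chain(matrix(rnorm(4000), ncol = 1), burn_in = 0.2)
  grid <- seq(-2, 2, length.out = 9)

  cst <- predictive_envelope(chain, function(th, g) rep(3.14, length(g)),
                             grid, n_draws = 200, seed = 1)
  expect_true(all(cst$lower == 3.14) && all(cst$upper == 3.14))

  env <- predictive_envelope(chain, function(th, g) th * g, grid,
                             levels = c(0.5, 0.9, 0.95, 0.99),
                             n_draws = 1000, seed = 2)
  # nesting at every grid point, and lower <= median <= upper
  for (k in 2:length(env$levels)) {
    expect_true(all(env$lower[, k] <= env$lower[, k - 1]))
    expect_true(all(env$upper[, k] >= env$upper[, k - 1]))
  }
  expect_true(all(env$lower[, 1] <= env$median & env$median <= env$upper[, 1]))
})

test_that("envelope quantiles match the analytic bands of a Gaussian chain", {
  set.seed(8)
  chain <- pseudo_chain(matrix(rnorm(20000), ncol = 1), burn_in = 0)
  grid <- c(0.5, 1, 2)
  env <- predictive_envelope(chain, function(th, g) th * g, grid,
                             levels = 0.95, n_draws = 20000, seed = 3)
  # theta ~ N(0,1) so the 95% band at g is +- 1.96 g
  expect_equal(drop(env$upper), qnorm(0.975) * grid, tolerance = 0.06)
  expect_equal(drop(env$lower), qnorm(0.025) * grid, tolerance = 0.06)
})

test_that("oversized draw requests are capped with a warning", {
  chain <- pseudo_chain(matrix(rnorm(100), ncol = 1), burn_in = 0)
  expect_warning(
    env <- predictive_envelope(chain, function(th, g) th * g, 1:3,
                               n_draws = 1e4, seed = 1),
    "capped"
  )
  expect_equal(length(env$median), 3)
})

test_that("chain diagnostics report known moments and acceptance arithmetic", {
  set.seed(13)
  chain <- pseudo_chain(matrix(rnorm(20000), ncol = 1), burn_in = 0)
  d <- chain_diagnostics(chain, burn_in = 0)
  expect_equal(unname(d$mean), 0, tolerance = 0.03)
  expect_equal(unname(d$sd), 1, tolerance = 0.03)
  expect_equal(d$n_used, 20000)  # burn_in = 0 keeps the full chain

  fake <- pseudo_chain(matrix(rnorm(1000), ncol = 1))
  fake$accept_stage1 <- 500L
  expect_equal(chain_diagnostics(fake, burn_in = 0)$accept_rate_stage1, 0.5)
  expect_error(chain_diagnostics(fake, burn_in = 1), "burn_in")
})

test_that("replicate harness varies seeds deterministically", {
  y <- gauss_target(n = 10)
  reps <- dram_replicates(2, init = 0, config = mcmc_config(200, seed = 31),
                          ssfun = function(th) sum((y - th)^2), n_obs = 10)
  expect_length(reps, 2)
  expect_false(identical(reps[[1]]$samples, reps[[2]]$samples))
  expect_equal(reps[[2]]$config$seed, 32L)
})

test_that("chains serialize to CSV with named columns and a meta sidecar", {
  y <- gauss_target(n = 10)
  ch <- dram_sample(init = 0, config = mcmc_config(50, seed = 2),
                    ssfun = function(th) sum((y - th)^2), n_obs = 10)
  path <- tempfile(fileext = ".csv")
  write_chain_csv(ch, path, par_names = "mu")
  back <- read.csv(path)
  expect_equal(names(back), c("mu", "s2", "logpost"))
  expect_equal(back$mu, drop(ch$samples))
  expect_true(file.exists(paste0(path, ".meta")))
})
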