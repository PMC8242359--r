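#' Configuration for the DRAM sampler
#'
#' Settings for [dram_sample()]: chain length, adaptation schedule,
#' delayed-rejection shrinkage, initial proposal covariance, the conjugate
#' prior on the observation variance, and the RNG seed.
#'
#' @param n_steps Chain length (>= 1).
#' @param seed Integer RNG seed (mandatory: chains are exactly reproducible
#'   and never seeded from the clock).
#' @param adapt_start Step index at which proposal-covariance adaptation
#'   begins (>= 1).
#' @param adapt_interval Steps between covariance re-estimations.
#' @param dr_scale Shrink factor applied to the proposal scale for the
#'   delayed-rejection second stage, in (0, 1); default 1/5.
#' @param n_stages 2 for DRAM (default); 1 disables delayed rejection,
#'   reducing the sampler to (adaptive) Metropolis.
#' @param init_cov Optional initial proposal covariance matrix; default
#'   `diag((0.1 |init| + 1e-3)^2)` built from the start value.
#' @param error_prior_n0,error_prior_s20 Weight (pseudo-observations) and
#'   scale of the scaled-inverse-chi-square prior on the observation
#'   variance; `error_prior_s20 = NULL` uses the initial residual mean
#'   square.
#' @param burn_in Fraction of the chain discarded by summaries/envelopes.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_steps = 5000, seed, adapt_start = 200,
                        adapt_interval = 100, dr_scale = 0.2, n_stages = 2,
                        init_cov = NULL, error_prior_n0 = 1,
                        error_prior_s20 = NULL, burn_in = 0.2) {
  stopifnot(n_steps >= 1, adapt_start >= 1, adapt_interval >= 1,
            dr_scale > 0, dr_scale < 1, n_stages %in% c(1, 2),
            burn_in >= 0, burn_in < 1)
  if (missing(seed)) stop("an explicit RNG seed is required")
  structure(list(n_steps = as.integer(n_steps), seed = as.integer(seed),
                 adapt_start = as.integer(adapt_start),
                 adapt_interval = as.integer(adapt_interval),
                 dr_scale = dr_scale, n_stages = n_stages,
                 init_cov = init_cov, error_prior_n0 = error_prior_n0,
                 error_prior_s20 = error_prior_s20, burn_in = burn_in),
            class = "mcmc_config")
}

# Gaussian quadratic form ||R^-T (b - a)||^2 where C = R'R (R upper chol)
chol_quad <- function(R, d) {
  z <- forwardsolve(t(R), d)
  sum(z^2)
}

#' Delayed-rejection adaptive Metropolis (DRAM) sampling
#'
#' Random-walk Metropolis with (a) proposal covariance adapted from the
#' accumulated chain history (scaled by `2.38^2/d` plus a `1e-10` diagonal
#' regularizer) at every `adapt_interval` steps after `adapt_start`; (b) on
#' first-stage rejection, a second narrower proposal (scale shrunk by
#' `dr_scale`) accepted with the delayed-rejection ratio that preserves
#' detailed balance; and (c) after every sweep, an observation-variance
#' draw from its scaled-inverse-chi-square full conditional based on the
#' current residual sum of squares (when a sum-of-squares target is used).
#'
#' The target may be given either as a sum-of-squares function `ssfun`
#' (Gaussian likelihood, `sigma2` then sampled alongside the parameters) or
#' as a direct `log_likelihood` (in which case `sigma2` stays fixed at
#' `sigma2_init` and `s2chain` is constant). A log-likelihood evaluating to
#' `NaN` is treated as `-Inf` (rejection), never an error.
#'
#' @param init Numeric start vector (must have finite log-posterior).
#' @param config An [mcmc_config()].
#' @param ssfun Function `theta -> residual sum of squares`, or `NULL`.
#' @param n_obs Number of observations behind `ssfun` (required with it).
#' @param log_likelihood Function `theta -> log-likelihood`, or `NULL`;
#'   exactly one of `ssfun`/`log_likelihood` must be given.
#' @param lower,upper Box prior support (recycled to `length(init)`);
#'   proposals outside are rejected.
#' @param log_prior Optional function `theta -> log prior density` added on
#'   the support.
#' @param sigma2_init Initial observation variance.
#' @param update_sigma2 Draw the variance chain? Default: yes iff `ssfun`
#'   is used.
#' @return An object of class `dram_chain`: `samples` (`n_steps x d`
#'   matrix), `s2chain`, `logpost`, acceptance counts by stage
#'   (`accept_stage1`, `accept_stage2`), `n_stage2_tries`, the `config`,
#'   and a `flagged` marker when no proposal was ever accepted.
#' @examples
#' # posterior of a Gaussian mean, flat prior
#' y <- c(0.3, -0.1, 0.5, 0.2)
#' ch <- dram_sample(init = 0, config = mcmc_config(2000, seed = 1),
#'                   ssfun = function(th) sum((y - th)^2), n_obs = length(y),
#'                   sigma2_init = 1, update_sigma2 = FALSE)
#' mean(ch$samples[-(1:400), 1])
#' @export
dram_sample <- function(init, config, ssfun = NULL, n_obs = NULL,
                        log_likelihood = NULL, lower = -Inf, upper = Inf,
                        log_prior = NULL, sigma2_init = 1,
                        update_sigma2 = !is.null(ssfun)) {
  stopifnot(inherits(config, "mcmc_config"))
  if (is.null(ssfun) == is.null(log_likelihood))
    stop("give exactly one of ssfun or log_likelihood")
  if (!is.null(ssfun) && is.null(n_obs))
    stop("n_obs is required with ssfun")
  if (update_sigma2 && is.null(ssfun))
    stop("sigma2 updating requires a sum-of-squares target")
  d <- length(init)
  lower <- rep_len(lower, d); upper <- rep_len(upper, d)
  if (any(init < lower | init > upper)) stop("init outside prior support")

  n0 <- config$error_prior_n0
  loglik_ss <- function(ss, sigma2)
    -0.5 * ss / sigma2 - 0.5 * n_obs * log(2 * pi * sigma2)
  lprior <- function(theta) {
    if (any(theta < lower | theta > upper)) return(-Inf)
    if (is.null(log_prior)) 0 else {
      v <- log_prior(theta)
      if (is.nan(v)) -Inf else v
    }
  }
  # returns list(lp, ss); ss NA for direct log-likelihood targets
  evaluate <- function(theta, sigma2) {
    pv <- lprior(theta)
    if (!is.finite(pv)) return(list(lp = -Inf, ss = NA_real_))
    if (!is.null(ssfun)) {
      ss <- ssfun(theta)
      if (!is.finite(ss)) return(list(lp = -Inf, ss = Inf))
      list(lp = loglik_ss(ss, sigma2) + pv, ss = ss)
    } else {
      ll <- log_likelihood(theta)
      if (is.nan(ll) || is.na(ll)) ll <- -Inf
      list(lp = ll + pv, ss = NA_real_)
    }
  }

  with_seed(config$seed, {
    sigma2 <- sigma2_init
    cur <- evaluate(init, sigma2)
    if (!is.finite(cur$lp)) stop("log-posterior not finite at init")
    s20 <- config$error_prior_s20 %||%
      (if (!is.null(ssfun)) max(cur$ss / max(n_obs, 1), 1e-12) else 1)

    C0 <- config$init_cov %||% diag((0.1 * abs(init) + 1e-3)^2, d)
    R <- chol(C0)
    sd_fac <- 2.38^2 / d

    samples <- matrix(NA_real_, config$n_steps, d)
    s2chain <- numeric(config$n_steps)
    logpost <- numeric(config$n_steps)
    acc1 <- 0L; acc2 <- 0L; n2try <- 0L
    theta <- as.numeric(init)
    # running moments of the history for covariance adaptation
    hist_mean <- theta; hist_m2 <- matrix(0, d, d); hist_n <- 1

    for (step in seq_len(config$n_steps)) {
      y1 <- theta + drop(rnorm(d) %*% R)
      cand1 <- evaluate(y1, sigma2)
      a1 <- if (!is.finite(cand1$lp)) 0 else min(1, exp(cand1$lp - cur$lp))
      u1 <- runif(1)
      if (u1 < a1) {
        theta <- y1; cur <- cand1; acc1 <- acc1 + 1L
      } else if (config$n_stages >= 2) {
        n2try <- n2try + 1L
        R2 <- R * config$dr_scale
        y2 <- theta + drop(rnorm(d) %*% R2)
        cand2 <- evaluate(y2, sigma2)
        u2 <- runif(1)
        if (is.finite(cand2$lp)) {
          # alpha1 evaluated from y2 toward y1
          a1_rev <- if (!is.finite(cand1$lp)) 0 else
            min(1, exp(cand1$lp - cand2$lp))
          if (a1_rev < 1) {
            # symmetric stage-1 kernel: only the q1(.|y1) ratio survives
            lq_num <- -0.5 * chol_quad(R, y1 - y2)
            lq_den <- -0.5 * chol_quad(R, y1 - theta)
            la2 <- (cand2$lp - cur$lp) + (lq_num - lq_den) +
              log1p(-a1_rev) - log1p(-a1)
            if (u2 < min(1, exp(la2))) {
              theta <- y2; cur <- cand2; acc2 <- acc2 + 1L
            }
          }
        }
      }

      if (update_sigma2) {
        sigma2 <- (n0 * s20 + cur$ss) / rchisq(1, n0 + n_obs)
        cur$lp <- loglik_ss(cur$ss, sigma2) + lprior(theta)
      }

      samples[step, ] <- theta
      s2chain[step] <- sigma2
      logpost[step] <- cur$lp

      # accumulate history and refresh the proposal covariance
      hist_n <- hist_n + 1
      delta <- theta - hist_mean
      hist_mean <- hist_mean + delta / hist_n
      hist_m2 <- hist_m2 + tcrossprod(delta, theta - hist_mean)
      if (step >= config$adapt_start && step %% config$adapt_interval == 0) {
        Ch <- hist_m2 / (hist_n - 1)
        Cp <- sd_fac * (Ch + diag(1e-10, d))
        Rn <- tryCatch(chol(Cp), error = function(e) NULL)
        if (!is.null(Rn)) R <- Rn
      }
    }

    structure(list(
      samples = samples, s2chain = s2chain, logpost = logpost,
      accept_stage1 = acc1, accept_stage2 = acc2, n_stage2_tries = n2try,
      config = config,
      flagged = if (acc1 + acc2 == 0L) "no proposal accepted" else NULL
    ), class = "dram_chain")
  })
}

#' @export
print.dram_chain <- function(x, ...) {
  n <- x$config$n_steps
  cat(sprintf("DRAM chain: %d steps, %d parameter(s)\n", n, ncol(x$samples)))
  cat(sprintf("  stage-1 acceptance %.3f; stage-2 %s\n",
              x$accept_stage1 / n,
              if (x$n_stage2_tries > 0)
                sprintf("%.3f of %d tries", x$accept_stage2 / x$n_stage2_tries,
                        x$n_stage2_tries) else "unused"))
  if (!is.null(x$flagged)) cat("  FLAGGED:", x$flagged, "\n")
  invisible(x)
}

post_burn_rows <- function(chain, burn_in) {
  stopifnot(burn_in >= 0, burn_in < 1)
  n <- nrow(chain$samples)
  keep <- seq.int(floor(n * burn_in) + 1, n)
  if (!length(keep)) stop("no post-burn-in samples")
  keep
}

# effective sample size via the initial positive sequence of autocorrelations
ess <- function(x) {
  n <- length(x)
  if (n < 10 || sd(x) == 0) return(n)
  rho <- drop(acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf)[-1]
  pos <- which(rho < 0)
  if (length(pos)) rho <- rho[seq_len(pos[1] - 1)]
  max(1, n / (1 + 2 * sum(rho)))
}

#' Posterior and posterior-predictive envelopes over a predictor grid
#'
#' Evaluates `model_fn` on a random subsample of post-burn-in chain rows
#' over `grid` and returns pointwise central quantile bands at the
#' requested coverage levels, plus the pointwise median. With
#' `include_observation_noise`, Gaussian noise with variance drawn from the
#' chain's `s2chain` is added to each curve before taking quantiles,
#' producing predictive rather than credible bands. Bands at increasing
#' levels are nested at every grid point by construction (quantiles of a
#' common sample).
#'
#' @param chain A [dram_sample()] result.
#' @param model_fn Function `(theta, grid) -> numeric(length(grid))`.
#' @param grid Ordered predictor values.
#' @param levels Coverage probabilities in (0, 1); default
#'   `c(0.5, 0.9, 0.95, 0.99)`.
#' @param n_draws Chain rows to use (capped at the post-burn-in length,
#'   with a warning).
#' @param include_observation_noise Add observation noise drawn from
#'   `s2chain`?
#' @param burn_in Fraction discarded before subsampling; default from the
#'   chain's config.
#' @param seed Optional seed for the subsampling (and noise) draws.
#' @return A `predictive_envelope`: `grid`, `median`, `levels`, and
#'   matrices `lower`/`upper` (`length(grid) x length(levels)`).
#' @export
predictive_envelope <- function(chain, model_fn, grid,
                                levels = c(0.5, 0.9, 0.95, 0.99),
                                n_draws = 500,
                                include_observation_noise = FALSE,
                                burn_in = NULL, seed = NULL) {
  stopifnot(inherits(chain, "dram_chain"), length(grid) >= 1,
            all(levels > 0), all(levels < 1))
  levels <- sort(levels)
  keep <- post_burn_rows(chain, burn_in %||% chain$config$burn_in)
  if (n_draws > length(keep)) {
    warning("n_draws exceeds post-burn-in chain length; capped at ",
            length(keep))
    n_draws <- length(keep)
  }
  with_seed(seed, {
    rows <- sample(keep, n_draws, replace = FALSE)
    G <- length(grid)
    curves <- matrix(NA_real_, n_draws, G)
    for (k in seq_len(n_draws)) {
      f <- model_fn(chain$samples[rows[k], ], grid)
      if (include_observation_noise)
        f <- f + rnorm(G, 0, sqrt(chain$s2chain[rows[k]]))
      curves[k, ] <- f
    }
    lower <- sapply(levels, function(L)
      apply(curves, 2, quantile, probs = (1 - L) / 2, names = FALSE))
    upper <- sapply(levels, function(L)
      apply(curves, 2, quantile, probs = 1 - (1 - L) / 2, names = FALSE))
    lower <- matrix(lower, G, dimnames = list(NULL, levels))
    upper <- matrix(upper, G, dimnames = list(NULL, levels))
    structure(list(grid = grid, levels = levels,
                   median = apply(curves, 2, median),
                   lower = lower, upper = upper,
                   include_observation_noise = include_observation_noise),
              class = "predictive_envelope")
  })
}

#' Summary diagnostics of a DRAM chain
#'
#' @param chain A [dram_sample()] result.
#' @param burn_in Fraction of the chain discarded (default from the chain's
#'   config; 0 summarizes the full chain).
#' @param ci_level Credible-interval coverage (default 0.95, central).
#' @return A list: per-parameter `mean`, `sd`, `ci` (matrix), `ess`;
#'   `sigma2` posterior mean; acceptance rates by stage; `n_used`.
#' @export
chain_diagnostics <- function(chain, burn_in = NULL, ci_level = 0.95) {
  stopifnot(inherits(chain, "dram_chain"))
  keep <- post_burn_rows(chain, burn_in %||% chain$config$burn_in)
  S <- chain$samples[keep, , drop = FALSE]
  a <- (1 - ci_level) / 2
  n <- chain$config$n_steps
  list(
    mean = colMeans(S),
    sd = apply(S, 2, sd),
    ci = t(apply(S, 2, quantile, probs = c(a, 1 - a))),
    ess = apply(S, 2, ess),
    sigma2_mean = mean(chain$s2chain[keep]),
    accept_rate_stage1 = chain$accept_stage1 / n,
    accept_rate_stage2 = if (chain$n_stage2_tries > 0)
      chain$accept_stage2 / chain$n_stage2_tries else NA_real_,
    accept_rate_overall = (chain$accept_stage1 + chain$accept_stage2) / n,
    n_used = length(keep)
  )
}

#' Replicate-run harness for DRAM
#'
#' Repeats [dram_sample()] with consecutive seeds and collects the chains;
#' off by default in all analyses, provided for variability studies of the
#' sampler itself.
#'
#' @param n_replicates Number of independent chains.
#' @param init,config,... Passed to [dram_sample()]; replicate `k` runs
#'   with seed `config$seed + k - 1`.
#' @return A list of `dram_chain` objects.
#' @export
dram_replicates <- function(n_replicates, init, config, ...) {
  stopifnot(n_replicates >= 1)
  lapply(seq_len(n_replicates), function(k) {
    cfg <- config
    cfg$seed <- config$seed + k - 1L
    dram_sample(init = init, config = cfg, ...)
  })
}

#' Serialize / restore a chain as CSV plus a JSON-free config sidecar
#'
#' Writes one row per step with named parameter columns plus `s2` and
#' `logpost`; the config and acceptance bookkeeping go to a plain
#' key-value sidecar `<path>.meta`.
#'
#' @param chain A `dram_chain`.
#' @param path Output CSV path.
#' @param par_names Optional parameter column names.
#' @return `path`, invisibly.
#' @export
write_chain_csv <- function(chain, path, par_names = NULL) {
  stopifnot(inherits(chain, "dram_chain"))
  d <- ncol(chain$samples)
  par_names <- par_names %||% paste0("par", seq_len(d))
  df <- as.data.frame(chain$samples)
  names(df) <- par_names
  df$s2 <- chain$s2chain
  df$logpost <- chain$logpost
  write.csv(df, path, row.names = FALSE)
  meta <- c(unlist(chain$config[c("n_steps", "seed", "adapt_start",
                                  "adapt_interval", "dr_scale", "n_stages",
                                  "burn_in")]),
            accept_stage1 = chain$accept_stage1,
            accept_stage2 = chain$accept_stage2,
            n_stage2_tries = chain$n_stage2_tries)
  writeLines(paste(names(meta), meta, sep = " = "),
             paste0(path, ".meta"))
  invisible(path)
}
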