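#' Fit the two-parameter Monod growth law by least squares
#'
#' Minimizes `sum((mu_obs - theta1 * S / (theta2 + S))^2)` with a
#' derivative-free Nelder-Mead simplex search, started from the
#' double-reciprocal (Lineweaver-Burk-style) linearization of `1/mu`
#' against `1/S`. Intended for specific-growth-rate observations at low
#' substrate, where substrate- and product-inhibition terms are negligible
#' and the full growth law reduces to Monod form.
#'
#' @param data Data frame with columns `S` (g/L, >= 0) and `mu_obs` (1/h,
#'   >= 0); at least 3 points at >= 2 distinct substrate levels.
#' @param start Optional `c(theta1, theta2)` start; default from the
#'   double-reciprocal plot.
#' @param n_starts Extra deterministic rescaled starts (both parameters
#'   scaled by 1/4x to 4x) to guard against poor linearization starts;
#'   default 5.
#' @return A `monod_fit` list: `theta1` (max rate, 1/h), `theta2`
#'   (saturation constant, g/L), `ssq`, `n_points`, `n_params` (2),
#'   `converged`, `start`, and the `data` and objective used.
#' @examples
#' S <- c(5, 10, 15, 20, 25)
#' fit_monod(data.frame(S = S, mu_obs = 0.48 * S / (1.71 + S)))
#' @export
fit_monod <- function(data, start = NULL, n_starts = 5) {
  stopifnot(all(c("S", "mu_obs") %in% names(data)))
  if (any(data$S < 0) || any(data$mu_obs < 0))
    stop("S and mu_obs must be nonnegative")
  if (nrow(data) < 3 || length(unique(data$S)) < 2)
    stop("need >= 3 points at >= 2 distinct substrate levels")
  if (all(data$mu_obs == 0)) stop("all growth rates are zero; nothing to fit")
  obj <- function(th) {
    if (any(th <= 0)) return(Inf)
    sum((data$mu_obs - th[1] * data$S / (th[2] + data$S))^2)
  }
  if (is.null(start)) {
    ok <- data$S > 0 & data$mu_obs > 0
    start <- if (sum(ok) >= 2) {
      lb <- coef(lm(I(1 / data$mu_obs[ok]) ~ I(1 / data$S[ok])))
      th1 <- 1 / lb[1]
      th2 <- lb[2] / lb[1]
      if (!all(is.finite(c(th1, th2))) || th1 <= 0 || th2 <= 0)
        c(max(data$mu_obs) * 1.1, stats::median(data$S))
      else unname(c(th1, th2))
    } else c(max(data$mu_obs) * 1.1, stats::median(data$S))
  }
  scales <- c(1, 0.5, 2, 0.25, 4)[seq_len(max(1, n_starts))]
  best <- NULL
  for (s in scales) {
    o <- optim(start * s, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
  }
  structure(list(theta1 = best$par[1], theta2 = best$par[2],
                 ssq = best$value, n_points = nrow(data), n_params = 2L,
                 converged = best$convergence == 0, start = start,
                 objective = obj, estimates = setNames(best$par,
                                                       c("theta1", "theta2")),
                 data = data),
            class = c("monod_fit", "growth_fit"))
}

#' Fit the substrate-inhibition (Haldane) growth law by least squares
#'
#' Minimizes `sum((mu_obs - mu_m * S / (S + K_S + S^2/K_I))^2)` over
#' `(mu_m, K_S, K_I)` by Nelder-Mead from data-driven starts (Monod
#' linearization for `mu_m`, `K_S`; twice the largest substrate level for
#' `K_I`), with the same deterministic multi-start ladder as [fit_monod()].
#' Note `K_I` is only weakly identified unless the data extend beyond the
#' growth optimum `sqrt(K_S K_I)`.
#'
#' @inheritParams fit_monod
#' @param start Optional `c(mu_m, K_S, K_I)` start.
#' @return A `haldane_fit` list analogous to [fit_monod()], with
#'   `estimates` named `mu_m`, `K_S`, `K_I` and `n_params` 3.
#' @export
fit_haldane <- function(data, start = NULL, n_starts = 5) {
  stopifnot(all(c("S", "mu_obs") %in% names(data)))
  if (nrow(data) < 4 || length(unique(data$S)) < 3)
    stop("need >= 4 points at >= 3 distinct substrate levels")
  if (all(data$mu_obs == 0)) stop("all growth rates are zero; nothing to fit")
  obj <- function(th) {
    if (any(th <= 0)) return(Inf)
    sum((data$mu_obs - th[1] * data$S / (data$S + th[2] + data$S^2 / th[3]))^2)
  }
  if (is.null(start)) {
    m <- tryCatch(fit_monod(data), error = function(e) NULL)
    start <- if (!is.null(m)) c(m$theta1, max(m$theta2, 1e-2), 2 * max(data$S))
             else c(max(data$mu_obs) * 1.2, stats::median(data$S),
                    2 * max(data$S))
  }
  scales <- c(1, 0.5, 2, 0.25, 4)[seq_len(max(1, n_starts))]
  best <- NULL
  for (s in scales) {
    o <- optim(start * s, obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
  }
  structure(list(estimates = setNames(best$par, c("mu_m", "K_S", "K_I")),
                 ssq = best$value, n_points = nrow(data), n_params = 3L,
                 converged = best$convergence == 0, start = start,
                 objective = obj, data = data),
            class = c("haldane_fit", "growth_fit"))
}

#' Weighted sum of squares between a simulation and an observed time course
#'
#' Simulates the batch model at the observed sampling times (initial state
#' taken from the fit spec, or the first observed row) and accumulates
#' weighted squared residuals over the four state variables. By default
#' each variable is weighted by the inverse square of its observed range,
#' so glucose (tens of g/L) does not dominate biomass (a few g/L).
#' Simulation failure yields `+Inf` (optimizer-safe), not an error.
#'
#' @param params A [kinetic_params()] object.
#' @param observed A `timecourse` data frame (`t`, `X`, `S`, `P_Ba`,
#'   `P_Aa`), nonempty.
#' @param weights Optional named per-variable weights (`X`, `S`, `P_Ba`,
#'   `P_Aa`); default `1/range^2` per variable (1 for constant variables).
#' @param initial Optional [fermentation_state()]; default the first
#'   observed row.
#' @return The scalar weighted sum of squares.
#' @export
ssq_timecourse <- function(params, observed, weights = NULL, initial = NULL) {
  vars <- c("X", "S", "P_Ba", "P_Aa")
  stopifnot(nrow(observed) >= 1, all(c("t", vars) %in% names(observed)))
  if (is.null(weights)) {
    rg <- vapply(vars, function(v) diff(range(observed[[v]])), numeric(1))
    weights <- setNames(ifelse(rg > 0, 1 / rg^2, 1), vars)
  }
  weights <- weights[vars]
  ord <- order(observed$t)
  obs <- observed[ord, ]
  if (is.null(initial))
    initial <- fermentation_state(t = obs$t[1], X = obs$X[1], S = obs$S[1],
                                  P_Ba = obs$P_Ba[1], P_Aa = obs$P_Aa[1])
  sim <- tryCatch(
    simulate_batch(params, initial, t_eval = unique(obs$t)),
    error = function(e) NULL
  )
  if (is.null(sim)) return(Inf)
  idx <- match(obs$t, sim$t)
  sum(vapply(vars, function(v)
    weights[[v]] * sum((obs[[v]] - sim[[v]][idx])^2), numeric(1)))
}

#' Specification of a time-course fit
#'
#' Declares which kinetic parameters are free, their starting values and
#' box bounds, the fixed remainder, residual weights and the initial state.
#'
#' @param free Named numeric vector of starting values for the parameters
#'   to estimate (names from [kinetic_params()]).
#' @param fixed A [kinetic_params()] object supplying every parameter not
#'   being estimated (free entries override it during fitting).
#' @param lower,upper Named bounds for the free parameters; defaults: rates
#'   (`mu_m`, `K_d`, `m_S`, `beta_*`) in `[1e-6, 10]`, concentrations and
#'   the rest in `[1e-3, 1e4]`.
#' @param weights Optional per-variable residual weights (see
#'   [ssq_timecourse()]).
#' @param initial_state A [fermentation_state()].
#' @return A `timecourse_fit_spec` list.
#' @export
timecourse_fit_spec <- function(free, fixed, lower = NULL, upper = NULL,
                                weights = NULL, initial_state) {
  stopifnot(inherits(fixed, "kinetic_params"), is.numeric(free))
  if (length(free) && is.null(names(free))) stop("free must be named")
  bad <- setdiff(names(free), PARAM_NAMES)
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  rate_like <- c("mu_m", "K_d", "m_S", "beta_Ba", "beta_Aa")
  def_lo <- ifelse(names(free) %in% rate_like, 1e-6, 1e-3)
  def_hi <- ifelse(names(free) %in% rate_like, 10, 1e4)
  lower <- setNames(as.numeric(lower %||% def_lo), names(free))
  upper <- setNames(as.numeric(upper %||% def_hi), names(free))
  if (length(free) && any(lower >= upper))
    stop("need lower < upper for every free parameter")
  if (length(free) && any(free < lower | free > upper))
    stop("free starting values must lie within their bounds")
  structure(list(free = free, fixed = fixed, lower = lower, upper = upper,
                 weights = weights, initial_state = initial_state),
            class = "timecourse_fit_spec")
}

#' Fit kinetic parameters to an observed fermentation time course
#'
#' Estimates the free parameters of a [timecourse_fit_spec()] by weighted
#' least squares on [ssq_timecourse()]. `method = "simplex"` uses
#' derivative-free local search (Brent within bounds for one free
#' parameter, Nelder-Mead with bound rejection otherwise).
#' `method = "mcmc"` runs [dram_sample()] on the same sum-of-squares
#' target (Gaussian likelihood, conjugate error-variance chain) and
#' returns posterior means alongside the chain.
#'
#' @param observed A `timecourse` data frame of observations.
#' @param spec A [timecourse_fit_spec()].
#' @param method `"simplex"` or `"mcmc"`.
#' @param mcmc_config An [mcmc_config()] (required for `"mcmc"`).
#' @return A `timecourse_fit` list: `estimates` (free parameters),
#'   `params` (full [kinetic_params()] with estimates substituted),
#'   `objective` value at the estimate, `converged`, `at_bound` warning
#'   flag, `method`, `spec`, and `chain`/`diagnostics` for MCMC fits. With
#'   no free parameters the fixed set is returned unchanged with its
#'   objective.
#' @examples
#' \donttest{
#' p <- load_fixture("table4")
#' tc <- generate_timecourse(p, fermentation_state(S = 60),
#'                           t_eval = seq(0, 72, 8), sigma = 0.02, seed = 1)
#' sp <- timecourse_fit_spec(free = c(mu_m = 0.3), fixed = p,
#'                           initial_state = fermentation_state(S = 60))
#' fit_timecourse(tc, sp)$estimates
#' }
#' @export
fit_timecourse <- function(observed, spec, method = c("simplex", "mcmc"),
                           mcmc_config = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "timecourse_fit_spec"))
  n_free <- length(spec$free)
  obj <- function(v) {
    th <- setNames(v, names(spec$free))
    if (any(v < spec$lower | v > spec$upper)) return(Inf)
    p <- tryCatch(update_params(spec$fixed, th), error = function(e) NULL)
    if (is.null(p)) return(Inf)
    ssq_timecourse(p, observed, weights = spec$weights,
                   initial = spec$initial_state)
  }
  if (n_free == 0) {
    return(structure(list(estimates = numeric(0), params = spec$fixed,
                          objective = ssq_timecourse(spec$fixed, observed,
                                                     spec$weights,
                                                     spec$initial_state),
                          converged = TRUE, at_bound = FALSE,
                          method = method, spec = spec),
                     class = "timecourse_fit"))
  }

  if (method == "simplex") {
    if (n_free == 1) {
      o <- optim(spec$free, obj, method = "Brent",
                 lower = spec$lower, upper = spec$upper,
                 control = list(reltol = 1e-12))
    } else {
      o <- optim(spec$free, obj, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-10))
    }
    est <- setNames(o$par, names(spec$free))
    conv <- o$convergence == 0
    value <- o$value
    chain <- NULL; diag <- NULL
  } else {
    if (is.null(mcmc_config)) stop("mcmc_config is required for method 'mcmc'")
    n_obs <- nrow(observed) * 4L
    chain <- dram_sample(init = spec$free, config = mcmc_config,
                         ssfun = obj, n_obs = n_obs,
                         lower = spec$lower, upper = spec$upper)
    diag <- chain_diagnostics(chain)
    est <- setNames(diag$mean, names(spec$free))
    conv <- is.null(chain$flagged)
    value <- obj(est)
  }
  at_bound <- any(abs(est - spec$lower) < 1e-8 * pmax(1, abs(spec$lower))) ||
    any(abs(est - spec$upper) < 1e-8 * pmax(1, abs(spec$upper)))
  if (at_bound)
    warning("estimate lies on a bound; treat convergence with caution")
  structure(list(estimates = est,
                 params = update_params(spec$fixed, est),
                 objective = value, converged = conv, at_bound = at_bound,
                 method = method, spec = spec, chain = chain,
                 diagnostics = diag, objective_fn = obj,
                 n_points = nrow(observed) * 4L, n_params = n_free),
            class = "timecourse_fit")
}

#' Residual and curvature diagnostics of a least-squares fit
#'
#' Reports the residual sum of squares `S_R`, the number of observations
#' `n` and parameters `p`, the residual mean square `S_R / (n - p)`, and
#' per-parameter approximate confidence intervals from a finite-difference
#' curvature (Hessian) estimate of the sum-of-squares surface:
#' `cov = 2 * s2 * H^-1`, t-based intervals on `n - p` degrees of freedom.
#' With zero residuals the intervals collapse onto the estimates.
#'
#' @param fit A [fit_monod()], [fit_haldane()] or [fit_timecourse()]
#'   result.
#' @param level Confidence level (default 0.95).
#' @return A list: `S_R`, `n`, `p`, `residual_mean_square`, `estimates`,
#'   `se`, `ci` (matrix with `lower`/`upper`).
#' @examples
#' S <- c(5, 10, 15, 20, 25)
#' f <- fit_monod(data.frame(S = S, mu_obs = 0.48 * S / (1.71 + S) +
#'                                   c(0.001, -0.002, 0.001, 0, -0.001)))
#' fit_diagnostics(f)$residual_mean_square
#' @export
fit_diagnostics <- function(fit, level = 0.95) {
  if (inherits(fit, "growth_fit")) {
    est <- fit$estimates; n <- fit$n_points; p <- fit$n_params
    obj <- fit$objective; S_R <- fit$ssq
  } else if (inherits(fit, "timecourse_fit")) {
    est <- fit$estimates; n <- fit$n_points; p <- fit$n_params
    obj <- fit$objective_fn; S_R <- fit$objective
    if (p == 0) stop("no free parameters to report intervals for")
  } else stop("unsupported fit object")
  if (n <= p) stop("need n > p for residual diagnostics")
  s2 <- S_R / (n - p)
  se <- rep(0, p)
  if (S_R > 0) {
    H <- fd_hessian(obj, unname(est))
    cv <- tryCatch(2 * s2 * solve(H), error = function(e) NULL)
    if (!is.null(cv)) {
      dg <- diag(as.matrix(cv))
      se <- ifelse(dg > 0, sqrt(dg), NA_real_)
    } else se <- rep(NA_real_, p)
  }
  tq <- qt(1 - (1 - level) / 2, df = n - p)
  ci <- cbind(lower = est - tq * se, upper = est + tq * se)
  list(S_R = S_R, n = n, p = p, residual_mean_square = s2,
       estimates = est, se = setNames(se, names(est)), ci = ci)
}
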