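#' Construct a survival table for dose-lethality analysis
#'
#' A survival table holds, for one irradiated sample, the number of colony
#' strains exposed at each dose and the number killed. Lethality is modelled
#' downstream as binomial with a logistic dependence on log10(dose);
#' survival is always `1 - lethality`.
#'
#' @param sample_id Character label for the sample (e.g. `"Q36-8"`).
#' @param dose_gy Numeric vector of irradiation doses in Gy, strictly
#'   increasing and positive.
#' @param n_total Integer vector, colonies irradiated at each dose.
#' @param n_lethal Integer vector, colonies killed at each dose
#'   (`0 <= n_lethal <= n_total`).
#' @return A `survival_table`: a data frame with columns `sample_id`,
#'   `dose_gy`, `log_dose` (= log10 dose), `n_total`, `n_lethal` and
#'   `survival_prop` (= `(n_total - n_lethal) / n_total`).
#' @examples
#' survival_table("demo", c(50, 80), c(6000, 6000), c(900, 5900))
#' @export
survival_table <- function(sample_id, dose_gy, n_total, n_lethal) {
  stopifnot(length(dose_gy) == length(n_total),
            length(dose_gy) == length(n_lethal))
  if (!all(is.finite(dose_gy)) || any(dose_gy <= 0))
    stop("doses must be finite and > 0")
  if (is.unsorted(dose_gy, strictly = TRUE))
    stop("doses must be strictly increasing")
  if (any(n_total <= 0)) stop("n_total must be positive")
  if (any(n_lethal < 0) || any(n_lethal > n_total))
    stop("n_lethal must satisfy 0 <= n_lethal <= n_total")
  out <- data.frame(
    sample_id = as.character(sample_id),
    dose_gy = as.numeric(dose_gy),
    log_dose = log10(dose_gy),
    n_total = as.numeric(n_total),
    n_lethal = as.numeric(n_lethal),
    survival_prop = (n_total - n_lethal) / n_total,
    stringsAsFactors = FALSE
  )
  class(out) <- c("survival_table", "data.frame")
  out
}

#' Read survival tables from CSV
#'
#' Expects columns `sample_id,dose_gy,n_total,n_lethal` (extra columns are
#' ignored). Log-dose and survival proportions are always derived from the
#' counts, never read from the file.
#'
#' @param path Path to the CSV file.
#' @param sample Optional sample id to extract; default returns all samples
#'   as a named list of [survival_table()] objects.
#' @return A `survival_table` (when `sample` is given) or a named list of
#'   them, one per sample.
#' @export
read_survival_csv <- function(path, sample = NULL) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "dose_gy", "n_total", "n_lethal")
  if (!all(need %in% names(raw)))
    stop("CSV must have columns ", paste(need, collapse = ", "))
  tables <- lapply(split(raw, raw$sample_id), function(d) {
    d <- d[order(d$dose_gy), ]
    survival_table(d$sample_id[1], d$dose_gy, d$n_total, d$n_lethal)
  })
  if (is.null(sample)) return(tables[unique(raw$sample_id)])
  if (!sample %in% names(tables)) stop("no sample '", sample, "' in ", path)
  tables[[sample]]
}

#' Logistic regression parameters for dose lethality
#'
#' @param beta0 Intercept on the logit scale (dimensionless).
#' @param beta1 Slope per unit covariate (per log10 Gy with the default
#'   log10-dose covariate).
#' @return An object of class `logistic_params`.
#' @export
logistic_params <- function(beta0, beta1) {
  stopifnot(is.finite(beta0), is.finite(beta1))
  structure(list(beta0 = as.numeric(beta0), beta1 = as.numeric(beta1)),
            class = "logistic_params")
}

#' Lethality probability under the logistic dose model
#'
#' Computes `p = exp(b0 + b1 x) / (1 + exp(b0 + b1 x))` with
#' `x = log10(dose)`, i.e. `logit(p) = beta0 + beta1 * x`.
#'
#' @param params A [logistic_params()] object.
#' @param log_dose Numeric vector of log10-dose values.
#' @return Lethality probabilities in (0, 1).
#' @examples
#' lethality_prob(logistic_params(0, 0), 1.8)  # 0.5
#' @export
lethality_prob <- function(params, log_dose) {
  stopifnot(inherits(params, "logistic_params"))
  if (!all(is.finite(log_dose))) stop("log_dose must be finite")
  plogis(params$beta0 + params$beta1 * log_dose)
}

#' Binomial log-likelihood of a survival table
#'
#' Sum over doses of the log binomial pmf of the lethal counts, with the
#' lethality probability given by [lethality_prob()] at each row's
#' log10-dose. The binomial coefficient is included, both here and in every
#' reported -2 log-likelihood, so likelihood values are comparable across
#' fitting and reporting. A fitted probability of exactly 0 or 1 that
#' disagrees with the observed counts yields `-Inf`, not an error.
#'
#' @param params A [logistic_params()] object.
#' @param table A [survival_table()].
#' @param covariate `"log10"` (default) or `"raw"` dose covariate.
#' @return The log-likelihood (scalar, possibly `-Inf`).
#' @export
binomial_loglik <- function(params, table, covariate = c("log10", "raw")) {
  covariate <- match.arg(covariate)
  stopifnot(inherits(table, "survival_table"))
  x <- if (covariate == "log10") table$log_dose else table$dose_gy
  p <- lethality_prob(params, x)
  sum(dbinom(table$n_lethal, table$n_total, p, log = TRUE))
}

# complete separation: some dose threshold splits the data into all-survive
# below and all-die above (MLE then diverges).
detect_separation <- function(table) {
  all_die <- table$n_lethal == table$n_total
  all_live <- table$n_lethal == 0
  any(vapply(seq_len(nrow(table) - 1), function(k) {
    all(all_live[1:k]) && all(all_die[(k + 1):nrow(table)])
  }, logical(1)))
}

# OLS on empirical logits with a 0.5 continuity correction; robust start
# for tables containing 0% or 100% lethality rows.
empirical_logit_start <- function(table, x) {
  p_emp <- (table$n_lethal + 0.5) / (table$n_total + 1)
  fit <- lm(qlogis(p_emp) ~ x)
  unname(coef(fit))
}

#' Maximum-likelihood fit of the binomial-logistic dose-lethality model
#'
#' Maximizes [binomial_loglik()] over `(beta0, beta1)` by Nelder-Mead from
#' an ordinary-least-squares start on continuity-corrected empirical logits,
#' then polishes with BFGS. Rows with 0% or 100% survival are retained in
#' the likelihood; the continuity correction is used only to initialize.
#'
#' @param table A [survival_table()] with at least 2 distinct doses and not
#'   all-survive or all-die at every dose.
#' @param covariate `"log10"` (default, matching the log-dose design) or
#'   `"raw"`.
#' @return A `dose_response_fit` list: `params` ([logistic_params()]),
#'   `m2ll` (-2 log-likelihood at the optimum, binomial coefficients
#'   included), `converged`, `separation` flag, `fitted_lethality` and
#'   `fitted_survival` per dose, plus the `table` and `covariate` used.
#'   Complete separation is flagged and warned about, with the (boundary)
#'   parameters still returned.
#' @examples
#' tab <- load_fixture("table2")$`Q36-8`
#' fit <- fit_mle(tab)
#' fit$params
#' @export
fit_mle <- function(table, covariate = c("log10", "raw")) {
  covariate <- match.arg(covariate)
  stopifnot(inherits(table, "survival_table"))
  if (length(unique(table$dose_gy)) < 2)
    stop("need at least 2 distinct doses")
  if (all(table$n_lethal == 0) || all(table$n_lethal == table$n_total))
    stop("degenerate table: no information on the dose effect")
  x <- if (covariate == "log10") table$log_dose else table$dose_gy
  start <- empirical_logit_start(table, x)
  nll <- function(b) {
    v <- binomial_loglik(logistic_params(b[1], b[2]), table, covariate)
    if (!is.finite(v)) return(1e10)
    -v
  }
  opt <- optim(start, nll, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  opt <- optim(opt$par, nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  sep <- detect_separation(table)
  if (sep)
    warning("complete separation: MLE lies on the parameter-space boundary; ",
            "estimates reflect the optimizer's stopping point")
  params <- logistic_params(opt$par[1], opt$par[2])
  p_hat <- lethality_prob(params, x)
  structure(list(
    params = params,
    m2ll = 2 * nll(opt$par),
    loglik = -nll(opt$par),
    converged = opt$convergence == 0,
    separation = sep,
    fitted_lethality = p_hat,
    fitted_survival = 1 - p_hat,
    table = table,
    covariate = covariate
  ), class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("Binomial-logistic dose-lethality fit (", x$covariate,
      "-dose covariate)\n", sep = "")
  cat(sprintf("  beta0 = %.4f, beta1 = %.4f\n",
              x$params$beta0, x$params$beta1))
  cat(sprintf("  -2 log-likelihood = %.2f; converged: %s%s\n", x$m2ll,
              x$converged, if (x$separation) "; SEPARATION" else ""))
  invisible(x)
}

#' Merge the counts of several survival tables dose-by-dose
#'
#' Pools samples irradiated under a common dose design into a single table
#' (counts summed per dose), e.g. to fit one lethality curve to all samples.
#'
#' @param tables A list of [survival_table()] objects sharing the same doses.
#' @param sample_id Label for the pooled table.
#' @return A [survival_table()].
#' @export
pool_survival_tables <- function(tables, sample_id = "pooled") {
  stopifnot(length(tables) >= 1)
  doses <- tables[[1]]$dose_gy
  for (t in tables)
    if (!isTRUE(all.equal(t$dose_gy, doses)))
      stop("all tables must share the same dose design")
  survival_table(sample_id, doses,
                 Reduce(`+`, lapply(tables, `[[`, "n_total")),
                 Reduce(`+`, lapply(tables, `[[`, "n_lethal")))
}

#' Survival proportions of a table, with reporting rounding
#'
#' Recomputes each row's survival proportion from the counts and reports it
#' rounded half-up to 4 decimals (the printed-table convention), together
#' with the min/max over the nonzero entries.
#'
#' @param table A [survival_table()].
#' @return A list with `proportions` (raw), `reported` (4-decimal half-up),
#'   and `range_nonzero` (min/max of the nonzero raw proportions).
#' @examples
#' survival_summary(survival_table("x", c(50, 80), c(5900, 6200), c(900, 6200)))
#' @export
survival_summary <- function(table) {
  stopifnot(inherits(table, "survival_table"))
  if (any(table$n_total == 0)) stop("n_total must be positive")
  prop <- (table$n_total - table$n_lethal) / table$n_total
  nz <- prop[prop > 0]
  list(
    proportions = prop,
    reported = round_half_up(prop, 4),
    range_nonzero = if (length(nz)) range(nz) else c(NA_real_, NA_real_)
  )
}
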