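#' Butyrate-to-acetate productivity ratio
#'
#' The screening statistic delta = r_butyric / r_acetic used to call
#' improved mutants. Returned rounded half-up to 2 decimals (the reporting
#' convention of the screening tables); the raw ratio is attached as
#' attribute `"raw"`.
#'
#' @param r_butyric Butyric acid specific productivity (vectorized).
#' @param r_acetic Acetic acid specific productivity, > 0.
#' @return Rounded ratio(s) with attribute `raw`.
#' @examples
#' delta_ratio(34.32, 11.24)  # 3.05
#' @export
delta_ratio <- function(r_butyric, r_acetic) {
  if (any(!is.finite(r_acetic)) || any(r_acetic <= 0))
    stop("r_acetic must be finite and > 0")
  if (any(!is.finite(r_butyric)) || any(r_butyric < 0))
    stop("r_butyric must be finite and nonnegative")
  raw <- r_butyric / r_acetic
  structure(round_half_up(raw, 2), raw = raw)
}

#' Call a mutant positive or negative against the wild-type ratio
#'
#' A strain is "positive" (improved) iff its delta strictly exceeds the
#' wild-type delta; ties are negative.
#'
#' @param delta Mutant delta ratio(s).
#' @param wild_type_delta Baseline ratio; default 3.05, the wild-type
#'   butyrate:acetate productivity ratio.
#' @return Character vector, `"positive"` or `"negative"`.
#' @examples
#' classify_mutant(c(5.45, 3.05, 2.36))
#' @export
classify_mutant <- function(delta, wild_type_delta = 3.05) {
  stopifnot(all(delta > 0), wild_type_delta > 0)
  ifelse(as.numeric(delta) > wild_type_delta, "positive", "negative")
}

#' Screening-rate summary from group counts
#'
#' Computes the mutation rate `R_M/T = 100 M / T` and the positive rate
#' `R_P/T = 100 P / T` (percent) from the screening counts: `T` colonies
#' screened in total, of which `M` fall in the mutant subtotal and `P` in
#' the positive subtotal. Reported values are rounded half-up to 1
#' decimal; raw percentages are retained.
#'
#' @param P,M,T Nonnegative counts with `P, M <= T` and `T > 0`.
#' @return A `screening_summary` list: `n_total`, `n_positive_subtotal`,
#'   `n_subtotal_M`, `rate_M_over_T`, `rate_P_over_T` (1-decimal), and
#'   `raw` with the unrounded percentages.
#' @examples
#' screening_rates(P = 24, M = 81, T = 409)
#' @export
screening_rates <- function(P, M, T) {
  stopifnot(length(P) == 1, length(M) == 1, length(T) == 1)
  if (T <= 0) stop("T must be positive")
  if (P < 0 || M < 0 || P > T || M > T)
    stop("need 0 <= P, M <= T")
  raw <- c(rate_M_over_T = 100 * M / T, rate_P_over_T = 100 * P / T)
  structure(list(n_total = T, n_positive_subtotal = P, n_subtotal_M = M,
                 rate_M_over_T = round_half_up(raw[["rate_M_over_T"]], 1),
                 rate_P_over_T = round_half_up(raw[["rate_P_over_T"]], 1),
                 raw = raw),
            class = "screening_summary")
}

#' @export
print.screening_summary <- function(x, ...) {
  cat(sprintf("Screening summary: T = %d, M = %d, P = %d\n",
              x$n_total, x$n_subtotal_M, x$n_positive_subtotal))
  cat(sprintf("  R_M/T = %.1f%%  R_P/T = %.1f%%\n",
              x$rate_M_over_T, x$rate_P_over_T))
  invisible(x)
}

#' MTT-assay survival fraction
#'
#' `2^(-n)` with `n = t_delay / t_doubling`: the viability loss implied by
#' the delay (relative to unirradiated controls) in reaching a reference
#' absorbance, measured in population doublings.
#'
#' @param t_delay Hours of growth delay, >= 0.
#' @param t_doubling Population doubling time, hours, > 0.
#' @return Survival fraction(s) in (0, 1].
#' @examples
#' mtt_survival_fraction(10, 5)  # 0.25
#' @export
mtt_survival_fraction <- function(t_delay, t_doubling) {
  if (any(!is.finite(t_delay)) || any(t_delay < 0))
    stop("t_delay must be finite and nonnegative")
  if (any(!is.finite(t_doubling)) || any(t_doubling <= 0))
    stop("t_doubling must be finite and positive")
  2^(-t_delay / t_doubling)
}

#' Screen a productivity table for positive mutants
#'
#' Recomputes delta for every record and calls each strain against the
#' wild-type baseline.
#'
#' @param records Data frame with columns `sample_id`, `r_butyric`,
#'   `r_acetic` (and optionally `delta_printed`).
#' @param wild_type_delta Baseline ratio (default 3.05).
#' @return The input with added columns `delta` (2-decimal), `delta_raw`,
#'   and `call`.
#' @export
screen_mutants <- function(records, wild_type_delta = 3.05) {
  stopifnot(all(c("sample_id", "r_butyric", "r_acetic") %in% names(records)))
  d <- delta_ratio(records$r_butyric, records$r_acetic)
  records$delta <- as.numeric(d)
  records$delta_raw <- attr(d, "raw")
  # calls use the reported (2-decimal) ratio, so a strain tied with the
  # wild type at reporting precision is negative
  records$call <- classify_mutant(records$delta, wild_type_delta)
  records
}

#' Log disagreements between printed and recomputed delta ratios
#'
#' Compares each record's printed delta against the ratio recomputed from
#' its own productivities and reports rows differing by more than `tol`.
#' Printed values are data: they are reported, never overwritten.
#'
#' @param records Data frame with `sample_id`, `r_butyric`, `r_acetic`,
#'   `delta_printed`.
#' @param tol Absolute tolerance on the ratio (default 0.03, one reporting
#'   unit plus rounding slack).
#' @return Data frame of mismatching rows with `delta_printed`,
#'   `delta_computed` and `diff` columns (zero rows when all agree).
#' @export
delta_mismatch_log <- function(records, tol = 0.03) {
  stopifnot("delta_printed" %in% names(records))
  comp <- round_half_up(records$r_butyric / records$r_acetic, 2)
  diffs <- comp - records$delta_printed
  out <- data.frame(sample_id = records$sample_id,
                    delta_printed = records$delta_printed,
                    delta_computed = comp, diff = diffs,
                    stringsAsFactors = FALSE)
  out[abs(diffs) > tol, , drop = FALSE]
}

#' Read a screening productivity table from CSV
#'
#' Expects columns `sample_id,r_butyric,r_butyric_sd,r_acetic,r_acetic_sd`
#' (sd columns optional; extra columns kept).
#'
#' @param path CSV path.
#' @return A data frame of screening records.
#' @export
read_screening_csv <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "r_butyric", "r_acetic")
  if (!all(need %in% names(raw)))
    stop("CSV must have columns ", paste(need, collapse = ", "))
  if (any(raw$r_acetic <= 0)) stop("r_acetic must be > 0")
  raw
}
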