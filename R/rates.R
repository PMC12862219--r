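# Mutation-rate estimators and summaries.

#' False-negative rate from a spike-in simulation
#'
#' `FNR = 1 - n_detected / n_simulated`.
#'
#' @param n_detected,n_simulated Detected and spiked mutation counts.
#' @return Fraction in \[0, 1\].
#' @export
false_negative_rate <- function(n_detected, n_simulated) {
  stopifnot(n_simulated > 0)
  if (n_detected > n_simulated)
    stop("n_detected exceeds n_simulated")
  1 - n_detected / n_simulated
}

#' Germline mutation rate with false-negative correction
#'
#' Point estimate `mu = n_dnm / (callable_sum_bp * (1 - fnr))`.  The callable
#' size is the sum over offspring of per-offspring callable genome sizes and
#' is *not* doubled: the inherited contig set already represents an
#' approximately diploid genome per offspring.  The confidence interval is an
#' exact Poisson interval on the DNM count propagated through the same
#' denominator.
#'
#' @param n_dnm Total DNM count.
#' @param callable_sum_bp Summed callable size (bp) across offspring.
#' @param fnr False-negative rate in \[0, 1).
#' @param conf_level Confidence level (default 0.95).
#' @return List of class `rate_estimate`: `n_dnm, callable_sum_bp, fnr, mu,
#'   ci_low, ci_high, ci_method`.
#' @export
mutation_rate <- function(n_dnm, callable_sum_bp, fnr = 0,
                          conf_level = 0.95) {
  stopifnot(callable_sum_bp > 0, n_dnm >= 0)
  if (fnr < 0 || fnr >= 1) stop("fnr must be in [0, 1)")
  denom <- callable_sum_bp * (1 - fnr)
  a <- 1 - conf_level
  lo <- if (n_dnm == 0) 0 else stats::qchisq(a / 2, 2 * n_dnm) / 2
  hi <- stats::qchisq(1 - a / 2, 2 * (n_dnm + 1)) / 2
  structure(list(n_dnm = n_dnm, callable_sum_bp = callable_sum_bp,
                 fnr = fnr, mu = n_dnm / denom,
                 ci_low = lo / denom, ci_high = hi / denom,
                 ci_method = "poisson_exact"), class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf(
    "mutation rate: %.4g per base per generation (%d DNMs / %.4g bp, FNR %.3g)\n  95%% CI [%.4g, %.4g] (%s)\n",
    x$mu, x$n_dnm, x$callable_sum_bp, x$fnr, x$ci_low, x$ci_high,
    x$ci_method))
  invisible(x)
}

#' Male mutation bias (alpha)
#'
#' Raw alpha is the paternal/maternal DNM count ratio; corrected alpha
#' normalizes each count by the parent-specific callable size summed over
#' offspring.  The CI is Clopper-Pearson on the paternal fraction, mapped to
#' the alpha scale.
#'
#' @param n_paternal,n_maternal Phased DNM counts by origin (unphased DNMs
#'   are excluded beforehand).
#' @param paternal_callable_bp,maternal_callable_bp Optional parent-specific
#'   callable sizes; corrected alpha is reported only when both are given.
#' @param conf_level Confidence level (default 0.95).
#' @return List of class `alpha_estimate`.
#' @export
alpha_estimate <- function(n_paternal, n_maternal,
                           paternal_callable_bp = NULL,
                           maternal_callable_bp = NULL,
                           conf_level = 0.95) {
  stopifnot(n_paternal >= 0, n_maternal >= 0)
  raw <- if (n_maternal == 0) NA_real_ else n_paternal / n_maternal
  n <- n_paternal + n_maternal
  a <- 1 - conf_level
  p_lo <- if (n_paternal == 0) 0 else
    stats::qbeta(a / 2, n_paternal, n_maternal + 1)
  p_hi <- if (n_paternal == n) 1 else
    stats::qbeta(1 - a / 2, n_paternal + 1, n_maternal)
  to_alpha <- function(p) if (p >= 1) Inf else p / (1 - p)
  corr <- ci_scale <- NA_real_
  if (!is.null(paternal_callable_bp) && !is.null(maternal_callable_bp)) {
    stopifnot(paternal_callable_bp > 0, maternal_callable_bp > 0)
    ci_scale <- maternal_callable_bp / paternal_callable_bp
    corr <- if (is.na(raw)) NA_real_ else raw * ci_scale
  } else ci_scale <- 1
  structure(list(
    n_paternal = n_paternal, n_maternal = n_maternal,
    alpha_raw = raw, alpha_corrected = corr,
    ci_low = to_alpha(p_lo) * ci_scale,
    ci_high = to_alpha(p_hi) * ci_scale), class = "alpha_estimate")
}

#' Effective population size from nucleotide diversity
#'
#' Under neutrality `pi = 4 Ne mu`, so `Ne = pi / (4 mu)`.
#'
#' @param pi Nucleotide diversity (e.g. at synonymous sites).
#' @param mu Per-base per-generation mutation rate.
#' @return List with `pi`, `mu`, `ne`.
#' @export
effective_population_size <- function(pi, mu) {
  if (!is.numeric(pi) || !is.numeric(mu) || pi <= 0 || mu <= 0)
    stop("pi and mu must be positive")
  list(pi = pi, mu = mu, ne = pi / (4 * mu))
}

#' Fisher's exact contrast of a 2x2 origin table
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @return List with `odds_ratio`, `p_value`, `degenerate` (TRUE when a
#'   margin is zero; then p = 1 by convention).
#' @export
origin_contrast <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(odds_ratio = NA_real_, p_value = 1, degenerate = TRUE))
  ft <- stats::fisher.test(tab)
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value,
       degenerate = FALSE)
}
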