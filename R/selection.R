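#' Assemble a McDonald-Kreitman 2x2 table
#'
#' Fixed and polymorphic substitution counts inside (TFBS) and outside
#' (NTFBS) binding sites under one annotation method.
#'
#' @param fixed_tfbs,fixed_ntfbs,poly_tfbs,poly_ntfbs non-negative counts.
#' @param method_label annotation method the table refers to.
#' @return object of class `mk_table`.
#' @export
mk_table <- function(fixed_tfbs, fixed_ntfbs, poly_tfbs, poly_ntfbs,
                     method_label = "") {
  cells <- c(fixed_tfbs, fixed_ntfbs, poly_tfbs, poly_ntfbs)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  structure(list(fixed_tfbs = fixed_tfbs, fixed_ntfbs = fixed_ntfbs,
                 poly_tfbs = poly_tfbs, poly_ntfbs = poly_ntfbs,
                 method_label = method_label),
            class = "mk_table")
}

#' @export
print.mk_table <- function(x, ...) {
  m <- matrix(c(x$fixed_tfbs, x$fixed_ntfbs, x$poly_tfbs, x$poly_ntfbs), 2L,
              dimnames = list(c("TFBS", "NTFBS"), c("fixed", "polymorphic")))
  cat("mk_table [", x$method_label, "]\n", sep = "")
  print(m)
  cat("two-tailed Fisher P =", format(mk_fisher_test(x)), "\n")
  invisible(x)
}

#' Two-tailed Fisher exact test of an MK table
#'
#' Exact P-value by summation over the hypergeometric support: with margins
#' fixed, the two-tailed P is the sum of the probabilities of all tables
#' whose probability does not exceed that of the observed table (the
#' dominant convention in population-genetics software).  A one-sided tail
#' is available via `alternative`.
#'
#' @param table an `mk_table`, or a 2x2 numeric matrix.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (association of the TFBS row with the fixed column).
#' @return the P-value, or `NA` if a margin is zero.
#' @export
mk_fisher_test <- function(table, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  m <- if (inherits(table, "mk_table"))
    matrix(c(table$fixed_tfbs, table$fixed_ntfbs,
             table$poly_tfbs, table$poly_ntfbs), 2L)
  else as.matrix(table)
  a <- m[1L, 1L]
  r1 <- sum(m[1L, ]); r2 <- sum(m[2L, ]); c1 <- sum(m[, 1L])
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(m[, 2L]) == 0) return(NA_real_)
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  switch(alternative,
         two.sided = sum(probs[probs <= p_obs * (1 + 1e-7)]),
         greater = sum(probs[support >= a]),
         less = sum(probs[support <= a]))
}

#' Equilibrium relative fixation rate in binding sites
#'
#' Under gain/loss equilibrium, half of the gain-or-loss substitutions occur
#' inside sites, so the best estimate of the number of fixed substitutions
#' occurring in TFBS bases is `T = n_gain_plus_loss / 2 + n_change`.  The
#' relative fixation rate in TFBSs versus NTFBSs is
#' `T / (total_fixed * frac_tfbs)`.
#'
#' @param n_gain_plus_loss substitutions that create or destroy a site.
#' @param n_change substitutions converting one site into another.
#' @param total_fixed all fixed substitutions.
#' @param frac_tfbs TFBS base fraction, in (0,1).
#' @return list with `equilibrium_tfbs_subs` (T), `relative_rate`,
#'   `percent_change` (`(rate - 1) * 100`).
#' @export
equilibrium_relative_rate <- function(n_gain_plus_loss, n_change,
                                      total_fixed, frac_tfbs) {
  if (total_fixed <= 0) stop("total_fixed must be positive")
  if (frac_tfbs <= 0 || frac_tfbs >= 1)
    stop("domain error: frac_tfbs must be in (0,1)")
  T_eq <- n_gain_plus_loss / 2 + n_change
  rate <- T_eq / (total_fixed * frac_tfbs)
  list(equilibrium_tfbs_subs = T_eq, relative_rate = rate,
       percent_change = (rate - 1) * 100)
}

#' Chi-squared test of substitution counts against base composition
#'
#' Compares observed TFBS/NTFBS substitution counts with the expectation
#' under equal per-base rates (`E_tfbs = N * frac`, `E_ntfbs = N * (1 -
#' frac)`), df = 1.
#'
#' @param observed_tfbs,observed_ntfbs observed substitution counts.
#' @param frac_tfbs TFBS base fraction.
#' @param yates apply Yates' continuity correction (default `FALSE`).
#' @return list with `chi2`, `p`, `expected` (named vector) and a validity
#'   `warning_small_expected` flag when an expected cell is below 1.
#' @export
composition_expected_chisq <- function(observed_tfbs, observed_ntfbs,
                                       frac_tfbs, yates = FALSE) {
  N <- observed_tfbs + observed_ntfbs
  if (N <= 0) stop("no observations")
  E <- c(tfbs = N * frac_tfbs, ntfbs = N * (1 - frac_tfbs))
  O <- c(tfbs = observed_tfbs, ntfbs = observed_ntfbs)
  dev <- abs(O - E)
  if (yates) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / E)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE),
       expected = E, warning_small_expected = any(E < 1))
}

#' Relative per-base substitution rate inside versus outside a footprint
#'
#' `(subs_in / frac_in) / (subs_out / frac_out)`; fractions may be given as
#' base-count shares or raw base counts (only their ratio matters).
#'
#' @param subs_in,subs_out substitution counts inside / outside.
#' @param frac_in,frac_out base fractions (or counts) inside / outside.
#' @return list with `relative_rate` and `percent_change`
#'   (`(rate - 1) * 100`; negative = slower inside).
#' @export
footprint_relative_rate <- function(subs_in, subs_out, frac_in, frac_out) {
  if (subs_out <= 0 || frac_in <= 0 || frac_out <= 0)
    stop("undefined rate: zero denominator")
  rate <- (subs_in / frac_in) / (subs_out / frac_out)
  list(relative_rate = rate, percent_change = (rate - 1) * 100)
}

#' Exact binomial test for an excess of losses over gains
#'
#' Two-sided exact binomial test of `n_gain` successes in
#' `n_gain + n_loss` trials against p = 1/2 (probability-mass summation,
#' matching [stats::binom.test()]).
#'
#' @param n_gain,n_loss counted gains and losses.
#' @return two-sided P-value.
#' @export
gain_loss_excess_test <- function(n_gain, n_loss) {
  n <- n_gain + n_loss
  if (n < 1L) stop("need at least one gain or loss")
  probs <- stats::dbinom(0:n, n, 0.5)
  sum(probs[probs <= probs[n_gain + 1L] * (1 + 1e-7)])
}
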