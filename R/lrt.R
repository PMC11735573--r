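## ------------------------------------------------------------------------
## Likelihood ratio tests with data-dependent degrees of freedom.
## ------------------------------------------------------------------------

#' Dimension of the null parameter manifold
#'
#' Number of free parameters under the null hypothesis of no segregation
#' distortion, reduced by boundary attainment (the data-dependent degrees of
#' freedom strategy for boundary parameters). If both parents are in
#' \{0, 4\} the null is a point (dimension 0). A shared double reduction
#' direction exists when a parent is simplex or triplex; each duplex parent
#' contributes one preferential-pairing direction (double reduction and
#' pairing collapse to a single direction within a duplex parent's gamete
#' law, so a lone duplex parent adds dimension 1, not 2). One dimension is
#' subtracted for each active direction whose estimate lies on the boundary
#' of its range, floored at 0.
#'
#' @inheritParams mle_null
#' @param boundary Named logical vector of per-direction boundary indicators,
#'   as returned in the `boundary` element of [mle_null()]. Defaults to no
#'   boundary attainment.
#' @return Non-negative integer.
#' @export
null_dimension <- function(ell1, ell2, boundary = logical(0)) {
  ell1 <- stop_if_not_dosage(ell1)
  ell2 <- stop_if_not_dosage(ell2)
  ells <- c(ell1, ell2)
  if (all(ells %in% c(0L, 4L))) return(0L)
  d0 <- sum(ells == 2L) + as.integer(any(ells %in% c(1L, 3L)))
  max(0L, d0 - sum(boundary))
}

new_lrt_result <- function(stat, df, p_value, null_fit, alt_q, ells,
                           impossible = FALSE) {
  structure(
    list(
      stat = stat, df = df, p_value = p_value,
      null_fit = null_fit, alt_q = alt_q,
      parents_used = ells, impossible = impossible
    ),
    class = "tetseg_lrt"
  )
}

#' @export
print.tetseg_lrt <- function(x, ...) {
  cat("Likelihood ratio test for segregation distortion\n")
  cat("  parents: (", x$parents_used[1], ",", x$parents_used[2], ")\n", sep = "")
  if (x$impossible) {
    cat("  offspring observed at genotypes impossible under the null; p = 0\n")
  } else {
    cat("  statistic:", format(x$stat), " df:", x$df,
        " p-value:", format.pval(x$p_value), "\n")
  }
  invisible(x)
}

## p-value from the statistic/df pair, with the df = 0 convention:
## p = 1 for a null-compatible fit (lambda ~ 0), otherwise fall back to the
## conservative df = 1 survival function.
chisq_pvalue_ddf <- function(stat, df) {
  if (df == 0L) {
    if (stat <= 1e-8) 1 else stats::pchisq(stat, df = 1, lower.tail = FALSE)
  } else {
    stats::pchisq(stat, df = df, lower.tail = FALSE)
  }
}

#' Likelihood ratio test for segregation distortion, known genotypes
#'
#' Compares the multinomial likelihood at the unrestricted MLE `x / n`
#' against the maximum over the null meiosis model, with data-dependent
#' degrees of freedom. If any offspring is observed at a genotype that is
#' impossible under the null for the given parents (over the *whole* null
#' parameter space), the test returns `p = 0`. Otherwise the number of
#' alternative parameters is the number of theoretically possible genotypes
#' minus 1, and the degrees of freedom are that number minus the (boundary
#' reduced) null dimension, floored at 0.
#'
#' @inheritParams mle_null
#' @param x Five offspring genotype counts (dosages 0..4).
#' @return Object of class `"tetseg_lrt"` with elements `stat`, `df`,
#'   `p_value`, `null_fit`, `alt_q`, `parents_used`.
#'
#' @examples
#' lrt_counts(c(130, 100, 10, 0, 0), ell1 = 1, ell2 = 0)
#' @export
lrt_counts <- function(x, ell1, ell2, dr_cap = DR_CAP_DEFAULT) {
  x <- check_counts(x)
  ell1 <- stop_if_not_dosage(ell1)
  ell2 <- stop_if_not_dosage(ell2)
  possible <- possible_offspring_genotypes(ell1, ell2)
  observed <- which(x > 0) - 1L
  if (any(!(observed %in% possible))) {
    return(new_lrt_result(Inf, NA_integer_, 0, NULL, mle_alt_counts(x),
                          c(ell1, ell2), impossible = TRUE))
  }
  fit0 <- mle_null(x, ell1, ell2, dr_cap = dr_cap)
  qA <- mle_alt_counts(x)
  stat <- 2 * (loglik_counts(x, qA) - fit0$loglik)
  if (stat < -1e-6) warning("likelihood ratio statistic below -1e-6; check optimizer")
  stat <- max(stat, 0)
  alt_dim <- length(possible) - 1L
  df <- max(0L, alt_dim - null_dimension(ell1, ell2, fit0$boundary))
  new_lrt_result(stat, df, chisq_pvalue_ddf(stat, df), fit0, qA, c(ell1, ell2))
}

#' Likelihood ratio test for segregation distortion, genotype likelihoods
#'
#' As [lrt_counts()] but the data are an n x 5 genotype-likelihood matrix.
#' The alternative MLE is computed by EM ([mle_alt_gl()]). The number of
#' alternative parameters is 4 minus the number of genotype classes that are
#' both theoretically impossible under the null (for the given parents) and
#' estimated to have frequency at most `zero_tol` under the alternative.
#'
#' @inheritParams mle_null
#' @inheritParams loglik_gl
#' @param zero_tol Threshold below which an estimated alternative frequency
#'   counts as zero in the degrees-of-freedom rule.
#' @return Object of class `"tetseg_lrt"`.
#' @export
lrt_gl <- function(G, ell1, ell2, dr_cap = DR_CAP_DEFAULT, zero_tol = 1e-8) {
  G <- check_gl(G)
  ell1 <- stop_if_not_dosage(ell1)
  ell2 <- stop_if_not_dosage(ell2)
  fit0 <- mle_null(G, ell1, ell2, dr_cap = dr_cap)
  qA <- mle_alt_gl(G)
  llA <- attr(qA, "loglik")
  stat <- 2 * (llA - fit0$loglik)
  stat <- max(stat, 0)
  possible <- possible_offspring_genotypes(ell1, ell2)
  impossible_k <- setdiff(0:4, possible)
  n_dropped <- sum(qA[impossible_k + 1L] <= zero_tol)
  alt_dim <- 4L - n_dropped
  df <- max(0L, alt_dim - null_dimension(ell1, ell2, fit0$boundary))
  new_lrt_result(stat, df, chisq_pvalue_ddf(stat, df), fit0,
                 as.numeric(qA), c(ell1, ell2))
}

#' Likelihood ratio test with unknown parental genotypes
#'
#' Estimates the parental dosages by maximizing
#' `a[ell1] b[ell2] f(G | q(., ell1, ell2))` over the 25 dosage pairs, then
#' runs [lrt_gl()] as if the estimated parents were known.
#'
#' @inheritParams lrt_gl
#' @inheritParams estimate_parents
#' @return Object of class `"tetseg_lrt"`; `parents_used` records the
#'   estimated dosages.
#' @export
lrt_gl_unknown_parents <- function(G, a = rep(1, 5), b = rep(1, 5),
                                   dr_cap = DR_CAP_DEFAULT) {
  ells <- estimate_parents(G, a = a, b = b, dr_cap = dr_cap)
  lrt_gl(G, ells[1], ells[2], dr_cap = dr_cap)
}
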