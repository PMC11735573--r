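## ------------------------------------------------------------------------
## Competitor tests: the classical chi-squared segregation test and an
## approximation of polymapR's checkF1() segregation test.
## ------------------------------------------------------------------------

new_baseline_result <- function(p_value, method, details = list()) {
  structure(list(p_value = p_value, method = method, details = details),
            class = "tetseg_baseline")
}

#' @export
print.tetseg_baseline <- function(x, ...) {
  cat(x$method, "segregation test: p =", format.pval(x$p_value), "\n")
  invisible(x)
}

#' Classical chi-squared test for segregation distortion
#'
#' Compares observed offspring genotype counts against the frequencies
#' expected under strict polysomic inheritance with no double reduction and
#' no preferential pairing (hypergeometric gamete model). Categories with
#' zero expected frequency are excluded from the statistic; observing any
#' count in such a category yields `p = 0`.
#'
#' @inheritParams lrt_counts
#' @return Object of class `"tetseg_baseline"` with `p_value`, `method`, and
#'   `details` (`stat`, `df`, `expected`).
#' @export
chisq_test <- function(x, ell1, ell2) {
  x <- check_counts(x)
  ell1 <- stop_if_not_dosage(ell1)
  ell2 <- stop_if_not_dosage(ell2)
  n <- sum(x)
  q <- offspring_freq(hypergeometric_gamete(ell1), hypergeometric_gamete(ell2))
  pos <- q > 0
  if (any(x[!pos] > 0)) {
    return(new_baseline_result(0, "chisq",
                               list(stat = Inf, df = sum(pos) - 1L,
                                    expected = n * q,
                                    invalid = sum(x[!pos]))))
  }
  df <- sum(pos) - 1L
  stat <- sum((x[pos] - n * q[pos])^2 / (n * q[pos]))
  p <- if (df == 0L) 1 else stats::pchisq(stat, df = df, lower.tail = FALSE)
  new_baseline_result(p, "chisq",
                      list(stat = stat, df = df, expected = n * q, invalid = 0))
}

## Candidate gamete distributions per parent under polymapR-style segregation
## patterns: fully polysomic (random bivalents) or fully disomic. Only duplex
## parents distinguish the patterns.
parent_patterns <- function(ell) {
  if (ell == 2L) {
    list(polysomic = hypergeometric_gamete(2),
         disomic_lo = gamete_freq_2p(2, 0, 0),
         disomic_hi = gamete_freq_2p(2, 0, 1))
  } else {
    list(polysomic = hypergeometric_gamete(ell))
  }
}

#' Approximate reimplementation of polymapR's checkF1 segregation test
#'
#' For every candidate segregation pattern (each parent fully polysomic or
#' fully disomic), a chi-squared test of the "valid" genotype counts against
#' the pattern's expected ratios is combined with a one-sided binomial test
#' of the "invalid" genotype count (expected proportion of invalid genotypes
#' `invalid_rate`, 3% by default). The per-pattern score is the product of
#' the two p-values, and the reported p-value is the maximum score over
#' patterns. This follows the published description of the procedure; the
#' exact internal thresholds of polymapR are not public, so the
#' implementation is faithful in spirit but not bit-compatible.
#'
#' A posterior-probability matrix (n x 5) may be given instead of counts, in
#' which case per-genotype posterior sums below `collapse_threshold` are
#' rounded to zero and the vector is renormalized to the sample size before
#' testing, mirroring checkF1's handling of genotype uncertainty.
#'
#' @inheritParams lrt_counts
#' @param data Length-5 genotype counts or an n x 5 posterior-probability
#'   matrix.
#' @param invalid_rate Expected upper bound on the proportion of invalid
#'   genotypes for the binomial test.
#' @param collapse_threshold Posterior-sum rounding threshold; defaults to
#'   `0.1 * n * 0.01`.
#' @return Object of class `"tetseg_baseline"`; `details` holds the
#'   per-pattern scores and the invalid count of the best pattern.
#' @export
polymapr_like_test <- function(data, ell1, ell2, invalid_rate = 0.03,
                               collapse_threshold = NULL) {
  ell1 <- stop_if_not_dosage(ell1)
  ell2 <- stop_if_not_dosage(ell2)
  if (!is.null(dim(data))) {
    post <- as.matrix(data)
    if (ncol(post) != 5L) stop("posterior matrix must have 5 columns", call. = FALSE)
    n <- nrow(post)
    x <- colSums(post / pmax(rowSums(post), 1e-300))
    thr <- if (is.null(collapse_threshold)) 0.1 * n * 0.01 else collapse_threshold
    x[x < thr] <- 0
    if (sum(x) <= 0) stop("all posterior mass removed by collapsing", call. = FALSE)
    x <- x / sum(x) * n
  } else {
    x <- check_counts(data)
    n <- sum(x)
  }

  pats1 <- parent_patterns(ell1)
  pats2 <- parent_patterns(ell2)
  scores <- c()
  best <- list(score = -Inf)
  for (n1 in names(pats1)) {
    for (n2 in names(pats2)) {
      q <- clip_prob_vec(conv5(pats1[[n1]], pats2[[n2]]))
      valid <- q > 1e-12
      n_valid <- sum(x[valid])
      n_invalid <- n - n_valid
      ## chi-squared on valid genotypes against the pattern's ratios
      if (n_valid > 0) {
        qv <- q[valid] / sum(q[valid])
        exp_v <- n_valid * qv
        stat <- sum((x[valid] - exp_v)^2 / exp_v)
        df <- sum(valid) - 1L
        p_chisq <- if (df == 0L) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
      } else {
        p_chisq <- 0
      }
      ## one-sided binomial test: P(X >= n_invalid) at rate invalid_rate
      k <- round(n_invalid)
      p_binom <- if (k <= 0) 1 else {
        stats::pbinom(k - 1, size = round(n), prob = invalid_rate,
                      lower.tail = FALSE)
      }
      sc <- p_chisq * p_binom
      lbl <- paste(n1, n2, sep = "x")
      scores[lbl] <- sc
      if (sc > best$score) {
        best <- list(score = sc, pattern = lbl, p_chisq = p_chisq,
                     p_binom = p_binom, invalid = n_invalid)
      }
    }
  }
  new_baseline_result(best$score, "polymapr_like",
                      list(pattern = best$pattern, scores = scores,
                           p_chisq = best$p_chisq, p_binom = best$p_binom,
                           invalid = best$invalid))
}
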