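#' tetseg: tests for segregation distortion in tetraploid F1 populations
#'
#' Likelihood ratio and Bayesian tests for segregation distortion at biallelic
#' SNPs in tetraploid F1 populations, built on a gamete-frequency model that
#' accounts for both double reduction and (partial) preferential pairing, with
#' optional genotype uncertainty through genotype likelihoods.
#'
#' The main user-facing entry points are:
#' \itemize{
#'   \item [lrt_counts()], [lrt_gl()], [lrt_gl_unknown_parents()] — likelihood
#'     ratio tests with data-dependent degrees of freedom.
#'   \item [bayes_test()] — Bayes factors (null over alternative).
#'   \item [chisq_test()], [polymapr_like_test()] — baseline competitor tests.
#'   \item [seg_test_markers()], [read_vcf()], [read_counts_table()] — batch
#'     testing over files of markers.
#'   \item [run_null_study()], [run_alt_study()], [roc_summary()] — simulation
#'     harness.
#' }
#'
#' @name tetseg-package
#' @keywords internal
"_PACKAGE"

## Default cap on the double reduction rate: the maximum under the complete
## equational segregation model of tetraploid meiosis.
DR_CAP_DEFAULT <- 1 / 6

## ------------------------------------------------------------------------
## validation helpers
## ------------------------------------------------------------------------

stop_if_not_dosage <- function(ell) {
  if (length(ell) != 1L || is.na(ell) || ell != round(ell) || ell < 0 || ell > 4) {
    stop("parent dosage must be a single integer in {0,...,4}", call. = FALSE)
  }
  invisible(as.integer(ell))
}

stop_if_not_prob <- function(x, name, lo = 0, hi = 1) {
  if (length(x) != 1L || is.na(x) || x < lo - 1e-12 || x > hi + 1e-12) {
    stop(sprintf("%s must be in [%g, %g]", name, lo, hi), call. = FALSE)
  }
  invisible(min(max(x, lo), hi))
}

## Clip tiny negative entries caused by floating-point cancellation and
## renormalize; a deficit larger than `tol` signals an invalid parameter
## combination and is an error.
clip_prob_vec <- function(p, tol = 1e-10) {
  neg <- p < 0
  if (any(neg)) {
    if (any(p[neg] < -tol)) {
      stop("probability vector has entries below -", format(tol),
           "; invalid parameter combination", call. = FALSE)
    }
    p[neg] <- 0
    p <- p / sum(p)
  }
  p
}

## ------------------------------------------------------------------------
## gamete frequencies
## ------------------------------------------------------------------------

#' Tetraploid gamete frequencies under the two-parameter meiosis model
#'
#' Probability that a tetraploid parent of dosage `ell` transmits a gamete of
#' dosage 0, 1, or 2, given the double reduction rate `alpha` and (for duplex
#' parents) the preferential pairing parameter `xi`. `xi = 1/3` corresponds to
#' polysomic (random bivalent) pairing; `xi = 0` or `1` to fully disomic
#' pairing.
#'
#' @param ell Parent dosage, integer in 0..4.
#' @param alpha Double reduction rate, in `[0, dr_cap]`.
#' @param xi Preferential pairing parameter, in `[0, 1]`. Only used when
#'   `ell == 2`; accepted but ignored for other dosages (the model has no
#'   pairing parameter outside the duplex row).
#' @param dr_cap Maximum double reduction rate; defaults to 1/6, the maximum
#'   under the complete equational segregation model.
#'
#' @return Numeric vector of length 3: probabilities of gamete dosage 0, 1, 2.
#'
#' @examples
#' gamete_freq_2p(2, 1 / 6, 1 / 3)  # (2, 5, 2) / 9
#' gamete_freq_2p(1, 1 / 6, 1 / 3)  # (13, 10, 1) / 24
#' @export
gamete_freq_2p <- function(ell, alpha, xi = 1 / 3, dr_cap = DR_CAP_DEFAULT) {
  ell <- stop_if_not_dosage(ell)
  alpha <- stop_if_not_prob(alpha, "alpha", 0, dr_cap)
  xi <- stop_if_not_prob(xi, "xi", 0, 1)
  p <- switch(as.character(ell),
    "0" = c(1, 0, 0),
    "1" = c(1 / 2 + alpha / 4, 1 / 2 - alpha / 2, alpha / 4),
    "2" = {
      p0 <- alpha / 2 + (1 - alpha) * (1 - xi) / 4
      c(p0, (1 - alpha) * (1 + xi) / 2, p0)
    },
    "3" = c(alpha / 4, 1 / 2 - alpha / 2, 1 / 2 + alpha / 4),
    "4" = c(0, 0, 1)
  )
  clip_prob_vec(p)
}

#' Tetraploid gamete frequencies under the three-parameter meiosis model
#'
#' Gamete dosage distribution in terms of the probability of quadrivalent
#' formation `tau`, the probability of double reduction given quadrivalent
#' formation `beta`, and the probability `gamma` that, given bivalent
#' formation, chromosomes pair along shared alleles (only relevant for duplex
#' parents).
#'
#' @inheritParams gamete_freq_2p
#' @param tau Probability of quadrivalent formation, in `[0, 1]`.
#' @param beta Probability of double reduction given quadrivalent formation,
#'   in `[0, dr_cap]`.
#' @param gamma Probability of AA:aa bivalent pairing, in `[0, 1]`; only used
#'   when `ell == 2`.
#'
#' @return Numeric vector of length 3.
#' @seealso [map_3p_to_2p()] for the reduction to the two-parameter model.
#' @export
gamete_freq_3p <- function(ell, tau, beta, gamma = 1 / 3, dr_cap = DR_CAP_DEFAULT) {
  ell <- stop_if_not_dosage(ell)
  tau <- stop_if_not_prob(tau, "tau", 0, 1)
  beta <- stop_if_not_prob(beta, "beta", 0, dr_cap)
  gamma <- stop_if_not_prob(gamma, "gamma", 0, 1)
  bt <- beta * tau
  p <- switch(as.character(ell),
    "0" = c(1, 0, 0),
    "1" = c(1 / 2 + bt / 4, 1 / 2 - bt / 2, bt / 4),
    "2" = {
      p0 <- bt / 3 + tau / 6 + (1 - tau) * (1 - gamma) / 4
      p1 <- -2 * bt / 3 + 2 * tau / 3 + (1 - tau) * (1 + gamma) / 2
      c(p0, p1, p0)
    },
    "3" = c(bt / 4, 1 / 2 - bt / 2, 1 / 2 + bt / 4),
    "4" = c(0, 0, 1)
  )
  clip_prob_vec(p)
}

#' Reduce the three-parameter meiosis model to the two-parameter model
#'
#' Maps `(tau, beta, gamma1, gamma2)` to `(alpha, xi1, xi2)` such that the
#' two-parameter gamete frequencies reproduce the three-parameter ones exactly
#' for every parental dosage. The double reduction rate is `alpha = beta * tau`;
#' the pairing parameter is
#' `xi_j = 1 - ((2/3) tau (1 - beta) + (1 - tau)(1 - gamma_j)) / (1 - beta tau)`.
#'
#' @inheritParams gamete_freq_3p
#' @param gamma1,gamma2 Per-parent AA:aa pairing probabilities.
#'
#' @return List with elements `alpha`, `xi1`, `xi2`.
#' @export
map_3p_to_2p <- function(tau, beta, gamma1 = 1 / 3, gamma2 = 1 / 3,
                         dr_cap = DR_CAP_DEFAULT) {
  tau <- stop_if_not_prob(tau, "tau", 0, 1)
  beta <- stop_if_not_prob(beta, "beta", 0, dr_cap)
  gamma1 <- stop_if_not_prob(gamma1, "gamma1", 0, 1)
  gamma2 <- stop_if_not_prob(gamma2, "gamma2", 0, 1)
  alpha <- beta * tau
  xi_of <- function(gamma) {
    1 - ((2 / 3) * tau * (1 - beta) + (1 - tau) * (1 - gamma)) / (1 - alpha)
  }
  list(alpha = alpha, xi1 = xi_of(gamma1), xi2 = xi_of(gamma2))
}

#' Hypergeometric gamete frequencies (strict bivalent polysomic model)
#'
#' Gamete dosage distribution for a parent of dosage `ell` in a `K`-ploid with
#' strict bivalent pairing, no double reduction, and no preferential pairing:
#' `p_k = choose(ell, k) choose(K - ell, K/2 - k) / choose(K, K/2)`.
#'
#' @param ell Parent dosage, integer in 0..K.
#' @param K Even ploidy level (default 4).
#' @return Numeric vector of length `K/2 + 1`.
#' @export
hypergeometric_gamete <- function(ell, K = 4) {
  if (length(K) != 1L || K != round(K) || K < 2 || K %% 2 != 0) {
    stop("ploidy K must be a positive even integer", call. = FALSE)
  }
  if (length(ell) != 1L || ell != round(ell) || ell < 0 || ell > K) {
    stop("parent dosage must be an integer in {0,...,K}", call. = FALSE)
  }
  k <- 0:(K / 2)
  p <- choose(ell, k) * choose(K - ell, K / 2 - k) / choose(K, K / 2)
  p / sum(p)
}

#' Offspring genotype frequencies from two gamete distributions
#'
#' Discrete linear convolution of the two parental gamete dosage
#' distributions: `q_k = sum_i p1[i] * p2[k - i]`.
#'
#' @param p1,p2 Gamete dosage distributions (length 3 for tetraploids).
#' @return Numeric vector of length `length(p1) + length(p2) - 1` summing to 1.
#' @export
offspring_freq <- function(p1, p2) {
  if (abs(sum(p1) - 1) > 1e-8 || abs(sum(p2) - 1) > 1e-8 ||
      any(p1 < -1e-10) || any(p2 < -1e-10)) {
    stop("gamete distributions must be probability vectors", call. = FALSE)
  }
  q <- as.numeric(convolve(p1, rev(p2), type = "open"))
  clip_prob_vec(q)
}

#' Bounds on the preferential pairing parameter given a double reduction rate
#'
#' When the maximum double reduction rate is `c`, the preferential pairing
#' parameter of a duplex parent is confined to
#' `lo = (1/3) (alpha / (1 - alpha)) ((1 - c)/c) <= xi <= 1 - 2 lo`.
#'
#' @param alpha Double reduction rate, `0 <= alpha <= dr_cap`.
#' @param dr_cap Maximum double reduction rate `c` (`alpha <= c < 1`).
#' @return Numeric vector `c(lo, hi)`.
#' @export
xi_bounds <- function(alpha, dr_cap = DR_CAP_DEFAULT) {
  if (dr_cap <= 0) {
    if (alpha > 0) stop("dr_cap = 0 is incompatible with alpha > 0", call. = FALSE)
    return(c(lo = 0, hi = 1))
  }
  alpha <- stop_if_not_prob(alpha, "alpha", 0, dr_cap)
  lo <- (1 / 3) * (alpha / (1 - alpha)) * ((1 - dr_cap) / dr_cap)
  c(lo = lo, hi = 1 - 2 * lo)
}

#' Offspring genotypes possible under the null for given parent dosages
#'
#' Union, over the whole null parameter space (any double reduction up to the
#' cap, any preferential pairing), of the offspring dosages with positive
#' probability. Per parent, a nullplex transmits only dosage-0 gametes and a
#' quadruplex only dosage-2; any other dosage can transmit 0, 1, or 2 (extreme
#' gametes arise through double reduction or disomic pairing).
#'
#' @param ell1,ell2 Parent dosages, integers in 0..4.
#' @return Sorted integer vector of possible offspring dosages.
#' @export
possible_offspring_genotypes <- function(ell1, ell2) {
  ell1 <- stop_if_not_dosage(ell1)
  ell2 <- stop_if_not_dosage(ell2)
  gam <- function(ell) {
    if (ell == 0) 0L else if (ell == 4) 2L else 0:2
  }
  sort(unique(as.integer(outer(gam(ell1), gam(ell2), `+`))))
}

## Gamete-frequency rows and their gradients in (tau, beta, gamma) space.
## Returns list(p, dtau, dbeta, dgamma); used by the null-model optimizer.
gamete_freq_3p_grad <- function(ell, tau, beta, gamma) {
  zero <- c(0, 0, 0)
  switch(as.character(ell),
    "0" = list(p = c(1, 0, 0), dtau = zero, dbeta = zero, dgamma = zero),
    "1" = list(
      p = c(1 / 2 + beta * tau / 4, 1 / 2 - beta * tau / 2, beta * tau / 4),
      dtau = c(beta / 4, -beta / 2, beta / 4),
      dbeta = c(tau / 4, -tau / 2, tau / 4),
      dgamma = zero
    ),
    "2" = {
      bt <- beta * tau
      p0 <- bt / 3 + tau / 6 + (1 - tau) * (1 - gamma) / 4
      p1 <- -2 * bt / 3 + 2 * tau / 3 + (1 - tau) * (1 + gamma) / 2
      d0_tau <- beta / 3 + 1 / 6 - (1 - gamma) / 4
      d1_tau <- -2 * beta / 3 + 2 / 3 - (1 + gamma) / 2
      list(
        p = c(p0, p1, p0),
        dtau = c(d0_tau, d1_tau, d0_tau),
        dbeta = c(tau / 3, -2 * tau / 3, tau / 3),
        dgamma = c(-(1 - tau) / 4, (1 - tau) / 2, -(1 - tau) / 4)
      )
    },
    "3" = list(
      p = c(beta * tau / 4, 1 / 2 - beta * tau / 2, 1 / 2 + beta * tau / 4),
      dtau = c(beta / 4, -beta / 2, beta / 4),
      dbeta = c(tau / 4, -tau / 2, tau / 4),
      dgamma = zero
    ),
    "4" = list(p = c(0, 0, 1), dtau = zero, dbeta = zero, dgamma = zero)
  )
}

## Plain (unchecked, unclipped) convolution used in hot loops.
conv5 <- function(p1, p2) {
  c(
    p1[1] * p2[1],
    p1[1] * p2[2] + p1[2] * p2[1],
    p1[1] * p2[3] + p1[2] * p2[2] + p1[3] * p2[1],
    p1[2] * p2[3] + p1[3] * p2[2],
    p1[3] * p2[3]
  )
}

## Offspring frequencies under the null directly from (tau, beta, gamma1,
## gamma2) for given parent dosages.
offspring_freq_null <- function(ell1, ell2, tau, beta, gamma1, gamma2,
                                dr_cap = DR_CAP_DEFAULT) {
  p1 <- gamete_freq_3p(ell1, tau, beta, gamma1, dr_cap = dr_cap)
  p2 <- gamete_freq_3p(ell2, tau, beta, gamma2, dr_cap = dr_cap)
  clip_prob_vec(conv5(p1, p2))
}
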