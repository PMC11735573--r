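## ------------------------------------------------------------------------
## Bayes-factor tests via marginal likelihoods: closed-form
## Dirichlet-multinomial under the alternative (known genotypes), Monte
## Carlo prior integration with log-sum-exp pooling elsewhere.
## ------------------------------------------------------------------------

## Evaluate expr under a temporary RNG state seeded with `seed` (global RNG
## state is restored afterwards). seed = NULL leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## log-mean-exp with a delta-method Monte Carlo standard error of the log.
log_mean_exp_se <- function(ll) {
  n <- length(ll)
  m <- max(ll)
  if (!is.finite(m)) {
    warning("all Monte Carlo draws have zero likelihood; log-marginal is -Inf")
    return(c(log_marginal = -Inf, mc_se = NA_real_))
  }
  w <- exp(ll - m)
  mu <- mean(w)
  c(log_marginal = m + log(mu),
    mc_se = stats::sd(w) / (mu * sqrt(n)))
}

#' Default prior over the null meiosis parameters
#'
#' Returns the prior used in the numerator of the Bayes factor:
#' `tau ~ Unif(0, 1)`, `beta ~ Unif(0, dr_cap)`, and independent
#' `gamma_j ~ Beta(5/9, 10/9)` per parent (mean 1/3, the value under
#' tetrasomic inheritance, with the variance of a uniform prior, 1/12).
#' Any component can be overridden with a user sampler.
#'
#' @param dr_cap Maximum double reduction rate (upper bound of the beta prior).
#' @param rtau,rbeta_dr,rgamma_pp Functions of `n` returning `n` prior draws
#'   for `tau`, `beta`, and each `gamma_j` respectively.
#' @return List of class `"tetseg_null_prior"` with the samplers and `dr_cap`.
#' @export
null_prior <- function(dr_cap = DR_CAP_DEFAULT,
                       rtau = NULL, rbeta_dr = NULL, rgamma_pp = NULL) {
  force(dr_cap)
  structure(
    list(
      dr_cap = dr_cap,
      rtau = if (is.null(rtau)) function(n) stats::runif(n) else rtau,
      rbeta_dr = if (is.null(rbeta_dr)) {
        function(n) stats::runif(n, 0, dr_cap)
      } else rbeta_dr,
      rgamma_pp = if (is.null(rgamma_pp)) {
        function(n) stats::rbeta(n, 5 / 9, 10 / 9)
      } else rgamma_pp
    ),
    class = "tetseg_null_prior"
  )
}

#' Closed-form log marginal likelihood under the alternative, known genotypes
#'
#' Dirichlet-multinomial log mass of the genotype counts under a Dirichlet
#' prior on the genotype frequencies.
#'
#' @inheritParams loglik_counts
#' @param conc Dirichlet concentration parameters (default `rep(1/2, 5)`,
#'   the multinomial Jeffreys prior).
#' @return Log marginal likelihood (scalar).
#' @export
log_marginal_alt_counts <- function(x, conc = rep(1 / 2, 5)) {
  if (length(conc) != 5L || any(conc <= 0)) {
    stop("concentration parameters must be five positive reals", call. = FALSE)
  }
  if (sum(x) == 0) return(0)
  x <- check_counts(x)
  n <- sum(x)
  A <- sum(conc)
  lgamma(n + 1) - sum(lgamma(x + 1)) +
    lgamma(A) - lgamma(n + A) +
    sum(lgamma(x + conc) - lgamma(conc))
}

## Vectorized Table-1 gamete rows: N x 3 matrix for N parameter draws.
gamete_rows_3p <- function(ell, tau, beta, gamma) {
  n <- length(tau)
  bt <- beta * tau
  switch(as.character(ell),
    "0" = cbind(rep(1, n), 0, 0),
    "1" = cbind(1 / 2 + bt / 4, 1 / 2 - bt / 2, bt / 4),
    "2" = {
      p0 <- bt / 3 + tau / 6 + (1 - tau) * (1 - gamma) / 4
      cbind(p0, -2 * bt / 3 + 2 * tau / 3 + (1 - tau) * (1 + gamma) / 2, p0)
    },
    "3" = cbind(bt / 4, 1 / 2 - bt / 2, 1 / 2 + bt / 4),
    "4" = cbind(rep(0, n), 0, 1)
  )
}

## Vectorized convolution of per-draw gamete rows: N x 5.
conv_rows <- function(P1, P2) {
  cbind(
    P1[, 1] * P2[, 1],
    P1[, 1] * P2[, 2] + P1[, 2] * P2[, 1],
    P1[, 1] * P2[, 3] + P1[, 2] * P2[, 2] + P1[, 3] * P2[, 1],
    P1[, 2] * P2[, 3] + P1[, 3] * P2[, 2],
    P1[, 3] * P2[, 3]
  )
}

## Draws of the null genotype-frequency vector q: N x 5 matrix.
draw_null_q <- function(n_draws, ell1, ell2, prior) {
  active <- null_active_params(ell1, ell2)
  tau <- if (active["tau"]) prior$rtau(n_draws) else rep(0.5, n_draws)
  beta <- if (active["beta"]) prior$rbeta_dr(n_draws) else rep(0, n_draws)
  g1 <- if (active["gamma1"]) prior$rgamma_pp(n_draws) else rep(1 / 3, n_draws)
  g2 <- if (active["gamma2"]) prior$rgamma_pp(n_draws) else rep(1 / 3, n_draws)
  pmax(conv_rows(gamete_rows_3p(ell1, tau, beta, g1),
                 gamete_rows_3p(ell2, tau, beta, g2)), 0)
}

#' Log marginal likelihood under the null (Monte Carlo)
#'
#' Estimates the integral of the data likelihood over the null prior on the
#' meiosis parameters by plain Monte Carlo with log-sum-exp pooling.
#' Integration runs only over parameters that affect the likelihood for the
#' given parent dosages; when both parents are in \{0, 4\} the integral is
#' computed exactly (the likelihood is constant).
#'
#' @inheritParams mle_null
#' @param prior A [null_prior()] object.
#' @param n_draws Number of Monte Carlo prior draws.
#' @param seed Optional integer seed used locally for the draws.
#' @return Numeric vector `c(log_marginal, mc_se)`.
#' @export
log_marginal_null <- function(data, ell1, ell2, prior = null_prior(),
                              n_draws = 50000L, seed = NULL) {
  ell1 <- stop_if_not_dosage(ell1)
  ell2 <- stop_if_not_dosage(ell2)
  is_counts <- is.null(dim(data))
  if (is_counts) x <- check_counts(data) else G <- check_gl(data)

  if (!any(null_active_params(ell1, ell2))) {
    q <- offspring_freq_null(ell1, ell2, 0.5, 0, 1 / 3, 1 / 3)
    ll <- if (is_counts) loglik_counts(x, q) else loglik_gl(G, q)
    return(c(log_marginal = ll, mc_se = 0))
  }

  Q <- with_seed(seed, draw_null_q(n_draws, ell1, ell2, prior))
  if (is_counts) {
    lc <- lgamma(sum(x) + 1) - sum(lgamma(x + 1))
    lq <- log(Q)
    lq[Q <= 0] <- -Inf
    use <- x > 0
    ll <- lc + as.numeric(lq[, use, drop = FALSE] %*% x[use])
    ll[is.nan(ll)] <- -Inf
  } else {
    ll <- gl_loglik_draws(G, Q)
  }
  log_mean_exp_se(ll)
}

## Per-draw genotype-likelihood log-likelihoods, chunked to bound memory.
gl_loglik_draws <- function(G, Q, chunk = 2000L) {
  n_draws <- nrow(Q)
  ll <- numeric(n_draws)
  for (start in seq(1L, n_draws, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n_draws)
    L <- G %*% t(Q[idx, , drop = FALSE])   # n x |idx|
    ll[idx] <- colSums(log(pmax(L, 1e-300)))
  }
  ll
}

#' Log marginal likelihood under the alternative, genotype likelihoods
#'
#' Monte Carlo average of the genotype-likelihood data likelihood over
#' Dirichlet draws of the genotype frequencies.
#'
#' @inheritParams loglik_gl
#' @inheritParams log_marginal_alt_counts
#' @inheritParams log_marginal_null
#' @return Numeric vector `c(log_marginal, mc_se)`.
#' @export
log_marginal_alt_gl <- function(G, conc = rep(1 / 2, 5), n_draws = 50000L,
                                seed = NULL) {
  G <- check_gl(G)
  if (length(conc) != 5L || any(conc <= 0)) {
    stop("concentration parameters must be five positive reals", call. = FALSE)
  }
  Q <- with_seed(seed, {
    g <- matrix(stats::rgamma(n_draws * 5, shape = rep(conc, each = n_draws)),
                nrow = n_draws)
    g / rowSums(g)
  })
  log_mean_exp_se(gl_loglik_draws(G, Q))
}

#' Bayes factor test for segregation distortion
#'
#' Computes `log BF = log Pr(data | H0) - log Pr(data | H1)`, the log ratio
#' of the marginal likelihood under the null meiosis model (no segregation
#' distortion) to the marginal likelihood under an unrestricted Dirichlet
#' alternative. **Positive values favor the null** (no distortion); as a
#' summary guideline, log BF below about -16 is strong evidence of
#' distortion. With genotype counts the alternative marginal is the exact
#' Dirichlet-multinomial; otherwise both marginals are Monte Carlo estimates.
#' When parental dosages are not supplied they are estimated first by
#' maximum likelihood (see [estimate_parents()]).
#'
#' @inheritParams log_marginal_null
#' @inheritParams estimate_parents
#' @param data Length-5 genotype counts or an n x 5 genotype-likelihood matrix.
#' @param ell1,ell2 Parent dosages; leave `NULL` to estimate them from the
#'   data (optionally with parent genotype likelihoods `a`, `b`).
#' @param conc Dirichlet concentration parameters of the alternative prior.
#' @return Object of class `"tetseg_bayes"`: list with `log_bf`, `mc_se`,
#'   `draws`, `parents_used`, `log_marginal_null`, `log_marginal_alt`.
#'
#' @examples
#' x <- c(28, 22, 0, 0, 0)
#' bayes_test(x, ell1 = 1, ell2 = 0, n_draws = 5000, seed = 1)
#' @export
bayes_test <- function(data, ell1 = NULL, ell2 = NULL,
                       a = rep(1, 5), b = rep(1, 5),
                       prior = null_prior(), conc = rep(1 / 2, 5),
                       n_draws = 50000L, seed = NULL) {
  if (is.null(ell1) || is.null(ell2)) {
    ells <- estimate_parents(data, a = a, b = b, dr_cap = prior$dr_cap)
    ell1 <- ells[1]
    ell2 <- ells[2]
  }
  m0 <- log_marginal_null(data, ell1, ell2, prior = prior,
                          n_draws = n_draws, seed = seed)
  if (is.null(dim(data))) {
    m1 <- c(log_marginal_alt_counts(data, conc = conc), 0)
  } else {
    m1 <- log_marginal_alt_gl(data, conc = conc, n_draws = n_draws,
                              seed = if (is.null(seed)) NULL else seed + 1L)
  }
  structure(
    list(
      log_bf = unname(m0[1] - m1[1]),
      mc_se = unname(sqrt(m0[2]^2 + m1[2]^2)),
      draws = n_draws,
      parents_used = c(ell1, ell2),
      log_marginal_null = unname(m0[1]),
      log_marginal_alt = unname(m1[1])
    ),
    class = "tetseg_bayes"
  )
}

#' @export
print.tetseg_bayes <- function(x, ...) {
  cat("Bayes test for segregation distortion\n")
  cat("  parents: (", x$parents_used[1], ",", x$parents_used[2], ")\n", sep = "")
  cat("  log BF (null / alternative):", format(x$log_bf),
      " MC se:", format(x$mc_se), "\n")
  cat("  positive log BF favors no distortion\n")
  invisible(x)
}
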