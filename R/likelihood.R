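## ------------------------------------------------------------------------
## Likelihoods and maximum-likelihood estimation, for known genotypes
## (multinomial counts) and genotype-likelihood data.
## ------------------------------------------------------------------------

check_counts <- function(x) {
  if (length(x) != 5L || any(is.na(x)) || any(x < 0) || any(x != round(x))) {
    stop("genotype counts must be five non-negative integers (dosages 0..4)",
         call. = FALSE)
  }
  if (sum(x) < 1) stop("need at least one offspring (n >= 1)", call. = FALSE)
  as.numeric(x)
}

check_gl <- function(G) {
  G <- as.matrix(G)
  if (ncol(G) != 5L) {
    stop("genotype-likelihood matrix must have 5 columns (dosages 0..4)",
         call. = FALSE)
  }
  if (any(!is.finite(G)) || any(G < 0)) {
    stop("genotype likelihoods must be finite and non-negative", call. = FALSE)
  }
  rmax <- apply(G, 1, max)
  if (any(rmax <= 0)) {
    stop("every genotype-likelihood row needs at least one positive entry",
         call. = FALSE)
  }
  ## scale invariance: normalize each row to max 1 to avoid underflow
  G / rmax
}

#' Multinomial log-likelihood of genotype counts
#'
#' Log-likelihood of the five offspring genotype counts given genotype
#' frequencies `q`, including the multinomial coefficient. Returns `-Inf`
#' when a category with zero probability is observed.
#'
#' @param x Five genotype counts (dosages 0..4).
#' @param q Offspring genotype frequency vector (length 5, sums to 1).
#' @return Log-likelihood (scalar).
#' @export
loglik_counts <- function(x, q) {
  x <- check_counts(x)
  n <- sum(x)
  if (any(x > 0 & q <= 0)) return(-Inf)
  pos <- x > 0
  lgamma(n + 1) - sum(lgamma(x + 1)) + sum(x[pos] * log(q[pos]))
}

#' Log-likelihood of genotype-likelihood data
#'
#' `sum_i log sum_k g_ik q_k` for an n x 5 genotype-likelihood matrix `G`.
#' Rows are normalized to maximum 1 on input (the likelihood is invariant to
#' per-row scaling).
#'
#' @param G n x 5 genotype-likelihood matrix; `G[i, k]` is the probability of
#'   individual i's read data given dosage `k - 1`.
#' @param q Offspring genotype frequency vector (length 5).
#' @return Log-likelihood (scalar).
#' @export
loglik_gl <- function(G, q) {
  G <- check_gl(G)
  lik <- as.numeric(G %*% q)
  if (any(lik <= 0)) return(-Inf)
  sum(log(lik))
}

#' Alternative-hypothesis MLE of genotype frequencies from counts
#'
#' Under the unrestricted alternative the maximum likelihood estimate of the
#' genotype frequencies is simply `x / n`.
#'
#' @inheritParams loglik_counts
#' @return Length-5 frequency vector.
#' @export
mle_alt_counts <- function(x) {
  x <- check_counts(x)
  x / sum(x)
}

#' Alternative-hypothesis MLE of genotype frequencies from genotype likelihoods
#'
#' EM algorithm for the mixture proportions `q` in
#' `prod_i sum_k g_ik q_k`: iterate
#' `q_k <- mean_i g_ik q_k / sum_l g_il q_l` from a uniform start until the
#' relative change in log-likelihood falls below `tol`.
#'
#' @inheritParams loglik_gl
#' @param tol Relative log-likelihood convergence tolerance.
#' @param maxit Maximum number of EM iterations.
#' @return Length-5 frequency vector with attributes `loglik` (final
#'   log-likelihood) and `iterations`.
#' @export
mle_alt_gl <- function(G, tol = 1e-10, maxit = 2000L) {
  G <- check_gl(G)
  n <- nrow(G)
  q <- rep(1 / 5, 5)
  ll_old <- -Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    num <- G * rep(q, each = n)      # n x 5
    denom <- rowSums(num)
    q_new <- colSums(num / denom) / n
    ll <- sum(log(as.numeric(G %*% q_new)))
    if (is.finite(ll_old) && ll < ll_old - 1e-8) {
      ## EM guarantees monotone ascent; a drop indicates numerical trouble
      q_new <- q
      ll <- ll_old
      break
    }
    if (iter >= maxit ||
        (is.finite(ll_old) && abs(ll - ll_old) <= tol * (abs(ll_old) + 1e-12))) {
      q <- q_new
      break
    }
    q <- q_new
    ll_old <- ll
  }
  structure(q, loglik = ll, iterations = iter)
}

## ------------------------------------------------------------------------
## null-model maximum likelihood
## ------------------------------------------------------------------------

## Hard-coded multistart points in (tau, beta-fraction-of-cap, gamma1, gamma2):
## one canonical start plus four fixed pseudo-random interior points.
NULL_STARTS <- rbind(
  c(0.500, 0.500, 1 / 3, 1 / 3),
  c(0.266, 0.372, 0.573, 0.908),
  c(0.898, 0.945, 0.201, 0.662),
  c(0.057, 0.129, 0.852, 0.379),
  c(0.735, 0.789, 0.111, 0.494)
)

null_active_params <- function(ell1, ell2) {
  ells <- c(ell1, ell2)
  c(
    tau = any(ells %in% 1:3),
    beta = any(ells %in% 1:3),
    gamma1 = ell1 == 2,
    gamma2 = ell2 == 2
  )
}

#' Maximum likelihood fit of the null (no segregation distortion) model
#'
#' Maximizes the likelihood of the data over the three-parameter meiosis model
#' `(tau, beta, gamma1, gamma2)` for fixed parent dosages, using bounded
#' quasi-Newton ascent (`L-BFGS-B` with analytic gradients) from a canonical
#' start plus four fixed interior restarts. Parameters that cannot affect the
#' likelihood (e.g. `gamma1` when parent 1 is not duplex) are frozen.
#'
#' @param data Either a length-5 vector of genotype counts, or an n x 5
#'   genotype-likelihood matrix.
#' @param ell1,ell2 Parent dosages, integers in 0..4.
#' @param dr_cap Maximum double reduction rate (default 1/6).
#' @param boundary_tol Distance from a box limit below which a parameter is
#'   declared to be on the boundary.
#'
#' @return Object of class `"tetseg_null_fit"`: a list with elements `params`
#'   (`tau`, `beta`, `gamma1`, `gamma2`), `alpha`, `xi1`, `xi2` (two-parameter
#'   mapping; unreliable as point estimates, see Details), `q0hat`, `loglik`,
#'   `boundary` (named logical vector over the active null directions),
#'   `ells`, and `dr_cap`.
#'
#' @details The mapped estimates `alpha`, `xi1`, `xi2` are exposed for
#'   diagnostics only. At a single biallelic locus they are non-identified
#'   when a parent is duplex, and biased with high variance otherwise; they
#'   should not be used as substantive estimates of meiotic rates.
#' @export
mle_null <- function(data, ell1, ell2, dr_cap = DR_CAP_DEFAULT,
                     boundary_tol = 1e-4) {
  ell1 <- stop_if_not_dosage(ell1)
  ell2 <- stop_if_not_dosage(ell2)
  is_counts <- is.null(dim(data))
  if (is_counts) {
    x <- check_counts(data)
    possible <- possible_offspring_genotypes(ell1, ell2) + 1L
    x_in <- x
    x_in[-possible] <- 0  # impossible categories contribute a constant (-Inf)
    impossible_seen <- any(x > 0 & !(seq_along(x) %in% possible))
  } else {
    G <- check_gl(data)
    impossible_seen <- FALSE
  }

  active <- null_active_params(ell1, ell2)
  if (dr_cap <= 0) active["beta"] <- FALSE  # no double reduction direction
  lower <- c(0, 0, 0, 0)
  upper <- c(1, dr_cap, 1, 1)
  canon <- c(0.5, dr_cap / 2, 1 / 3, 1 / 3)

  objgrad <- function(theta_act) {
    theta <- canon
    theta[active] <- theta_act
    g1 <- gamete_freq_3p_grad(ell1, theta[1], theta[2], theta[3])
    g2 <- gamete_freq_3p_grad(ell2, theta[1], theta[2], theta[4])
    q <- pmax(conv5(g1$p, g2$p), 0)
    dq <- cbind(
      tau = conv5(g1$dtau, g2$p) + conv5(g1$p, g2$dtau),
      beta = conv5(g1$dbeta, g2$p) + conv5(g1$p, g2$dbeta),
      gamma1 = conv5(g1$dgamma, g2$p),
      gamma2 = conv5(g1$p, g2$dgamma)
    )
    if (is_counts) {
      pos <- x_in > 0
      qp <- pmax(q[pos], 1e-300)
      val <- sum(x_in[pos] * log(qp))
      gr <- colSums(x_in[pos] / qp * dq[pos, , drop = FALSE])
    } else {
      lik <- pmax(as.numeric(G %*% q), 1e-300)
      val <- sum(log(lik))
      gr <- colSums((G %*% dq) / lik)
    }
    list(value = -val, grad = -gr[active])
  }

  n_act <- sum(active)
  if (n_act == 0L) {
    theta <- canon
  } else {
    best <- NULL
    for (s in seq_len(nrow(NULL_STARTS))) {
      st <- NULL_STARTS[s, ]
      st[2] <- st[2] * dr_cap
      st_act <- st[active]
      fit <- tryCatch(
        stats::optim(
          par = st_act,
          fn = function(p) objgrad(p)$value,
          gr = function(p) objgrad(p)$grad,
          method = "L-BFGS-B",
          lower = lower[active], upper = upper[active],
          control = list(maxit = 200L)
        ),
        error = function(e) NULL
      )
      if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
    }
    if (is.null(best)) stop("null-model optimization failed for all restarts",
                            call. = FALSE)
    theta <- canon
    theta[active] <- best$par
  }
  names(theta) <- c("tau", "beta", "gamma1", "gamma2")

  q0 <- offspring_freq_null(ell1, ell2, theta[1], theta[2], theta[3], theta[4],
                            dr_cap = dr_cap)
  ll <- if (is_counts) loglik_counts(x, q0) else loglik_gl(G, q0)

  map <- map_3p_to_2p(theta[1], theta[2], theta[3], theta[4], dr_cap = dr_cap)

  ## Boundary attainment per active null *direction* (reduced, identifiable
  ## parameterization): the double reduction direction exists when a parent is
  ## simplex/triplex; each duplex parent contributes a pairing direction.
  boundary <- logical(0)
  dr_active <- any(c(ell1, ell2) %in% c(1L, 3L))
  if (dr_active) {
    boundary <- c(boundary, dr = (map$alpha <= boundary_tol) ||
                    (map$alpha >= dr_cap - boundary_tol))
  }
  for (j in 1:2) {
    ellj <- if (j == 1) ell1 else ell2
    if (ellj != 2L) next
    xij <- if (j == 1) map$xi1 else map$xi2
    if (dr_active) {
      bnd <- xi_bounds(min(max(map$alpha, 0), dr_cap), dr_cap)
      on_b <- (xij <= bnd[1] + boundary_tol) || (xij >= bnd[2] - boundary_tol)
    } else {
      ## double reduction not identified: use the duplex gamete heterozygote
      ## frequency, whose attainable range over the whole null space is [1/2, 1]
      p1mid <- (1 - map$alpha) * (1 + xij) / 2
      on_b <- (p1mid <= 1 / 2 + boundary_tol) || (p1mid >= 1 - boundary_tol)
    }
    boundary <- c(boundary, stats::setNames(on_b, paste0("pp", j)))
  }
  ## Duplex x duplex: the offspring frequencies are symmetric in the two
  ## parents' heterozygote gamete frequencies, so the null manifold is the
  ## quotient of the (p1, p1) square by the swap -- a surface with a fold
  ## along the diagonal. A fit landing on the diagonal is a boundary
  ## attainment of that quotient and loses one dimension.
  if (ell1 == 2L && ell2 == 2L && !any(boundary)) {
    p1a <- (1 - map$alpha) * (1 + map$xi1) / 2
    p1b <- (1 - map$alpha) * (1 + map$xi2) / 2
    boundary <- c(boundary, fold = abs(p1a - p1b) <= boundary_tol)
  }

  structure(
    list(
      params = theta,
      alpha = map$alpha, xi1 = map$xi1, xi2 = map$xi2,
      q0hat = q0,
      loglik = ll,
      boundary = boundary,
      impossible_seen = impossible_seen,
      ells = c(ell1, ell2),
      dr_cap = dr_cap
    ),
    class = "tetseg_null_fit"
  )
}

#' @export
print.tetseg_null_fit <- function(x, ...) {
  cat("Null (no segregation distortion) fit, parents (",
      x$ells[1], ",", x$ells[2], ")\n", sep = "")
  cat("  log-likelihood:", format(x$loglik), "\n")
  cat("  q0hat:", paste(format(round(x$q0hat, 4)), collapse = " "), "\n")
  cat("  alpha-hat:", format(round(x$alpha, 4)),
      "(diagnostic only; unreliable at a single locus)\n")
  if (length(x$boundary)) {
    cat("  boundary:", paste(names(x$boundary), x$boundary, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Estimate parental dosages from genotype likelihoods
#'
#' Maximizes `a[ell1] * b[ell2] * max_params f(G | q(., ell1, ell2))` over the
#' 25 ordered parent-dosage pairs by exhaustive search. Ties are broken by the
#' lexicographically smallest pair.
#'
#' @param a,b Length-5 genotype-likelihood vectors for parents 1 and 2
#'   (uniform by default, i.e. no parental data).
#' @inheritParams mle_null
#' @param data Offspring data: a length-5 counts vector or an n x 5
#'   genotype-likelihood matrix.
#' @return Integer vector `c(ell1, ell2)` with attribute `log_score` (the 5 x 5
#'   matrix of profile log-likelihoods, `-Inf` where a parent likelihood is 0).
#' @export
estimate_parents <- function(data, a = rep(1, 5), b = rep(1, 5),
                             dr_cap = DR_CAP_DEFAULT) {
  if (length(a) != 5L || length(b) != 5L || any(a < 0) || any(b < 0)) {
    stop("parent likelihoods must be non-negative vectors of length 5",
         call. = FALSE)
  }
  if (max(a) <= 0 || max(b) <= 0) {
    stop("all-zero parent genotype likelihoods", call. = FALSE)
  }
  a <- a / max(a)
  b <- b / max(b)
  score <- matrix(-Inf, 5, 5, dimnames = list(ell1 = 0:4, ell2 = 0:4))
  for (l1 in 0:4) {
    if (a[l1 + 1] <= 0) next
    for (l2 in 0:4) {
      if (b[l2 + 1] <= 0) next
      fit <- mle_null(data, l1, l2, dr_cap = dr_cap)
      score[l1 + 1, l2 + 1] <- log(a[l1 + 1]) + log(b[l2 + 1]) + fit$loglik
    }
  }
  if (all(!is.finite(score))) {
    stop("no parent-dosage pair has positive likelihood", call. = FALSE)
  }
  idx <- which(score == max(score), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ]
  structure(c(ell1 = unname(idx[1]) - 1L, ell2 = unname(idx[2]) - 1L),
            log_score = score)
}

## Indicator genotype-likelihood matrix from a counts vector (known genotypes
## expressed in the likelihood formulation).
counts_to_indicator_gl <- function(x) {
  x <- check_counts(x)
  dos <- rep(0:4, times = x)
  G <- matrix(0, nrow = length(dos), ncol = 5)
  G[cbind(seq_along(dos), dos + 1L)] <- 1
  G
}
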