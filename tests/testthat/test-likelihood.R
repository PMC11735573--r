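test_that("multinomial log-likelihood handles certain and impossible outcomes", {
  expect_equal(loglik_counts(c(2, 0, 0, 0, 0), c(1, 0, 0, 0, 0)), 0)
  expect_equal(loglik_counts(c(1, 1, 0, 0, 0), c(1 / 2, 1 / 2, 0, 0, 0)),
               log(1 / 2))
  expect_equal(loglik_counts(c(1, 0, 0, 0, 1), c(1 / 2, 1 / 2, 0, 0, 0)), -Inf)
})

test_that("genotype-likelihood log-likelihood is a stabilized mixture sum", {
  G <- matrix(1, nrow = 4, ncol = 5)
  expect_equal(loglik_gl(G, c(0.2, 0.2, 0.2, 0.2, 0.2)), 0)
  G1 <- matrix(c(1, 0, 0, 0, 0), nrow = 1)
  expect_equal(loglik_gl(G1, c(0.3, 0.7, 0, 0, 0)), log(0.3))
  ## indicator rows recover the counts likelihood up to the multinomial term
  x <- c(3, 2, 1, 0, 0)
  q <- c(0.5, 0.3, 0.1, 0.05, 0.05)
  lc <- loglik_counts(x, q) - (lgamma(sum(x) + 1) - sum(lgamma(x + 1)))
  expect_equal(loglik_gl(indicator_gl(x), q), lc, tolerance = 1e-12)
  expect_error(loglik_gl(matrix(0, 1, 5), q), "positive")
})

test_that("alternative MLE from counts is the empirical frequency vector", {
  expect_equal(mle_alt_counts(c(1, 1, 1, 1, 1)), rep(0.2, 5))
  expect_equal(mle_alt_counts(c(10, 0, 0, 0, 0)), c(1, 0, 0, 0, 0))
  ## brute-force oracle: x/n beats random simplex points
  set.seed(31)
  x <- c(7, 3, 5, 0, 2)
  ll_hat <- loglik_counts(x, mle_alt_counts(x))
  rand_q <- matrix(rexp(2000 * 5), ncol = 5)
  rand_q <- rand_q / rowSums(rand_q)
  ll_rand <- apply(rand_q, 1, function(q) loglik_counts(x, q))
  expect_true(all(ll_hat >= ll_rand))
})

test_that("EM for the genotype-likelihood MLE is exact, monotone, and optimal", {
  ## indicator rows: EM reproduces the counts MLE
  x <- c(5, 3, 0, 1, 1)
  qhat <- mle_alt_gl(indicator_gl(x))
  expect_equal(as.numeric(qhat), x / sum(x), tolerance = 1e-8)
  ## flat likelihood: the uniform start is already a fixed point
  qu <- mle_alt_gl(matrix(1, 6, 5))
  expect_equal(as.numeric(qu), rep(0.2, 5), tolerance = 1e-12)
  ## stochastic oracle on a random instance
  set.seed(41)
  G <- random_gl(8)
  qhat <- mle_alt_gl(G)
  ll_hat <- loglik_gl(G, as.numeric(qhat))
  rand_q <- matrix(rexp(1000 * 5), ncol = 5)
  rand_q <- rand_q / rowSums(rand_q)
  ll_rand <- apply(rand_q, 1, function(q) loglik_gl(G, q))
  expect_true(all(ll_hat >= ll_rand - 1e-9))
  ## per-iteration monotonicity of the EM map
  q <- rep(0.2, 5)
  ll_old <- loglik_gl(G, q)
  for (it in 1:50) {
    num <- G * rep(q, each = nrow(G))
    q <- colSums(num / rowSums(num)) / nrow(G)
    ll <- loglik_gl(G, q)
    expect_gte(ll, ll_old - 1e-10)
    ll_old <- ll
  }
})

test_that("null fit handles the parameter-free nullplex cross", {
  fit <- mle_null(c(50, 0, 0, 0, 0), 0, 0)
  expect_equal(fit$loglik, 0)
  expect_equal(fit$q0hat, c(1, 0, 0, 0, 0))
  expect_length(fit$boundary, 0)
})

test_that("null fit recovers the 13:10:1 simplex ratio at the DR cap", {
  x <- c(130, 100, 10, 0, 0)
  fit <- mle_null(x, 1, 0)
  expect_equal(fit$alpha, 1 / 6, tolerance = 1e-4)
  expect_equal(fit$q0hat, c(13, 10, 1, 0, 0) / 24, tolerance = 1e-4)
  ## 1-D profile-likelihood oracle over the double reduction rate
  prof <- optimize(function(a) {
    q <- offspring_freq(gamete_freq_2p(1, a), c(1, 0, 0))
    loglik_counts(x, q)
  }, c(0, 1 / 6), maximum = TRUE, tol = 1e-10)
  expect_equal(fit$loglik, prof$objective, tolerance = 1e-6)
})

test_that("null fit matches a 1-D profile oracle on random simplex crosses", {
  set.seed(51)
  for (i in 1:10) {
    q_true <- offspring_freq(gamete_freq_2p(1, runif(1, 0, 1 / 6)), c(1, 0, 0))
    x <- as.numeric(rmultinom(1, 150, q_true))
    fit <- mle_null(x, 1, 0)
    prof <- optimize(function(a) {
      q <- offspring_freq(gamete_freq_2p(1, a), c(1, 0, 0))
      loglik_counts(x, q)
    }, c(0, 1 / 6), maximum = TRUE, tol = 1e-10)
    expect_equal(fit$loglik, prof$objective, tolerance = 1e-5)
    ## null likelihood can never exceed the alternative
    expect_lte(fit$loglik, loglik_counts(x, mle_alt_counts(x)) + 1e-6)
  }
})

test_that("fitted null frequencies are consistent at large n", {
  set.seed(61)
  for (sc in list(list(ells = c(1, 2), a = 1 / 12, xi = 0.5),
                  list(ells = c(2, 2), a = 0, xi = 0.8))) {
    q_true <- offspring_freq(
      gamete_freq_2p(sc$ells[1], sc$a, sc$xi),
      gamete_freq_2p(sc$ells[2], sc$a, sc$xi)
    )
    x <- as.numeric(rmultinom(1, 1e5, q_true))
    fit <- mle_null(x, sc$ells[1], sc$ells[2])
    expect_lt(sum(abs(fit$q0hat - q_true)) / 2, 0.01)
  }
})

test_that("null fit with a zero DR cap reduces to the hypergeometric model", {
  set.seed(71)
  for (ells in list(c(1, 0), c(1, 3), c(3, 4))) {
    q_true <- offspring_freq(hypergeometric_gamete(ells[1]),
                             hypergeometric_gamete(ells[2]))
    x <- as.numeric(rmultinom(1, 100, q_true))
    fit <- mle_null(x, ells[1], ells[2], dr_cap = 0)
    expect_equal(fit$q0hat, q_true, tolerance = 1e-8)
  }
})

test_that("parent estimation maximizes the joint likelihood over dosage pairs", {
  ind <- function(k) { v <- rep(0, 5); v[k + 1] <- 1; v }
  G <- indicator_gl(c(10, 12, 3, 0, 0))
  ## parents known with certainty are returned untouched
  est <- estimate_parents(G, a = ind(2), b = ind(2))
  expect_equal(as.numeric(est), c(2, 2))
  ## one parent known, the other pinned
  est <- estimate_parents(G, a = ind(1), b = ind(0))
  expect_equal(as.numeric(est), c(1, 0))
  ## uninformative parents on clean simplex x nullplex data:
  ## (1,0) or its flip maximizes the likelihood
  set.seed(81)
  sim <- sim_offspring_genotypes(200, 1, 0, alpha = 0)
  est <- estimate_parents(indicator_gl(sim$x))
  expect_true(all(sort(unname(est)) == c(0, 1)))
  expect_error(estimate_parents(G, a = rep(0, 5)), "zero")
})
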