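test_that("null manifold dimension follows the parent configuration", {
  expect_equal(null_dimension(0, 4), 0L)
  expect_equal(null_dimension(0, 0), 0L)
  expect_equal(null_dimension(1, 0), 1L)
  expect_equal(null_dimension(1, 1), 1L)
  expect_equal(null_dimension(1, 3), 1L)
  expect_equal(null_dimension(2, 0), 1L)
  expect_equal(null_dimension(2, 2), 2L)
  expect_equal(null_dimension(1, 2), 2L)
  ## boundary attainment removes dimensions, floored at zero
  expect_equal(null_dimension(1, 0, c(dr = TRUE)), 0L)
  expect_equal(null_dimension(2, 2, c(pp1 = TRUE, pp2 = FALSE)), 1L)
  expect_equal(null_dimension(2, 2, c(pp1 = TRUE, pp2 = TRUE)), 0L)
})

test_that("null dimension equals the numeric Jacobian rank at interior points", {
  ## oracle: rank of dq/d(tau, beta, gamma1, gamma2) at an interior point
  jac_rank <- function(ell1, ell2) {
    th0 <- c(0.47, 0.09, 0.41, 0.58)
    h <- 1e-6
    J <- sapply(1:4, function(j) {
      up <- th0; up[j] <- up[j] + h
      dn <- th0; dn[j] <- dn[j] - h
      (tetseg:::offspring_freq_null(ell1, ell2, up[1], up[2], up[3], up[4]) -
         tetseg:::offspring_freq_null(ell1, ell2, dn[1], dn[2], dn[3], dn[4])) /
        (2 * h)
    })
    qr(J, tol = 1e-7)$rank
  }
  for (ells in list(c(0, 0), c(0, 4), c(1, 0), c(1, 1), c(1, 3),
                    c(2, 0), c(2, 2), c(1, 2), c(2, 3))) {
    expect_equal(null_dimension(ells[1], ells[2]), jac_rank(ells[1], ells[2]),
                 info = paste(ells, collapse = ","))
  }
})

test_that("count-based LRT handles degenerate and impossible configurations", {
  r <- lrt_counts(c(50, 0, 0, 0, 0), 0, 0)
  expect_equal(r$stat, 0)
  expect_equal(r$p_value, 1)
  ## impossible genotype observed: immediate p = 0
  r <- lrt_counts(c(5, 0, 0, 3, 0), 1, 0)
  expect_equal(r$p_value, 0)
  expect_true(r$impossible)
})

test_that("count-based LRT statistic matches the 1-D profile oracle", {
  set.seed(91)
  for (i in 1:6) {
    q_true <- offspring_freq(gamete_freq_2p(1, runif(1, 0, 1 / 6)), c(1, 0, 0))
    x <- as.numeric(rmultinom(1, 120, q_true))
    r <- lrt_counts(x, 1, 0)
    prof <- optimize(function(a) {
      q <- offspring_freq(gamete_freq_2p(1, a), c(1, 0, 0))
      loglik_counts(x, q)
    }, c(0, 1 / 6), maximum = TRUE, tol = 1e-10)
    lam_oracle <- 2 * (loglik_counts(x, mle_alt_counts(x)) - prof$objective)
    expect_equal(r$stat, max(lam_oracle, 0), tolerance = 1e-4)
    expect_gte(r$stat, 0)
  }
  ## the 13:10:1 data are perfectly explained by double reduction at the cap
  r <- lrt_counts(c(130, 100, 10, 0, 0), 1, 0)
  expect_lt(r$stat, 1e-6)
  expect_equal(r$p_value, 1)
})

test_that("GL-based LRT agrees with the counts LRT on indicator rows", {
  set.seed(101)
  for (ells in list(c(1, 0), c(2, 2), c(1, 2))) {
    sim <- sim_offspring_genotypes(120, ells[1], ells[2], alpha = 1 / 12)
    rc <- lrt_counts(sim$x, ells[1], ells[2])
    rg <- lrt_gl(indicator_gl(sim$x), ells[1], ells[2])
    if (!rc$impossible) {
      expect_equal(rg$stat, rc$stat, tolerance = 1e-4)
      expect_equal(rg$df, rc$df)
      expect_equal(rg$p_value, rc$p_value, tolerance = 1e-4)
    }
  }
})

test_that("uninformative genotype likelihoods yield no evidence of distortion", {
  G <- matrix(1, 100, 5)
  r <- lrt_gl(G, 2, 2)
  expect_lt(r$stat, 1e-6)
  expect_equal(r$p_value, 1, tolerance = 1e-6)
})

test_that("doubling all counts never decreases the LRT statistic", {
  set.seed(111)
  for (i in 1:8) {
    q <- as.numeric(rexp(5)); q <- q / sum(q)
    x <- as.numeric(rmultinom(1, 80, q))
    r1 <- lrt_counts(x, 2, 2)
    r2 <- lrt_counts(2 * x, 2, 2)
    expect_gte(r2$stat + 1e-6, r1$stat)
  }
})

test_that("unknown-parent LRT reduces to the known-parent test when parents are certain", {
  ind <- function(k) { v <- rep(0, 5); v[k + 1] <- 1; v }
  set.seed(121)
  sim <- sim_offspring_genotypes(150, 1, 2, alpha = 1 / 12)
  G <- indicator_gl(sim$x)
  r1 <- lrt_gl_unknown_parents(G, a = ind(1), b = ind(2))
  r2 <- lrt_gl(G, 1, 2)
  expect_equal(unname(r1$parents_used), c(1, 2))
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-8)
  expect_error(lrt_gl_unknown_parents(G, a = rep(0, 5)), "zero")
})

test_that("estimated parents reproduce the true-parent decision on clean data", {
  set.seed(131)
  agree <- 0
  reps <- 30
  for (r in 1:reps) {
    sim <- sim_offspring_genotypes(200, 1, 0, alpha = 1 / 12)
    G <- indicator_gl(sim$x)
    d_true <- lrt_counts(sim$x, 1, 0)$p_value <= 0.05
    d_est <- lrt_gl_unknown_parents(G)$p_value <= 0.05
    if (d_true == d_est) agree <- agree + 1
  }
  expect_gte(agree / reps, 0.95)
})

test_that("the LRT has power against a strongly distorted simplex pattern", {
  ## 3:1 segregation cannot be produced by any tetraploid meiosis here
  set.seed(141)
  rej <- 0
  reps <- 50
  for (r in 1:reps) {
    sim <- sim_offspring_genotypes(200, q = c(3 / 4, 1 / 4, 0, 0, 0))
    est <- estimate_parents(sim$x)
    if (lrt_counts(sim$x, est[1], est[2])$p_value <= 0.05) rej <- rej + 1
  }
  expect_gt(rej / reps, 0.5)
})

test_that("the LRT controls type I error across the known-genotype null grid", {
  grid <- null_sim_grid(n = 200, depth = Inf)
  res <- run_null_study(grid, reps = 200, methods = "lrt", seed = 1)
  rate <- aggregate(p_value ~ ell1 + ell2 + alpha + xi1 + xi2, data = res,
                    FUN = function(p) mean(p <= 0.05))
  expect_lte(max(rate$p_value), 0.10)
  expect_lte(mean(res$p_value <= 0.05), 0.06)
})
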