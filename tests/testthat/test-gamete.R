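test_that("duplex gamete frequencies match the known special cases", {
  expect_equal(gamete_freq_2p(2, 1 / 6, 1 / 3), c(2, 5, 2) / 9, tolerance = 1e-12)
  expect_equal(gamete_freq_2p(2, 0, 1 / 3), c(1, 4, 1) / 6, tolerance = 1e-12)
  expect_equal(gamete_freq_2p(2, 0, 0), c(1, 2, 1) / 4, tolerance = 1e-12)
  expect_equal(gamete_freq_2p(2, 0, 1), c(0, 1, 0), tolerance = 1e-12)
})

test_that("non-duplex rows follow the double-reduction-only pattern", {
  expect_equal(gamete_freq_2p(0, 0.1, 0.9), c(1, 0, 0))
  expect_equal(gamete_freq_2p(4, 0.1, 0.2), c(0, 0, 1))
  expect_equal(gamete_freq_2p(1, 1 / 6), c(13, 10, 1) / 24, tolerance = 1e-12)
  ## xi is accepted but ignored away from the duplex row
  expect_equal(gamete_freq_2p(1, 1 / 12, 0), gamete_freq_2p(1, 1 / 12, 1))
})

test_that("invalid dosages and parameters are rejected", {
  expect_error(gamete_freq_2p(5, 0), "dosage")
  expect_error(gamete_freq_2p(2, 0.5), "alpha")
  expect_error(gamete_freq_2p(2, 0, 1.5), "xi")
  expect_error(gamete_freq_3p(2, 1.2, 0), "tau")
  expect_error(hypergeometric_gamete(2, 5), "even")
})

test_that("three-parameter rows reduce correctly at the corners", {
  expect_equal(gamete_freq_3p(4, 0.3, 0.1, 0.8), c(0, 0, 1))
  ## pure quadrivalents without double reduction give the tetrasomic row
  expect_equal(gamete_freq_3p(2, 1, 0, 0.42), c(1, 4, 1) / 6, tolerance = 1e-12)
  ## pure bivalents with full AA:aa pairing transmit only heterozygous gametes
  expect_equal(gamete_freq_3p(2, 0, 0, 1), c(0, 1, 0), tolerance = 1e-12)
})

test_that("gamete and offspring distributions sum to one on a dense grid", {
  for (tau in seq(0, 1, length.out = 7)) {
    for (beta in seq(0, 1 / 6, length.out = 5)) {
      for (gamma in seq(0, 1, length.out = 5)) {
        for (ell in 0:4) {
          p <- gamete_freq_3p(ell, tau, beta, gamma)
          expect_true(all(p >= 0) && abs(sum(p) - 1) < 1e-12)
        }
      }
    }
  }
  for (a in seq(0, 1 / 6, length.out = 5)) {
    for (xi in seq(0, 1, length.out = 5)) {
      for (l1 in 0:4) for (l2 in 0:4) {
        q <- offspring_freq(gamete_freq_2p(l1, a, xi), gamete_freq_2p(l2, a, xi))
        expect_true(all(q >= 0) && abs(sum(q) - 1) < 1e-12)
      }
    }
  }
})

test_that("allele-flip symmetry holds for gametes and offspring", {
  for (a in c(0, 1 / 12, 1 / 6)) {
    for (xi in c(0, 1 / 3, 0.8)) {
      for (ell in 0:4) {
        expect_equal(rev(gamete_freq_2p(ell, a, xi)),
                     gamete_freq_2p(4 - ell, a, xi), tolerance = 1e-12)
      }
      for (l1 in 0:4) for (l2 in 0:4) {
        q <- offspring_freq(gamete_freq_2p(l1, a, xi), gamete_freq_2p(l2, a, xi))
        qf <- offspring_freq(gamete_freq_2p(4 - l1, a, xi),
                             gamete_freq_2p(4 - l2, a, xi))
        expect_equal(rev(q), qf, tolerance = 1e-12)
      }
    }
  }
})

test_that("two-parameter mapping reproduces the three-parameter model", {
  expect_equal(map_3p_to_2p(1, 0.1)$alpha, 0.1)
  expect_equal(map_3p_to_2p(1, 0.1)$xi1, 1 / 3, tolerance = 1e-12)
  m <- map_3p_to_2p(0, 0.05, gamma1 = 0.77)
  expect_equal(m$alpha, 0)
  expect_equal(m$xi1, 0.77, tolerance = 1e-12)
  set.seed(21)
  for (i in 1:50) {
    tau <- runif(1); beta <- runif(1, 0, 1 / 6)
    g1 <- runif(1); g2 <- runif(1)
    m <- map_3p_to_2p(tau, beta, g1, g2)
    for (ell in 0:4) {
      expect_equal(gamete_freq_2p(ell, m$alpha, m$xi1),
                   gamete_freq_3p(ell, tau, beta, g1), tolerance = 1e-12)
      expect_equal(gamete_freq_2p(ell, m$alpha, m$xi2),
                   gamete_freq_3p(ell, tau, beta, g2), tolerance = 1e-12)
    }
  }
})

test_that("the duplex model is not identified in (alpha, xi)", {
  expect_equal(gamete_freq_2p(2, 1 / 6, 1 / 3), gamete_freq_2p(2, 0, 1 / 9),
               tolerance = 1e-12)
})

test_that("hypergeometric gametes agree with the no-DR polysomic model", {
  expect_equal(hypergeometric_gamete(2, 4), c(1, 4, 1) / 6)
  expect_equal(hypergeometric_gamete(0, 4), c(1, 0, 0))
  expect_equal(hypergeometric_gamete(1, 4), c(1 / 2, 1 / 2, 0))
  for (ell in 0:4) {
    expect_equal(gamete_freq_2p(ell, 0, 1 / 3), hypergeometric_gamete(ell, 4),
                 tolerance = 1e-12)
  }
  ## hexaploid row sanity: sums to one
  expect_equal(sum(hypergeometric_gamete(3, 6)), 1)
})

test_that("offspring convolution matches the hand expansion and is symmetric", {
  expect_equal(offspring_freq(c(1, 0, 0), c(1, 0, 0)), c(1, 0, 0, 0, 0))
  expect_equal(offspring_freq(c(1 / 2, 1 / 2, 0), c(1, 0, 0)),
               c(1 / 2, 1 / 2, 0, 0, 0))
  q <- offspring_freq(c(13, 10, 1) / 24, c(1, 0, 0))
  expect_equal(q[1] / q[3], 13, tolerance = 1e-12)
  expect_equal(q[2] / q[3], 10, tolerance = 1e-12)
  p1 <- c(0.2, 0.5, 0.3); p2 <- c(0.6, 0.3, 0.1)
  expect_equal(offspring_freq(p1, p2), offspring_freq(p2, p1), tolerance = 1e-12)
})

test_that("preferential pairing bounds follow the double reduction rate", {
  expect_equal(unname(xi_bounds(0, 1 / 6)), c(0, 1))
  expect_equal(unname(xi_bounds(1 / 6, 1 / 6)), c(1 / 3, 1 / 3), tolerance = 1e-12)
  b <- xi_bounds(1 / 12, 1 / 6)
  expect_equal(unname(b), c(5 / 33, 1 - 10 / 33), tolerance = 1e-12)
  expect_true(b[1] <= b[2])
  expect_error(xi_bounds(0.1, 0), "incompatible")
})

test_that("possible offspring genotype sets are Minkowski sums of gamete supports", {
  expect_equal(possible_offspring_genotypes(0, 0), 0L)
  expect_equal(possible_offspring_genotypes(1, 0), 0:2)
  expect_equal(possible_offspring_genotypes(1, 4), 2:4)
  expect_equal(possible_offspring_genotypes(4, 4), 4L)
  expect_equal(possible_offspring_genotypes(2, 2), 0:4)
  expect_equal(possible_offspring_genotypes(0, 4), 2L)
})
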