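## ------------------------------------------------------------------------
## Synthetic data generation (offspring genotypes, read-based genotype
## likelihoods) and the null/alternative simulation studies.
## ------------------------------------------------------------------------

#' Simulate offspring genotypes for one SNP
#'
#' Draws `n` offspring genotypes from the multinomial implied either by the
#' null meiosis model (parent dosages plus double reduction rate and
#' per-parent preferential pairing) or by an arbitrary genotype frequency
#' vector `q` (the segregation-distortion alternative).
#'
#' @param n Number of offspring.
#' @param ell1,ell2 Parent dosages (null model); ignored when `q` is given.
#' @param alpha Double reduction rate.
#' @param xi1,xi2 Preferential pairing parameters (used only for duplex
#'   parents); must satisfy the bound implied by `alpha` and `dr_cap`.
#' @param q Optional genotype frequency vector of length 5 (alternative).
#' @param dr_cap Maximum double reduction rate.
#' @return List with `x` (length-5 genotype counts), `dosage` (length-n
#'   integer vector), and `q` (the true genotype frequencies).
#' @export
sim_offspring_genotypes <- function(n, ell1 = NULL, ell2 = NULL, alpha = 0,
                                    xi1 = 1 / 3, xi2 = 1 / 3, q = NULL,
                                    dr_cap = DR_CAP_DEFAULT) {
  if (is.null(q)) {
    bnd <- xi_bounds(alpha, dr_cap)
    for (xi in c(xi1, xi2)) {
      if (xi < bnd[1] - 1e-9 || xi > bnd[2] + 1e-9) {
        stop("xi outside the bounds implied by alpha and dr_cap", call. = FALSE)
      }
    }
    q <- offspring_freq(
      gamete_freq_2p(ell1, alpha, xi1, dr_cap = dr_cap),
      gamete_freq_2p(ell2, alpha, xi2, dr_cap = dr_cap)
    )
  } else {
    if (length(q) != 5L || any(q < 0) || abs(sum(q) - 1) > 1e-8) {
      stop("q must be a probability vector of length 5", call. = FALSE)
    }
  }
  dosage <- sample(0:4, size = n, replace = TRUE, prob = q)
  x <- tabulate(dosage + 1L, nbins = 5L)
  list(x = x, dosage = dosage, q = q)
}

## Beta-binomial log mass with intra-class correlation rho
## (shapes a = f(1-rho)/rho, b = (1-f)(1-rho)/rho); rho -> 0 is binomial and
## f in {0, 1} degenerates to a point mass.
dbetabinom_log <- function(y, size, f, rho) {
  if (f <= 0) return(ifelse(y == 0, 0, -Inf))
  if (f >= 1) return(ifelse(y == size, 0, -Inf))
  if (rho <= 0) return(stats::dbinom(y, size, f, log = TRUE))
  a <- f * (1 - rho) / rho
  b <- (1 - f) * (1 - rho) / rho
  lchoose(size, y) + lbeta(y + a, size - y + b) - lbeta(a, b)
}

rbetabinom <- function(n, size, f, rho) {
  f <- rep_len(f, n)
  if (rho <= 0) return(stats::rbinom(n, size, f))
  y <- integer(n)
  interior <- f > 0 & f < 1
  if (any(!interior)) y[!interior] <- stats::rbinom(sum(!interior), size, f[!interior])
  if (any(interior)) {
    fi <- f[interior]
    a <- fi * (1 - rho) / rho
    b <- (1 - fi) * (1 - rho) / rho
    y[interior] <- stats::rbinom(sum(interior), size,
                                 stats::rbeta(sum(interior), a, b))
  }
  y
}

## Reference-vs-alternative read fraction for a dosage k individual, with
## sequencing error eps and allele bias h (h = 1: no bias).
read_fraction <- function(k, eps, bias = 1) {
  f <- (k / 4) * (1 - eps) + (1 - k / 4) * eps
  f / (f + bias * (1 - f))
}

#' Simulate read-based genotype likelihoods
#'
#' For each offspring with true dosage `dosage[i]`, draws an
#' alternative-allele read count from a beta-binomial read model (fixed
#' `depth` reads, sequencing error `seq_error`, overdispersion
#' `overdispersion` as an intra-class correlation, allele bias `bias`), then
#' evaluates the beta-binomial likelihood of that count under each candidate
#' dosage 0..4. Rows are normalized to maximum 1.
#'
#' @param dosage Integer vector of true offspring dosages (0..4).
#' @param depth Reads per individual (default 10). Zero-depth individuals get
#'   uniform (uninformative) rows with a warning.
#' @param seq_error Sequencing error rate (default 0.01).
#' @param overdispersion Beta-binomial intra-class correlation (default 0.01;
#'   0 gives binomial reads).
#' @param bias Allele bias (default 1, none).
#' @return n x 5 genotype-likelihood matrix.
#' @export
sim_genotype_likelihoods <- function(dosage, depth = 10, seq_error = 0.01,
                                     overdispersion = 0.01, bias = 1) {
  if (any(!(dosage %in% 0:4))) stop("dosages must be in 0..4", call. = FALSE)
  if (depth < 0) stop("depth must be non-negative", call. = FALSE)
  n <- length(dosage)
  if (depth == 0) {
    warning("depth 0: returning uninformative (uniform) genotype likelihoods")
    return(matrix(1, n, 5))
  }
  f_true <- read_fraction(dosage, seq_error, bias)
  y <- rbetabinom(n, depth, f_true, overdispersion)
  ## likelihoods can coincide for equal f_true, so evaluate per candidate k
  G <- matrix(0, n, 5)
  for (k in 0:4) {
    fk <- read_fraction(k, seq_error, bias)
    G[, k + 1L] <- exp(dbetabinom_log(y, depth, fk, overdispersion))
  }
  G / apply(G, 1, max)
}

#' The fixed menu of alternative genotype frequency vectors
#'
#' Fourteen genotype-frequency vectors used as segregation-distortion
#' alternatives in the simulation studies.
#'
#' @return List of 14 numeric vectors of length 5, each summing to 1.
#' @seealso [sample_simplex_q()] for uniform draws from the 4-simplex.
#' @export
alternative_q_menu <- function() {
  list(
    c(1, 1, 1, 1, 1) / 5,
    c(1, 1, 1, 1, 0) / 4,
    c(4, 3, 2, 1, 0) / 10,
    c(1, 2, 3, 4, 0) / 10,
    c(1, 1, 1, 0, 0) / 3,
    c(0, 1, 1, 1, 0) / 3,
    c(3, 2, 1, 0, 0) / 6,
    c(0, 3, 2, 1, 0) / 6,
    c(1, 2, 3, 0, 0) / 6,
    c(0, 1, 2, 3, 0) / 6,
    c(3, 1, 0, 0, 0) / 4,
    c(1, 3, 0, 0, 0) / 4,
    c(0, 3, 1, 0, 0) / 4,
    c(0, 1, 3, 0, 0) / 4
  )
}

#' Uniform draws from the 4-simplex
#'
#' @param n Number of draws.
#' @return n x 5 matrix of genotype frequency vectors (rows sum to 1).
#' @export
sample_simplex_q <- function(n) {
  g <- matrix(stats::rexp(n * 5), nrow = n)
  g / rowSums(g)
}

#' Null simulation scenario grid
#'
#' Builds the grid of null scenarios: parent-dosage pairs, sample sizes,
#' double reduction rates, the three-point preferential pairing menu
#' `{(5/3) a/(1-a), 1/3, 1 - (10/3) a/(1-a)}` (varied only for duplex
#' parents; at `alpha = 1/6` the bound pins `xi` to 1/3), and read depths
#' (`Inf` = known genotypes).
#'
#' @param ells List of parent-dosage pairs.
#' @param n Sample sizes.
#' @param alpha Double reduction rates.
#' @param depth Read depths; `Inf` for known genotypes.
#' @return Data frame with columns `ell1`, `ell2`, `n`, `alpha`, `xi1`,
#'   `xi2`, `depth` (duplicate scenarios removed).
#' @export
null_sim_grid <- function(ells = list(c(0, 1), c(0, 2), c(1, 1), c(1, 2), c(2, 2)),
                          n = c(20, 200), alpha = c(0, 1 / 12, 1 / 6),
                          depth = c(10, Inf)) {
  xi_menu <- function(a) {
    unique(c((5 / 3) * a / (1 - a), 1 / 3, 1 - (10 / 3) * a / (1 - a)))
  }
  rows <- list()
  for (el in ells) {
    for (a in alpha) {
      menu <- xi_menu(a)
      x1s <- if (el[1] == 2) menu else 1 / 3
      x2s <- if (el[2] == 2) menu else 1 / 3
      for (x1 in x1s) for (x2 in x2s) for (nn in n) for (d in depth) {
        rows[[length(rows) + 1L]] <-
          data.frame(ell1 = el[1], ell2 = el[2], n = nn, alpha = a,
                     xi1 = x1, xi2 = x2, depth = d)
      }
    }
  }
  unique(do.call(rbind, rows))
}

## Apply the requested methods to one simulated data set; returns a list of
## per-method rows. Known-genotype data come as counts; read-based data as a
## genotype-likelihood matrix.
apply_methods <- function(methods, x, G, ell1, ell2, known_parents,
                          dr_cap, n_draws, bayes_seed) {
  out <- list()
  gl_mode <- !is.null(G)
  if (!known_parents) {
    est <- if (gl_mode) estimate_parents(G, dr_cap = dr_cap) else
      estimate_parents(x, dr_cap = dr_cap)
    e1 <- est[1]; e2 <- est[2]
  } else {
    e1 <- ell1; e2 <- ell2
  }
  for (m in methods) {
    p <- NA_real_
    lbf <- NA_real_
    stat <- NA_real_
    if (m == "lrt") {
      r <- if (gl_mode) lrt_gl(G, e1, e2, dr_cap = dr_cap) else
        lrt_counts(x, e1, e2, dr_cap = dr_cap)
      p <- r$p_value; stat <- r$stat
    } else if (m == "chisq") {
      xx <- if (gl_mode) post_mode_counts(G) else x
      r <- chisq_test(xx, e1, e2)
      p <- r$p_value; stat <- r$details$stat
    } else if (m == "polymapr") {
      r <- if (gl_mode) polymapr_like_test(G / rowSums(G), e1, e2) else
        polymapr_like_test(x, e1, e2)
      p <- r$p_value
    } else if (m == "bayes") {
      r <- bayes_test(if (gl_mode) G else x, ell1 = e1, ell2 = e2,
                      prior = null_prior(dr_cap = dr_cap),
                      n_draws = n_draws, seed = bayes_seed)
      lbf <- r$log_bf
    } else {
      stop("unknown method: ", m, call. = FALSE)
    }
    out[[m]] <- data.frame(method = m, p_value = p, log_bf = lbf, stat = stat,
                           ell1_used = e1, ell2_used = e2)
  }
  out
}

## Posterior-mode genotype counts from a genotype-likelihood matrix under a
## uniform prior over dosages.
post_mode_counts <- function(G) {
  mode <- max.col(G, ties.method = "first") - 1L
  tabulate(mode + 1L, nbins = 5L)
}

#' Run the null simulation study
#'
#' For each scenario row of `grid` and each replicate, simulates offspring
#' genotypes under the null meiosis model (and, at finite depth, read-based
#' genotype likelihoods), applies the requested tests with the true parent
#' dosages, and returns a long-format table of p-values / log Bayes factors.
#'
#' @param grid Scenario data frame as from [null_sim_grid()].
#' @param reps Replicates per scenario (the full study uses 200).
#' @param methods Subset of `c("lrt", "bayes", "chisq", "polymapr")`.
#' @param seed Integer seed; the whole study is reproducible given it.
#' @param n_draws Monte Carlo draws for the Bayes test.
#' @param dr_cap Maximum double reduction rate.
#' @return Long-format data frame: scenario columns, `rep`, `method`,
#'   `p_value`, `log_bf`, `stat`, parents used.
#' @export
run_null_study <- function(grid = null_sim_grid(), reps = 200L,
                           methods = c("lrt", "chisq"), seed = 1L,
                           n_draws = 2000L, dr_cap = DR_CAP_DEFAULT) {
  stopifnot(all(c("ell1", "ell2", "n", "alpha", "xi1", "xi2", "depth")
                %in% names(grid)))
  set.seed(seed)
  out <- vector("list", nrow(grid) * reps)
  k <- 0L
  for (s in seq_len(nrow(grid))) {
    sc <- grid[s, ]
    for (r in seq_len(reps)) {
      sim <- sim_offspring_genotypes(sc$n, sc$ell1, sc$ell2, sc$alpha,
                                     sc$xi1, sc$xi2, dr_cap = dr_cap)
      G <- if (is.finite(sc$depth)) {
        sim_genotype_likelihoods(sim$dosage, depth = sc$depth)
      } else NULL
      rows <- apply_methods(methods, sim$x, G, sc$ell1, sc$ell2,
                            known_parents = TRUE, dr_cap = dr_cap,
                            n_draws = n_draws, bayes_seed = NULL)
      k <- k + 1L
      out[[k]] <- cbind(sc, rep = r, do.call(rbind, rows), row.names = NULL)
    }
  }
  res <- do.call(rbind, out[seq_len(k)])
  rownames(res) <- NULL
  res
}

#' Run the alternative simulation study
#'
#' As [run_null_study()] but offspring genotypes are drawn from arbitrary
#' genotype frequency vectors and parental dosages are *estimated* by
#' maximum likelihood before testing, matching the intended use on real data
#' where the truth is unknown.
#'
#' @param q_list List of genotype frequency vectors (e.g.
#'   [alternative_q_menu()]).
#' @param n Sample sizes.
#' @param depth Read depths; `Inf` for known genotypes.
#' @inheritParams run_null_study
#' @return Long-format data frame with a `q_id` scenario column.
#' @export
run_alt_study <- function(q_list = alternative_q_menu(), n = c(20, 200),
                          depth = c(10, Inf), reps = 200L,
                          methods = c("lrt", "chisq"), seed = 1L,
                          n_draws = 2000L, dr_cap = DR_CAP_DEFAULT) {
  set.seed(seed)
  out <- list()
  for (qi in seq_along(q_list)) {
    q <- q_list[[qi]]
    for (nn in n) for (d in depth) {
      for (r in seq_len(reps)) {
        sim <- sim_offspring_genotypes(nn, q = q)
        G <- if (is.finite(d)) sim_genotype_likelihoods(sim$dosage, depth = d)
          else NULL
        rows <- apply_methods(methods, sim$x, G, NA, NA,
                              known_parents = FALSE, dr_cap = dr_cap,
                              n_draws = n_draws, bayes_seed = NULL)
        out[[length(out) + 1L]] <- cbind(
          data.frame(q_id = qi, n = nn, depth = d, rep = r),
          do.call(rbind, rows), row.names = NULL
        )
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' ROC summary over pooled null and alternative simulation results
#'
#' Pools replicates per method and computes the empirical true positive rate
#' at each achievable false positive rate. For p-value methods the rejection
#' score is the p-value (small = distortion); for the Bayes test the score
#' is the log Bayes factor (small = distortion).
#'
#' @param null_table,alt_table Results from [run_null_study()] /
#'   [run_alt_study()]; must share method labels.
#' @param fpr_grid Optional false positive rates at which to report; default
#'   reports every achievable FPR.
#' @return Data frame with columns `method`, `fpr`, `tpr`.
#' @export
roc_summary <- function(null_table, alt_table, fpr_grid = NULL) {
  if (nrow(null_table) == 0 || nrow(alt_table) == 0) {
    stop("need non-empty null and alternative tables", call. = FALSE)
  }
  methods <- intersect(unique(null_table$method), unique(alt_table$method))
  if (length(methods) == 0) stop("no shared method labels", call. = FALSE)
  score_of <- function(tab, m) {
    tt <- tab[tab$method == m, ]
    if (m == "bayes") tt$log_bf else tt$p_value
  }
  out <- list()
  for (m in methods) {
    s0 <- score_of(null_table, m)
    s1 <- score_of(alt_table, m)
    thr <- sort(unique(c(-Inf, s0, s1)))
    fpr <- vapply(thr, function(t) mean(s0 <= t), numeric(1))
    tpr <- vapply(thr, function(t) mean(s1 <= t), numeric(1))
    if (!is.null(fpr_grid)) {
      tpr <- vapply(fpr_grid, function(f) {
        ok <- fpr <= f + 1e-12
        if (any(ok)) max(tpr[ok]) else 0
      }, numeric(1))
      fpr <- fpr_grid
    }
    out[[m]] <- data.frame(method = m, fpr = fpr, tpr = tpr)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
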