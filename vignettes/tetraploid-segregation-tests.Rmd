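---
title: "Testing for segregation distortion in tetraploid F1 populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing for segregation distortion in tetraploid F1 populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetseg)
```

## The problem

In an F1 population of tetraploids, every offspring receives one gamete from
each parent. Under Mendelian segregation the offspring dosage frequencies at
a biallelic locus are determined by the parental dosages — but only if
meiosis is "textbook". Tetraploid meiosis is not: quadrivalent formation can
place sister-chromatid segments into the same gamete (*double reduction*),
and homologues may pair non-randomly into bivalents (*preferential
pairing*). Both processes move the gamete frequencies away from the strict
bivalent (hypergeometric) expectations without any genotyping artifact being
present. A test for segregation distortion that ignores them — the classical
chi-squared test — rejects well-behaved markers wholesale, particularly at
simplex × nullplex loci where double reduction produces dosage-2 offspring
that are "impossible" under the naive model.

`tetseg` tests the composite null that the offspring frequencies are
*consistent with some admissible tetraploid meiosis*, rather than with one
fixed segregation ratio.

## The gamete-frequency model

Two equivalent parameterizations are implemented.

* **Three parameters** (`gamete_freq_3p`): τ, the probability of
  quadrivalent formation; β, the probability of double reduction given a
  quadrivalent; γ, the probability (per duplex parent) that bivalents form
  along shared alleles. This is the mechanistic space over which the null
  likelihood is maximized and the null prior is placed.
* **Two parameters** (`gamete_freq_2p`): the double reduction rate α and the
  preferential pairing parameter ξ, with α = βτ and
  ξ = 1 − [(2/3)τ(1−β) + (1−τ)(1−γ)] / (1 − βτ).
  ξ = 1/3 is tetrasomic inheritance; ξ ∈ {0, 1} fully disomic. The mapping
  was re-derived by equating the two duplex rows and is enforced by a grid
  identity test at 10⁻¹² precision.

Offspring frequencies are the discrete convolution of the two parental
gamete distributions (`offspring_freq`). Two structural facts shape
everything downstream:

* **Constraint.** With a cap c on the double reduction rate (default
  c = 1/6, the complete-equational-segregation maximum; user-settable via
  `dr_cap`), ξ is confined to
  (1/3)(α/(1−α))((1−c)/c) ≤ ξ ≤ 1 − (2/3)(α/(1−α))((1−c)/c)
  (`xi_bounds`). At α = c the interval collapses to {1/3}.
* **Non-identifiability.** For duplex parents, (α, ξ) pairs collapse:
  (1/6, 1/3) and (0, 1/9) give identical gamete frequencies. The package
  therefore treats α̂, ξ̂ as diagnostics only — they are exposed with a
  documented warning, since even where identified (simplex/triplex parents)
  they are badly biased and highly variable at a single locus.

The two parents share one double reduction rate α but carry separate ξ₁,
ξ₂: which chromosomes "share alleles" differs between parents, so forcing
ξ₁ = ξ₂ would be wrong. For the same reason the model holds for a single F1
generation only and must not be chained across generations.

## Likelihood ratio tests

With known genotypes the data are multinomial counts; with sequencing data
they are an n × 5 genotype-likelihood matrix G, giving the mixture
likelihood ∏ᵢ Σₖ gᵢₖ qₖ. The alternative MLE is x/n (counts) or the EM fixed
point of qₖ ← meanᵢ gᵢₖqₖ/Σₗ gᵢₗqₗ (uniform start, relative tolerance 10⁻¹⁰,
cap 2000 iterations; monotone ascent is asserted in tests). The null MLE
maximizes over (τ, β, γ₁, γ₂) with L-BFGS-B using hand-derived analytic
gradients, from one canonical start (τ = 1/2, β = c/2, γ = 1/3) plus four
fixed interior restarts — the likelihood has ridges along the
non-identifiable directions, so single starts are fragile. Parameters that
cannot affect the likelihood (τ, β when both parents are in {0, 4}; γⱼ
unless parent j is duplex) are frozen.

**Degrees of freedom.** The null parameter space has boundaries, so the χ²
calibration uses data-dependent degrees of freedom. The base null dimension
is 0 when both parents are in {0, 4}; otherwise one dimension for the shared
double reduction direction if a parent is simplex or triplex, plus one per
duplex parent (within a duplex parent, α and ξ collapse onto the single
heterozygote-gamete-frequency direction — a lone duplex parent contributes
1, not 2). This rule is validated in the tests against the numerical rank of
the Jacobian of q(τ, β, γ₁, γ₂). One dimension is subtracted for every
active direction whose estimate lands on its boundary (tolerance 10⁻⁴ from
the limit), floored at zero.

Two boundary subtleties deserve note:

* **The duplex × duplex fold.** The offspring frequencies are symmetric in
  the two parents' heterozygote gamete frequencies (p₁⁽¹⁾, p₁⁽²⁾), so the
  null manifold is the quotient of the square [1/2, 1]² by the swap — a
  surface with a *fold* along the diagonal. When ξ₁ = ξ₂ in truth the true
  parameter lies on that fold, the constrained fit lands exactly on the
  diagonal about half the time, and treating those fits as interior leaves
  the test anti-conservative *even asymptotically* (we measured ≈0.08
  rejection at nominal 0.05 that persisted at n = 5000). A fit on the
  diagonal is therefore flagged as a boundary attainment, restoring ≈0.05.
* **df = 0 convention.** When the degrees of freedom floor at zero, p = 1 is
  returned for a statistic ≈ 0, with a conservative df = 1 survival value as
  fallback otherwise; the df = 0 branch is undefined in standard theory and
  this choice errs conservative.

If offspring are observed at genotypes impossible for the given parents over
the *whole* null space (e.g. dosage 3 from simplex × nullplex), the test
short-circuits to p = 0. For counts the alternative dimension is the number
of theoretically possible genotypes minus one; for genotype likelihoods it
is 4 minus the number of classes that are both theoretically impossible and
estimated below 10⁻⁸ by EM (EM reaches exact zeros only in the limit).

When parental genotypes are unknown, (ℓ₁, ℓ₂) maximizes
a₍ℓ₁₎b₍ℓ₂₎·maxₚₐᵣ f(G | q(·)) over all 25 ordered pairs (exhaustive, ties to
the lexicographically smallest pair), and the test proceeds as if they were
known. The impossible-genotype rule applies *after* parent estimation, which
is the only ordering that makes the estimated-parent workflow well defined.

## Bayesian tests

The Bayes factor is the ratio of marginal likelihoods, null over alternative
— positive log BF favors no distortion. Defaults: τ ~ Unif(0, 1),
β ~ Unif(0, c), γⱼ ~ Beta(5/9, 10/9) (mean 1/3, the tetrasomic value, with
the variance 1/12 of a uniform prior), all user-overridable via
`null_prior()`; the alternative is Dirichlet(1/2, …, 1/2), the multinomial
Jeffreys prior. With counts, the alternative marginal is the closed-form
Dirichlet-multinomial. All other integrals are estimated by plain Monte
Carlo over prior draws with log-sum-exp pooling: the active parameter space
is at most 4-dimensional and bounded, so prior sampling is adequate and
dependency-free, and every estimate carries a delta-method Monte Carlo
standard error. The estimator is validated against 1-D adaptive quadrature
over the pushforward density of α = τβ (log(c/α)/c on (0, c)) and against
the closed form. Default 50 000 draws; raise `n_draws` for sharper factors.
As a reporting guideline, log BF < −16 is strong evidence of distortion;
this threshold is documentation, not a hard-coded decision.

Expect negative log BFs at fixed-heterozygosity loci of true allopolyploids
(all offspring duplex): the default priors put little mass near full disomy.
Users studying a known allopolyploid should concentrate the γ priors near 0
or 1 accordingly.

## Baselines

`chisq_test` is the classical test against the no-DR, no-pairing
hypergeometric expectations (categories with zero expectation excluded;
observing one yields p = 0). `polymapr_like_test` follows the published
description of polymapR's `checkF1()` segregation screen: per candidate
pattern (each parent fully polysomic or fully disomic), a χ² test on the
"valid" genotypes times a one-sided binomial test of the "invalid" count at
a 3% expectation, maximized over patterns. Posterior-matrix input is
collapsed to counts with sub-threshold rounding (default 0.1·n·0.01 — the
original's threshold is not published, so ours is configurable). It is
faithful in spirit, not bit-compatible.

## What the simulator emulates — and what it does not

`sim_offspring_genotypes` draws multinomial genotypes from the meiosis model
(or an arbitrary q under the alternative). `sim_genotype_likelihoods`
emulates sequencing: a fixed number of reads per individual (default depth
10, read as a constant per-SNP depth), alternative-read counts from a
beta-binomial with sequencing error 0.01 and overdispersion 0.01 (intra-class
correlation; shapes a = f(1−ρ)/ρ, b = (1−f)(1−ρ)/ρ, binomial as ρ → 0) and
no allele bias; genotype likelihoods are the true beta-binomial masses under
each candidate dosage. Real pipelines estimate genotype likelihoods with an
empirical-Bayes genotyper rather than the true read model, depths vary
across individuals, and allele bias is rarely exactly 1 — so passing
simulations demonstrate correctness of the tests under the stated read
model, not robustness to genotyper misspecification.

The null study grid mirrors the standard design: parent pairs
{(0,1), (0,2), (1,1), (1,2), (2,2)}, n ∈ {20, 200}, α ∈ {0, 1/12, 1/6}, ξ
from the three-point menu {(5/3)α/(1−α), 1/3, 1 − (10/3)α/(1−α)} varied only
for duplex parents (the menu collapses to {1/3} at α = 1/6), depth
∈ {10, ∞}, 200 replicates per scenario. The alternative study uses the
fixed menu of 14 distortion vectors (`alternative_q_menu`) plus uniform
4-simplex draws, with parental dosages estimated before testing. The test
suite runs the full known-genotype grid at n = 200 with 200 replicates and a
reduced depth-10 grid, and uses 2 000–50 000 Monte Carlo draws depending on
the check; these sizes were chosen as the smallest at which the binomial
noise of the empirical rates is well inside the asserted tolerances.

## Numerical choices

* Probability vectors with floating-point deficits below 10⁻¹⁰ are clipped
  to zero and renormalized; larger deficits raise an error (they signal an
  invalid parameter combination, not round-off).
* Genotype-likelihood rows are normalized to maximum 1 on input (the
  likelihood is scale-invariant per row) to avoid underflow; all-zero rows
  are rejected.
* Likelihood-ratio statistics in (−10⁻⁶, 0) are clipped to 0; anything more
  negative triggers a warning about the optimizer.
* Monte Carlo marginals report −∞ with a warning if every draw has zero
  likelihood.
* Multistart points are fixed constants, so all fits are deterministic;
  simulation and Monte Carlo randomness is controlled by explicit seeds.

## Limitations

* Tetraploids only; the hypergeometric baseline accepts any even ploidy but
  the preferential-pairing model does not extend beyond K = 4 here.
* Point estimates of α and ξ from a single locus are unreliable by
  construction; the package exposes them only as diagnostics and implements
  no multi-locus smoothing.
* The Pearson-χ² variant of the model-based test and posterior inference on
  (τ, β, γ) are deliberately out of scope; only marginal likelihoods are
  computed.
* polymapR's additional quality scores and aggregation logic are not
  reproduced.
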