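# tetseg

Tests for segregation distortion at biallelic SNPs in **tetraploid F1
populations** (full-sib families from a biparental cross).

Breeding programs routinely discard SNPs whose offspring genotype frequencies
deviate from Mendelian expectations. In tetraploids, the classical chi-squared
test does this badly: polyploid meiosis naturally shifts gamete frequencies
through **double reduction** (rate α) and **preferential pairing** (ξ per
parent), and sequencing-based genotypes carry substantial uncertainty. Both
effects make naive tests flag perfectly well-behaved markers. `tetseg`
implements likelihood ratio and Bayesian tests built on a gamete-frequency
model that accommodates both meiotic processes and, optionally, genotype
uncertainty through genotype likelihoods.

## The model

A tetraploid parent of dosage ℓ ∈ {0,…,4} transmits gametes of dosage
x ∈ {0,1,2} with probabilities that depend on α and (for duplex parents, ℓ=2)
ξ:

| ℓ | x = 0 | x = 1 | x = 2 |
|---|-------|-------|-------|
| 0 | 1 | 0 | 0 |
| 1 | 1/2 + α/4 | 1/2 − α/2 | α/4 |
| 2 | α/2 + (1−α)(1−ξ)/4 | (1−α)(1+ξ)/2 | α/2 + (1−α)(1−ξ)/4 |
| 3 | α/4 | 1/2 − α/2 | 1/2 + α/4 |
| 4 | 0 | 0 | 1 |

ξ = 1/3 is tetrasomic (polysomic) inheritance; ξ = 0 or 1 is fully disomic;
intermediate values cover segmental allopolyploids. Offspring genotype
frequencies **q** are the convolution of the two parental gamete
distributions. The null hypothesis of *no segregation distortion* is that
**q** arises from this model for some admissible (α, ξ₁, ξ₂) — α ≤ 1/6 under
complete equational segregation, with ξ constrained by
(1/3)(α/(1−α))((1−c)/c) ≤ ξ ≤ 1 − (2/3)(α/(1−α))((1−c)/c).

The LRT compares this null against the unrestricted 4-simplex with
data-dependent degrees of freedom (boundary attainment of the null estimate
reduces the null dimension). The Bayesian test reports log BF = log Pr(data |
no distortion) − log Pr(data | Dirichlet(1/2) alternative); **positive log BF
favors no distortion**. Genotype uncertainty enters through per-individual
genotype likelihoods (a mixture likelihood, alternative MLE via EM), and
unknown parental dosages are estimated by maximizing the joint likelihood
over all 25 dosage pairs.

## Worked example

A simplex × nullplex marker with 240 offspring segregating roughly 13:10:1 —
the signature of double reduction at its maximum rate α = 1/6:

```r
library(tetseg)
x <- c(130, 100, 10, 0, 0)          # offspring counts at dosages 0..4
lrt_counts(x, ell1 = 1, ell2 = 0)
#> Likelihood ratio test for segregation distortion
#>   parents: (1,0)
#>   statistic: 0  df: 2  p-value: 1
bayes_test(x, ell1 = 1, ell2 = 0, n_draws = 50000, seed = 1)
#> Bayes test for segregation distortion
#>   parents: (1,0)
#>   log BF (null / alternative): 7.802873  MC se: 0.01206688
#>   positive log BF favors no distortion
chisq_test(x, 1, 0)
#> chisq segregation test: p = < 2.22e-16
polymapr_like_test(x, 1, 0)
#> polymapr_like segregation test: p = 0.0089785
```

The LRT and Bayes test recognise the 13:10:1 ratio as Mendelian-with-double-
reduction (p = 1; log BF ≈ +7.8, evidence *for* the null). The classical
chi-squared test, which expects 1:1 with no dosage-2 offspring, rejects
outright (p ≈ 0), and the polymapR-style test penalises the ten dosage-2
"invalid" genotypes (p ≈ 0.009) — both would wrongly discard the marker.

Batch interfaces: `read_vcf()` / `read_counts_table()` +
`seg_test_markers()` (Bonferroni and BH adjusted p-values, optional
monomorphic-marker screen), or the shell wrapper
`Rscript inst/cli/tetseg.R test --input snps.vcf --mode lrt --out results.tsv`.
Simulation harness: `run_null_study()`, `run_alt_study()`, `roc_summary()`.

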