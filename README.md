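# afset — adaptive Fisher association tests for SNV sets

`afset` tests a set of single nucleotide variants (SNVs) — typically all
variants in a gene plus flanking sequence — for joint association with a
binary or continuous trait. It is aimed at statistical geneticists running
gene-based scans over sequencing or imputed GWAS data, where the fraction
of truly associated variants in any given set is unknown: burden-style
tests win when many variants carry signal ("dense"), minimum-p tests win
when one or two do ("sparse"), and the weighted Adaptive Fisher (wAF)
family implemented here adapts between the two.

## The method

For minor-allele counts `G[i, k]` and trait `Y`, per-variant score
statistics are

    U_k = Σ_i (Y_i − Ȳ) G_ik,   V = σ̂² Σ_i (G_i − Ḡ)(G_i − Ḡ)ᵀ,

(σ̂² = Ȳ(1−Ȳ) binary, sample variance of Y continuous; with covariates,
trait and genotypes are replaced by their null-model residuals). The
standardized scores Ũ_k = U_k/√V_kk give marginal p-values
p_k = 2[1 − Φ(|Ũ_k|)], which are combined adaptively:

    R_k = −log p_k,   X_k = w_k R_k,   S*_k = Σ_{l≤k} X_(l)

with X_(1) ≥ … ≥ X_(K) the descending order and default weights
w_k = √(f_k(1−f_k)) from the in-sample allele frequency f_k. Each partial
sum gets a permutation p-value, and the wAF statistic is the minimum of
those over k — small when *some* prefix of the sorted evidence is
surprising, whatever that prefix's length. Trait residuals are permuted B
times to calibrate everything; the final p-value is the fraction of
permutation replicates at least as extreme, over B + 1. Variants include:
**AF** (flat weights), **wAF** (MAF-based weights), **wAFd** (adds both
one-sided versions and takes the minimum of three — stronger when effects
share a direction), and **Min-P** (smallest marginal p-value, the classic
sparse-signal comparator).

## Worked example

```r
library(afset)
set.seed(1)
sc <- sim_scenario(n = 400, K = 30, c = 0.9, pi = 0.1, delta = 1,
                   trait_type = "binary")
G <- simulate_genotypes(sc)          # AR(1)-correlated counts, log-uniform MAFs
beta <- sample_effects(sc)           # 3 of 30 variants carry an effect
Y <- simulate_trait(G, beta, "binary")
G <- drop_monomorphic(G, quiet = TRUE)
snvset_test(Y, G, methods = "all", B = 1000, seed = 7)
```

```
Adaptive Fisher SNV-set test (marginal model, binary trait)
  n = 400 subjects, K = 30 variants, B = 1000 permutations
 method statistic  p.value  K    B
    wAF 0.0089910 1.90e-02 30 1000
     AF 0.0069930 1.70e-02 30 1000
   wAFd 0.0039960 2.30e-02 30 1000
   MinP 0.0008324 5.99e-03 30 1000
```

All four tests share one permutation set. The `statistic` column is each
test's minimum partial-sum p-value (for Min-P, the smallest marginal
p-value); `p.value` is its permutation calibration — here every method
detects the planted sparse signal at the 5% level, Min-P most strongly,
as expected when only 3 of 30 variants are causal.

Other entry points:

* `snvset_test(Y, G, C = covariates, ...)` — covariate-adjusted testing.
* `adaptive_scan(genes, policy = scan_policy())` — step-up permutation
  budget over many genes: everything starts at B = 100 and only genes
  with p̂ < 5/B escalate to 10× the budget.
* `read_genotypes()` / `read_regions()` / `cli_test()` — VCF or matrix
  input, BED gene regions with ±5 kb flanks, ranked results table;
  `inst/cli/afset.R` is the shell wrapper
  (`Rscript inst/cli/afset.R test --vcf ... --pheno ... --regions ...`).
* `estimate_power()` / `cli_simulate()` — empirical type-I error and
  power with exact binomial confidence intervals.

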