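---
title: "Adaptive Fisher tests for SNV sets: model, calibration and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive Fisher tests for SNV sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afset)
```

## The testing problem

A gene-based association study asks whether *any* of the K single
nucleotide variants (SNVs) in a region is associated with a trait. With
minor-allele counts $G_{ik} \in \{0, 1, 2\}$ for subject $i$ at locus $k$,
the trait is modeled by a generalized linear model

$$h\big(E(Y_i)\big) = \beta_0 + \sum_{k=1}^K \beta_k G_{ik}
  \;\Big(+ \textstyle\sum_j \alpha_j C_{ij}\Big),$$

with a logit link for binary traits and the identity link for continuous
ones, and the null hypothesis is $\beta = 0$. A K-degree-of-freedom score
or likelihood-ratio test loses power rapidly as K grows, and how best to
pool the per-variant evidence depends on the unknown proportion of truly
associated variants: *burden*-style linear collapsing suits dense signals,
minimum-p (Min-P) selection suits sparse ones.

## The adaptive Fisher family

`afset` combines marginal score tests adaptively. The per-variant score
statistics are

$$U_k = \sum_i (Y_i - \bar Y)\, G_{ik}, \qquad
  V = \hat\sigma^2 \sum_i (G_i - \bar G)(G_i - \bar G)^T,$$

with $\hat\sigma^2 = \bar Y(1-\bar Y)$ for binary traits and the unbiased
sample variance of $Y$ for continuous traits. With covariates, $Y_i$ is
replaced by its residual from the covariate-only null model (logistic or
linear), each genotype column by its ordinary-least-squares residual on
the covariates, and $\hat\sigma^2$ by the corresponding null-model
variance estimate ($\frac1n\sum\hat\mu_i(1-\hat\mu_i)$, or the residual
variance). Standardized scores $\tilde U_k = U_k/\sqrt{V_{kk}}$ yield
two-sided marginal p-values $p_k = 2[1 - \Phi(|\tilde U_k|)]$.

The combination statistic transforms, weights, sorts and accumulates:

$$R_k = -\log p_k, \quad X_k = w_k R_k, \quad
  S^*_k = \sum_{l=1}^{k} X_{(l)},$$

where $X_{(1)} \ge \dots \ge X_{(K)}$ is the descending order. Each
partial sum $S^*_k$ gets a permutation p-value $P_{S^*_k}$, and the wAF
statistic is $T_{\mathrm{wAF}} = \min_k P_{S^*_k}$. Minimizing over the
truncation point $k$ is what makes the test adaptive: when few variants
matter, early partial sums dominate; when many contribute, later ones do.
AF is the flat-weight special case. The directed variant wAFd repeats the
construction on the one-sided p-values $p^+_k = 1-\Phi(\tilde U_k)$ and
$p^-_k = \Phi(\tilde U_k)$ and takes
$T_{\mathrm{wAFd}} = \min\{T_{\mathrm{wAF}}, T_{\mathrm{wAF+}},
T_{\mathrm{wAF-}}\}$, which helps when most effects share a direction.
Min-P ($\min_k p_k$, permutation-calibrated) is included as the classical
sparse-scenario comparator.

## Permutation calibration

Residuals $e_i$ ($Y_i - \bar Y$, or $Y_i - \hat\mu_{Y_i}$ under the
covariate null) are permuted B times; each permutation is scored as
$U^{(b)} = \sum_i e^{(b)}_i G_i$ (adjusted genotypes under covariates)
while $V$ stays fixed at its observed value, and the whole
transform–weight–sort–accumulate pipeline is recomputed. Partial-sum
p-values use inclusive counting over the pooled $B+1$ profiles (observed
replicate included), so each is at least $1/(B+1)$; the final p-value is

$$\hat p = \frac{1}{B+1} \sum_{b=1}^{B}
  \mathbb I\{T^{(b)} \le T^{(0)}\}.$$

Because the numerator omits the observed replicate, $\hat p$ can in
principle be exactly 0 when the observed statistic strictly dominates all
B permutations; we keep this form deliberately so that the reported value
is exactly the Monte-Carlo estimator defined by the procedure. All
methods requested in one `snvset_test()` call share the same permutation
set, which makes power comparisons between methods paired and is several
times cheaper than separate runs; when two methods' powers are compared,
the Monte-Carlo error of the difference is therefore the paired standard
error (standard deviation of the per-replicate rejection difference over
√reps), typically several-fold smaller than the unpaired combination —
the classical common-random-numbers variance reduction. For wAFd the three component statistics
are computed from the same permuted scores and the min-of-three is taken
within each replicate, preserving their joint null dependence (the
construction is stated only up to "a similar permutation procedure", so
this sharing is a design choice of the package).

Permutations are sampled uniformly with replacement from the permutation
group. For samples of size $n \le 6$ the engine accepts an explicit
enumeration of all $n!$ orderings through the `perm` argument, which the
test suite uses to verify exact agreement with a brute-force
implementation. Fixing $V$ (and $\hat\mu$, $\hat G$) at their observed
values across permutations keeps the per-permutation work to one matrix
product; recomputing the residual variance per permutation is a possible
alternative for the continuous adjusted model, but it changes only a
scalar common to all K variants per replicate and therefore the ranks
entering the partial-sum p-values only through ties, while costing an
extra pass per replicate.

## Weights

The default weight is $w_k = \sqrt{f_k(1 - f_k)}$ with $f_k$ the
in-sample allele frequency of variant $k$ (unitless, in $(0, 0.5]$ →
$w_k \in (0, 0.5]$). It is the standard deviation of a haplotype draw,
symmetric under allele flips, and grows with frequency: common variants,
whose score statistics are better powered, are up-weighted relative to a
flat weighting but only by a bounded factor. User weight vectors and flat
weights are accepted; with flat weights wAF coincides with AF exactly,
because scaling all $X_k$ by a constant preserves every comparison in the
partial-sum p-values.

Marginal p-values that underflow to zero in double precision are clamped
to the smallest positive normalized double before the $-\log$ transform
(with a warning) so partial sums stay finite; natural logarithms are
used, though any fixed base gives the identical test by monotonicity.
Monomorphic variants, for which $V_{kk} = 0$ makes $\tilde U_k$
undefined, are rejected by the scoring functions and removed (with a
warning) by the import and simulation paths. Sort ties in the descending
order of $X$ need no explicit tie-break: the partial sums depend only on
the multiset of values.

## The adaptive scan budget

Genome scans test thousands of genes but only the smallest p-values need
precision. `adaptive_scan()` implements a step-up budget: every gene is
tested at $B_{\text{init}} = 100$; genes with $\hat p < 5/B$ are retested
at $10\times$ the budget, iterating until no gene beats the threshold or
a cap $B_{\max}$ (default $10^6$) is reached, in which case the gene is
flagged `censored`. The cap is ours — the step-up rule as stated has no
terminal round — and bounds worst-case runtime. Under the null a gene
escalates past the first round with probability about 5%, so the
expected cost stays close to $B_{\text{init}}$ per gene.

## The simulation framework

`sim_scenario()` / `estimate_power()` reproduce the generating model used
in the package's calibration and power studies:

* **Genotypes.** Two independent latent haplotype vectors
  $Z_1, Z_2 \sim N(0, A)$ per subject with AR(1) covariance
  $A_{kk'} = c^{|k-k'|}$, $c = 0.9$ by default, thresholded as
  $G_{ik} = \mathbb I(\Phi(Z_{1k}) \le \text{MAF}_k) + \mathbb
  I(\Phi(Z_{2k}) \le \text{MAF}_k)$. The AR(1) latent correlation mimics
  linkage disequilibrium decaying with distance; the two haplotypes are
  independent (no inter-haplotype LD).
* **MAFs.** Redrawn for every simulated dataset: $\log \text{MAF} \sim
  U(\log 0.001, \log 0.5)$ by default, or $\text{MAF} \sim U(0.001,
  0.01)$ in the rare-variant regime.
* **Effects.** $\text{round}(\pi K)$ positions drawn without
  replacement; nonzero effects uniform on $[-\delta, \delta]$, or on
  $[0, \delta]$ in the same-direction regime.
* **Traits.** Binary: Bernoulli with logit$^{-1}$ of the genetic score,
  zero intercept (null prevalence 0.5; under alternatives the prevalence
  drifts slightly with the effects — prevalence control is not part of
  the design). Continuous: genetic score plus standard normal error.

What this generator does *not* emulate: population structure and
relatedness, Hardy-Weinberg departures, genotyping or imputation error,
and realistic recombination-driven LD blocks. Calibration and power
results under this model therefore demonstrate the statistical behavior
of the combination machinery, not robustness to confounding — covariate
adjustment is provided for that purpose but is only as good as the
covariates.

## Problem sizes and numerical choices

The bundled calibration studies use $n = 500$ subjects, $K = 50$ variants
($K = 100$ for the power-ordering comparisons), $B = 500$ permutations
per test and 500–1000 simulation replicates; with the vectorized
permutation engine (one $(B{+}1) \times n$ by $n \times K$ product plus
row-wise sorting per test) a full calibration run completes in well under
a minute per condition on a single core. Nominal level is $\alpha =
0.05$ throughout; a 99% binomial band around it at 1000 replicates is
$[0.032, 0.068]$. Replicate-level seeds derive deterministically from a
single master seed (a fixed 31-bit linear map), so every table the
package produces is exactly reproducible from `(scenario, seed)`.

Known limitations: p-values are bounded below by the permutation budget
(use the adaptive scan for genome-wide significance claims); no analytic
null approximation is provided for the wAF statistic; multiplicity
across genes is left to the user.

## A worked example

```{r example}
set.seed(1)
sc <- sim_scenario(n = 400, K = 30, c = 0.9, pi = 0.1, delta = 1,
                   trait_type = "binary")
G <- simulate_genotypes(sc)
beta <- sample_effects(sc)
Y <- simulate_trait(G, beta, "binary")
G <- drop_monomorphic(G, quiet = TRUE)   # filter after trait generation
snvset_test(Y, G, methods = "all", B = 1000, seed = 7)
```

The four rows share one permutation set; `wAF` and `wAFd` typically lead
when a moderate fraction of variants carries signal, `MinP` when a single
variant does.
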