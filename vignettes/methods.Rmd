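---
title: "Full-model QTS mapping: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Full-model QTS mapping: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`qtsmap` fits a full genetic model for a quantitative trait observed on
inbred-derived lines across environments:

$$
y_{hk} = \mu + \sum_i (a_i x^A_{ik} + d_i x^D_{ik})
 + \sum_{i<j} (aa_{ij} x^A_i x^A_j + ad_{ij} x^A_i x^D_j + da_{ij} x^D_i x^A_j + dd_{ij} x^D_i x^D_j)
 + E_h + \text{G}\times\text{E}_h + e_{hk},
$$

where $x^A \in \{-1, 0, 1\}$ codes the two homozygotes (non-common-parent
homozygote $QQ \mapsto 1$, common-parent homozygote $qq \mapsto -1$) and
$x^D \in \{0, 1\}$ is the heterozygote indicator. Every fixed genetic term
has a companion random genotype-by-environment term (`ae`, `de`, `aae`,
`ade`, `dae`, `dde`) whose levels are per-environment deviations from the
general effect. The additive model is the restriction to `a` and `ae`.

Assumptions: biallelic markers; Gaussian residuals; environment main effects
fixed; G×E deviations exchangeable across environments within a term. The
population mean $\mu$ is reported alongside plans and partitions but never
folded into genotypic values.

## Coding conventions

* Dominance is coded 1/0 (heterozygote indicator), so $d$ is the
  heterozygote deviation from the homozygote midpoint. The source analysis
  states only the additive codes; the indicator coding is this package's
  documented choice, and all epistasis coefficients are elementwise products
  of the parent single-locus codings.
* A missing call is coded exactly as a heterozygote ($x^A = 0$, $x^D = 1$).
  This is algebraically the indicator-variable device for missing
  genotypes: a dominance-type term gains significance only if missing cells
  deviate from the average of the corresponding homozygotes.
* Epistatic pairs are stored with the lower (chromosome, position) marker
  first; `ad` always means additive at the first marker times dominance at
  the second, and supplying a pair in the opposite order swaps `ad`/`da`
  (and `ade`/`dae`) automatically.

# Hypothesis testing

## Henderson method III reductions

`henderson3_f()` tests a term group by the method of fitting constants. All
model columns — fixed terms plus the random interaction slices — form one
flattened design; the numerator is the reduction in sums of squares gained
by the tested group, the denominator the residual mean square of the fullest
model, whose degrees of freedom absorb every fitted column.

Two structural points deserve emphasis because they are easy to get wrong:

1. **Slice redundancy.** A random term's $E$ per-environment slices sum
   exactly to its parent fixed column. The reduction matrix therefore keeps
   only $E-1$ slices per block — the identical column span without the exact
   collinearity — otherwise every fixed-term test would be degenerate.
2. **Marginality.** Even with $E-1$ slices, a fixed term's own interaction
   slices leave only one environment's worth of unique signal for the parent
   column. Reductions for a group are therefore computed in the submodel
   that excludes the group's own child interaction slices (main effects sit
   below their interactions in the fitting hierarchy), while the denominator
   still comes from the fullest model. Tests of a random block itself
   condition on everything, including its parent.

An earlier implementation tested candidates marginally (base + single term);
it was replaced because an epistasis column such as $x^A_i x^D_j$ can proxy
the main effect $a_i$ on the rows where $x^D_j = 1$, producing spurious
dominance-related significance — visible in the missing-genotype experiment
— unless the other terms are conditioned on.

## Permutation experiment-wise thresholds

`permutation_threshold()` shuffles phenotypes across lines within
environment (one line permutation applied consistently in every environment,
so a line's whole vector moves as a unit on balanced data and the
within-environment multiset is preserved), recomputes every candidate's F,
and records the maximum per permutation. The critical value is the empirical
$(1-\alpha_{EW})$ quantile of that max-F null; the experiment-wise p-value of
an observed F is the smoothed exceedance $(1 + \#\{\max F \ge F\})/(n_{perm}+1)$.
The reference analysis used 2,000 permutations; tests here scale down
(100–500) and say so. Because a finite permutation count bounds
$-\log_{10} P_{EW}$ at $\log_{10}(n_{perm}+1)$, reported values are capped
there and flagged (`at_cap`); published values like 99.7 are unreachable by
any finite permutation scheme and are treated as "beyond cap".

`scan_candidates()` tests each candidate locus (its `a`/`d` columns jointly)
and pair (the four epistasis columns jointly), selects at
$P_{EW} < \alpha_{EW}$, then prunes backwards in the joint model: the
weakest (largest p) non-significant group is dropped and the model refit
until stable, with locus groups protected while a surviving pair references
them. Ties in the drop order fall back to marker order.

# Effect estimation and heritability

`gibbs_fit()` runs a normal–inverse-gamma Gibbs cycle: flat priors on fixed
effects, IG(0.001, 0.001) on every variance component, full random blocks
(all $E$ slices). Identification of the main-vs-deviation split uses
hierarchical centering: after each block draw the block mean is swept into
the parent fixed effect, a likelihood-invariant move that makes fixed
effects environment averages and random levels sum-to-zero deviations —
matching how the simulator defines its G×E truth. All conditionals work
from cached cross-products, so iteration cost is independent of the number
of observations. Defaults follow the reference analysis (20,000 iterations;
burn-in 2,000; thinning 5); the tests use shorter chains and a split-chain
$\widehat R$ on the residual variance as a convergence flag. Divergence
(variance draws beyond $10^{12}\,\mathrm{Var}(y)$) aborts with diagnostics.
Rank-deficient fixed columns — e.g. a `dd` coefficient with no informative
observations in a small sample — are dropped with a warning rather than
poisoning the chain; dropped terms simply carry no estimate.

`partition_heritability()` defines each component as
$100 \cdot \mathrm{Var}(\text{fitted contribution of that kind}) / \mathrm{Var}(y)$
over the observations, with environment-interaction kinds evaluated at the
predicted per-environment levels. `h2_T` is the sum of all components and
`h2_D+` the dominance-related subset (`D`, `AD`, `DA`, `DD`, `DE`, plus
`ADE`/`DAE`/`DDE` when present) — the aggregation identity that the
acceptance suite checks exactly against the published three-trait table.
Because components are variances of separate contribution vectors, their sum
ignores covariances between kinds; totals are interpreted through the same
convention used for the published components.

# Genotype plans

`total_genotypic_value()` evaluates an assignment under the architecture;
per-environment values add the environment's interaction effects with the
same coefficients. `superior_plan()` optimizes exactly: the pair graph is
split into connected components (`epistasis_components()`), each component
is enumerated exhaustively ($2^k$ homozygous-only for the superior line,
$3^k$ for the superior hybrid; enumeration is chunked to bound memory), and
the optimum concatenates across components because the value is additive
across them. A component larger than the cap (default 16 loci) raises an
explicit error instead of switching to a silent heuristic. Ties break
toward the common-parent homozygote `qq`, then by lexicographic enumeration
order over loci sorted by marker position — plans are deterministic.

# The synthetic NAM generator

`sim_config()` defaults state the emulated world: 25 biparental families
crossed to a common parent and selfed 5 generations (residual per-locus
heterozygosity $(1/2)^5 \approx 3.1\%$), 23% missing calls, 4 environments.
Recombination uses the Haldane map function (no interference) on a
configurable cM map — the simplest defensible choice, since the emulated
study is silent on maps. Founders are polymorphic against the common parent
at a configurable fraction of markers (default 0.5; the study reports no
per-family polymorphism rates). Environment main effects are drawn once per
environment from $N(0, \text{env\_sd}^2)$ and held fixed within a dataset.
Missing masking is uniform (`MCAR`) or heterozygote-biased with configurable
odds, emulating panels where apparent heterozygotes were set to missing.

What the generator does **not** emulate: linkage disequilibrium beyond
map-based recombination, selection or segregation distortion during
inbreeding, genotyping error, multi-allelic sites, and trait architectures
with more than digenic epistasis. A green recovery test therefore
establishes correctness of the estimation machinery under the stated model,
not robustness to realistic maize LD or ascertainment.

`architecture_from_shares()` converts target variance shares into effect
sizes using the realized coefficient variances of a reference panel, which
lets validation worlds state their truth directly in heritability units.
Terms whose coefficient variance is below `min_var` (near-monomorphic) are
dropped with a warning rather than assigned absurd effect sizes.

# Validation harnesses and their stated worlds

`missing_genotype_experiment()` reproduces the published Monte-Carlo check
of the missing-as-heterozygote policy: under `truth_homozygous` the masked
cells are truly homozygous (drawn QQ/qq at random) and the truth carries no
dominance effects, so dominance-related terms should stay at the type-I
level; under `truth_heterozygous` the masked cells are truly heterozygous
and dominance power should be retained. Since the published supplement does
not print its scenario parameters, the harness exposes them; the acceptance
world uses per-QTS shares of 2–3% of variance and heterozygote ratios in the
published 3–9% band.

`recovery_experiment()` runs simulate → (optional pre-scan) → test →
estimate → partition per replicate and aggregates bias, RMSE,
credible-interval coverage, selection sensitivity, and heritability
recovery. Two truth conventions are supported. The default,
`truth_from = "analysis"`, generates phenotypes from the masked matrix the
fitter sees, making recovery a clean identity test (the stated design
choice that truth generation uses the identical coding as the fitter);
`truth_from = "true_calls"` generates from the unmasked genotypes, so any
degradation is attributable to the missing-data policy — which is precisely
what `missing_genotype_experiment()` measures in isolation.

The acceptance recovery world places the published width-trait share profile
(additive 13.4%, dominance 10.9%, `da` 16.1%, `dd` 25.4%, small G×E) on a
compact 6-locus/4-pair architecture, 2,000 lines × 4 environments, 5%
missing at the causal map (the identified dominance loci in the source data
show 2.7–9% heterozygote ratios post-imputation, i.e. low local
missingness, while 23% is the genome-wide figure). Realized truth totals
sit below the nominal share sum because environment variance and
between-kind covariances inflate the phenotypic variance denominator;
recovery is always scored against the realized per-replicate truth, not the
nominal shares.

# Numerical choices and degenerate inputs

* Rank decisions use QR with column pivoting; a tested group whose columns
  are fully spanned by the conditioning set yields an explicit degenerate
  signal (`df1 = 0`) rather than a silent zero.
* The permutation critical value at $\alpha_{EW} = 1$ is the minimum of the
  permuted maxima (quantile index floors at 1).
* GMDR cells with no training data take the global training-score sign;
  ties at exactly zero are labelled low-risk. Fold assignment is a
  deterministic seeded round-robin stratified by environment.
* Zero phenotypic variance, empty locus sets, unknown genotype codes,
  duplicate phenotype records and architecture references to unknown
  markers all fail fast with named offenders.
* All stochastic stages are bit-reproducible from their seed.

# Known limitations

* The testing stage absorbs random blocks as fitting constants rather than
  using REML-based mixed-model F approximations; this matches the
  fitting-constants mechanics and keeps thousands of permutations feasible,
  but environment-specific effect tests have only the slice degrees of
  freedom.
* 3D and higher-order epistasis scans are out of scope; the 2D pair universe
  is restricted to the top 1D candidates unless exhaustive search is
  requested.
* Experiment-wise p-values are bounded by the permutation count; an optional
  fitted-tail extrapolation is deliberately not attempted.
* Kinship/population-structure correction beyond the family design and
  environment blocks is not implemented.
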