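---
title: "Whole-genome epistatic QTL mapping with the empirical Bayes Lasso"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-genome epistatic QTL mapping with the empirical Bayes Lasso}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Quantitative traits in crop populations — grain yield and its component
traits in rice being the motivating case — are shaped by many loci and,
prominently, by pairwise (digenic) interactions between loci. An
immortalized F2 (IMF2) population is built by intercrossing pairs of
recombinant inbred lines (RILs): it reconstitutes F2-like genotype
frequencies (two homozygotes and a heterozygote per locus) while every
genotype can be regrown, which makes it a workhorse design for epistatic
QTL mapping.

Given a bin map of m marker bins, genotypes coded A/H/B, and a phenotype
per cross, this package fits one joint sparse regression over *all*
candidate effects:

* additive main effects, coded x_A = +1/0/−1 for A/H/B;
* dominance main effects, coded x_D = 0/+1/0;
* all four interaction families AA, AD, DA, DD over every bin pair, each
  interaction column the element-wise product of the two coded main-effect
  columns.

With interactions the candidate count is k = 2m + 4·m(m−1)/2; at m = 1,619
bins that is 5,242,322 columns for n of a few hundred individuals. The
design matrix is therefore never stored: columns are materialized blockwise
on demand (`column_blocks()`), and memory stays O(n · block size).

## The model

The phenotype model is y = μ + Xβ + ε with ε ~ N(0, σ²ₑI) and a three-level
normal–exponential–gamma (NEG) shrinkage hierarchy on each coefficient:
β_j ~ N(0, σ²_j), σ²_j ~ Exp(λ), λ ~ Gamma(a, b). Empirical-Bayes
estimation maximizes the marginal likelihood over the per-effect variances
σ²_j; most land exactly on the boundary σ²_j = 0, leaving a small active
set with a closed-form Gaussian posterior (β̂, Σ̂). Significance of each
retained effect is then judged by t_j = β̂_j / √Σ̂_jj with df = n − M − 1
(M = active effects, one further df for μ; the reference distribution is a
documented choice — the source method leaves df unstated — and a normal
approximation is available via `use_normal = TRUE`).

For a single coordinate with sparsity factor s = x'C₋ⱼ⁻¹x and quality
factor q = x'C₋ⱼ⁻¹(y − μ1) (C₋ⱼ excludes the coordinate's own
contribution), the penalized objective is

  ℓ(v) = −½ log(1 + v s) + ½ q² v / (1 + v s) − λ v,

maximized in closed form by `coordinate_update()`: v* > 0 exactly when
q² > s + 2λ. All factors are computed through the active-set posterior
(Woodbury identity), never by forming the n×n covariance.

## Fitting discipline

The solver (`eblasso_fit()`) centers the phenotype once (μ = mean(y)) and
then alternates, per sweep:

1. **Scan** — stream every candidate column and compute (s, q) at the
   frozen sweep-start state.
2. **Re-estimate / delete** — apply `coordinate_update()` to each active
   column (exactly, in layout order); v* = 0 deletes.
3. **Admit** — inactive columns that passed the inclusion rule in the scan
   are re-evaluated one by one, in decreasing order of their
   marginal-likelihood gain, against the *current* active set, so that
   once an effect enters, its correlated neighbours ("shards") are turned
   away within the same sweep.
4. **Refresh hyperparameters** — σ²ₑ by its stationary-point update
   RSS / (n − M + Σ Σ̂_jj/σ²_j), and λ by the damped posterior-mode update
   (M + a − 1)/(Σσ²_j + b).

Three numerical/statistical guards around this loop are deliberate design
choices, each motivated by a failure mode we observed and reproduced:

* **λ floor (score threshold).** The raw posterior-mode λ equilibrates far
  below the multiple-testing scale of millions of candidates: with it, a
  large fraction of pure-noise columns satisfies q² > s + 2λ (q²/s is
  ~χ²(1) under the null), the active set balloons, and true signals are
  shattered across many small correlated shards. The fit therefore floors
  λ at the value that keeps the inclusion threshold at `score_threshold`
  on the χ² scale for a column of typical variance. The default 12
  (χ²(1) tail ≈ 5×10⁻⁴) was calibrated once on the synthetic reference
  population so that admission screening and the downstream p ≤ 0.01
  t-filter are mutually consistent under shrinkage; the conservative
  universal threshold 2·log k proved too strict *in combination with* NEG
  shrinkage, because marginally detectable effects are shrunk just below
  the t-test's significance bar.
* **λ damping.** The undamped λ refresh alternates between mass deletion
  (λ high) and mass admission (λ low) — a limit cycle, since the counting
  term M·log λ changes with membership and the joint objective is not a
  single ascent function. A geometric half-step on the log scale converges
  to the same fixed point.
* **Leakage and marginality guards at admission.** A candidate must carry
  signal beyond the *least-squares* fit of the current active set (not
  merely mop up what shrinkage left of an admitted effect), and an
  interaction over bins (i, j) is rejected while a main effect at either
  bin explains a comparable share of the same residual. The second rule is
  the classical marginality principle: with ~1 cM bins, the product of two
  flanking additive columns is numerically almost the dominance column of
  the bin between them, and composite "bridge" columns can out-score each
  of the two real effects they straddle; preferring the parsimonious main
  effect resolves both ambiguities deterministically.

An optional relaxation phase (`relax = TRUE`) re-runs the coordinate
updates over the final active set only, with λ released to its raw
posterior-mode update, debiasing β̂ in the spirit of the relaxed lasso;
it is off by default because it also debiases any surviving shard.

Sweeps are deterministic: identical inputs and controls give bit-identical
active sets. Convergence requires a full sweep with no membership change
and relative variance changes below `tol` (default 1e-4, max 50 sweeps;
a fit that exhausts the budget carries `converged = FALSE`).

## Hyperparameter selection

`cv_path()` reproduces the three-step five-fold cross-validation over
(a, b) minimizing the prediction error PE = Σ(y_i − ŷ_i)²: step 1 examines
the diagonal a = b ∈ {0.001, 0.01, 0.1, 1}; step 2 fixes b and scans 15
values of a from −0.9 to 1; step 3 fixes a and scans b over
{0.01, 0.1, 1, 2, …, 10}. Within steps 2 and 3 the scan proceeds in the
listed (ascending) order and stops early once the current mean PE exceeds
the running minimum by more than one standard error of that minimum
(sd of the five fold PEs / √5 — the standard reading of the one-SE rule;
the source describes the rule without defining the SE). PE is reported as
the across-fold mean; minimization is invariant to that constant. Ties
break toward stronger shrinkage (larger b, then larger a).

## Reporting

`qtl_report()` assembles, per trait: the t-test table (β̂, sd, p, per-effect
variance explained h²_j = var(x_j)β̂²_j / var(y)); the total variance
explained by the significant set, from an ordinary least-squares refit with
intercept (1 − RSS/TSS; rank-deficient columns dropped least-significant
first); QTL groups from single-linkage chaining within 20 cM along each
chromosome (groups never span chromosomes — cross-chromosome distances are
treated as incomparable, `Inf`); and gene associations within 20 cM
(inclusive), highlighted within 2 cM (inclusive). No multiple-testing
correction is applied at the default α = 0.01, replicating the source
analysis; a Bonferroni option exists and is off by default. Note that
Σ h²_j is *not* constrained to match the refit total (the design columns
are collinear); both are reported.

## The synthetic population

`simulate_imf2_dataset()` emulates the study design that motivated the
package: 240 RILs intercrossed into 278 IMF2 crosses on a ~1.0 cM bin map.
RIL chromosomes are two-state Markov chains with switch probability
R = 2r/(1 + 2r) (map expansion of RILs by selfing at the F∞ limit) from the
Haldane fraction r = ½(1 − e^(−2d/100)); residual F9 heterozygosity
(~0.4%) is ignored as negligible. Crosses are sampled as distinct
unordered RIL pairs without a diallel structure, and heterozygotes arise
wherever the parents differ. Phenotypes come from a planted truth; the
default plants six effects — one additive main, one dominance main, and
one interaction of each family — with |β| ∈ [1.2, 1.5] (≥ half a
phenotypic SD) at fixed relative positions chosen so the ten involved loci
are mutually ≥ 25 cM apart or on different chromosomes, and sets σ²ₑ from
the realized genetic variance so total h² ≈ 0.6. The desk-scale default
genome is 5 chromosomes × 40 bins (m = 200): large enough for an 80,000
column candidate space, small enough for a 20-seed regression band in
minutes.

What the generator does *not* emulate: varying bin lengths (the real map's
bins vary around 1 cM), crossover interference (Haldane, not Kosambi),
field-trial environmental structure, and relatedness beyond the shared-RIL
parentage the crossing design implies. A green recovery test therefore
establishes that the solver finds well-separated planted effects of
moderate size in a realistically collinear IMF2 design — not that it would
match any particular real-data effect table.

Recovery scoring (`score_recovery()`) calls a planted effect HIT when a
significant reported effect of the same class (main vs interaction) has
every involved bin within the mapping tolerance (5 cM by default, best of
the two orientations for interactions); power is the hit fraction, FDR the
fraction of significant reports matching no planted effect. This class
rule is deliberately strict: a dominance main reported as a flanking AA
interaction counts as both a miss and a false discovery.

## Known limitations

* Closely linked dominance-involving effects (within ~15 cM) are not
  reliably separable from composite surrogate columns at n ≈ 278; the
  marginality guard prefers the main-effect reading, which is usually but
  not always the generative one.
* The λ floor's default was calibrated on the synthetic reference design;
  markedly different designs (backcross, much denser maps, very small n)
  may warrant re-examining `score_threshold`.
* The per-sweep λ refresh follows the active-set-counting posterior mode;
  the alternative that counts all k coordinates drives λ to levels that
  empty the model and is exposed only through `update_lambda()` for
  experimentation.
* Total-PVE refits on large significant sets can be optimistic (OLS on
  selected columns); the per-effect h² values are shrinkage-based and more
  conservative.
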