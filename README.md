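# epiQTL

Whole-genome epistatic QTL mapping for biparental crop populations with an
empirical-Bayes Lasso.

## What it does, and for whom

Breeders and quantitative geneticists mapping yield-type traits in
immortalized F2 (IMF2) or recombinant-inbred-line (RIL) populations face a
model with far more candidate effects than individuals: additive and
dominance main effects for every marker bin plus all four families of
digenic interactions (additive×additive, additive×dominance,
dominance×additive, dominance×dominance). For m = 1,619 bins that is

    k = 2m + 4·m(m−1)/2 = 5,242,322

candidate effects for a few hundred crosses. `epiQTL` fits them jointly
with a sparse three-level shrinkage prior (normal–exponential–gamma):
each coefficient β_j ~ N(0, σ²_j), σ²_j ~ Exp(λ), λ ~ Gamma(a, b).
Coordinate ascent on the marginal likelihood drives most σ²_j exactly to
zero; the surviving effects get a closed-form Gaussian posterior (β̂, Σ̂),
t-based p-values (t_j = β̂_j/√Σ̂_jj), per-effect variance explained
h²_j = var(x_j)·β̂²_j / σ̂²_P, and a total-PVE OLS refit. Hyperparameters
(a, b) can be chosen by the built-in three-step five-fold cross-validation
with the one-standard-error rule. The design matrix is never stored;
columns stream in blocks, so memory is O(n × block size) regardless of k.

A first-class synthetic IMF2 generator (RIL Markov chains under the
Haldane map function, RIL-pair crossing, planted sparse main + epistatic
effects) stands in for real data, with power/FDR scoring of recovered
effects against the planted truth.

## Worked example

```r
library(epiQTL)

# a synthetic IMF2 population: 240 RILs -> 278 crosses, 200 bins (~1 cM),
# six planted effects (2 main + 4 digenic), total heritability ~0.6
ds  <- simulate_imf2_dataset(sim_config(seed = 1))

fit <- eblasso_fit(ds$G, ds$y, design_spec(ds$G, include_interactions = TRUE),
                   prior_spec(a = 0.5, b = 0.5))
fit
#> Empirical-Bayes Lasso fit: 8 active effect(s) of 80,000 candidates
#>   mu = 1.311, sigma2_e = 1.827, lambda = 2.699, prior (a, b) = (0.5, 0.5)

rep <- qtl_report(fit, ds$y, ds$map)
rep
#> QTL report: 8 significant effect(s) of 8 active (p <= 0.01)
#>   12 QTL bin(s) in 10 group(s); total h2 (refit) = 0.6091

print(rep$significant[, c("family", "i", "j", "beta_hat", "sd", "p_value", "h2")],
      digits = 3)
#>   family   i   j beta_hat    sd  p_value     h2
#> 1      A   5   5    1.206 0.112 1.40e-22 0.1832
#> 2      A 186 186   -0.323 0.113 4.44e-03 0.0136
#> 3      D  45  45    0.420 0.117 4.12e-04 0.0109
#> 4     AA  35 115    0.935 0.176 2.13e-07 0.0427
#> 5     AA  45  46   -0.901 0.125 6.70e-12 0.0497
#> 6     AD  74 165    1.221 0.158 2.32e-13 0.0940
#> 7     DA  91 196   -0.597 0.157 1.83e-04 0.0246
#> 8     DD 126 153    1.046 0.172 4.18e-09 0.0540

score_recovery(rep$significant, ds$truth, ds$map, tol_cM = 5)[c("power", "fdr")]
#> $power
#> [1] 0.8333333
#> $fdr
#> [1] 0.375
```

Reading the table against the planted truth of this seed: five of the six
planted effects are recovered at their bins or 1–6 bins away (the additive
main at bin 5, the dominance main at 45, AA 35x115, AD 74x165 at 75x165,
DD 126x153 for 125x155); `AA 45x46` is a flanking-product surrogate of the
dominance main — the strict class-matching of `score_recovery()` counts it
as a false discovery — and the DA report at 91x196 misses its planted bin
(85) by 6 cM, one past the 5 cM tolerance. Averaged over 20 seeds the
pipeline scores mean power 0.83 at mean FDR 0.17 (the regression band in
`test-acceptance.R` asserts >= 0.75 and <= 0.25). The solver is
deterministic: identical inputs and controls give identical fits.

The same stages run from the command line:

```sh
Rscript inst/cli/epiqtl.R run --out_dir=run1 --seed=1
Rscript inst/cli/epiqtl.R recover --effects=run1/effects.tsv \
    --truth=run1/truth.json --map=run1/map.tsv --out=run1/recovery.json
```

`run` writes `map.tsv`, `genotypes.tsv`, `phenotypes.tsv`, `truth.json`,
`effects.tsv` (the per-effect table with a `#`-metadata block), `groups.tsv`
(QTLs grouped within 20 cM), `edges.tsv` (an interaction edge list for
network drawing), `recovery.json`, and a `manifest.json` recording the
configuration hash and every artifact. Supplying `--map/--genotypes/
--phenotypes` (TSV; see `read_bin_map`, `read_genotypes`,
`read_phenotypes`) analyses real data instead of simulating; a gene
catalog (`genes.tsv`) adds proximity annotation within 20 cM and a ≤2 cM
highlight, mirroring the published table layout.

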