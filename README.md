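# pedqtl

Phenology trait derivation and pedigree-based Bayesian QTL mapping for
multiparental fruit-tree populations.

Budbreak and flowering dates in temperate fruit trees are set by two
successive temperature signals: accumulation of *chilling* during winter
dormancy (the chilling requirement, CR, in chilling hours) and
accumulation of *heat* afterwards (the heat requirement, HR, in growing
degree hours, GDH). Breeders who want to adapt phenology to warming
climates need to know which genomic regions control each signal and which
parents carry the favorable alleles. pedqtl implements a complete
analysis chain for that question in interconnected full-sib families:

1. **Phenology** — cosine GDH response (zero at TB = 4 °C, peak
   F·(TU−TB) = 21 at TU = 25 °C, zero again at TC = 36 °C), chilling
   hours in (0, 7.2] °C, sequential CR-then-HR stage prediction, and the
   three analysis traits `BB_CD` (budbreak day of year), `BB_GDH`
   (GDH from a reference dormancy-release date to budbreak) and
   `Delta_GDH` (GDH from budbreak to flowering).
2. **Mixed model** — REML fit of
   `y = X1·site + X2·year + Z1·genotype + Z2·genotype:year + e`
   with year-specific interaction variances and an unstructured
   within-tree residual covariance across years; genotypic and
   genotype-by-year BLUPs; broad-sense heritability
   `h² = σG² / (σG² + σG×Y²/k + σε²/n)`.
3. **Haploblocks** — 1 cM map segmentation, trio phasing with
   minimum-recombination reconstruction of parental phases, parental
   origins per meiosis, and double-recombination QC at marker and
   haploblock resolution.
4. **QTL mapping** — a bi-allelic additive QTL model
   `y = 1μ + Wa + e` with covariates `[QQ, Qq, qq] = [1, 0, −1]`,
   founder alleles plus segregation indicators for identity-by-descent,
   reversible-jump MCMC over the QTL count (Poisson prior, mean 5),
   `2×lnBF` evidence (thresholds 2/5/10 = positive/strong/decisive),
   posterior QTL intensities, per-QTL effect/frequency/variance
   summaries (`var = 2·f·(1−f)·a²`), per-individual QTL genotype
   probabilities, and favorable-allele tracing through the pedigree.
5. **Synthetic data** — a first-class generator for the study-style
   design (five interconnected families on two sites, ~430 offspring,
   17 linkage groups at 1 cM haploblock spacing, seasonal+diurnal
   temperature series) so every stage is testable end to end.

## Worked example

Simulate an interconnected pedigree, plant one QTL, and map it from
phased haploblocks:

```r
library(pedqtl)

cfg  <- study_pedigree_config(c(XB = 30, SG = 60, HIVW = 80, N = 20, P = 20))
ped  <- simulate_pedigree(cfg)
map  <- make_map(n_lg = 5, length_cM = 60, spacing = 1)
geno <- drop_gametes(ped, map, founder_freq = 0.5, seed = 7)

truth <- qtl_truth(lg = 3, pos = 25, effect = 1.2, f = 0.5)
obs   <- simulate_phenotypes(ped, geno, truth,
                             phenotype_design(sigma_G = 1), seed = 7)
y     <- attr(obs, "genotype_values")

phased <- phase_pedigree(unphase(geno), ped, map)
engine <- build_ibd_engine(ped, phased)
chain  <- mcmc_run(y, engine, qtl_priors(lambda = 3),
                   mcmc_settings(n_iter = 20000, n_store = 1000, seed = 7))

bayes_factor(chain, "lg", lg = 3)
#> $two_ln_bf
#> [1] 12.81695
#> $label
#> [1] "decisive"

posterior_intensity(chain)$intervals
#>   lg start end max_local_2lnbf
#> 1  3    20  32        5.794426
#> 2  3    34  42        5.307476
#> 3  5    20  22        2.077496
#> 4  5    28  30        2.808055

qtl_region_summary(chain, 3, c(20, 32))
#> $add          1.323648
#> $fq           0.456651
#> $var          0.8694375
#> $pct_var      54.2008
```

The linkage group carrying the planted QTL reaches decisive evidence
(`2×lnBF` = 12.8 at the LG scale, i.e. far beyond the "strong" threshold
of 5); the first reported interval (20–32 cM) covers the true position
(25 cM); the posterior additive effect (1.32) and favorable-allele
frequency (0.46) recover the planted values (1.2 and 0.5); and the region
explains 54% of the phenotype variance. Secondary intervals with `2×lnBF`
just above the "positive" threshold of 2 are the expected noise floor at
this chain length.

The full pipeline (temperatures → traits → BLUPs → QTL scans → report
tables) runs through `run_pipeline(pipeline_config(...))`, and
`inst/cli/pedqtl.R` wraps it for shell use.

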