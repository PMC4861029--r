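---
title: "Models and methods behind pedqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pedqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

pedqtl implements the computational chain used to dissect budbreak and
flowering phenology in interconnected full-sib fruit-tree families: from
hourly temperatures to chill/heat-based traits, from tree-level
observations to genotypic BLUPs, and from BLUPs to pedigree-based Bayesian
QTL maps with favorable-allele tracing. This vignette explains each model,
its assumptions, the tunable parameters, and the design decisions taken
where more than one reasonable implementation exists.

## 1. Phenology: chill, heat and the three traits

Bud dormancy is treated sequentially. During endodormancy the bud counts
*chilling hours*: an hour contributes when its temperature lies in
`(lower, upper]` degrees C (defaults 0 and 7.2, accumulation starting
1 September). Dormancy is released at the first hour at which the
cumulative count reaches the genotype's chilling requirement CR. Only
then does heat perception start: *growing degree hours* (GDH) accumulate
according to a cosine response that is zero at or below the base
temperature `TB` (4 °C), rises to a maximum of `F*(TU - TB)` (= 21 with
the defaults `TU` = 25 °C, `F` = 1) and falls back to zero at the critical
temperature `TC` (36 °C). A stage (budbreak, flowering) is predicted at
the first hour whose cumulative GDH from release reaches the heat
requirement HR. The two phases never overlap; overlap models are out of
scope.

Printed versions of this GDH formula in the horticultural literature
often carry transcription artifacts (a negative `(TB - TU)/2` factor and
a `(TC - TB)` denominator in the supra-optimal branch) that would make
the response negative and discontinuous; the standard continuous form is
therefore implemented, and a literal transcription of the artifact-bearing
form is kept behind `gdh_params(form = "as_printed")` for audit.
Continuity at `TU` (value 21) and a zero at `TC` are taken as defining.

Three traits are derived per tree, site and year:

* `BB_CD` — budbreak date in calendar days from 1 January (Jan 1 = 1);
  carries variation in *both* CR and HR fulfillment.
* `BB_GDH` — GDH accumulated between the site-year *reference* dormancy
  release date (a high-chill reference cultivar) and the observed
  budbreak; isolates heat-requirement variation, up to the "leak" caused
  by genotypes releasing later than the reference.
* `Delta_GDH` — GDH between budbreak and the beginning of flowering.
  The flowering date itself is dropped downstream, being nearly collinear
  with `BB_CD`.

Budbreak observed before the reference release is reported as
`BB_GDH = 0` with a flag rather than as a negative heat sum. All windows
are half-open `[start, end)` at hourly resolution; daily minima/maxima are
accepted through a half-sine interpolation (minimum at 05:00, maximum at
14:00, linear night decay) that preserves the daily extremes exactly.

## 2. Mixed model, BLUPs and heritability

Each trait is modeled as

y = X1 b_site + X2 b_year + Z1 u_G + Z2 u_GxY + e

with genotype effects `u_G ~ N(0, sG2)`, genotype-by-year effects with a
variance per year, and within-tree residuals correlated across years
through an unstructured covariance `R` (year-heterogeneous variances on
both terms, reflecting the strong year effects typical of phenology).
Because all random terms are nested in genotype, the restricted
likelihood factorizes into independent per-genotype blocks; the fitter
exploits this by grouping genotypes with identical designs and computing
one Cholesky factor per pattern. Variance components are estimated by
direct numerical optimization (Nelder-Mead polish + BFGS) of the
restricted log-likelihood over a log/Cholesky parameterization; BLUPs
solve the mixed-model equations at the converged components.

One identifiability caveat matters in practice: with a single tree per
genotype, the interaction variance and the residual variances appear only
as sums, and with an unstructured `R` the genotypic variance is absorbed
into the residual covariances. Replicated trees (one family in the emulated
design is planted twice) or the `diagonal`/`simple` residual options restore
identification; the package's recovery tests use identifiable designs.
The reported broad-sense heritability is
`h2 = sG2 / (sG2 + sGY2/k + se2/n)` with `sGY2` and `se2` the across-year
means (stated in the fit metadata), `k` the number of years and `n` the
number of observations. BLUPs are mapped raw; a standardization flag
exists but defaults off.

Analyses run on three data sets — both sites pooled, and the two
complementary per-site subsets — yielding, per subset, a genotypic BLUP
and one interaction BLUP per year for each of the three traits (the
twelve mapped variables of the full scheme).

## 3. Haploblocks, phasing and QC

The genetic map is divided into successive half-open 1 cM segments
(0-based per linkage group); the SNPs of each segment form one haploblock
whose phased alleles are recoded as a single multi-allelic locus, with
allele codes assigned in first-seen order among founders (haplotype
allele labels are opaque identifiers, so any deterministic coding is
equivalent).

Phasing is trio-deterministic first: a child's maternal/paternal alleles
are resolved wherever transmission is unambiguous (homozygous child, or
heterozygous child with an informative parent pair); unresolved sites stay
unknown, never guessed. Parental origins — which of the parent's two
homologs was transmitted — require the parent's own phase: taken from its
trio where available, otherwise reconstructed by minimum-recombination
linkage across its gametes (adjacent-locus co-transmission majority,
chained; the homolog labeling of such reconstructions is arbitrary per
parent and linkage group and flagged as unanchored). Mendelian violations
are reported per locus, the offending trio-locus masked, and loci failing
in more than a configurable number of families (default 2) are masked
genome-wide.

Double-recombination QC counts X-Y-X origin patterns across three
consecutive informative positions spanning at most 5 cM (reported double-recombination
rates in this literature come without a stated window; 5 cM is this
package's declared choice, configurable). Aggregating to haploblock origins by
majority vote damps isolated genotyping errors, which is exactly why the
block-level rate is expected not to exceed the marker-level rate.

## 4. Pedigree-based Bayesian QTL mapping

BLUPs are regressed on latent bi-allelic QTLs: `y = 1 mu + W a + e`, with
QTL genotype codes `[QQ, Qq, qq] = [1, 0, -1]` (additive effects only).
Each QTL carries a map position (uniform prior over the map), an additive
effect `a ~ N(0, s2a)` with a per-QTL explained variance `s2a`, a founder
allele frequency `f ~ Beta(1, 1)`, alleles on every *base homolog* (the
two homologs of each founder, and the missing side of any half-known
parentage), and segregation indicators on every tracked meiosis. The
genotype of every pedigree member is implied deterministically by the
founder alleles and the indicators — this is the identity-by-descent
construction that lets multiparental families share information and that
controls the false positives relatedness would otherwise cause.
Ungenotyped members simply lack informative origins; their latent
variables are integrated by sampling. `s2a` and the residual variance
`se2` have inverse-gamma priors whose scales default, at run time, to
0.25 and 0.5 times the variance of the mapped phenotype, so that the
prior lives on the trait's own scale; the shapes default to 1. The QTL
count has a Poisson prior (mean 5 by default).

The sampler is a reversible-jump MCMC written in C++: per sweep,
single-site Gibbs updates of every segregation indicator (prior given by
the flanking informative origins through Haldane recombination fractions,
likelihood through the cascade of descendants that inherit the toggled
homolog) and every base allele; conjugate updates of `f` (Beta), `a`
(normal), `s2a` and `se2` (inverse-gamma) and `mu`; a random-walk
Metropolis move on each position within its linkage group (step 10 cM by
default); and one birth/death jump whose new component is drawn entirely
from its prior, so the acceptance ratio reduces to the likelihood ratio
times the Poisson count ratio. Any sampler satisfying detailed balance is
acceptable here; the contract is prior recovery — with the likelihood
switched off the chain must reproduce the Poisson count, uniform
positions and uniform allele frequencies, and the test suite checks
exactly that, alongside closed-form conjugate oracles for the Gibbs
steps. Chains are reproducible from a single integer seed.

Default chain settings mirror the reference workflow: up to 500 000
sweeps, 1000 stored samples, 20% burn-in, and a minimum effective sample
size of 100 (initial-positive-sequence estimator) below which the result
is returned but flagged non-converged. Tests and examples use shorter
chains (10-100k sweeps) at reduced pedigree sizes; the acceptance suite
states its sizes explicitly (e.g. 400 offspring, 17 linkage groups, 50k
sweeps per seed).

Inference follows the Bayes-factor convention: `2 ln BF` between models
differing by one QTL, computed from posterior and prior odds of the QTL
count within a scope; per-linkage-group and per-bin prior means are
allocated proportionally to genetic length (a declared choice of this
package; no standard allocation rule exists). Thresholds 2/5/10 label positive/strong/decisive evidence.
Positions are summarized by the posterior QTL intensity (expected QTLs
per 2 cM bin, matching the even-cM interval endpoints conventional in
QTL report tables); contiguous bins with local `2 ln BF > 2` form reported
intervals. For region summaries, the components a stored sample places in
the region are first aggregated into one effective QTL (net per-individual
effect, least-squares effective effect, |a|-weighted frequency): the
posterior occasionally splits one true QTL across co-located components,
and the aggregate — not any single component — is the quantity the data
identify. The explained variance `2 f (1-f) a^2` is reported both from
the posterior means and as the posterior mean of the per-sample value,
since the two differ slightly and report tables in this literature are
consistent with the former. QTL genotype probabilities per individual are the frequencies
of the implied genotypes among region-visiting samples, oriented so Q
increases the trait; calls below a 0.80 top-probability threshold are
reported as ignorance (0.80 is this package's declared default). Favorable-allele tracing walks carriers
up the pedigree, keeping every ancestor chain consistent with
transmission and flagging carriers whose parents are both called
non-carriers.

## 5. The synthetic-data generator

Real orchard phenotypes and dense genotypes are rarely shareable, so the
package ships a generator that emulates the target study design: an
interconnected
five-family pedigree (two families on a warm site, three on a cool site,
shared parents and grandparents, one ungenotyped founder; family sizes
58/115/171/42/45 by default, about 430 offspring), a 17-linkage-group map
at 1 cM haploblock spacing, founder haplotypes drawn locus-wise at stated
allele frequencies (linkage equilibrium among founders), gamete dropping
with Poisson (no-interference) crossovers so that recombination follows
Haldane's map function, and two-site/three-year temperature series built
from seasonal and diurnal cosines plus stationary AR(1) noise. Genotype
values are QTL codes times effects plus an independent polygenic normal
deviate; observations add site and year effects, year-specific
interaction draws and within-tree residuals from a full covariance
matrix. Phenology phenotypes plant chilling and heat requirements per
genotype (free configuration; defaults of 900 chill hours and 4000/5500
GDH with modest polygenic spread are this package's realistic-scale
choice, since no per-genotype CR/HR distributions are established for
this design) and
run the same sequential predictor the analysis uses, so round-trip
recovery is exact at date resolution when observation jitter is zero.
Because heat accumulates hourly but observations carry dates, the
generator reports its truth re-expressed at date resolution; that is the
quantity trait derivation can and does recover exactly.

Two generator behaviors are deliberate: all randomness descends from one
master seed through labeled substreams, and founder gametes are re-drawn
(up to 50 attempts) until every planted QTL segregates in a minimum
number of families (default 3), because a QTL monomorphic in all families
is undetectable by construction and would make a detection test vacuous
rather than informative. What the generator does *not* emulate: epistasis,
dominance, imprinting, marker ascertainment, genotype-by-site interaction
(inestimable when each family grows on a single site, as here), and
genotyping error beyond simple masking/flips added by tests. Passing
tests on this generator therefore validate the machinery and its
statistical calibration, not the biology of any particular orchard.

## 6. Numerical choices and limitations

* Windows are half-open and hourly; stage prediction is inclusive of the
  fulfilling hour, so a vanishing heat requirement collapses the stage
  onto the release hour.
* Indicator probabilities are clamped to `[1e-12, 1 - 1e-12]` to keep
  log-odds finite at fully informative markers.
* REML convergence is declared on optimizer convergence with relative
  tolerance 1e-10; a truth-initialized start can never beat the free
  optimum by more than numerical tolerance, and a test asserts this.
* The sequential phenology model strongly buffers chilling-requirement
  differences when springs are warm (a multi-day release shift compresses
  into a much smaller budbreak shift), and budbreak dates quantize on
  weather events; planted physiological effects therefore translate into
  much smaller trait-level variance shares than naive unit conversion
  suggests. This is faithful to the biology and is why the integration
  tests plant physiologically large effects.
* Bayes factors computed from 1000 stored samples saturate near
  `2 ln[(1 - 1/1000) / (1/1000)]` minus the prior log-odds; empty
  posterior cells are reported as bounds at that resolution, never as
  infinities.
* The minimum-recombination founder phasing is a deterministic rule of
  this package (pedigree phasing tools differ in unpublished tie-breaking
  details); its homolog labels are arbitrary per founder and linkage group, which downstream
  consumers (the IBD engine, the QC) treat consistently.
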