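Package: pedqtl
Title: Phenology Trait Derivation and Pedigree-Based Bayesian QTL Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the genetics of budbreak and flowering
    phenology in multiparental fruit-tree pedigrees. Derives chill- and
    heat-based phenology traits (budbreak day-of-year, growing degree
    hours to budbreak, and growing degree hours from budbreak to
    flowering) from temperature series; fits mixed models with
    year-heterogeneous variances to extract genotypic and genotype-by-year
    BLUPs and broad-sense heritability; builds 1 cM haploblocks with
    trio-based phasing and double-recombination quality control; and maps
    QTLs on the BLUPs with a pedigree-based Bayesian model (bi-allelic
    additive QTLs, founder alleles plus segregation indicators for
    identity by descent, reversible-jump MCMC over QTL number,
    Bayes-factor and posterior-intensity inference, QTL genotype
    probabilities and favorable-allele tracing). A synthetic-data module
    generates interconnected full-sib pedigrees, genotypes, phenotypes and
    temperature series with the statistical structure the analysis
    assumes, so the full chain is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    lme4,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
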