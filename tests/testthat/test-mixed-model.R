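make_obs <- function(n_gen = 200, sigma_G = 2, sigma_GY = 1, r_diag = 1,
                     seed = 1, replicates = 1) {
  ped <- simulate_pedigree(cross_config(n = n_gen))
  map <- make_map(1, 10, 5)
  geno <- drop_gametes(ped, map, 0.5, seed = seed)
  des <- phenotype_design(sites = "S", site_effects = c(S = 0),
                          sigma_G = sigma_G,
                          sigma_GY = setNames(rep(sigma_GY, 3),
                                              as.character(2012:2014)),
                          R = diag(r_diag, 3), replicates = replicates,
                          family_sites = c(F = "S"))
  simulate_phenotypes(ped, geno, qtl_truth(integer(), numeric(),
                                           numeric(), numeric()),
                      des, seed = seed)
}

test_that("heritability follows its variance-ratio definition", {
  expect_equal(heritability(1, 0, 0, 3, 100), 1)
  expect_equal(heritability(2, 3, 4, 3, 100), 2 / (2 + 1 + 0.04))
  expect_equal(heritability(0, 3, 4, 3, 100), 0)
  ## monotonicity
  expect_gt(heritability(3, 1, 1, 3, 50), heritability(2, 1, 1, 3, 50))
  expect_lt(heritability(2, 2, 1, 3, 50), heritability(2, 1, 1, 3, 50))
  expect_lt(heritability(2, 1, 2, 3, 50), heritability(2, 1, 1, 3, 50))
  expect_error(heritability(0, 0, 0, 3, 100),
               class = "pedqtl_degenerate")
})

test_that("REML recovers the genotypic variance", {
  est <- vapply(1:4, function(s) {
    obs <- make_obs(n_gen = 300, seed = s)
    fit_mixed(obs, spec = mixed_model_spec(gxy = "homogeneous",
                                           residual = "simple"))$varcomp$sG2
  }, numeric(1))
  expect_lt(abs(median(est) / 4 - 1), 0.15)
})

test_that("with no noise, BLUPs equal centred true genotype effects", {
  obs <- make_obs(n_gen = 80, sigma_G = 2, sigma_GY = 1e-4,
                  r_diag = 1e-6, seed = 3)
  gv <- attr(obs, "genotype_values")
  fit <- fit_mixed(obs, spec = mixed_model_spec(gxy = "homogeneous",
                                                residual = "simple"))
  b <- setNames(fit$blups$G_blup, fit$blups$genotype)
  expect_equal(unname(b[names(gv)]), unname(gv - mean(gv)),
               tolerance = 1e-2)
})

test_that("degenerate designs raise explicit confounding errors", {
  obs <- make_obs(n_gen = 30, seed = 2, replicates = 2)
  one <- obs[obs$year == 2012, ]
  expect_error(fit_mixed(one), class = "pedqtl_bad_design")  # single year
  two <- obs[!duplicated(obs$genotype), ]  # one observation per genotype
  expect_error(fit_mixed(two), class = "pedqtl_confounded")
})

test_that("REML and BLUPs agree with lme4 on the homogeneous model", {
  skip_if_not_installed("lme4")
  obs <- make_obs(n_gen = 120, seed = 6, replicates = 2)
  fit <- fit_mixed(obs, spec = mixed_model_spec(gxy = "homogeneous",
                                                residual = "simple"))
  lf <- lme4::lmer(value ~ year_f + (1 | genotype) + (1 | genotype:year_f),
                   data = transform(obs, year_f = factor(year)),
                   REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(fit$varcomp$sG2,
               vc$vcov[vc$grp == "genotype"], tolerance = 1e-3)
  expect_equal(unname(fit$varcomp$sGY2[1]),
               vc$vcov[vc$grp == "genotype:year_f"], tolerance = 1e-3)
  expect_equal(fit$meta$se2_mean, vc$vcov[vc$grp == "Residual"],
               tolerance = 1e-3)
  rr <- lme4::ranef(lf)$genotype
  expect_equal(setNames(fit$blups$G_blup, fit$blups$genotype)[rownames(rr)],
               setNames(rr[, 1], rownames(rr)), tolerance = 1e-3)
})

test_that("BLUPs shrink relative to adjusted genotype means", {
  obs <- make_obs(n_gen = 100, seed = 7)
  fit <- fit_mixed(obs, spec = mixed_model_spec(gxy = "homogeneous",
                                                residual = "simple"))
  adj <- obs$value - fit$beta[1] -
    ifelse(obs$year == 2013, fit$beta["year2013"],
           ifelse(obs$year == 2014, fit$beta["year2014"], 0))
  gm <- tapply(adj, obs$genotype, mean)
  gm <- gm - mean(gm)
  b <- setNames(fit$blups$G_blup, fit$blups$genotype)
  expect_true(all(abs(b[names(gm)]) <= abs(gm) + 1e-6))
  ## BLUPs are centred
  expect_lt(abs(mean(b)), 0.05)
})

test_that("restricted likelihood at the optimum dominates a truth start", {
  obs <- make_obs(n_gen = 100, seed = 8)
  spec <- mixed_model_spec(gxy = "by_year", residual = "diagonal")
  free <- fit_mixed(obs, spec = spec)
  at_truth <- fit_mixed(obs, spec = spec,
                        start = list(sG2 = 4, sGY2 = rep(1, 3),
                                     R = diag(3)), max_iter = 1)
  expect_gte(free$logLik, at_truth$logLik - 1e-6)
})

test_that("run_trait_analyses respects the site subsets", {
  ped <- simulate_pedigree(small_study_config())
  map <- make_map(2, 20, 2)
  geno <- drop_gametes(ped, map, 0.5, seed = 4)
  des <- phenotype_design(sigma_G = 1.5)
  obs <- simulate_phenotypes(ped, geno, qtl_truth(1, 10, 1, 0.5), des,
                             seed = 4)
  traits <- data.frame(obs[, c("tree", "genotype", "site", "year")],
                       BB_CD = obs$value, BB_GDH = 100 * obs$value)
  res <- run_trait_analyses(traits,
                            subsets = list(multisite = NULL, Mtp = "Mtp",
                                           Ang = "Ang"),
                            trait_names = c("BB_CD", "BB_GDH"),
                            spec = mixed_model_spec(gxy = "homogeneous",
                                                    residual = "simple"))
  ang_gen <- unique(traits$genotype[traits$site == "Ang"])
  expect_setequal(res$Ang$BB_CD$blups$genotype, ang_gen)
  expect_equal(sort(c(res$Mtp$BB_CD$blups$genotype,
                      res$Ang$BB_CD$blups$genotype)),
               sort(res$multisite$BB_CD$blups$genotype))
  ## traits sharing genetic control give correlated genotypic BLUPs
  expect_gt(cor(res$multisite$BB_CD$blups$G_blup,
                res$multisite$BB_GDH$blups$G_blup), 0.9)
  expect_error(run_trait_analyses(traits,
                                  subsets = list(empty = "Nowhere"),
                                  trait_names = "BB_CD"),
               class = "pedqtl_empty_subset")
})
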