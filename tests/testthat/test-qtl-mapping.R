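## a compact interconnected fixture with known founder QTL genotypes:
## A is QQ, B is qq, C is heterozygous; families A x C, B x C and A x B
## (the third cross ties the founders together, as the shared parents do in
## the study-style pedigree, which is what identifies founder genotypes)
qtl_fixture <- function(n_fam = c(70, 70, 40), effect = 1.5, seed = 21) {
  cfg <- list(founders = c("A", "B", "C"),
              families = data.frame(
                label = c("F1", "F2", "F3"), parent1 = c("A", "B", "A"),
                parent2 = c("C", "C", "B"), n_offspring = n_fam,
                stringsAsFactors = FALSE))
  ped <- simulate_pedigree(cfg)
  map <- make_map(3, 40, 1)
  L <- nrow(map)
  qtl_j <- which(map$lg == 2 & map$pos == 20)
  set.seed(seed)
  fh <- list(
    A = list(m = rbinom(L, 1, 0.5), p = rbinom(L, 1, 0.5)),
    B = list(m = rbinom(L, 1, 0.5), p = rbinom(L, 1, 0.5)),
    C = list(m = rbinom(L, 1, 0.5), p = rbinom(L, 1, 0.5)))
  fh$A$m[qtl_j] <- fh$A$p[qtl_j] <- 1L
  fh$B$m[qtl_j] <- fh$B$p[qtl_j] <- 0L
  fh$C$m[qtl_j] <- 1L; fh$C$p[qtl_j] <- 0L
  geno <- drop_gametes(ped, map, founder_haplotypes = fh, seed = seed)
  off <- ped$id[!is.na(ped$family)]
  w <- geno$hap_m[, qtl_j] + geno$hap_p[, qtl_j] - 1L
  set.seed(seed + 1)
  y <- setNames(effect * w[off] + rnorm(length(off)), off)
  list(ped = ped, map = map, geno = geno, off = off, w = w, y = y,
       engine = build_ibd_engine(ped, geno))
}

test_that("segregation probabilities follow two-locus transmission algebra", {
  ped <- simulate_pedigree(cross_config(n = 2))
  map <- genetic_map(c("L1", "L2"), c(1, 1), c(0, 20))
  geno <- drop_gametes(ped, map, 0.5, seed = 1)
  eng <- build_ibd_engine(ped, geno)
  o <- geno$origin_m["F_001", ]
  ## at an informative marker the indicator is pinned to the observed origin
  p_at <- ibd_origin_prob(eng, "F_001", "m", 1, 0)
  expect_equal(p_at, as.numeric(o[1] == 2), tolerance = 1e-9)
  ## midway between agreeing flanks: (1-r)^2 / ((1-r)^2 + r^2)
  r <- haldane(10)
  p_mid <- ibd_origin_prob(eng, "F_001", "m", 1, 10)
  if (o[1] == o[2]) {
    expected <- (1 - r)^2 / ((1 - r)^2 + r^2)
    expect_equal(p_mid, if (o[1] == 2) expected else 1 - expected)
  } else {
    expect_equal(p_mid, 0.5)  # disagreeing flanks at equal distance
  }
  expect_error(ibd_origin_prob(eng, "F_001", "m", 1, 25),
               class = "pedqtl_off_map")
  ## a founder has no tracked meiosis
  expect_error(ibd_origin_prob(eng, "A", "m", 1, 5),
               class = "pedqtl_no_meiosis")
})

test_that("uninformative meioses fall back to the 1/2 prior", {
  ped <- simulate_pedigree(cross_config(n = 2))
  map <- genetic_map(c("L1", "L2"), c(1, 1), c(0, 20))
  geno <- drop_gametes(ped, map, 0.5, seed = 2)
  geno$origin_m[] <- NA_integer_  # wipe informativeness on every meiosis
  geno$origin_p[] <- NA_integer_
  eng <- build_ibd_engine(ped, geno)
  expect_equal(ibd_origin_prob(eng, "F_001", "m", 1, 10), 0.5)
})

test_that("conjugate updates match their closed-form posteriors", {
  fx <- qtl_fixture(n_fam = c(30, 30, 20))
  W <- matrix(as.numeric(fx$w[fx$off]), ncol = 1)
  y <- unname(fx$y)
  se2 <- 1.3; s2a <- 4
  ## effect draws with the residual variance held fixed: exact normal
  prec <- sum(W^2) / se2 + 1 / s2a
  m_star <- sum(W * y) / se2 / prec
  set.seed(5)
  d1 <- pedqtl:::gibbs_fixed_cpp(y, W, s2a, 0, se2, 1, 1, 10000,
                                 update_a = TRUE, update_se2 = FALSE,
                                 a_init = 0)
  mc_se <- sqrt(1 / prec) / sqrt(10000)
  expect_lt(abs(mean(d1$a) - m_star), 2 * mc_se)
  expect_lt(abs(var(d1$a[, 1]) - 1 / prec),
            2 * (1 / prec) * sqrt(2 / 9999))
  ## residual-variance draws with the effect held fixed: exact inverse-gamma
  a_fix <- 1.4; e_shape <- 3; e_scale <- 2
  r <- y - a_fix * W[, 1]
  sh <- e_shape + length(y) / 2
  ra <- e_scale + sum(r^2) / 2
  set.seed(6)
  d2 <- pedqtl:::gibbs_fixed_cpp(y, W, s2a, 0, 1, e_shape, e_scale, 10000,
                                 update_a = FALSE, update_se2 = TRUE,
                                 a_init = a_fix)
  ig_mean <- ra / (sh - 1)
  ig_sd <- sqrt(ra^2 / ((sh - 1)^2 * (sh - 2)))
  expect_lt(abs(mean(d2$se2) - ig_mean), 2 * ig_sd / sqrt(10000))
})

test_that("the sampler is reproducible from its seed", {
  fx <- qtl_fixture(n_fam = c(12, 12, 8))
  st <- mcmc_settings(n_iter = 2000, n_store = 100, seed = 11)
  ch1 <- mcmc_run(fx$y, fx$engine, qtl_priors(), st)
  ch2 <- mcmc_run(fx$y, fx$engine, qtl_priors(), st)
  expect_identical(ch1$count, ch2$count)
  expect_identical(ch1$qtls, ch2$qtls)
  expect_identical(ch1$W, ch2$W)
  ch3 <- mcmc_run(fx$y, fx$engine, qtl_priors(),
                  mcmc_settings(n_iter = 2000, n_store = 100, seed = 12))
  expect_false(identical(ch1$qtls, ch3$qtls))
})

test_that("a strong planted QTL is localized and its genotypes recovered", {
  fx <- qtl_fixture(effect = 1.5)
  ch <- mcmc_run(fx$y, fx$engine,
                 qtl_priors(lambda = 2, a_scale = 0.25 * var(fx$y),
                            e_scale = 0.5 * var(fx$y)),
                 mcmc_settings(n_iter = 12000, n_store = 500, seed = 31,
                               pos_step = 4))
  expect_gt(bayes_factor(ch, "lg", lg = 2)$two_ln_bf, 5)
  inten <- posterior_intensity(ch, bin_width = 2)
  ## the intensity integrates to the posterior mean QTL count exactly
  expect_equal(sum(inten$profile$intensity), mean(ch$count),
               tolerance = 1e-9)
  ## the reported interval covers the true position
  iv <- inten$intervals[inten$intervals$lg == 2, ]
  expect_true(any(iv$start <= 20 & iv$end >= 20))
  ## genotype probabilities: normalized, founders called correctly
  gp <- qtl_genotype_probs(ch, 2, c(14, 26))
  expect_equal(gp$P_QQ + gp$P_Qq + gp$P_qq, rep(1, nrow(gp)),
               tolerance = 1e-9)
  expect_gt(gp$P_QQ[gp$id == "A"], 0.9)
  expect_gt(gp$P_qq[gp$id == "B"], 0.9)
  expect_equal(gp$call[gp$id == "C"], "Qq")  # the heterozygous parent
  ## no confident calls contradict the truth
  called <- gp$call != "ignorance"
  truth_call <- c("qq", "Qq", "QQ")[fx$w + 2][match(gp$id, names(fx$w))]
  expect_gt(mean(gp$call[called] == truth_call[called]), 0.95)
})

test_that("Bayes factors transform posterior and prior odds correctly", {
  fake <- structure(list(
    count = c(rep(1L, 900), rep(0L, 100)),
    qtls = data.frame(sample = integer(), lg = integer(),
                      pos = numeric(), a = numeric(), s2a = numeric(),
                      f = numeric()),
    n_store = 1000, lgs = 1L, lg_len = 100,
    priors = qtl_priors(lambda = log(2))), class = "qtl_chain")
  bf <- bayes_factor(fake, "genome")
  expect_equal(bf$two_ln_bf, 2 * log(9), tolerance = 1e-9)
  expect_equal(bf$label, "positive")
  ## posterior odds equal to prior odds: evidence zero
  fake$count <- c(rep(1L, 500), rep(0L, 500))
  expect_equal(bayes_factor(fake, "genome")$two_ln_bf, 0, tolerance = 1e-9)
  ## thresholds: 6 is "strong", 12 "decisive", and empty cells are bounds
  fake$count <- c(rep(1L, 953), rep(0L, 47))
  bf6 <- bayes_factor(fake, "genome")
  expect_gt(bf6$two_ln_bf, 5)
  expect_equal(bf6$label, "strong")
  fake$count <- rep(1L, 1000)
  bfb <- bayes_factor(fake, "genome")
  expect_equal(bfb$bound, ">")
})

test_that("explained variance follows 2 f (1-f) a^2", {
  expect_equal(round(explained_variance(1.76, 0.21)$var, 2), 1.03)
  expect_equal(round(explained_variance(106.4, 0.53)$var, 0), 5640)
  expect_equal(explained_variance(5, 0)$var, 0)
  expect_equal(explained_variance(5, 1)$var, 0)
  ev <- explained_variance(2, 0.5, total_variance = 10)
  expect_equal(ev$var, 2)
  expect_equal(ev$pct, 20)
  expect_error(explained_variance(1, 0.5, total_variance = 0),
               class = "pedqtl_bad_total_variance")
})

test_that("favorable-allele paths respect the pedigree and the calls", {
  ped <- simulate_pedigree(list(
    founders = c("G1", "G2", "G3", "G4"),
    members = data.frame(id = c("P1", "P2"), sire = c("G1", "G3"),
                         dam = c("G2", "G4")),
    families = data.frame(label = "F", parent1 = "P1", parent2 = "P2",
                          n_offspring = 1)))
  calls <- data.frame(
    id = c("G1", "G2", "G3", "G4", "P1", "P2", "F_001"),
    call = c("Qq", "qq", "qq", "qq", "Qq", "qq", "Qq"),
    stringsAsFactors = FALSE)
  tr <- trace_allele(ped, calls)
  ## the single carrier parent is the definite source, up to the founder
  expect_equal(tr$paths[["F_001"]], list(c("F_001", "P1", "G1")))
  expect_false(any(tr$status$inconsistent))
  ## a carrier with two called non-carrier parents is flagged
  calls$call[calls$id == "P1"] <- "qq"
  tr2 <- trace_allele(ped, calls)
  expect_true(tr2$status$inconsistent[tr2$status$id == "F_001"])
  ## ambiguity is preserved: two possible carrier parents, two paths
  calls$call[calls$id == "P1"] <- "Qq"
  calls$call[calls$id == "P2"] <- "ignorance"
  tr3 <- trace_allele(ped, calls)
  expect_equal(length(tr3$paths[["F_001"]]), 2L)
  expect_error(trace_allele(ped, data.frame(id = "G1", call = "qq")),
               class = "pedqtl_no_carriers")
})

test_that("effective sample size tracks the autocorrelation structure", {
  set.seed(8)
  expect_true(abs(effective_sample_size(rnorm(1000)) - 1000) < 200)
  cst <- effective_sample_size(rep(3.2, 100))
  expect_equal(as.numeric(cst), 1)
  expect_true(attr(cst, "degenerate"))
  x <- as.numeric(arima.sim(list(ar = 0.9), 20000))
  target <- 20000 * (1 - 0.9) / (1 + 0.9)
  expect_lt(abs(effective_sample_size(x) - target) / target, 0.5)
  expect_error(effective_sample_size(rnorm(5)))
})
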