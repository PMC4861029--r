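test_that("simulate_pedigree keeps family bookkeeping and topology", {
  cfg <- cross_config(n = 58, founders = sprintf("F%d", 1:8))
  ped <- simulate_pedigree(cfg)
  expect_equal(nrow(ped), 66)
  expect_equal(sum(ped$sire %in% "F1" & ped$dam %in% "F2"), 58)
  ## founders only
  ped0 <- simulate_pedigree(list(founders = c("X", "Y")))
  expect_equal(nrow(ped0), 2)
  expect_true(all(is.na(ped0$sire)), all(is.na(ped0$dam)))
  ## errors
  expect_error(simulate_pedigree(list(
    founders = "A",
    families = data.frame(label = "F", parent1 = "A", parent2 = "ZZ",
                          n_offspring = 3))),
    class = "pedqtl_undeclared_parent")
  expect_error(simulate_pedigree(list(
    founders = "A",
    members = data.frame(id = c("u", "v"), sire = c("v", "u"),
                         dam = c("A", "A")))),
    class = "pedqtl_cycle")
})

test_that("the study-style pedigree shares parents across families", {
  ped <- simulate_pedigree(small_study_config())
  ## parents precede offspring (topological order by construction)
  seen <- character(0)
  for (i in seq_len(nrow(ped))) {
    p <- c(ped$sire[i], ped$dam[i])
    expect_true(all(is.na(p) | p %in% seen))
    seen <- c(seen, ped$id[i])
  }
  ## the shared parent feeds exactly two families
  fams <- unique(ped$family[!is.na(ped$family) &
                              (ped$sire == "X-3263" |
                                 ped$dam == "X-3263")])
  expect_setequal(fams, c("XB", "HIVW"))
  ## a grandmother shared by two parents
  expect_equal(ped$dam[ped$id == "X-3305"], "Chantecler")
  expect_equal(ped$dam[ped$id == "X-3259"], "Chantecler")
})

test_that("drop_gametes respects Mendelian transmission exactly", {
  ped <- simulate_pedigree(small_study_config())
  map <- make_map(3, 20, 2)
  geno <- drop_gametes(ped, map, 0.5, seed = 42)
  pid <- setNames(seq_len(nrow(ped)), ped$id)
  viol <- 0L
  for (i in seq_len(nrow(ped))) {
    if (!is.na(ped$dam[i])) {
      d <- pid[[ped$dam[i]]]
      viol <- viol + sum(geno$hap_m[i, ] != geno$hap_m[d, ] &
                           geno$hap_m[i, ] != geno$hap_p[d, ])
    }
    if (!is.na(ped$sire[i])) {
      s <- pid[[ped$sire[i]]]
      viol <- viol + sum(geno$hap_p[i, ] != geno$hap_m[s, ] &
                           geno$hap_p[i, ] != geno$hap_p[s, ])
    }
  }
  expect_identical(viol, 0L)
})

test_that("recombination follows the Haldane map function", {
  ## 10,000 meioses on locus pairs at 0, 1, 10, 20 and 50 cM
  cfg <- cross_config(n = 10000)
  ped <- simulate_pedigree(cfg)
  off <- !is.na(ped$family)
  for (d in c(0, 1, 10, 20, 50)) {
    map <- genetic_map(c("L1", "L2"), c(1, 1), c(0, d))
    geno <- drop_gametes(ped, map, 0.5, seed = 100 + d)
    om <- geno$origin_m[off, ]
    rhat <- mean(om[, 1] != om[, 2])
    r <- haldane(d)
    se <- sqrt(max(r * (1 - r), 1e-12) / sum(off))
    if (d == 0) expect_identical(rhat, 0) else
      expect_lt(abs(rhat - r), 3 * se)
  }
  expect_equal(haldane(20), (1 - exp(-0.4)) / 2, tolerance = 1e-12)
})

test_that("simulate_phenotypes realizes the declared observation model", {
  ped <- simulate_pedigree(small_study_config())
  map <- make_map(2, 20, 2)
  geno <- drop_gametes(ped, map, 0.5, seed = 5)
  years <- 2012:2014
  ## all variances zero, no QTLs: observations equal site + year means
  des0 <- phenotype_design(sigma_G = 0,
                           sigma_GY = setNames(rep(0, 3),
                                               as.character(years)),
                           R = diag(1e-12, 3))
  obs0 <- simulate_phenotypes(ped, geno, qtl_truth(integer(), numeric(),
                                                   numeric(), numeric()),
                              des0, seed = 1)
  expected <- des0$site_effects[obs0$site] +
    des0$year_effects[as.character(obs0$year)]
  expect_equal(obs0$value, unname(expected), tolerance = 1e-4)
  ## a single additive QTL shifts QQ and qq means by 2a
  tr <- qtl_truth(1, 10, 3, 0.5)
  des <- phenotype_design(sigma_G = 0.5)
  obs <- simulate_phenotypes(ped, geno, tr, des, seed = 2)
  codes <- attr(obs, "qtl_codes")[unique(obs$genotype), 1]
  gv <- attr(obs, "genotype_values")
  d <- mean(gv[names(codes)[codes == 1]]) -
    mean(gv[names(codes)[codes == -1]])
  expect_lt(abs(d - 2 * 3), 0.6)
})

test_that("polygenic genotype variance matches its target", {
  cfg <- cross_config(n = 400)
  ped <- simulate_pedigree(cfg)
  map <- make_map(1, 10, 5)
  geno <- drop_gametes(ped, map, 0.5, seed = 3)
  des <- phenotype_design(sites = "S", site_effects = c(S = 0),
                          sigma_G = 2, family_sites = c(F = "S"))
  obs <- simulate_phenotypes(ped, geno,
                             qtl_truth(integer(), numeric(), numeric(),
                                       numeric()), des, seed = 9)
  v <- var(attr(obs, "genotype_values"))
  ## chi-square 99.9% band for a sample variance at sigma^2 = 4, n = 400
  n <- 400
  band <- 4 * qchisq(c(5e-4, 1 - 5e-4), n - 1) / (n - 1)
  expect_gt(v, band[1])
  expect_lt(v, band[2])
})

test_that("simulated temperatures carry the declared structure", {
  cp0 <- climate_params(seasonal_amplitude = 0, diurnal_amplitude = 0,
                        noise_sd = 0, n_days = 10)
  s0 <- simulate_temperatures(cp0, seed = 1)
  expect_equal(nrow(s0), 240)
  expect_true(all(s0$temp_C == cp0$annual_mean))
  ## midsummer diurnal range is twice the diurnal amplitude
  cp1 <- climate_params(seasonal_amplitude = 8, diurnal_amplitude = 4,
                        noise_sd = 0, start_date = as.Date("2012-07-14"),
                        n_days = 3)
  s1 <- simulate_temperatures(cp1, seed = 1)
  day2 <- s1$temp_C[25:48]
  expect_equal(max(day2) - min(day2), 8, tolerance = 0.05)
  ## AR(1) noise autocorrelation survives the estimator
  cp2 <- climate_params(seasonal_amplitude = 0, diurnal_amplitude = 0,
                        noise_sd = 1, noise_autocorrelation = 0.8,
                        n_days = 365)
  s2 <- simulate_temperatures(cp2, seed = 4)
  r1 <- acf(s2$temp_C - mean(s2$temp_C), lag.max = 1,
            plot = FALSE)$acf[2]
  expect_lt(abs(r1 - 0.8), 0.03)
  expect_error(climate_params(seasonal_amplitude = -1))
})

test_that("assign_genotype_dates is deterministic in CR/HR and monotone", {
  ser <- list(S = list("2012" = season_series()))
  crhr <- data.frame(genotype = c("g1", "g2", "g3"), site = "S",
                     CR = c(600, 600, 600),
                     HR_budbreak = c(800, 800, 1600),
                     HR_flowering = c(2000, 2000, 2400))
  out <- assign_genotype_dates(crhr, ser, jitter_days = 0, seed = 1)
  ob <- out$observations
  ## identical requirements give identical dates
  expect_equal(ob$budbreak_date[ob$genotype == "g1"],
               ob$budbreak_date[ob$genotype == "g2"])
  ## larger budbreak HR never advances budbreak
  expect_gte(as.numeric(ob$budbreak_date[ob$genotype == "g3"]),
             as.numeric(ob$budbreak_date[ob$genotype == "g1"]))
  expect_error(assign_genotype_dates(
    data.frame(genotype = "g", site = "S", CR = -1, HR_budbreak = 1,
               HR_flowering = 2), ser))
})

test_that("traits derived from simulated dates recover the planted truth", {
  ## round trip at zero jitter: derived BB_GDH equals the date-resolution
  ## heat requirement recorded by the generator, exactly
  ser <- list(S = list("2012" = season_series(warm_hours = 4000)))
  set.seed(7)
  n <- 40
  crhr <- data.frame(genotype = sprintf("g%02d", 1:n), site = "S",
                     CR = 600,
                     HR_budbreak = runif(n, 500, 3000))
  crhr$HR_flowering <- crhr$HR_budbreak + runif(n, 200, 1000)
  out <- assign_genotype_dates(crhr, ser, jitter_days = 0, seed = 2)
  ref <- data.frame(site = "S", year = 2012,
                    release_date = unique(out$truth$release_date))
  expect_equal(nrow(ref), 1L)  # common CR, common release
  tt <- derive_traits(out$observations, ref,
                      list(S = ser$S[["2012"]]))
  tru <- out$truth[match(tt$genotype, out$truth$genotype), ]
  expect_equal(tt$BB_GDH, tru$bb_gdh_true)
  expect_equal(tt$Delta_GDH, tru$delta_gdh_true)
  expect_equal(tt$BB_CD,
               as.integer(format(tru$budbreak_date, "%j")))
  ## derived heat correlates with the planted requirement
  expect_gt(cor(tt$BB_GDH, crhr$HR_budbreak[match(tt$genotype,
                                                  crhr$genotype)]), 0.99)
})
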