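## Synthetic data: interconnected full-sib pedigrees, gamete dropping along a
## genetic map, phenotype simulation under the mixed model, and seasonal
## temperature series. These generators define the study conditions every
## downstream stage is tested against.

#' Haldane map function
#'
#' Recombination fraction between two loci `d` cM apart under a Poisson
#' (no-interference) crossover process: `r = (1 - exp(-2 d / 100)) / 2`.
#'
#' @param d map distance in cM.
#' @return recombination fraction in `[0, 0.5)`.
#' @export
haldane <- function(d) (1 - exp(-2 * d / 100)) / 2

#' Construct a genetic map
#'
#' @param marker character marker (or haploblock) names, unique.
#' @param lg integer linkage group of each locus.
#' @param pos position in cM, non-decreasing within each linkage group.
#' @return a `data.frame` of class `genetic_map`.
#' @export
genetic_map <- function(marker, lg, pos) {
  stopifnot(length(marker) == length(lg), length(lg) == length(pos),
            all(pos >= 0))
  if (anyDuplicated(marker))
    pedqtl_stop("pedqtl_bad_map", "duplicate marker names")
  for (g in unique(lg)) {
    p <- pos[lg == g]
    if (is.unsorted(p))
      pedqtl_stop("pedqtl_bad_map",
                  "positions not non-decreasing on linkage group %s", g)
  }
  structure(data.frame(marker = as.character(marker), lg = as.integer(lg),
                       pos = as.numeric(pos), stringsAsFactors = FALSE),
            class = c("genetic_map", "data.frame"))
}

#' Build an evenly spaced genetic map
#'
#' @param n_lg number of linkage groups.
#' @param length_cM length of each linkage group (recycled).
#' @param spacing locus spacing in cM (default 1, emulating 1 cM haploblocks).
#' @return a [genetic_map()].
#' @export
make_map <- function(n_lg = 17, length_cM = 60, spacing = 1) {
  length_cM <- rep_len(length_cM, n_lg)
  parts <- lapply(seq_len(n_lg), function(g) {
    p <- seq(0, length_cM[g], by = spacing)
    data.frame(marker = sprintf("HB%02d_%03d", g, seq_along(p)),
               lg = g, pos = p, stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, parts)
  genetic_map(all$marker, all$lg, all$pos)
}

#' Simulate an interconnected multi-family pedigree
#'
#' Builds a pedigree from declared founders, optional named intermediate
#' members (parents with their own parentage, possibly with one unknown
#' parent), and full-sib family specifications. Shared parents appear once
#' and feed all their families.
#'
#' @param config list with elements `founders` (character ids), optional
#'   `members` (`data.frame` with `id`, `sire`, `dam`; `NA` for unknown),
#'   `families` (`data.frame` with `label`, `parent1`, `parent2`,
#'   `n_offspring`), optional `ungenotyped` (character ids).
#' @param seed integer seed (offspring naming is deterministic; kept for
#'   interface uniformity).
#' @return a `data.frame` of class `pedigree` with columns `id`, `sire`,
#'   `dam`, `genotyped`, `family` (NA off-family), in topological order, with
#'   the family table as attribute `families`.
#' @export
simulate_pedigree <- function(config, seed = 1) {
  founders <- as.character(config$founders %||% character())
  members <- config$members
  families <- config$families
  ungen <- as.character(config$ungenotyped %||% character())
  ped <- data.frame(id = founders, sire = NA_character_,
                    dam = NA_character_, family = NA_character_,
                    stringsAsFactors = FALSE)
  if (!is.null(members) && nrow(members)) {
    members$id <- as.character(members$id)
    ## topological insertion; detects cycles / undeclared parents
    pending <- members
    guard <- 0L
    while (nrow(pending)) {
      known <- ped$id
      ready <- vapply(seq_len(nrow(pending)), function(i) {
        p <- c(pending$sire[i], pending$dam[i])
        all(is.na(p) | p %in% known)
      }, logical(1))
      if (!any(ready)) {
        undeclared <- setdiff(stats::na.omit(c(pending$sire, pending$dam)),
                              c(known, pending$id))
        if (length(undeclared))
          pedqtl_stop("pedqtl_undeclared_parent",
                      "undeclared parent(s): %s",
                      paste(undeclared, collapse = ", "))
        pedqtl_stop("pedqtl_cycle", "cycle in parentage among: %s",
                    paste(pending$id, collapse = ", "))
      }
      add <- pending[ready, , drop = FALSE]
      ped <- rbind(ped, data.frame(id = add$id, sire = add$sire,
                                   dam = add$dam, family = NA_character_,
                                   stringsAsFactors = FALSE))
      pending <- pending[!ready, , drop = FALSE]
      guard <- guard + 1L
      if (guard > 10000L) pedqtl_stop("pedqtl_cycle", "cycle in parentage")
    }
  }
  if (!is.null(families) && nrow(families)) {
    for (i in seq_len(nrow(families))) {
      p1 <- as.character(families$parent1[i])
      p2 <- as.character(families$parent2[i])
      if (!all(c(p1, p2) %in% ped$id))
        pedqtl_stop("pedqtl_undeclared_parent",
                    "family %s parent not declared", families$label[i])
      k <- families$n_offspring[i]
      ids <- sprintf("%s_%03d", families$label[i], seq_len(k))
      ped <- rbind(ped, data.frame(id = ids, sire = p1, dam = p2,
                                   family = as.character(families$label[i]),
                                   stringsAsFactors = FALSE))
    }
  }
  if (anyDuplicated(ped$id))
    pedqtl_stop("pedqtl_bad_pedigree", "duplicate ids in pedigree")
  ped$genotyped <- !(ped$id %in% ungen)
  structure(ped[, c("id", "sire", "dam", "genotyped", "family")],
            class = c("pedigree", "data.frame"),
            families = families)
}

#' Study-style five-family pedigree configuration
#'
#' A configuration emulating the interconnected apple pedigree analyzed by
#' the package's reference workflow: five full-sib families sharing parents
#' (one parent feeds two families on each site), grandparents shared through
#' a common mother, and one ungenotyped founder.
#'
#' @param n_offspring named integer vector of family sizes (defaults
#'   `XB = 58`, `SG = 115`, `HIVW = 171`, `N = 42`, `P = 45`).
#' @return a config list for [simulate_pedigree()]; the `family_sites`
#'   element maps families to sites (`Mtp` for XB/SG, `Ang` for the rest).
#' @export
study_pedigree_config <- function(n_offspring = c(XB = 58, SG = 115,
                                                  HIVW = 171, N = 42,
                                                  P = 45)) {
  founders <- c("GoldenDel", "Clochard", "ReiDuMans", "Wagenerap", "Winesap",
                "GrannySmith", "Belrene", "PRI_A", "PRI_B", "Frida")
  members <- data.frame(
    id   = c("Delicious", "Starkrimson", "Chantecler", "PRI672-3",
             "PRI14-126", "Rubinette", "Baujade", "X-3263", "X-3259",
             "X-3305"),
    sire = c("Winesap", "Delicious", "GoldenDel", "GoldenDel", "GoldenDel",
             "GoldenDel", "GrannySmith", "PRI672-3", "PRI14-126", "Baujade"),
    dam  = c(NA, NA, "Clochard", "PRI_A", "PRI_B", "ReiDuMans", "Frida",
             "Wagenerap", "Chantecler", "Chantecler"),
    stringsAsFactors = FALSE)
  families <- data.frame(
    label = c("XB", "SG", "HIVW", "N", "P"),
    parent1 = c("X-3263", "Starkrimson", "X-3263", "X-3259", "X-3305"),
    parent2 = c("Belrene", "GrannySmith", "X-3259", "X-3305", "Rubinette"),
    n_offspring = as.integer(n_offspring[c("XB", "SG", "HIVW", "N", "P")]),
    stringsAsFactors = FALSE)
  list(founders = founders, members = members, families = families,
       ungenotyped = "Winesap",
       family_sites = c(XB = "Mtp", SG = "Mtp", HIVW = "Ang", N = "Ang",
                        P = "Ang"))
}

## base homolog: a homolog not received through a tracked meiosis (both
## homologs of a founder; the missing side of a half-known parentage)
pedigree_index <- function(pedigree) {
  idx <- setNames(seq_len(nrow(pedigree)), pedigree$id)
  sire_i <- ifelse(is.na(pedigree$sire), NA_integer_, idx[pedigree$sire])
  dam_i <- ifelse(is.na(pedigree$dam), NA_integer_, idx[pedigree$dam])
  list(idx = idx, sire = unname(sire_i), dam = unname(dam_i))
}

#' Drop gametes through a pedigree
#'
#' Simulates phased diploid genotypes for every pedigree member: base
#' (founder) homologs are drawn locus-wise from the founder allele
#' frequencies (linkage equilibrium) unless explicit haplotypes are given;
#' every other homolog is a recombinant mosaic of its parent's two homologs,
#' with crossovers from a no-interference process so that the recombination
#' fraction between loci `d` cM apart is Haldane's `(1 - exp(-2d/100))/2`.
#'
#' @param pedigree a [simulate_pedigree()] result.
#' @param map a [genetic_map()].
#' @param founder_freq allele-1 frequency for base homologs, scalar or one
#'   value per locus (default 0.5).
#' @param founder_haplotypes optional named list `id -> list(m=, p=)` of 0/1
#'   vectors over all map loci, overriding random founder draws.
#' @param seed integer seed.
#' @return an object of class `phased_genotypes`: list with 0/1 allele
#'   matrices `hap_m`, `hap_p` (individual x locus; maternal and paternal
#'   homolog), origin matrices `origin_m`, `origin_p` (1 = the parent's
#'   maternal homolog, 2 = paternal, `NA` for base homologs), the `map` and
#'   the `pedigree`.
#' @export
drop_gametes <- function(pedigree, map, founder_freq = 0.5,
                         founder_haplotypes = NULL, seed = 1) {
  set.seed(substream_seed(seed, "drop_gametes"))
  n <- nrow(pedigree)
  L <- nrow(map)
  freq <- rep_len(founder_freq, L)
  pidx <- pedigree_index(pedigree)
  hap_m <- hap_p <- matrix(0L, n, L, dimnames = list(pedigree$id, map$marker))
  origin_m <- origin_p <- matrix(NA_integer_, n, L,
                                 dimnames = list(pedigree$id, map$marker))
  lg_split <- split(seq_len(L), map$lg)
  rfrac <- lapply(lg_split, function(ii) haldane(diff(map$pos[ii])))

  base_hap <- function(id, side) {
    if (!is.null(founder_haplotypes) && !is.null(founder_haplotypes[[id]])) {
      h <- founder_haplotypes[[id]][[side]]
      if (length(h) != L)
        pedqtl_stop("pedqtl_bad_haplotypes",
                    "founder haplotype for %s does not cover all loci", id)
      as.integer(h)
    } else as.integer(rbinom(L, 1L, freq))
  }
  meiosis <- function(parent_row) {
    orig <- integer(L)
    for (gi in seq_along(lg_split)) {
      ii <- lg_split[[gi]]
      state <- sample(1:2, 1L)
      o <- integer(length(ii))
      o[1L] <- state
      r <- rfrac[[gi]]
      if (length(ii) > 1L) {
        sw <- rbinom(length(r), 1L, r) == 1L
        for (j in seq_along(r)) {
          if (sw[j]) state <- 3L - state
          o[j + 1L] <- state
        }
      }
      orig[ii] <- o
    }
    allele <- ifelse(orig == 1L, hap_m[parent_row, ], hap_p[parent_row, ])
    list(allele = as.integer(allele), origin = orig)
  }
  for (i in seq_len(n)) {
    if (is.na(pidx$dam[i])) {
      hap_m[i, ] <- base_hap(pedigree$id[i], "m")
    } else {
      g <- meiosis(pidx$dam[i])
      hap_m[i, ] <- g$allele
      origin_m[i, ] <- g$origin
    }
    if (is.na(pidx$sire[i])) {
      hap_p[i, ] <- base_hap(pedigree$id[i], "p")
    } else {
      g <- meiosis(pidx$sire[i])
      hap_p[i, ] <- g$allele
      origin_p[i, ] <- g$origin
    }
  }
  structure(list(hap_m = hap_m, hap_p = hap_p, origin_m = origin_m,
                 origin_p = origin_p, map = map, pedigree = pedigree),
            class = "phased_genotypes")
}

#' QTL truth set
#'
#' @param lg linkage group of each QTL.
#' @param pos position in cM; must coincide with a map locus.
#' @param effect additive effect `a` in trait units (QTL genotypes QQ, Qq,
#'   qq contribute `+a`, `0`, `-a`).
#' @param f frequency of allele Q among base (founder) homologs, in `[0,1]`.
#' @return a `data.frame` of class `qtl_truth`.
#' @export
qtl_truth <- function(lg, pos, effect, f) {
  stopifnot(all(f >= 0 & f <= 1))
  structure(data.frame(lg = as.integer(lg), pos = as.numeric(pos),
                       effect = as.numeric(effect), f = as.numeric(f)),
            class = c("qtl_truth", "data.frame"))
}

## QTL genotype code per individual: +1 QQ, 0 Qq, -1 qq (allele 1 = Q)
qtl_codes <- function(genotypes, truth) {
  map <- genotypes$map
  sapply(seq_len(nrow(truth)), function(k) {
    j <- which(map$lg == truth$lg[k] & abs(map$pos - truth$pos[k]) < 1e-9)
    if (!length(j))
      pedqtl_stop("pedqtl_bad_truth", "QTL %d not on a map locus", k)
    genotypes$hap_m[, j[1L]] + genotypes$hap_p[, j[1L]] - 1L
  })
}

#' Phenotype simulation design
#'
#' Mixed-model structure used to simulate tree-level observations: fixed
#' site and year effects, a genotypic value (QTL codes times effects plus an
#' independent polygenic draw), a genotype-by-year interaction with
#' year-specific variances, and within-tree residuals correlated across
#' years through an unstructured covariance matrix.
#'
#' @param sites character site ids.
#' @param years integer years.
#' @param site_effects,year_effects named numeric fixed effects.
#' @param sigma_G polygenic (non-QTL) genotypic standard deviation.
#' @param sigma_GY named numeric interaction sd per year.
#' @param R residual covariance matrix across years (symmetric positive
#'   definite), within tree.
#' @param replicates trees per genotype (recycled over genotypes).
#' @param family_sites named character: site of each family.
#' @return an object of class `phenotype_design`.
#' @export
phenotype_design <- function(sites = c("Mtp", "Ang"), years = 2012:2014,
                             site_effects = c(Mtp = 0, Ang = 2),
                             year_effects = c("2012" = 0, "2013" = 3,
                                              "2014" = -3),
                             sigma_G = 2,
                             sigma_GY = c("2012" = 1, "2013" = 1,
                                          "2014" = 1),
                             R = diag(3),
                             replicates = 1,
                             family_sites = c(XB = "Mtp", SG = "Mtp",
                                              HIVW = "Ang", N = "Ang",
                                              P = "Ang")) {
  R <- as.matrix(R)
  if (!isSymmetric(unname(R)) || any(eigen(R, symmetric = TRUE,
                                           only.values = TRUE)$values <= 0))
    pedqtl_stop("pedqtl_bad_R", "R must be symmetric positive definite")
  stopifnot(sigma_G >= 0, all(sigma_GY >= 0), nrow(R) == length(years))
  structure(list(sites = sites, years = years, site_effects = site_effects,
                 year_effects = year_effects, sigma_G = sigma_G,
                 sigma_GY = sigma_GY, R = R, replicates = replicates,
                 family_sites = family_sites),
            class = "phenotype_design")
}

#' Simulate tree-level phenotype observations
#'
#' Observation model: `y = site effect + year effect + genotypic value +
#' genotype-by-year draw + residual`, where the genotypic value is the sum of
#' QTL genotype codes times their additive effects plus an independent
#' polygenic normal draw, the interaction draw has a year-specific variance,
#' and residuals of one tree are drawn jointly across years from `R`.
#' Only family offspring are phenotyped.
#'
#' @param pedigree a [simulate_pedigree()] result.
#' @param genotypes a [drop_gametes()] result.
#' @param truth a [qtl_truth()] table (may have zero rows).
#' @param design a [phenotype_design()].
#' @param seed integer seed.
#' @return `data.frame` with columns `tree`, `genotype`, `family`, `site`,
#'   `year`, `value`; the per-genotype total genotypic values are in
#'   attribute `genotype_values` and the QTL codes in attribute `qtl_codes`.
#' @export
simulate_phenotypes <- function(pedigree, genotypes, truth, design,
                                seed = 1) {
  set.seed(substream_seed(seed, "simulate_phenotypes"))
  off <- pedigree[!is.na(pedigree$family), , drop = FALSE]
  codes <- if (nrow(truth)) qtl_codes(genotypes, truth) else
    matrix(0L, nrow(pedigree), 0)
  rownames(codes) <- pedigree$id
  qval <- if (ncol(codes)) drop(codes[off$id, , drop = FALSE] %*%
                                  truth$effect) else numeric(nrow(off))
  gval <- qval + rnorm(nrow(off), 0, design$sigma_G)
  names(gval) <- off$id
  years <- design$years
  K <- length(years)
  Rchol <- chol(design$R)
  reps <- rep_len(design$replicates, nrow(off))
  rows <- vector("list", nrow(off))
  for (i in seq_len(nrow(off))) {
    g <- off$id[i]
    site <- design$family_sites[[off$family[i]]]
    gy <- rnorm(K, 0, design$sigma_GY[as.character(years)])
    tre <- sprintf("%s_t%d", g, seq_len(reps[i]))
    e <- matrix(rnorm(reps[i] * K), reps[i], K) %*% Rchol
    rows[[i]] <- data.frame(
      tree = rep(tre, each = K), genotype = g, family = off$family[i],
      site = site, year = rep(years, reps[i]),
      value = design$site_effects[[site]] +
        design$year_effects[as.character(rep(years, reps[i]))] +
        gval[[g]] + rep(gy, reps[i]) + as.vector(t(e)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "genotype_values") <- gval
  attr(out, "qtl_codes") <- codes
  out
}

#' Climate simulation parameters
#'
#' @param site site id.
#' @param annual_mean annual mean temperature, degrees C.
#' @param seasonal_amplitude amplitude of the seasonal cosine, degrees C.
#' @param diurnal_amplitude amplitude of the diurnal cosine, degrees C.
#' @param noise_sd stationary standard deviation of the AR(1) noise,
#'   degrees C.
#' @param noise_autocorrelation lag-1 autocorrelation of the noise, in
#'   `[0, 1)`.
#' @param start_date first day of the series.
#' @param n_days number of days (24 hourly values per day).
#' @return an object of class `climate_params`.
#' @export
climate_params <- function(site = "Mtp", annual_mean = 13,
                           seasonal_amplitude = 8, diurnal_amplitude = 4,
                           noise_sd = 2, noise_autocorrelation = 0.7,
                           start_date = as.Date("2011-09-01"),
                           n_days = 300) {
  stopifnot(seasonal_amplitude >= 0, diurnal_amplitude >= 0, noise_sd >= 0,
            noise_autocorrelation >= 0, noise_autocorrelation < 1,
            n_days >= 1)
  structure(list(site = site, annual_mean = annual_mean,
                 seasonal_amplitude = seasonal_amplitude,
                 diurnal_amplitude = diurnal_amplitude, noise_sd = noise_sd,
                 noise_autocorrelation = noise_autocorrelation,
                 start_date = as.Date(start_date), n_days = n_days),
            class = "climate_params")
}

#' Simulate an hourly temperature series
#'
#' Hourly temperature = annual mean + seasonal cosine (peaking in
#' mid-July) + diurnal cosine (peaking at 14:00) + stationary AR(1) noise.
#'
#' @param params a [climate_params()].
#' @param seed integer seed.
#' @return a [temperature_series()] of length `24 * n_days`.
#' @export
simulate_temperatures <- function(params, seed = 1) {
  set.seed(substream_seed(seed, paste0("simulate_temperatures_",
                                       params$site)))
  n <- 24L * params$n_days
  t0 <- as.POSIXct(paste(params$start_date, "00:00:00"), tz = "UTC")
  ts <- t0 + 3600 * (seq_len(n) - 1L)
  doy <- as.numeric(format(ts, "%j")) +
    as.numeric(format(ts, "%H")) / 24
  hour <- as.numeric(format(ts, "%H"))
  seasonal <- params$seasonal_amplitude * cos(2 * pi * (doy - 196) / 365.25)
  diurnal <- params$diurnal_amplitude * cos(2 * pi * (hour - 14) / 24)
  rho <- params$noise_autocorrelation
  noise <- numeric(n)
  if (params$noise_sd > 0) {
    z <- rnorm(n)
    noise[1L] <- params$noise_sd * z[1L]
    if (n > 1L) {
      innov_sd <- params$noise_sd * sqrt(1 - rho^2)
      for (i in 2:n) noise[i] <- rho * noise[i - 1L] + innov_sd * z[i]
    }
  }
  temperature_series(params$site, ts,
                     params$annual_mean + seasonal + diurnal + noise)
}

#' Assign budbreak and flowering dates to genotypes
#'
#' Runs the sequential chilling/heat predictor ([predict_stage_dates()]) per
#' genotype and site-year: dormancy release at fulfillment of the genotype's
#' chilling requirement, budbreak at fulfillment of its budbreak heat
#' requirement, flowering at fulfillment of the (larger) flowering heat
#' requirement; optional whole-day observation jitter is then added.
#'
#' Because heat accumulates on an hourly grid and observations carry date
#' resolution, the returned truth table reports the requirements
#' re-expressed at date resolution (`bb_gdh_true`, `delta_gdh_true`:
#' GDH between release date and budbreak date, and between budbreak and
#' flowering dates), which is what trait derivation can recover exactly.
#'
#' @param crhr `data.frame` with columns `genotype`, `site`, `CR` (chilling
#'   hours), `HR_budbreak`, `HR_flowering` (GDH, `HR_flowering >=
#'   HR_budbreak`).
#' @param series nested list `series[[site]][[as.character(year)]]`, each a
#'   [temperature_series()] covering one dormancy season.
#' @param replicates trees per genotype.
#' @param jitter_days standard deviation of whole-day observation noise
#'   (rounded normal; 0 = none).
#' @param seed integer seed.
#' @param chill a [chill_params()]; `gdh` a [gdh_params()].
#' @param gdh a [gdh_params()].
#' @return list with `observations` (`tree`, `genotype`, `site`, `year`,
#'   `budbreak_date`, `flowering_date`) and `truth` (per genotype-year
#'   release/budbreak/flowering dates and date-resolution GDH values).
#' @export
assign_genotype_dates <- function(crhr, series, replicates = 1,
                                  jitter_days = 0, seed = 1,
                                  chill = chill_params(),
                                  gdh = gdh_params()) {
  stopifnot(all(crhr$CR > 0), all(crhr$HR_budbreak > 0),
            all(crhr$HR_flowering >= crhr$HR_budbreak))
  set.seed(substream_seed(seed, "assign_genotype_dates"))
  obs <- list(); tru <- list()
  for (i in seq_len(nrow(crhr))) {
    g <- crhr$genotype[i]; site <- as.character(crhr$site[i])
    for (yr in names(series[[site]])) {
      ser <- series[[site]][[yr]]
      pb <- predict_stage_dates(crhr$CR[i], crhr$HR_budbreak[i], ser,
                                chill, gdh)
      pf <- predict_stage_dates(crhr$CR[i], crhr$HR_flowering[i], ser,
                                chill, gdh)
      rel_d <- pb$release_date; bb_d <- pb$flowering_date
      fl_d <- pf$flowering_date
      bb_true <- accumulate_gdh(ser, as.POSIXct(rel_d, tz = "UTC"),
                                as.POSIXct(bb_d, tz = "UTC"), gdh)
      dl_true <- accumulate_gdh(ser, as.POSIXct(bb_d, tz = "UTC"),
                                as.POSIXct(fl_d, tz = "UTC"), gdh)
      tru[[length(tru) + 1L]] <- data.frame(
        genotype = g, site = site, year = as.integer(yr),
        release_date = rel_d, budbreak_date = bb_d, flowering_date = fl_d,
        bb_gdh_true = bb_true, delta_gdh_true = dl_true,
        stringsAsFactors = FALSE)
      for (r in seq_len(replicates)) {
        jb <- if (jitter_days > 0) round(rnorm(1, 0, jitter_days)) else 0
        jf <- if (jitter_days > 0) round(rnorm(1, 0, jitter_days)) else 0
        obs[[length(obs) + 1L]] <- data.frame(
          tree = sprintf("%s_t%d", g, r), genotype = g, site = site,
          year = as.integer(yr), budbreak_date = bb_d + jb,
          flowering_date = max(fl_d + jf, bb_d + jb),
          stringsAsFactors = FALSE)
      }
    }
  }
  list(observations = do.call(rbind, obs), truth = do.call(rbind, tru))
}
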