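## Pipeline orchestration: simulate -> traits -> blup -> map-qtl ->
## summarize, as reproducible, configured, logged runs with the
## multisite / Mtp / Ang subset scheme.

#' Default simulation block of a pipeline configuration
#'
#' Defines the synthetic study: the interconnected five-family pedigree, a
#' 17-linkage-group map with 1 cM haploblock spacing, planted QTLs acting
#' on the chilling requirement (CR) and on the heat requirements (HR), the
#' climate of the two sites and the observation design.
#'
#' @param pedigree_config see [study_pedigree_config()].
#' @param n_lg,lg_length,spacing map layout (cM).
#' @param founder_freq founder allele frequency for neutral loci.
#' @param qtls `data.frame` with `trait` (`"CR"`, `"HR"` or `"delta"`),
#'   `lg`, `pos`, `effect`, `f`: planted QTLs and the physiological
#'   quantity they act on (chill hours for CR, GDH for HR/delta).
#' @param crhr_base baseline chilling requirement, budbreak heat
#'   requirement, and flowering-minus-budbreak heat increment.
#' @param polygenic_sd polygenic standard deviations of CR, HR and delta.
#' @param years observation years.
#' @param replicates trees per genotype.
#' @param jitter_days whole-day observation noise sd.
#' @param min_segregating_families founder gametes are re-drawn until each
#'   planted QTL has a heterozygous parent in at least this many families
#'   (a monomorphic QTL would make the run vacuous).
#' @return a list consumed by [run_pipeline()].
#' @export
simulate_config <- function(pedigree_config = study_pedigree_config(),
                            n_lg = 17, lg_length = 60, spacing = 1,
                            founder_freq = 0.5,
                            qtls = data.frame(
                              trait = c("CR", "HR"), lg = c(9, 7),
                              pos = c(5, 30), effect = c(250, 1300),
                              f = c(0.5, 0.5)),
                            crhr_base = c(CR = 900, HR_budbreak = 4000,
                                          delta = 1500),
                            polygenic_sd = c(CR = 40, HR = 120,
                                             delta = 60),
                            years = 2012:2014, replicates = 1,
                            jitter_days = 0,
                            min_segregating_families = 3) {
  list(pedigree_config = pedigree_config, n_lg = n_lg,
       lg_length = lg_length, spacing = spacing,
       founder_freq = founder_freq, qtls = qtls, crhr_base = crhr_base,
       polygenic_sd = polygenic_sd, years = years,
       replicates = replicates, jitter_days = jitter_days,
       min_segregating_families = min_segregating_families,
       climates = list(
         Mtp = climate_params(site = "Mtp", annual_mean = 14.5,
                              seasonal_amplitude = 8,
                              diurnal_amplitude = 5, noise_sd = 2,
                              noise_autocorrelation = 0.7),
         Ang = climate_params(site = "Ang", annual_mean = 12,
                              seasonal_amplitude = 7.5,
                              diurnal_amplitude = 4, noise_sd = 2,
                              noise_autocorrelation = 0.7)))
}

#' Pipeline run configuration
#'
#' @param seed master seed; every stochastic stage derives a substream.
#' @param out_dir output directory (created if missing).
#' @param simulate a [simulate_config()] block, or `NULL` when file inputs
#'   are given in `data`.
#' @param data optional in-memory inputs: `pedigree`, `map`, `genotypes`,
#'   `phenotypes`, `temperatures` (named list of series per site),
#'   `reference_release`.
#' @param traits trait columns to analyze.
#' @param subsets named list mapping analysis labels to site filters
#'   (`NULL` = all sites).
#' @param map_variables `"genotypic"` maps the genotypic BLUP per trait;
#'   `"all"` additionally maps each genotype-by-year interaction BLUP.
#' @param model_spec a [mixed_model_spec()].
#' @param priors a [qtl_priors()].
#' @param mcmc an [mcmc_settings()] (its seed is overridden per stage from
#'   the master seed).
#' @param gdh,chill phenology parameter objects.
#' @return an object of class `run_config`.
#' @export
pipeline_config <- function(seed = 1, out_dir = tempfile("pedqtl_run_"),
                            simulate = simulate_config(), data = NULL,
                            traits = c("BB_CD", "BB_GDH", "Delta_GDH"),
                            subsets = list(multisite = NULL, Mtp = "Mtp",
                                           Ang = "Ang"),
                            map_variables = c("genotypic", "all"),
                            model_spec = mixed_model_spec(),
                            priors = qtl_priors(),
                            mcmc = mcmc_settings(n_iter = 20000,
                                                 n_store = 1000),
                            gdh = gdh_params(), chill = chill_params()) {
  stopifnot(is.numeric(seed), seed >= 0)
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 simulate = simulate, data = data, traits = traits,
                 subsets = subsets,
                 map_variables = match.arg(map_variables),
                 model_spec = model_spec, priors = priors, mcmc = mcmc,
                 gdh = gdh, chill = chill),
            class = "run_config")
}

#' Validate pipeline inputs
#'
#' Checks pedigree acyclicity and parent declarations, map monotonicity,
#' genotype/pedigree id agreement, phenotype date parseability and
#' temperature coverage of the observed date ranges. All problems are
#' collected and returned together.
#'
#' @param config a [pipeline_config()]; in-memory `data` inputs are
#'   checked when present, simulated inputs are checked after generation
#'   by [run_pipeline()].
#' @return `data.frame` with columns `input`, `rule`, `message`;
#'   zero rows means the inputs pass.
#' @export
validate_inputs <- function(config) {
  probs <- list()
  add <- function(input, rule, message)
    probs[[length(probs) + 1L]] <<- data.frame(
      input = input, rule = rule, message = message,
      stringsAsFactors = FALSE)
  d <- config$data
  if (!is.null(d$pedigree)) {
    ped <- d$pedigree
    self <- ped$id[!is.na(ped$sire) & ped$id == ped$sire |
                     !is.na(ped$dam) & ped$id == ped$dam]
    for (s in self) add("pedigree", "acyclic",
                        sprintf("individual %s is its own parent", s))
    known <- character(0)
    remaining <- seq_len(nrow(ped))
    repeat {
      ready <- remaining[vapply(remaining, function(i) {
        p <- c(ped$sire[i], ped$dam[i])
        all(is.na(p) | p %in% known)
      }, logical(1))]
      if (!length(ready)) break
      known <- c(known, ped$id[ready])
      remaining <- setdiff(remaining, ready)
    }
    if (length(remaining)) {
      undecl <- setdiff(stats::na.omit(c(ped$sire[remaining],
                                         ped$dam[remaining])), ped$id)
      if (length(undecl))
        add("pedigree", "parents-declared",
            sprintf("undeclared parent(s): %s",
                    paste(undecl, collapse = ", ")))
      else
        add("pedigree", "acyclic",
            sprintf("cycle in parentage among: %s",
                    paste(ped$id[remaining], collapse = ", ")))
    }
  }
  if (!is.null(d$map)) {
    m <- d$map
    for (g in unique(m$lg))
      if (is.unsorted(m$pos[m$lg == g]))
        add("map", "monotone-positions",
            sprintf("positions decrease on linkage group %s", g))
  }
  if (!is.null(d$genotypes) && !is.null(d$pedigree)) {
    gid <- rownames(d$genotypes$hap_m) %||% rownames(d$genotypes)
    extra <- setdiff(gid, d$pedigree$id)
    if (length(extra))
      add("genotypes", "id-agreement",
          sprintf("genotyped ids not in pedigree: %s",
                  paste(extra, collapse = ", ")))
  }
  if (!is.null(d$phenotypes)) {
    ph <- d$phenotypes
    bb <- suppressWarnings(as.Date(as.character(ph$budbreak_date)))
    fl <- suppressWarnings(as.Date(as.character(ph$flowering_date)))
    if (anyNA(bb) || anyNA(fl))
      add("phenotypes", "dates-parseable",
          "unparseable budbreak/flowering dates")
    if (!is.null(d$temperatures)) {
      for (s in unique(ph$site)) {
        ser <- d$temperatures[[as.character(s)]]
        if (is.null(ser)) {
          add("temperatures", "coverage",
              sprintf("no series for site %s", s))
          next
        }
        span <- range(as.Date(ser$timestamp))
        ii <- ph$site == s & !is.na(bb) & !is.na(fl)
        bad <- ii & (bb < span[1] | fl > span[2])
        if (any(bad, na.rm = TRUE))
          add("temperatures", "coverage",
              sprintf("%d observation(s) at site %s outside series span",
                      sum(bad, na.rm = TRUE), s))
      }
    }
  }
  if (length(probs)) do.call(rbind, probs) else
    data.frame(input = character(), rule = character(),
               message = character(), stringsAsFactors = FALSE)
}

## simulate stage: full generative chain from climate to trait table
simulate_stage <- function(config) {
  sc <- config$simulate
  seed <- config$seed
  ped <- simulate_pedigree(sc$pedigree_config, seed)
  map <- make_map(sc$n_lg, sc$lg_length, sc$spacing)
  ## re-draw gametes until every planted QTL segregates in at least two
  ## families (a monomorphic QTL is undetectable by construction and would
  ## make the run vacuous, not informative)
  fam <- sc$pedigree_config$families
  pid <- setNames(seq_len(nrow(ped)), ped$id)
  geno <- NULL
  for (attempt in seq_len(50L)) {
    cand <- drop_gametes(ped, map, sc$founder_freq,
                         seed = seed + (attempt - 1L) * 1009L)
    ok <- TRUE
    if (nrow(sc$qtls)) {
      for (k in seq_len(nrow(sc$qtls))) {
        j <- which(map$lg == sc$qtls$lg[k] &
                     abs(map$pos - sc$qtls$pos[k]) < 1e-9)[1L]
        het <- (cand$hap_m[, j] != cand$hap_p[, j])
        n_seg <- sum(het[pid[fam$parent1]] | het[pid[fam$parent2]])
        if (n_seg < min(sc$min_segregating_families %||% 3L, nrow(fam))) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok) { geno <- cand; break }
  }
  if (is.null(geno))
    pedqtl_stop("pedqtl_simulation",
                "could not realize segregating planted QTLs in 50 draws")
  years <- sc$years
  sites <- names(sc$climates)
  span_start <- as.Date(sprintf("%d-09-01", min(years) - 1L))
  span_end <- as.Date(sprintf("%d-06-30", max(years)))
  n_days <- as.integer(span_end - span_start) + 1L
  temps <- lapply(sites, function(s) {
    cp <- sc$climates[[s]]
    cp$start_date <- span_start
    cp$n_days <- n_days
    simulate_temperatures(cp, seed = seed)
  })
  names(temps) <- sites
  seasons <- lapply(sites, function(s) {
    out <- lapply(years, function(y) {
      i0 <- as.POSIXct(sprintf("%d-09-01 00:00:00", y - 1L), tz = "UTC")
      i1 <- as.POSIXct(sprintf("%d-06-30 23:00:00", y), tz = "UTC")
      keep <- temps[[s]]$timestamp >= i0 & temps[[s]]$timestamp <= i1
      temperature_series(s, temps[[s]]$timestamp[keep],
                         temps[[s]]$temp_C[keep])
    })
    names(out) <- as.character(years)
    out
  })
  names(seasons) <- sites
  ## physiological genotype values from planted QTLs + polygenic noise
  off <- ped[!is.na(ped$family), , drop = FALSE]
  fam_sites <- sc$pedigree_config$family_sites
  set.seed(substream_seed(seed, "crhr"))
  gval <- function(trait, sdp) {
    qt <- sc$qtls[sc$qtls$trait == trait, , drop = FALSE]
    v <- rnorm(nrow(off), 0, sdp)
    if (nrow(qt)) {
      codes <- qtl_codes(geno, qtl_truth(qt$lg, qt$pos, qt$effect, qt$f))
      v <- v + drop(codes[off$id, , drop = FALSE] %*% qt$effect)
    }
    v
  }
  crhr <- data.frame(
    genotype = off$id, site = unname(fam_sites[off$family]),
    CR = pmax(sc$crhr_base[["CR"]] + gval("CR", sc$polygenic_sd[["CR"]]),
              100),
    stringsAsFactors = FALSE)
  hr <- pmax(sc$crhr_base[["HR_budbreak"]] +
               gval("HR", sc$polygenic_sd[["HR"]]), 300)
  dl <- pmax(sc$crhr_base[["delta"]] + gval("delta",
                                            sc$polygenic_sd[["delta"]]),
             100)
  crhr$HR_budbreak <- hr
  crhr$HR_flowering <- hr + dl
  dates <- assign_genotype_dates(crhr, seasons,
                                 replicates = sc$replicates,
                                 jitter_days = sc$jitter_days,
                                 seed = seed, chill = config$chill,
                                 gdh = config$gdh)
  ## reference dormancy release: baseline CR cultivar, per site-year
  ref <- do.call(rbind, lapply(sites, function(s) {
    do.call(rbind, lapply(as.character(years), function(y) {
      pr <- predict_stage_dates(sc$crhr_base[["CR"]], 1e-6,
                                seasons[[s]][[y]], config$chill,
                                config$gdh)
      data.frame(site = s, year = as.integer(y),
                 release_date = pr$release_date, stringsAsFactors = FALSE)
    }))
  }))
  obs <- dates$observations
  obs$family <- off$family[match(obs$genotype, off$id)]
  traits <- derive_traits(obs, ref, temps, config$gdh)
  list(pedigree = ped, map = map, genotypes = geno, temperatures = temps,
       seasons = seasons, crhr = crhr, observations = obs,
       reference_release = ref, traits = traits,
       truth = list(qtls = sc$qtls, crhr = crhr, dates = dates$truth))
}

#' Run the full pipeline
#'
#' Executes simulate (or load) -> trait derivation -> mixed-model BLUPs ->
#' QTL mapping -> summary for every trait and subset, writing stage
#' outputs and a run manifest to `out_dir`. Every stochastic stage is
#' seeded deterministically from the master seed, so re-running an
#' identical configuration reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return an object of class `run_result`: the stage outputs, the
#'   summary tables and the manifest (written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t_start <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) message(sprintf("[pedqtl %s] ",
                                           format(Sys.time(), "%H:%M:%S")),
                                   sprintf(...))
  if (is.null(config$simulate)) {
    probs <- validate_inputs(config)
    if (nrow(probs))
      pedqtl_stop("pedqtl_validation",
                  "input validation failed:\n%s",
                  paste(sprintf("- [%s/%s] %s", probs$input, probs$rule,
                                probs$message), collapse = "\n"))
    sim <- config$data
    sim$traits <- sim$traits %||% derive_traits(
      sim$phenotypes, sim$reference_release, sim$temperatures, config$gdh)
  } else {
    log_msg("simulate stage (seed %d)", config$seed)
    sim <- simulate_stage(config)
    probs <- validate_inputs(
      pipeline_config(seed = config$seed, simulate = NULL,
                      data = list(pedigree = sim$pedigree, map = sim$map,
                                  genotypes = sim$genotypes,
                                  phenotypes = sim$observations,
                                  temperatures = sim$temperatures)))
    if (nrow(probs))
      pedqtl_stop("pedqtl_validation", "simulated inputs failed validation")
  }
  write_pedigree_csv(sim$pedigree, file.path(config$out_dir,
                                             "pedigree.csv"))
  write_map_csv(sim$map, file.path(config$out_dir, "map.csv"))
  write_traits_csv(sim$traits, file.path(config$out_dir, "traits.csv"))

  log_msg("blup stage: %d trait(s) x %d subset(s)", length(config$traits),
          length(config$subsets))
  fits <- run_trait_analyses(sim$traits, config$subsets, config$traits,
                             config$model_spec)
  blup_rows <- list()
  for (s in names(fits)) for (tr in names(fits[[s]])) {
    b <- fits[[s]][[tr]]$blups
    blup_rows[[paste(s, tr)]] <- data.frame(subset = s, trait = tr, b,
                                            stringsAsFactors = FALSE)
  }
  write_blups_csv(do.call(rbind, blup_rows),
                  file.path(config$out_dir, "blups.csv"))

  log_msg("map-qtl stage")
  phased <- phase_pedigree(unphase(sim$genotypes), sim$pedigree, sim$map)
  engine <- build_ibd_engine(sim$pedigree, phased)
  chains <- list()
  for (s in names(fits)) {
    for (tr in names(fits[[s]])) {
      fit <- fits[[s]][[tr]]
      vars <- list(genotypic = setNames(fit$blups$G_blup,
                                        fit$blups$genotype))
      if (config$map_variables == "all") {
        for (yy in unique(fit$interaction$year)) {
          ii <- fit$interaction$year == yy
          vars[[paste0("int_", yy)]] <-
            setNames(fit$interaction$GxY_blup[ii],
                     fit$interaction$genotype[ii])
        }
      }
      for (v in names(vars)) {
        key <- paste(s, tr, v, sep = ".")
        st <- config$mcmc
        st$seed <- substream_seed(config$seed, paste0("mcmc_", key))
        chains[[key]] <- mcmc_run(vars[[v]], engine, config$priors, st)
        write_chain_csv(chains[[key]],
                        file.path(config$out_dir,
                                  paste0("chain_", key, ".csv")))
      }
    }
  }
  log_msg("summarize stage")
  summary <- summarize_run(list(fits = fits, chains = chains))
  write.csv(summary$qtl_table,
            file.path(config$out_dir, "qtl_summary.csv"),
            row.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("pedqtl")),
    config_hash = content_hash(config), seed = config$seed,
    started = format(t_start, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    stages = c("simulate", "traits", "blup", "map-qtl", "summarize"),
    convergence = lapply(chains, function(ch)
      list(converged = ch$converged, ess = as.list(ch$ess))),
    checksums = lapply(
      setNames(nm = list.files(config$out_dir, pattern = "\\.csv$")),
      function(f) content_hash(file.path(config$out_dir, f))))
  jsonlite::write_json(manifest, file.path(config$out_dir,
                                           "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  structure(list(sim = sim, fits = fits, chains = chains,
                 summary = summary, manifest = manifest,
                 out_dir = config$out_dir),
            class = "run_result")
}

#' Summarize QTL scans into report tables
#'
#' Builds a per-analysis QTL table in the standard layout (linkage group,
#' LG-scale and best local 2 ln BF, interval in cM, additive effect,
#' frequency of the positive allele, its variance and percentage of
#' variance explained), flagging regions whose LG-scale 2 ln BF exceeds 5.
#' Regions never visited by a chain are omitted with a note.
#'
#' @param run list with `chains` (named [mcmc_run()] results) and
#'   optionally `fits`; or a `run_result`.
#' @param bin_width intensity bin width in cM (default 2).
#' @return list with `qtl_table`, `heritability` (when fits are present)
#'   and `notes`.
#' @export
summarize_run <- function(run, bin_width = 2) {
  if (inherits(run, "run_result")) run <- list(chains = run$chains,
                                               fits = run$fits)
  rows <- list()
  notes <- character(0)
  for (key in names(run$chains)) {
    ch <- run$chains[[key]]
    inten <- posterior_intensity(ch, bin_width)
    if (!nrow(inten$intervals)) {
      notes <- c(notes, sprintf("%s: no region with positive evidence",
                                key))
      next
    }
    for (r in seq_len(nrow(inten$intervals))) {
      iv <- inten$intervals[r, ]
      reg <- qtl_region_summary(ch, iv$lg, c(iv$start, iv$end))
      if (is.null(reg)) {
        notes <- c(notes, sprintf("%s: LG%s region empty posterior", key,
                                  iv$lg))
        next
      }
      bf_lg <- bayes_factor(ch, "lg", lg = iv$lg)
      rows[[length(rows) + 1L]] <- data.frame(
        analysis = key, lg = iv$lg, two_ln_bf_lg = bf_lg$two_ln_bf,
        max_local_2lnbf = iv$max_local_2lnbf, pos_start = iv$start,
        pos_end = iv$end, add = reg$add, fq = reg$fq, var = reg$var,
        var_post_mean = reg$var_post_mean, pct_var = reg$pct_var,
        strong = bf_lg$two_ln_bf > 5, stringsAsFactors = FALSE)
    }
  }
  qtl_table <- if (length(rows)) do.call(rbind, rows) else
    data.frame(analysis = character(), lg = integer(),
               two_ln_bf_lg = numeric(), max_local_2lnbf = numeric(),
               pos_start = numeric(), pos_end = numeric(),
               add = numeric(), fq = numeric(), var = numeric(),
               var_post_mean = numeric(), pct_var = numeric(),
               strong = logical())
  herit <- NULL
  if (!is.null(run$fits)) {
    hr <- list()
    for (s in names(run$fits)) for (tr in names(run$fits[[s]]))
      hr[[paste(s, tr)]] <- data.frame(
        subset = s, trait = tr,
        h2 = run$fits[[s]][[tr]]$heritability %||% NA_real_,
        stringsAsFactors = FALSE)
    herit <- do.call(rbind, hr)
  }
  list(qtl_table = qtl_table, heritability = herit, notes = notes)
}

#' Posterior summaries of a QTL region
#'
#' Posterior means of the additive effect and favorable-allele frequency
#' among stored samples holding a QTL in the region. Co-located components
#' within one sample are first aggregated into a single effective QTL, and
#' samples are oriented so the reported allele increases the trait. The
#' explained variance is reported both as `2 f (1-f) a^2` of the posterior
#' means (`var`) and as the posterior mean of the per-sample
#' `2 f (1-f) a^2` (`var_post_mean`).
#'
#' @param chain a [mcmc_run()] result.
#' @param lg linkage group.
#' @param interval `c(start, end)` cM.
#' @return list with `add`, `fq`, `var`, `var_post_mean`, `pct_var`,
#'   `n_samples`; `NULL` if the region was never visited.
#' @export
qtl_region_summary <- function(chain, lg, interval) {
  q <- chain$qtls
  hit <- which(q$lg == lg & q$pos >= interval[1] & q$pos < interval[2])
  if (!length(hit)) return(NULL)
  agg <- region_aggregate(chain, hit)
  ## orientation: the favorable allele increases the trait
  a_mean <- mean(agg$a_eff)
  add <- abs(a_mean)
  fq <- if (a_mean >= 0) mean(agg$f_eff) else 1 - mean(agg$f_eff)
  v <- explained_variance(add, fq)$var
  v_pm <- mean(2 * agg$f_eff * (1 - agg$f_eff) * agg$a_eff^2)
  list(add = add, fq = fq, var = v, var_post_mean = v_pm,
       pct_var = 100 * v / chain$total_var, n_samples = length(agg$samples))
}
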