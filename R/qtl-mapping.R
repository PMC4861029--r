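## Pedigree-based Bayesian QTL mapping on BLUP phenotypes: IBD engine,
## RJ-MCMC wrapper, Bayes factors, posterior intensities, QTL genotype
## probabilities, explained variance and favorable-allele tracing.

#' Priors of the Bayesian QTL model
#'
#' @param lambda Poisson prior mean for the genome-wide QTL count
#'   (default 5).
#' @param a_shape,a_scale inverse-gamma prior for the per-QTL explained
#'   variance `s2a`. The default `a_scale = NULL` resolves at run time to
#'   `0.25 * var(y)` of the mapped phenotype, so the prior lives on the
#'   trait's own scale; pass a number to fix it.
#' @param e_shape,e_scale inverse-gamma prior for the residual variance;
#'   `e_scale = NULL` resolves to `0.5 * var(y)` at run time.
#' @param beta_a,beta_b Beta prior for the founder frequency of allele Q
#'   (default Beta(1, 1), uniform).
#' @return an object of class `qtl_priors`.
#' @export
qtl_priors <- function(lambda = 5, a_shape = 1, a_scale = NULL,
                       e_shape = 1, e_scale = NULL, beta_a = 1,
                       beta_b = 1) {
  stopifnot(lambda > 0, a_shape > 0, is.null(a_scale) || a_scale > 0,
            e_shape > 0, is.null(e_scale) || e_scale > 0,
            beta_a > 0, beta_b > 0)
  structure(list(lambda = lambda, a_shape = a_shape, a_scale = a_scale,
                 e_shape = e_shape, e_scale = e_scale, beta_a = beta_a,
                 beta_b = beta_b),
            class = "qtl_priors")
}

#' MCMC settings
#'
#' @param n_iter sweeps (default 500000, the cap used in the reference
#'   workflow; tests use far fewer).
#' @param n_store stored samples (default 1000).
#' @param burnin_frac burn-in fraction discarded before storage
#'   (default 0.2).
#' @param seed integer seed; two runs with the same seed and inputs give
#'   identical chains.
#' @param pos_step random-walk standard deviation for position moves, cM.
#' @param min_ess minimum effective sample size before the chain is
#'   considered converged (default 100).
#' @param max_qtl hard cap on the QTL count (default 25).
#' @param flat_likelihood if `TRUE` the phenotype likelihood is switched
#'   off and the sampler targets the prior (validation mode).
#' @return an object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_iter = 500000, n_store = 1000,
                          burnin_frac = 0.2, seed = 1, pos_step = 10,
                          min_ess = 100, max_qtl = 25,
                          flat_likelihood = FALSE) {
  stopifnot(n_store <= n_iter, min_ess >= 1, burnin_frac >= 0,
            burnin_frac < 1)
  structure(list(n_iter = as.integer(n_iter), n_store = as.integer(n_store),
                 burnin_frac = burnin_frac, seed = as.integer(seed),
                 pos_step = pos_step, min_ess = min_ess,
                 max_qtl = as.integer(max_qtl),
                 flat_likelihood = isTRUE(flat_likelihood)),
            class = "mcmc_settings")
}

#' Build the identity-by-descent transition structure
#'
#' Prepares the pedigree and the informative parental origins for the
#' sampler: every homolog of every member is either a base (founder)
#' homolog or the product of a tracked meiosis, and for any map position
#' the engine gives the probability of each segregation indicator given the
#' flanking informative origins, using Haldane recombination fractions.
#' Ungenotyped members simply have no informative origins, so their
#' indicators stay latent and are integrated by sampling.
#'
#' @param pedigree a [simulate_pedigree()]-style pedigree.
#' @param origins a [phase_pedigree()] result (haploblock-level origins) or
#'   a [drop_gametes()] result (locus-level truth origins).
#' @param map optional [genetic_map()]; defaults to the map carried by
#'   `origins`.
#' @return an object of class `ibd_engine`.
#' @export
build_ibd_engine <- function(pedigree, origins, map = NULL) {
  if (inherits(origins, "phased_haploblocks")) {
    map <- map %||% origins$map
    bl <- origins$blocks$blocks
    om <- origins$block_origin_m
    op <- origins$block_origin_p
    opos <- (bl$start + bl$end) / 2
    olg <- bl$lg
  } else if (inherits(origins, "phased_genotypes")) {
    map <- map %||% origins$map
    om <- origins$origin_m
    op <- origins$origin_p
    opos <- map$pos
    olg <- map$lg
  } else {
    pedqtl_stop("pedqtl_bad_origins",
                "origins must come from phase_pedigree() or drop_gametes()")
  }
  n <- nrow(pedigree)
  stopifnot(nrow(om) == n)
  pidx <- pedigree_index(pedigree)
  lgs <- sort(unique(map$lg))
  n_lg <- length(lgs)
  lg_len <- vapply(lgs, function(g) max(map$pos[map$lg == g]), numeric(1))
  par0 <- base0 <- meio0 <- matrix(-1L, n, 2)   # col 1 maternal, 2 paternal
  base_n <- 0L; meio_n <- 0L
  base_owner <- list(); meio_owner <- list()
  for (i in seq_len(n)) {
    for (s in 1:2) {
      p <- if (s == 1) pidx$dam[i] else pidx$sire[i]
      if (is.na(p)) {
        base0[i, s] <- base_n
        base_n <- base_n + 1L
        base_owner[[base_n]] <- data.frame(ind = i, side = s)
      } else {
        par0[i, s] <- p - 1L
        meio0[i, s] <- meio_n
        meio_n <- meio_n + 1L
        meio_owner[[meio_n]] <- data.frame(ind = i, side = s)
      }
    }
  }
  ## informative origins per (meiosis, lg): positions sorted, origins 0/1
  io <- vector("list", meio_n * n_lg)
  mo <- do.call(rbind, meio_owner)
  for (m in seq_len(meio_n)) {
    i <- mo$ind[m]
    ov <- if (mo$side[m] == 1) om[i, ] else op[i, ]
    for (gi in seq_len(n_lg)) {
      jj <- which(olg == lgs[gi] & !is.na(ov))
      jj <- jj[order(opos[jj])]
      io[[(m - 1L) * n_lg + gi]] <-
        list(pos = pmin(opos[jj], lg_len[gi]), org = ov[jj] - 1L)
    }
  }
  io_len <- vapply(io, function(x) length(x$pos), integer(1))
  structure(list(
    ids = pedigree$id, pedigree = pedigree, n = n, n_base = base_n,
    M = meio_n, n_lg = n_lg, lgs = lgs, lg_len = unname(lg_len),
    par = par0, base = base0, meio = meio0,
    base_owner = do.call(rbind, base_owner), meio_owner = mo,
    io_off = c(0L, cumsum(io_len)),
    io_pos = unlist(lapply(io, `[[`, "pos"), use.names = FALSE) %||%
      numeric(0),
    io_org = as.integer(unlist(lapply(io, `[[`, "org"),
                               use.names = FALSE) %||% integer(0))),
    class = "ibd_engine")
}

#' Segregation-indicator probability at a map position
#'
#' Probability that the indicated meiosis transmitted the parent's homolog
#' 2 at position `pos`, given the flanking informative origins, with
#' Haldane recombination fractions between the position and each flank.
#'
#' @param engine an [build_ibd_engine()] result.
#' @param individual individual id; `side` `"m"` (maternal) or `"p"`.
#' @param side which meiosis of the individual.
#' @param lg linkage group; `pos` position in cM.
#' @param pos position in cM, on the linkage group.
#' @return `P(indicator = homolog 2)`.
#' @export
ibd_origin_prob <- function(engine, individual, side = c("m", "p"), lg,
                            pos) {
  side <- match.arg(side)
  i <- match(individual, engine$ids)
  gi <- match(lg, engine$lgs)
  if (is.na(gi) || pos < 0 || pos > engine$lg_len[gi])
    pedqtl_stop("pedqtl_off_map", "position %s off linkage group %s",
                pos, lg)
  m <- engine$meio[i, if (side == "m") 1L else 2L]
  if (m < 0) pedqtl_stop("pedqtl_no_meiosis",
                         "%s has no tracked %s meiosis", individual, side)
  c0 <- m * engine$n_lg + (gi - 1L)
  jj <- if (engine$io_off[c0 + 1L] < engine$io_off[c0 + 2L])
    (engine$io_off[c0 + 1L] + 1L):engine$io_off[c0 + 2L] else integer(0)
  ppos <- engine$io_pos[jj]; porg <- engine$io_org[jj]
  w1 <- w0 <- 1
  left <- which(ppos <= pos); right <- which(ppos > pos)
  if (length(left)) {
    iL <- left[length(left)]
    r <- haldane(pos - ppos[iL])
    if (porg[iL] == 1L) { w1 <- w1 * (1 - r); w0 <- w0 * r }
    else { w1 <- w1 * r; w0 <- w0 * (1 - r) }
  }
  if (length(right)) {
    iR <- right[1L]
    r <- haldane(ppos[iR] - pos)
    if (porg[iR] == 1L) { w1 <- w1 * (1 - r); w0 <- w0 * r }
    else { w1 <- w1 * r; w0 <- w0 * (1 - r) }
  }
  w1 / (w0 + w1)
}

#' Run the reversible-jump MCMC QTL sampler
#'
#' Samples from the joint posterior of the bi-allelic additive QTL model:
#' each sweep Gibbs-updates segregation indicators and founder alleles
#' (single site), founder allele frequencies (Beta), additive effects
#' (normal), per-QTL and residual variances (inverse-gamma) and the
#' intercept; applies a random-walk Metropolis move to each QTL position
#' within its linkage group; and proposes one birth/death reversible jump
#' on the QTL count against the Poisson prior, with the new component
#' drawn from its prior.
#'
#' @param y named numeric phenotype (BLUP) vector; names are pedigree ids;
#'   members without phenotype are handled as latent.
#' @param engine an [build_ibd_engine()] result.
#' @param priors a [qtl_priors()] object.
#' @param settings an [mcmc_settings()] object.
#' @return an object of class `qtl_chain`: stored `count`, `mu`, `se2`
#'   traces, the per-sample QTL table `qtls` (`sample`, `lg`, `pos`, `a`,
#'   `s2a`, `f`), the stored QTL genotype matrix `W` (rows matching `qtls`,
#'   columns the pedigree ids), ESS diagnostics and a `converged` flag
#'   (the chain is returned either way, flagged).
#' @export
mcmc_run <- function(y, engine, priors = qtl_priors(),
                     settings = mcmc_settings()) {
  stopifnot(inherits(engine, "ibd_engine"), inherits(priors, "qtl_priors"),
            inherits(settings, "mcmc_settings"))
  yfull <- rep(NA_real_, engine$n)
  if (is.null(names(y))) {
    stopifnot(length(y) == engine$n)
    yfull <- as.numeric(y)
  } else {
    hit <- match(names(y), engine$ids)
    if (anyNA(hit))
      pedqtl_stop("pedqtl_bad_phenotype", "phenotype ids not in pedigree: %s",
                  paste(names(y)[is.na(hit)], collapse = ", "))
    yfull[hit] <- as.numeric(y)
  }
  ## resolve data-scale defaults of the variance priors
  v_y <- if (sum(!is.na(yfull)) > 1) stats::var(yfull[!is.na(yfull)]) else 1
  v_y <- max(v_y, 1e-12)
  if (is.null(priors$a_scale)) priors$a_scale <- 0.25 * v_y
  if (is.null(priors$e_scale)) priors$e_scale <- 0.5 * v_y
  eng <- list(n = engine$n, n_base = engine$n_base, M = engine$M,
              n_lg = engine$n_lg,
              par = as.integer(t(engine$par)),
              base = as.integer(t(engine$base)),
              meio = as.integer(t(engine$meio)),
              lg_len = engine$lg_len, io_off = engine$io_off,
              io_pos = engine$io_pos, io_org = engine$io_org)
  burnin <- as.integer(floor(settings$n_iter * settings$burnin_frac))
  set.seed(settings$seed)
  raw <- rjmcmc_cpp(eng, yfull, unclass(priors),
                    list(n_iter = settings$n_iter,
                         n_store = settings$n_store, burnin = burnin,
                         pos_step = settings$pos_step,
                         flat_likelihood = settings$flat_likelihood,
                         max_qtl = settings$max_qtl, store_w = TRUE))
  qtls <- data.frame(sample = raw$sample,
                     lg = engine$lgs[raw$lg], pos = raw$pos, a = raw$a,
                     s2a = raw$s2a, f = raw$f)
  W <- raw$W
  if (ncol(W)) colnames(W) <- engine$ids
  ess <- c(count = effective_sample_size(raw$count),
           se2 = effective_sample_size(raw$se2),
           mu = if (settings$flat_likelihood) NA_real_ else
             effective_sample_size(raw$mu))
  structure(list(count = raw$count, mu = raw$mu, se2 = raw$se2,
                 qtls = qtls, W = W, accept = raw$accept,
                 n_store = length(raw$count), lgs = engine$lgs,
                 lg_len = engine$lg_len, ids = engine$ids,
                 priors = priors, settings = settings,
                 total_var = stats::var(yfull[!is.na(yfull)]),
                 ess = ess,
                 converged = all(ess >= settings$min_ess, na.rm = TRUE)),
            class = "qtl_chain")
}

## prior Poisson mean allocated to a scope (genome, one LG, or a cM window)
scope_prior_mean <- function(chain, scope, lg = NULL, interval = NULL) {
  lam <- chain$priors$lambda
  total <- sum(chain$lg_len)
  switch(scope,
         genome = lam,
         lg = lam * chain$lg_len[match(lg, chain$lgs)] / total,
         bin = {
           len <- min(interval[2], chain$lg_len[match(lg, chain$lgs)]) -
             max(interval[1], 0)
           lam * max(len, 0) / total
         })
}

scope_counts <- function(chain, scope, lg = NULL, interval = NULL) {
  if (scope == "genome") return(chain$count)
  q <- chain$qtls
  keep <- switch(scope,
                 lg = q$lg == lg,
                 bin = q$lg == lg & q$pos >= interval[1] &
                   q$pos < interval[2])
  tabulate(q$sample[keep], nbins = chain$n_store)
}

#' Bayes factor for the presence of one more QTL
#'
#' Compares models differing by one QTL within a scope: `2 ln BF(l vs l-1)
#' = 2 ln[ (post P(count >= l) / post P(count < l)) / (prior P(count >= l)
#' / prior P(count < l)) ]`, with per-LG and per-bin prior means allocated
#' proportionally to genetic length from the genome-wide Poisson prior.
#' Evidence labels: `> 2` positive, `> 5` strong, `> 10` decisive.
#'
#' @param chain a [mcmc_run()] result.
#' @param scope `"genome"`, `"lg"` or `"bin"`.
#' @param lg linkage group (for `"lg"`/`"bin"`).
#' @param interval `c(start, end)` in cM (for `"bin"`).
#' @param l compare models with `>= l` QTLs against `< l` (default 1).
#' @return list with `two_ln_bf`, `label`, and `bound` (`""`, or `">"`/
#'   `"<"` when a posterior cell was empty and the value is reported at the
#'   1/(stored samples) resolution).
#' @export
bayes_factor <- function(chain, scope = c("genome", "lg", "bin"), lg = NULL,
                         interval = NULL, l = 1) {
  scope <- match.arg(scope)
  counts <- scope_counts(chain, scope, lg, interval)
  prior_mean <- scope_prior_mean(chain, scope, lg, interval)
  post_ge <- mean(counts >= l)
  prior_ge <- 1 - ppois(l - 1, prior_mean)
  eps <- 1 / chain$n_store
  bound <- ""
  if (post_ge == 0) { post_ge <- eps; bound <- "<" }
  if (post_ge == 1) { post_ge <- 1 - eps; bound <- ">" }
  bf2 <- 2 * (log(post_ge / (1 - post_ge)) -
                log(prior_ge / (1 - prior_ge)))
  label <- if (bf2 > 10) "decisive" else if (bf2 > 5) "strong" else
    if (bf2 > 2) "positive" else "none"
  list(two_ln_bf = bf2, label = label, bound = bound)
}

#' Posterior QTL intensity profile
#'
#' Expected number of QTLs per map bin under the posterior; contiguous bins
#' with local `2 ln BF > 2` are merged into reported QTL intervals.
#'
#' @param chain a [mcmc_run()] result.
#' @param bin_width bin width in cM (default 2).
#' @return list with `profile` (`lg`, `bin_start`, `bin_end`, `intensity`,
#'   `local_2lnbf`) and `intervals` (`lg`, `start`, `end`,
#'   `max_local_2lnbf`). The intensity integrates to the posterior mean
#'   QTL count.
#' @export
posterior_intensity <- function(chain, bin_width = 2) {
  stopifnot(bin_width > 0)
  rows <- list()
  for (gi in seq_along(chain$lgs)) {
    g <- chain$lgs[gi]
    edges <- seq(0, ceiling(chain$lg_len[gi] / bin_width) * bin_width,
                 by = bin_width)
    qq <- chain$qtls[chain$qtls$lg == g, , drop = FALSE]
    for (b in seq_len(length(edges) - 1L)) {
      iv <- c(edges[b], edges[b + 1L])
      inten <- sum(qq$pos >= iv[1] & qq$pos < iv[2]) / chain$n_store
      bf <- bayes_factor(chain, "bin", lg = g, interval = iv)
      rows[[length(rows) + 1L]] <- data.frame(
        lg = g, bin_start = iv[1], bin_end = iv[2], intensity = inten,
        local_2lnbf = bf$two_ln_bf, stringsAsFactors = FALSE)
    }
  }
  prof <- do.call(rbind, rows)
  ivs <- list()
  for (g in unique(prof$lg)) {
    pg <- prof[prof$lg == g, , drop = FALSE]
    on <- pg$local_2lnbf > 2
    r <- rle(on)
    stops <- cumsum(r$lengths)
    starts <- stops - r$lengths + 1L
    for (k in which(r$values)) {
      ivs[[length(ivs) + 1L]] <- data.frame(
        lg = g, start = pg$bin_start[starts[k]], end = pg$bin_end[stops[k]],
        max_local_2lnbf = max(pg$local_2lnbf[starts[k]:stops[k]]),
        stringsAsFactors = FALSE)
    }
  }
  list(profile = prof,
       intervals = if (length(ivs)) do.call(rbind, ivs) else
         data.frame(lg = integer(), start = numeric(), end = numeric(),
                    max_local_2lnbf = numeric()))
}

#' Bi-allelic additive QTL variance
#'
#' Variance explained by a bi-allelic additive QTL with effect `a` and
#' founder allele frequency `f` under founder Hardy-Weinberg:
#' `var = 2 f (1 - f) a^2`; optionally as a percentage of a total variance.
#'
#' @param a additive effect.
#' @param f frequency of the positive allele, in `[0, 1]`.
#' @param total_variance optional total trait (BLUP) variance for the
#'   percentage.
#' @return list with `var` and (if `total_variance` given) `pct`.
#' @examples
#' explained_variance(1.76, 0.21)$var  # 1.03 at two decimals
#' @export
explained_variance <- function(a, f, total_variance = NULL) {
  stopifnot(all(f >= 0), all(f <= 1))
  v <- 2 * f * (1 - f) * a^2
  out <- list(var = v)
  if (!is.null(total_variance)) {
    if (any(total_variance <= 0))
      pedqtl_stop("pedqtl_bad_total_variance", "total_variance must be > 0")
    out$pct <- 100 * v / total_variance
  }
  out
}

## Aggregate the QTL components a region holds in each stored sample into
## one effective QTL: per-individual net effect, effective codes -1/0/1,
## least-squares effective effect and an |a|-weighted allele frequency.
region_aggregate <- function(chain, rows) {
  q <- chain$qtls[rows, , drop = FALSE]
  net <- rowsum(chain$W[rows, , drop = FALSE] * q$a, q$sample,
                reorder = TRUE)
  amp <- apply(abs(net), 1, max)
  codes <- round(net / pmax(amp, 1e-12))
  a_eff <- rowSums(net * codes) / pmax(rowSums(codes^2), 1)
  wgt <- rowsum(abs(q$a), q$sample, reorder = TRUE)[, 1]
  f_eff <- rowsum(q$f * abs(q$a), q$sample, reorder = TRUE)[, 1] /
    pmax(wgt, 1e-12)
  list(codes = codes, a_eff = a_eff, f_eff = f_eff,
       samples = sort(unique(q$sample)))
}

#' Posterior QTL genotype probabilities in a region
#'
#' Frequency of each implied QTL genotype (QQ, Qq, qq) per individual among
#' the stored samples that contain a QTL in the region. When a sample holds
#' several co-located components they are aggregated into one effective QTL
#' (the per-individual net effect, rescaled to codes -1/0/1), so posterior
#' effect-splitting does not dilute the genotype evidence. Samples are
#' oriented so that Q is the trait-increasing allele. Calls are emitted
#' only when the top probability reaches `threshold`; below it the
#' individual is reported as `"ignorance"`.
#'
#' @param chain a [mcmc_run()] result.
#' @param lg linkage group of the region.
#' @param interval `c(start, end)` in cM.
#' @param threshold call threshold (default 0.80).
#' @return `data.frame` with `id`, `P_QQ`, `P_Qq`, `P_qq`, `call`,
#'   `n_samples` (region visits used).
#' @export
qtl_genotype_probs <- function(chain, lg, interval, threshold = 0.8) {
  q <- chain$qtls
  hit <- which(q$lg == lg & q$pos >= interval[1] & q$pos < interval[2])
  if (!length(hit))
    pedqtl_stop("pedqtl_region_unvisited",
                "no stored sample holds a QTL in LG%s [%s, %s)", lg,
                interval[1], interval[2])
  agg <- region_aggregate(chain, hit)
  cls <- agg$codes * sign(agg$a_eff)  # orient: Q increases the trait
  pQQ <- colMeans(cls == 1)
  pQq <- colMeans(cls == 0)
  pqq <- colMeans(cls == -1)
  top <- pmax(pQQ, pQq, pqq)
  call <- ifelse(top < threshold, "ignorance",
                 c("QQ", "Qq", "qq")[max.col(cbind(pQQ, pQq, pqq),
                                             ties.method = "first")])
  data.frame(id = chain$ids, P_QQ = pQQ, P_Qq = pQq, P_qq = pqq,
             call = call, n_samples = nrow(cls),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Trace transmission of the favorable allele through the pedigree
#'
#' For each called carrier of the favorable allele, lists the ancestor
#' chains consistent with identity-by-descent transmission: a parent that
#' is itself a called carrier is a definite source; a parent with an
#' ignorance call (or no call) is a possible source; ambiguity is reported
#' as multiple candidate paths, never collapsed. A carrier whose parents
#' are both called non-carriers is flagged as a Mendelian inconsistency.
#'
#' @param pedigree the pedigree.
#' @param calls `data.frame` with columns `id` and `call` (`"QQ"`, `"Qq"`,
#'   `"qq"` or `"ignorance"`), e.g. from [qtl_genotype_probs()].
#' @return list with `status` (per id: carrier / non-carrier / unknown,
#'   `inconsistent` flag) and `paths`: per carrier, a list of candidate
#'   ancestor chains (each a character vector starting at the carrier).
#' @export
trace_allele <- function(pedigree, calls) {
  call_of <- setNames(calls$call, calls$id)
  status_of <- function(id) {
    cl <- call_of[id]
    if (is.na(cl) || cl == "ignorance") "unknown"
    else if (cl %in% c("QQ", "Qq")) "carrier" else "non-carrier"
  }
  st <- vapply(pedigree$id, status_of, character(1))
  if (!any(st == "carrier"))
    pedqtl_stop("pedqtl_no_carriers", "no called carriers")
  pidx <- pedigree_index(pedigree)
  inconsistent <- character(0)
  paths <- list()
  expand <- function(id, depth = 0) {
    if (depth > nrow(pedigree)) return(list(id))
    i <- pidx$idx[[id]]
    pars <- c(pedigree$dam[i], pedigree$sire[i])
    pars <- pars[!is.na(pars)]
    if (!length(pars)) return(list(id))
    pst <- vapply(pars, status_of, character(1))
    if (length(pars) == 2L && all(pst == "non-carrier")) {
      inconsistent <<- union(inconsistent, id)
      return(list(id))
    }
    cand <- pars[pst != "non-carrier"]
    out <- list()
    for (p in cand)
      for (tail in expand(p, depth + 1L))
        out[[length(out) + 1L]] <- c(id, tail)
    if (!length(out)) out <- list(id)
    out
  }
  for (id in pedigree$id[st == "carrier"]) paths[[id]] <- expand(id)
  list(status = data.frame(id = pedigree$id, status = unname(st),
                           inconsistent = pedigree$id %in% inconsistent,
                           stringsAsFactors = FALSE),
       paths = paths)
}

#' Effective sample size of an MCMC trace
#'
#' `ESS = N / (1 + 2 * sum(rho_k))` with the autocorrelation sum truncated
#' at the first non-positive pair sum (initial positive sequence).
#'
#' @param x numeric trace (length >= 10).
#' @return estimated ESS; a constant trace returns 1 with attribute
#'   `degenerate = TRUE`.
#' @export
effective_sample_size <- function(x) {
  x <- as.numeric(x)
  N <- length(x)
  stopifnot(N >= 10)
  if (stats::sd(x) == 0)
    return(structure(1, degenerate = TRUE))
  rho <- stats::acf(x, lag.max = min(N - 2, 2000), plot = FALSE,
                    demean = TRUE)$acf[-1]
  s <- 0
  k <- 1
  while (k + 1 <= length(rho)) {
    pair <- rho[k] + rho[k + 1]
    if (pair <= 0) break
    s <- s + pair
    k <- k + 2
  }
  max(min(N / (1 + 2 * s), N), 1)
}
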