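## Mixed model: REML variance components, genotypic and genotype-by-year
## BLUPs, broad-sense heritability. The model is
##   y = X1 b_site + X2 b_year + Z1 u_G + Z2 u_GxY + e
## with u_G ~ N(0, sG2), u_GxY ~ N(0, sGY2[year]) and within-tree residuals
## correlated across years through an unstructured covariance R. Because
## all random effects are nested in genotype, the restricted likelihood
## factorizes into independent per-genotype blocks, which is what the
## fitter exploits.

#' Mixed-model specification
#'
#' @param gxy `"by_year"` (default) fits one interaction variance per year;
#'   `"homogeneous"` fits a single interaction variance.
#' @param residual `"unstructured"` (default) fits a full symmetric
#'   positive-definite covariance across years within tree;
#'   `"diagonal"` fits year-specific independent residual variances;
#'   `"simple"` fits one homogeneous residual variance.
#' @param standardize standardize BLUPs to unit variance before export
#'   (default `FALSE`; raw BLUPs are mapped).
#' @return an object of class `mixed_model_spec`.
#' @export
mixed_model_spec <- function(gxy = c("by_year", "homogeneous"),
                             residual = c("unstructured", "diagonal",
                                          "simple"),
                             standardize = FALSE) {
  structure(list(gxy = match.arg(gxy), residual = match.arg(residual),
                 standardize = standardize),
            class = "mixed_model_spec")
}

## parameter vector layout: log sdG | log sdGY (1 or K) | residual params
## residual: simple = 1 log sd; diagonal = K log sds;
## unstructured = K log diag + K(K-1)/2 off-diagonals of the Cholesky factor
theta_template <- function(spec, K) {
  n_gy <- if (spec$gxy == "by_year") K else 1L
  n_r <- switch(spec$residual, simple = 1L, diagonal = K,
                unstructured = K + K * (K - 1L) %/% 2L)
  list(n_gy = n_gy, n_r = n_r, K = K, total = 1L + n_gy + n_r)
}

theta_unpack <- function(theta, spec, K) {
  tpl <- theta_template(spec, K)
  sG2 <- exp(2 * theta[1L])
  sGY2 <- exp(2 * theta[1L + seq_len(tpl$n_gy)])
  if (spec$gxy == "homogeneous") sGY2 <- rep(sGY2, K)
  rp <- theta[1L + tpl$n_gy + seq_len(tpl$n_r)]
  if (spec$residual == "simple") {
    R <- diag(exp(2 * rp[1L]), K)
  } else if (spec$residual == "diagonal") {
    R <- diag(exp(2 * rp), K)
  } else {
    Lc <- matrix(0, K, K)
    diag(Lc) <- exp(rp[seq_len(K)])
    Lc[lower.tri(Lc)] <- rp[-seq_len(K)]
    R <- Lc %*% t(Lc)
  }
  list(sG2 = sG2, sGY2 = sGY2, R = R)
}

## per-genotype block covariance: obs i,j of the same genotype have
## cov = sG2 + [same year] sGY2[k] + [same tree] R[k_i, k_j]
block_V <- function(year_i, tree_i, vc) {
  m <- length(year_i)
  V <- matrix(vc$sG2, m, m)
  for (a in seq_len(m)) for (b in seq_len(m)) {
    if (year_i[a] == year_i[b]) V[a, b] <- V[a, b] + vc$sGY2[year_i[a]]
    if (tree_i[a] == tree_i[b]) V[a, b] <- V[a, b] + vc$R[year_i[a], year_i[b]]
  }
  V
}

#' Fit the phenology mixed model by REML
#'
#' Estimates the variance components of the genotype / genotype-by-year /
#' correlated-residual model by direct numerical optimization of the
#' restricted log-likelihood over a log/Cholesky parameterization, then
#' solves for fixed effects and BLUPs at the converged components.
#'
#' @param data `data.frame` with columns `tree`, `genotype`, `site`, `year`
#'   and the response named in `response`.
#' @param response response column name (default `"value"`).
#' @param spec a [mixed_model_spec()].
#' @param start optional named list with starting values `sG2`, `sGY2`
#'   (length-K), `R` (K x K).
#' @param max_iter optimizer iteration cap.
#' @return an object of class `blup_set`: genotypic BLUPs (`blups`),
#'   interaction BLUPs (`interaction`), `varcomp` (`sG2`, `sGY2`, `R`),
#'   fixed-effect estimates, REML log-likelihood, convergence flag and
#'   metadata (including the across-year means of the interaction and
#'   residual variances used by [heritability()]).
#' @export
fit_mixed <- function(data, response = "value", spec = mixed_model_spec(),
                      start = NULL, max_iter = 500) {
  stopifnot(all(c("tree", "genotype", "site", "year", response) %in%
                  names(data)))
  df <- data[!is.na(data[[response]]), , drop = FALSE]
  df$year <- factor(df$year)
  df$site <- factor(df$site)
  df$genotype <- as.character(df$genotype)
  y <- df[[response]]
  K <- nlevels(df$year)
  if (length(unique(df$genotype)) < 2L)
    pedqtl_stop("pedqtl_bad_design", "need at least 2 genotypes")
  if (max(table(df$genotype)) < 2L)
    pedqtl_stop("pedqtl_confounded",
                "every genotype observed once: genotype, interaction and residual variances are confounded")
  if (K < 2L) pedqtl_stop("pedqtl_bad_design", "need at least 2 years")
  X <- if (nlevels(df$site) >= 2L) model.matrix(~ site + year, df) else
    model.matrix(~ year, df)
  if (qr(X)$rank < ncol(X))
    pedqtl_stop("pedqtl_confounded", "singular fixed-effect design")
  ## canonical within-genotype ordering so identical designs share one
  ## covariance pattern (and one Cholesky) per likelihood evaluation
  ord <- order(df$genotype, df$year, df$tree)
  df <- df[ord, , drop = FALSE]
  y <- y[ord]
  X <- X[ord, , drop = FALSE]
  gl <- split(seq_len(nrow(df)), df$genotype)
  year_i <- as.integer(df$year)
  tree_i <- as.integer(factor(df$tree))
  pattern_of <- vapply(gl, function(ii) {
    paste(year_i[ii], match(tree_i[ii], unique(tree_i[ii])),
          apply(X[ii, , drop = FALSE], 1, paste, collapse = ","),
          collapse = ";")
  }, character(1))
  pat_groups <- split(seq_along(gl), pattern_of)
  ## per-pattern fixed data: shared design, stacked responses
  pats <- lapply(pat_groups, function(bs) {
    ii0 <- gl[[bs[1L]]]
    list(blocks = bs, ii = ii0, year = year_i[ii0],
         tree = match(tree_i[ii0], unique(tree_i[ii0])),
         Xp = X[ii0, , drop = FALSE],
         Y = vapply(bs, function(b) y[gl[[b]]], numeric(length(ii0))))
  })
  for (p in seq_along(pats)) if (is.null(dim(pats[[p]]$Y)))
    pats[[p]]$Y <- matrix(pats[[p]]$Y, ncol = length(pats[[p]]$blocks))

  pattern_chols <- function(vc) {
    lapply(pats, function(pp) {
      V <- block_V(pp$year, pp$tree, vc)
      tryCatch(chol(V), error = function(e) NULL)
    })
  }
  reml_ll <- function(theta) {
    vc <- theta_unpack(theta, spec, K)
    chs <- pattern_chols(vc)
    if (any(vapply(chs, is.null, logical(1)))) return(1e10)
    XtVX <- matrix(0, ncol(X), ncol(X))
    XtVy <- numeric(ncol(X))
    logdet <- 0; yVy <- 0
    for (p in seq_along(pats)) {
      pp <- pats[[p]]; ch <- chs[[p]]; B <- length(pp$blocks)
      logdet <- logdet + B * 2 * sum(log(diag(ch)))
      ViX <- backsolve(ch, forwardsolve(t(ch), pp$Xp))
      ViY <- backsolve(ch, forwardsolve(t(ch), pp$Y))
      XtVX <- XtVX + B * crossprod(pp$Xp, ViX)
      XtVy <- XtVy + crossprod(pp$Xp, rowSums(ViY))
      yVy <- yVy + sum(pp$Y * ViY)
    }
    chA <- tryCatch(chol(XtVX), error = function(e) NULL)
    if (is.null(chA)) return(1e10)
    beta <- backsolve(chA, forwardsolve(t(chA), XtVy))
    quad <- yVy - sum(beta * XtVy)  # GLS identity at the minimizing beta
    0.5 * (logdet + 2 * sum(log(diag(chA))) + quad)  # negative REML ll
  }

  tpl <- theta_template(spec, K)
  if (is.null(start)) {
    gm <- tapply(y, df$genotype, mean)
    v_between <- max(var(gm), 1e-3)
    v_within <- max(var(y - gm[df$genotype]), 1e-3)
    theta0 <- c(log(sqrt(v_between / 2)),
                rep(log(sqrt(v_within / 4)), tpl$n_gy),
                if (spec$residual == "unstructured")
                  c(rep(log(sqrt(v_within / 2)), K),
                    rep(0, K * (K - 1L) %/% 2L))
                else rep(log(sqrt(v_within / 2)), tpl$n_r))
  } else {
    sdG <- sqrt(start$sG2)
    sdGY <- sqrt(if (spec$gxy == "by_year") start$sGY2 else
      mean(start$sGY2))
    theta0 <- c(log(sdG), log(sdGY),
                if (spec$residual == "simple") log(sqrt(mean(diag(start$R))))
                else if (spec$residual == "diagonal")
                  log(sqrt(diag(start$R)))
                else {
                  Lc <- t(chol(start$R))
                  c(log(diag(Lc)), Lc[lower.tri(Lc)])
                })
  }
  opt <- optim(theta0, reml_ll, method = "Nelder-Mead",
               control = list(maxit = max_iter * 10, reltol = 1e-10))
  opt2 <- optim(opt$par, reml_ll, method = "BFGS",
                control = list(maxit = max_iter, reltol = 1e-10))
  if (opt2$value <= opt$value) opt <- opt2
  vc <- theta_unpack(opt$par, spec, K)

  ## GLS fixed effects and BLUPs at the converged components
  chs <- pattern_chols(vc)
  XtVX <- matrix(0, ncol(X), ncol(X)); XtVy <- numeric(ncol(X))
  for (p in seq_along(pats)) {
    pp <- pats[[p]]; ch <- chs[[p]]; B <- length(pp$blocks)
    ViX <- backsolve(ch, forwardsolve(t(ch), pp$Xp))
    ViY <- backsolve(ch, forwardsolve(t(ch), pp$Y))
    XtVX <- XtVX + B * crossprod(pp$Xp, ViX)
    XtVy <- XtVy + crossprod(pp$Xp, rowSums(ViY))
  }
  beta <- solve(XtVX, XtVy)
  gnames <- names(gl)
  G_blup <- setNames(numeric(length(gl)), gnames)
  GY_blup <- matrix(0, length(gl), K,
                    dimnames = list(gnames, levels(df$year)))
  for (p in seq_along(pats)) {
    pp <- pats[[p]]; ch <- chs[[p]]
    Rm <- pp$Y - as.vector(pp$Xp %*% beta)
    ViR <- backsolve(ch, forwardsolve(t(ch), Rm))
    G_blup[pp$blocks] <- vc$sG2 * colSums(ViR)
    for (k in seq_len(K)) {
      sel <- pp$year == k
      if (any(sel))
        GY_blup[pp$blocks, k] <- vc$sGY2[k] *
          colSums(ViR[sel, , drop = FALSE])
    }
  }
  inter <- lapply(seq_along(gl), function(b) data.frame(
    genotype = gnames[b], year = levels(df$year), GxY_blup = GY_blup[b, ],
    stringsAsFactors = FALSE))
  blups <- data.frame(genotype = gnames, G_blup = unname(G_blup),
                      stringsAsFactors = FALSE)
  interaction <- do.call(rbind, inter)
  if (isTRUE(spec$standardize)) {
    blups$G_blup <- as.numeric(scale(blups$G_blup))
    interaction$GxY_blup <- stats::ave(interaction$GxY_blup,
                                       interaction$year,
                                       FUN = function(v) as.numeric(scale(v)))
  }
  structure(list(
    blups = blups, interaction = interaction,
    varcomp = list(sG2 = vc$sG2, sGY2 = setNames(vc$sGY2, levels(df$year)),
                   R = vc$R),
    beta = setNames(as.numeric(beta), colnames(X)),
    logLik = -opt$value, convergence = opt$convergence == 0,
    meta = list(n = nrow(df), k = K, n_genotypes = length(gl),
                sGY2_mean = mean(vc$sGY2), se2_mean = mean(diag(vc$R)),
                spec = spec)),
    class = "blup_set")
}

#' Broad-sense heritability of genotype means
#'
#' `h2 = sG2 / (sG2 + sGY2/k + se2/n)` where `sGY2` and `se2` are the
#' across-year means of the interaction and residual variances, `k` the
#' number of years and `n` the total number of observations.
#'
#' @param sG2 genotypic variance.
#' @param sGY2 mean genotype-by-year interaction variance.
#' @param se2 mean residual variance.
#' @param k number of years.
#' @param n total number of observations.
#' @return heritability in `[0, 1]`.
#' @examples
#' heritability(2, 3, 4, 3, 100)  # 0.6579
#' @export
heritability <- function(sG2, sGY2, se2, k, n) {
  stopifnot(sG2 >= 0, sGY2 >= 0, se2 >= 0, k >= 1, n >= 1)
  den <- sG2 + sGY2 / k + se2 / n
  if (den == 0)
    pedqtl_stop("pedqtl_degenerate", "all variance components are zero")
  sG2 / den
}

#' Fit all traits on all site subsets
#'
#' Runs [fit_mixed()] for each trait column over the multisite set and the
#' per-site complementary subsets, mirroring the multisite / Montpellier /
#' Angers analysis scheme.
#'
#' @param traits a `trait_table` from [derive_traits()] (or any data frame
#'   with `tree`, `genotype`, `site`, `year` and the trait columns).
#' @param subsets named list of character family/site filters: each element
#'   is a character vector of site ids to keep (`NULL` = all).
#' @param trait_names trait columns to fit.
#' @param spec a [mixed_model_spec()].
#' @return nested list `result[[subset]][[trait]]`, each a `blup_set` with
#'   an added `heritability` element.
#' @export
run_trait_analyses <- function(traits,
                               subsets = list(multisite = NULL,
                                              Mtp = "Mtp", Ang = "Ang"),
                               trait_names = c("BB_CD", "BB_GDH",
                                               "Delta_GDH"),
                               spec = mixed_model_spec()) {
  out <- list()
  for (s in names(subsets)) {
    keep <- if (is.null(subsets[[s]])) rep(TRUE, nrow(traits)) else
      traits$site %in% subsets[[s]]
    sub <- traits[keep, , drop = FALSE]
    if (!nrow(sub)) pedqtl_stop("pedqtl_empty_subset", "subset %s empty", s)
    out[[s]] <- list()
    for (tr in trait_names) {
      fit <- fit_mixed(sub, response = tr, spec = spec)
      fit$heritability <- heritability(fit$varcomp$sG2,
                                       fit$meta$sGY2_mean,
                                       fit$meta$se2_mean,
                                       fit$meta$k, fit$meta$n)
      out[[s]][[tr]] <- fit
    }
  }
  out
}
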