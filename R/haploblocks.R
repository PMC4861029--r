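## Haploblocks: 1 cM map segmentation, pedigree-based phasing with parental
## origins, haploblock allele coding and double-recombination QC.

#' Segment a genetic map into haploblocks
#'
#' Divides each linkage group into successive half-open `[k*w, (k+1)*w)`
#' segments of width `w` cM (0-based origin) and assigns every locus to the
#' segment containing its position.
#'
#' @param map a [genetic_map()].
#' @param width segment width in cM (default 1).
#' @return an object of class `haploblock_set`: list with `blocks`
#'   (`block`, `lg`, `start`, `end`, `n_loci`) and `locus_block`, the block
#'   id of every map locus.
#' @export
segment_map <- function(map, width = 1) {
  stopifnot(width > 0)
  if (!nrow(map)) pedqtl_stop("pedqtl_bad_map", "empty map")
  locus_block <- character(nrow(map))
  blocks <- list()
  for (g in unique(map$lg)) {
    ii <- which(map$lg == g)
    n_blk <- floor(max(map$pos[ii]) / width) + 1L
    start <- (seq_len(n_blk) - 1L) * width
    ids <- sprintf("LG%02d_B%03d", g, seq_len(n_blk))
    k <- floor(map$pos[ii] / width) + 1L
    locus_block[ii] <- ids[k]
    blocks[[length(blocks) + 1L]] <- data.frame(
      block = ids, lg = g, start = start, end = start + width,
      n_loci = tabulate(k, n_blk), stringsAsFactors = FALSE)
  }
  structure(list(blocks = do.call(rbind, blocks), locus_block = locus_block,
                 width = width, map = map),
            class = "haploblock_set")
}

#' Collapse phased genotypes to unphased 0/1/2 dosages
#'
#' @param genotypes a [drop_gametes()] result.
#' @return integer matrix (individual x locus) counting allele 1.
#' @export
unphase <- function(genotypes) {
  genotypes$hap_m + genotypes$hap_p
}

## Mendelian feasibility of (child, mother, father) dosages at one locus;
## NA parents are unconstrained
mendel_ok <- function(gc, gm, gf) {
  can_give <- function(g, a) is.na(g) | (a == 0 & g <= 1) | (a == 1 & g >= 1)
  ok0 <- can_give(gm, 0) & can_give(gf, 0)
  ok2 <- can_give(gm, 1) & can_give(gf, 1)
  ok1 <- (can_give(gm, 0) & can_give(gf, 1)) |
    (can_give(gm, 1) & can_give(gf, 0))
  ifelse(is.na(gc), TRUE, ifelse(gc == 0, ok0, ifelse(gc == 2, ok2, ok1)))
}

## transmitted allele from one parent, or NA when ambiguous
transmitted <- function(gc, gp, go) {
  ## gc child dosage, gp this parent, go other parent
  out <- rep(NA_integer_, length(gc))
  out[!is.na(gc) & gc == 0] <- 0L
  out[!is.na(gc) & gc == 2] <- 1L
  het <- !is.na(gc) & gc == 1
  out[het & !is.na(gp) & gp == 0] <- 0L
  out[het & !is.na(gp) & gp == 2] <- 1L
  out[het & is.na(out) & !is.na(go) & go == 0] <- 1L
  out[het & is.na(out) & !is.na(go) & go == 2] <- 0L
  out
}

## chain relative phase of a parent's heterozygous loci along one LG from
## the co-transmission pattern of its gametes (minimum-recombination
## linkage); returns homolog-1 allele per het locus, anchored to `anchor`
## (named 0/1 vector of known homolog-1 alleles) where available
chain_phase <- function(het_idx, pos, gametes, anchor = NULL) {
  m <- length(het_idx)
  if (!m) return(integer(0))
  h <- rep(NA_integer_, m)
  rel <- rep(NA_integer_, m - 1L)  # 1: same allele on homolog 1; 0: opposite
  if (m > 1L) for (j in seq_len(m - 1L)) {
    a <- gametes[, j]; b <- gametes[, j + 1L]
    ok <- !is.na(a) & !is.na(b)
    if (any(ok)) {
      same <- sum(a[ok] == b[ok]); diff <- sum(a[ok] != b[ok])
      if (same != diff) rel[j] <- as.integer(same > diff)
    }
  }
  ## segment-wise assignment: anchor each chained segment if it contains a
  ## locus with known phase, else pick an arbitrary deterministic anchor
  seg_start <- 1L
  while (seg_start <= m) {
    seg_end <- seg_start
    while (seg_end < m && !is.na(rel[seg_end])) seg_end <- seg_end + 1L
    seg <- seg_start:seg_end
    val <- rep(NA_integer_, length(seg))
    val[1L] <- 1L
    if (length(seg) > 1L) for (j in 2:length(seg))
      val[j] <- if (rel[seg[j - 1L]] == 1L) val[j - 1L] else 1L - val[j - 1L]
    flip <- NA
    if (!is.null(anchor)) {
      hit <- which(!is.na(anchor[seg]))
      if (length(hit)) {
        votes <- anchor[seg][hit] == val[hit]
        flip <- mean(votes) < 0.5
      }
    }
    if (is.na(flip)) flip <- FALSE
    h[seg] <- if (flip) 1L - val else val
    seg_start <- seg_end + 1L
  }
  h
}

## repair the homolog-1 assignment of a parent along one linkage group:
## if the majority of gametes appear to switch origin across a junction,
## the relative phase across that junction is wrong (or an unanchored
## segment starts there) and the suffix is flipped. Votes pool every
## gamete whose nearest informative loci bracket the junction (span <=
## `span` loci), so single mis-chained adjacencies are outvoted.
repair_phase <- function(h, gam, span = 5L) {
  m <- length(h)
  if (m < 2L || is.null(dim(gam)) || nrow(gam) == 0L) return(h)
  ## per-gamete consecutive informative pairs with their switch status
  pair_c1 <- pair_c2 <- integer(0)
  pair_sw <- logical(0)
  for (r in seq_len(nrow(gam))) {
    inf <- which(!is.na(gam[r, ]))
    if (length(inf) < 2L) next
    o <- as.integer(gam[r, inf] != h[inf])  # 0 = homolog 1, 1 = homolog 2
    keep <- diff(inf) <= span
    pair_c1 <- c(pair_c1, inf[-length(inf)][keep])
    pair_c2 <- c(pair_c2, inf[-1L][keep])
    pair_sw <- c(pair_sw, (diff(o) != 0L)[keep])
  }
  if (!length(pair_c1)) return(h)
  flipped <- rep(FALSE, m)
  for (j in seq_len(m - 1L)) {
    sel <- pair_c1 <= j & pair_c2 > j
    if (sum(sel) < 3L) next
    eff <- pair_sw[sel] != (flipped[pair_c1[sel]] != flipped[pair_c2[sel]])
    if (mean(eff) > 0.5) flipped[(j + 1L):m] <- !flipped[(j + 1L):m]
  }
  ifelse(flipped, 1L - h, h)
}

#' Phase genotypes through a pedigree
#'
#' Trio-deterministic phasing first: a child's maternal/paternal alleles are
#' resolved wherever the transmitted allele is unambiguous (homozygous
#' child, or heterozygous child with an informative parent pair). Parental
#' origins (which of the parent's two homologs was transmitted) are then
#' assigned at loci where the parent is heterozygous, with the parent's own
#' homolog labels taken from its trio phase where available and otherwise
#' reconstructed by minimum-recombination linkage over its gametes (the
#' label of such reconstructed homologs is arbitrary per parent and linkage
#' group, flagged via `anchored`). Mendelian violations are reported
#' per locus and the offending trio-locus is masked; loci violating in more
#' than `mask_families` families are masked genome-wide. Unresolvable sites
#' stay `NA`, never guessed.
#'
#' @param geno integer dosage matrix (individual x locus, values 0/1/2, `NA`
#'   allowed), rownames = pedigree ids, colnames = map markers.
#' @param pedigree a [simulate_pedigree()] result.
#' @param map a [genetic_map()].
#' @param blocks optional [segment_map()] result (default 1 cM blocks).
#' @param mask_families mask a locus genome-wide when Mendelian errors hit
#'   more than this many families (default 2).
#' @return an object of class `phased_haploblocks`: locus-level `hap_m`,
#'   `hap_p` (0/1/`NA`), `origin_m`, `origin_p` (1 = parent's homolog 1,
#'   2 = homolog 2, `NA` unknown), block-level allele codes
#'   `block_alleles_m/p` and origins `block_origin_m/p`, the Mendelian
#'   report, and the `anchored` flags.
#' @export
phase_pedigree <- function(geno, pedigree, map, blocks = segment_map(map),
                           mask_families = 2) {
  n <- nrow(pedigree); L <- nrow(map)
  stopifnot(nrow(geno) == n, ncol(geno) == L)
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  geno[!pedigree$genotyped, ] <- NA_integer_
  pidx <- pedigree_index(pedigree)

  ## Mendelian QC
  viol <- matrix(FALSE, n, L)
  for (i in seq_len(n)) {
    if (is.na(pidx$sire[i]) && is.na(pidx$dam[i])) next
    gm <- if (!is.na(pidx$dam[i])) geno[pidx$dam[i], ] else
      rep(NA_integer_, L)
    gf <- if (!is.na(pidx$sire[i])) geno[pidx$sire[i], ] else
      rep(NA_integer_, L)
    viol[i, ] <- !mendel_ok(geno[i, ], gm, gf)
  }
  fam_hit <- sapply(seq_len(L), function(j) {
    length(unique(stats::na.omit(pedigree$family[viol[, j]])))
  })
  masked_loci <- fam_hit > mask_families
  mendel <- data.frame(marker = map$marker, lg = map$lg, pos = map$pos,
                       n_violations = colSums(viol),
                       families_affected = fam_hit, masked = masked_loci,
                       stringsAsFactors = FALSE)
  work <- geno
  work[, masked_loci] <- NA_integer_
  work[viol] <- NA_integer_   # mask the offending trio-locus

  dn <- list(pedigree$id, map$marker)
  hap_m <- hap_p <- matrix(NA_integer_, n, L, dimnames = dn)
  origin_m <- origin_p <- matrix(NA_integer_, n, L, dimnames = dn)
  ## founders/base sides: homozygous loci are trivially phased
  for (i in seq_len(n)) {
    hom <- !is.na(work[i, ]) & work[i, ] != 1L
    if (is.na(pidx$dam[i]) && is.na(pidx$sire[i])) {
      hap_m[i, hom] <- hap_p[i, hom] <- work[i, hom] %/% 2L
    }
  }
  ## trio-deterministic child phase
  for (i in seq_len(n)) {
    if (is.na(pidx$dam[i]) && is.na(pidx$sire[i])) next
    gm <- if (!is.na(pidx$dam[i])) work[pidx$dam[i], ] else
      rep(NA_integer_, L)
    gf <- if (!is.na(pidx$sire[i])) work[pidx$sire[i], ] else
      rep(NA_integer_, L)
    hap_m[i, ] <- transmitted(work[i, ], gm, gf)
    hap_p[i, ] <- transmitted(work[i, ], gf, gm)
  }

  ## parental origins: need the parent's homolog labels at its het loci
  anchored <- list()
  parents <- sort(unique(stats::na.omit(c(pidx$sire, pidx$dam))))
  for (p in parents) {
    children_m <- which(!is.na(pidx$dam) & pidx$dam == p)   # p transmits hap as dam
    children_p <- which(!is.na(pidx$sire) & pidx$sire == p)
    kids <- c(children_m, children_p)
    side_m <- c(rep(TRUE, length(children_m)), rep(FALSE, length(children_p)))
    for (g in unique(map$lg)) {
      ii <- which(map$lg == g)
      het <- ii[!is.na(work[p, ii]) & work[p, ii] == 1L]
      if (!length(het)) next
      ## gametes: transmitted alleles from p to each child at p's het loci
      gam <- matrix(NA_integer_, length(kids), length(het))
      for (ci in seq_along(kids)) {
        gam[ci, ] <- if (side_m[ci]) hap_m[kids[ci], het] else
          hap_p[kids[ci], het]
      }
      anchor <- hap_m[p, het]   # trio phase of the parent itself, if any
      anch_known <- any(!is.na(anchor))
      h1 <- chain_phase(het, map$pos[het], gam, anchor)
      h1 <- repair_phase(h1, gam)
      anchored[[paste0(pedigree$id[p], ":LG", g)]] <- anch_known
      ## record the parent's phase at loci reconstructed by linkage
      fill <- is.na(hap_m[p, het])
      hap_m[p, het[fill]] <- h1[fill]
      hap_p[p, het[fill]] <- 1L - h1[fill]
      ## origins of each gamete at p's het loci
      for (ci in seq_along(kids)) {
        x <- gam[ci, ]
        o <- ifelse(is.na(x), NA_integer_, ifelse(x == h1, 1L, 2L))
        if (side_m[ci]) origin_m[kids[ci], het] <- o else
          origin_p[kids[ci], het] <- o
      }
    }
  }

  ## block-level allele codes: first-seen order, founders first
  bl <- blocks$blocks
  nb <- nrow(bl)
  block_alleles_m <- block_alleles_p <-
    matrix(NA_integer_, n, nb, dimnames = list(pedigree$id, bl$block))
  founder_first <- order(!(is.na(pidx$sire) & is.na(pidx$dam)))
  for (b in seq_len(nb)) {
    jj <- which(blocks$locus_block == bl$block[b])
    if (!length(jj)) next
    seen <- character(0)
    for (i in founder_first) {
      for (side in c("m", "p")) {
        hp <- if (side == "m") hap_m[i, jj] else hap_p[i, jj]
        if (anyNA(hp)) next
        key <- paste(hp, collapse = "")
        if (!key %in% seen) seen <- c(seen, key)
        code <- match(key, seen)
        if (side == "m") block_alleles_m[i, b] <- code else
          block_alleles_p[i, b] <- code
      }
    }
  }
  ## block-level origins: majority of member-locus origins, ties -> NA
  consense <- function(o) {
    o <- o[!is.na(o)]
    if (!length(o)) return(NA_integer_)
    t1 <- sum(o == 1L); t2 <- sum(o == 2L)
    if (t1 == t2) NA_integer_ else if (t1 > t2) 1L else 2L
  }
  block_origin_m <- block_origin_p <-
    matrix(NA_integer_, n, nb, dimnames = list(pedigree$id, bl$block))
  for (b in seq_len(nb)) {
    jj <- which(blocks$locus_block == bl$block[b])
    if (!length(jj)) next
    block_origin_m[, b] <- apply(origin_m[, jj, drop = FALSE], 1, consense)
    block_origin_p[, b] <- apply(origin_p[, jj, drop = FALSE], 1, consense)
  }
  structure(list(hap_m = hap_m, hap_p = hap_p, origin_m = origin_m,
                 origin_p = origin_p, block_alleles_m = block_alleles_m,
                 block_alleles_p = block_alleles_p,
                 block_origin_m = block_origin_m,
                 block_origin_p = block_origin_p, blocks = blocks,
                 map = map, pedigree = pedigree, mendel = mendel,
                 anchored = unlist(anchored)),
            class = "phased_haploblocks")
}

#' Count double recombinants in one origin vector
#'
#' A double recombinant is an origin pattern X, Y, X across three
#' consecutive informative positions spanning at most `window` cM.
#'
#' @param origin integer origins (1/2, `NA` = uninformative) along one
#'   linkage group.
#' @param pos positions in cM, same length.
#' @param window maximum span in cM for a call (default 5).
#' @return integer count.
#' @export
double_recombinants <- function(origin, pos, window = 5) {
  keep <- !is.na(origin)
  o <- origin[keep]; p <- pos[keep]
  k <- length(o)
  if (k < 3L) return(0L)
  i <- seq_len(k - 2L)
  sum(o[i] == o[i + 2L] & o[i] != o[i + 1L] & (p[i + 2L] - p[i]) <= window)
}

#' Double-recombination QC at marker and haploblock resolution
#'
#' Scans every informative meiosis (each parent-child transmission) on every
#' linkage group for X-Y-X origin patterns within `window` cM, at the marker
#' level and after aggregation to haploblock origins.
#'
#' @param phased a [phase_pedigree()] result.
#' @param window maximum span in cM (default 5).
#' @return list with `per_meiosis` (`individual`, `side`, `lg`, marker- and
#'   block-level counts) and `rates`: the fraction of (meiosis, LG)
#'   combinations affected at each resolution.
#' @export
count_double_recombinants <- function(phased, window = 5) {
  ped <- phased$pedigree
  map <- phased$map
  bl <- phased$blocks$blocks
  pidx <- pedigree_index(ped)
  rows <- list()
  for (i in seq_len(nrow(ped))) {
    for (side in c("m", "p")) {
      par <- if (side == "m") pidx$dam[i] else pidx$sire[i]
      if (is.na(par)) next
      om <- if (side == "m") phased$origin_m[i, ] else phased$origin_p[i, ]
      ob <- if (side == "m") phased$block_origin_m[i, ] else
        phased$block_origin_p[i, ]
      for (g in unique(map$lg)) {
        jj <- which(map$lg == g)
        bb <- which(bl$lg == g)
        rows[[length(rows) + 1L]] <- data.frame(
          individual = ped$id[i], side = side, lg = g,
          marker_dr = double_recombinants(om[jj], map$pos[jj], window),
          block_dr = double_recombinants(
            ob[bb], (bl$start[bb] + bl$end[bb]) / 2, window),
          stringsAsFactors = FALSE)
      }
    }
  }
  per <- do.call(rbind, rows)
  list(per_meiosis = per,
       rates = c(marker = mean(per$marker_dr > 0),
                 haploblock = mean(per$block_dr > 0)))
}
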