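#' @include AllClasses.R phylo-core.R
NULL

# indicator matrices (sites x taxa) for A, C, G, T; anything else (gaps,
# ambiguity codes) is excluded pairwise
.baseIndicators <- function(sites) {
  sites <- toupper(sites)
  out <- list(A = t(sites == "A") * 1, C = t(sites == "C") * 1,
              G = t(sites == "G") * 1, T = t(sites == "T") * 1)
  out$V <- out$A + out$C + out$G + out$T
  out$R <- out$A + out$G
  out$Y <- out$C + out$T
  out
}

# all pairwise count matrices needed by the TN93 closed form, optionally
# with per-site resampling weights w; indicators are sites x taxa so the
# weights recycle down the columns without any rep()
.tn93Counts <- function(ind, w = NULL) {
  X <- ind
  sA <- if (is.null(w)) X$A else X$A * w
  sC <- if (is.null(w)) X$C else X$C * w
  sG <- if (is.null(w)) X$G else X$G * w
  sT <- if (is.null(w)) X$T else X$T * w
  V <- X$V
  R <- X$R
  Y <- X$Y
  sV <- if (is.null(w)) V else sA + sC + sG + sT
  n <- crossprod(sV, V)
  P1 <- crossprod(sA, X$G) + crossprod(sG, X$A)
  P2 <- crossprod(sC, X$T) + crossprod(sT, X$C)
  Q <- crossprod(sA + sG, Y) + crossprod(sC + sT, R)
  fr <- lapply(list(A = sA, C = sC, G = sG, T = sT), function(b) {
    m <- crossprod(b, V)
    m + t(m)
  })
  list(n = n, P1 = P1, P2 = P2, Q = Q, fA = fr$A, fC = fr$C, fG = fr$G,
       fT = fr$T)
}

# evaluate the TN93 closed form on count matrices; returns list(d, valid, n)
.tn93FromCounts <- function(cnt, minSites = 20, cap = 5) {
  n <- cnt$n
  nn <- pmax(n, 1)
  P1 <- cnt$P1 / nn; P2 <- cnt$P2 / nn; Q <- cnt$Q / nn
  gA <- cnt$fA / (2 * nn); gC <- cnt$fC / (2 * nn)
  gG <- cnt$fG / (2 * nn); gT <- cnt$fT / (2 * nn)
  gR <- gA + gG; gY <- gC + gT
  k1 <- 2 * gA * gG / pmax(gR, .Machine$double.eps)
  k2 <- 2 * gC * gT / pmax(gY, .Machine$double.eps)
  k3 <- 2 * (gR * gY - gA * gG * gY / pmax(gR, .Machine$double.eps)
             - gC * gT * gR / pmax(gY, .Machine$double.eps))
  w1 <- 1 - P1 / pmax(k1, .Machine$double.eps) - Q / (2 * pmax(gR, .Machine$double.eps))
  w2 <- 1 - P2 / pmax(k2, .Machine$double.eps) - Q / (2 * pmax(gY, .Machine$double.eps))
  w3 <- 1 - Q / (2 * pmax(gR * gY, .Machine$double.eps))
  sat <- (w1 <= 0 & k1 > 0) | (w2 <= 0 & k2 > 0) | (w3 <= 0)
  t1 <- t2 <- t3 <- array(0, dim(w1))
  i1 <- k1 > 0 & w1 > 0
  i2 <- k2 > 0 & w2 > 0
  i3 <- w3 > 0
  t1[i1] <- -k1[i1] * log(w1[i1])
  t2[i2] <- -k2[i2] * log(w2[i2])
  t3[i3] <- -k3[i3] * log(w3[i3])
  d <- t1 + t2 + t3
  d[sat] <- cap
  valid <- !sat & (n >= minSites)
  diag(d) <- 0
  diag(valid) <- TRUE
  list(d = d, valid = valid, n = n)
}

#' TN93 distance matrix with pairwise deletion
#'
#' Evaluates the Tamura-Nei (1993) closed-form distance for every sequence
#' pair, using the empirical base frequencies of the pair and the two
#' transition classes. Sites with a gap or ambiguity in either sequence are
#' excluded pairwise. Saturated pairs (non-positive logarithm argument) are
#' capped at \code{cap} and flagged invalid; pairs with fewer than
#' \code{minSites} comparable sites are flagged invalid.
#'
#' @param sites character site matrix (rows = taxa) as produced by
#'   \code{\link{selectCodonPositions}}, or a \code{CodonAlignment} (all
#'   retained positions are used).
#' @param minSites minimum number of comparable sites per pair.
#' @param cap distance assigned to saturated pairs.
#' @return a \code{DistanceMatrix}.
#' @export
tn93Matrix <- function(sites, minSites = 20, cap = 5) {
  if (is(sites, "CodonAlignment")) sites <- selectCodonPositions(sites, "Inc3rd")
  ind <- .baseIndicators(sites)
  res <- .tn93FromCounts(.tn93Counts(ind), minSites = minSites, cap = cap)
  lab <- rownames(sites)
  dimnames(res$d) <- dimnames(res$valid) <- dimnames(res$n) <- list(lab, lab)
  new("DistanceMatrix", d = res$d, valid = res$valid,
      sites = matrix(as.integer(round(res$n)), nrow(res$n),
                     dimnames = dimnames(res$n)))
}

#' TN93 distance between two aligned sequences
#'
#' @param seqI,seqJ aligned nucleotide sequences (equal-length character
#'   strings or character vectors of single sites).
#' @param minSites,cap see \code{\link{tn93Matrix}}.
#' @return the distance (numeric); attribute \code{valid} is FALSE for
#'   saturated pairs or pairs with too few comparable sites.
#' @export
tn93Distance <- function(seqI, seqJ, minSites = 20, cap = 5) {
  tochar <- function(s) if (length(s) == 1L) strsplit(s, "")[[1L]] else s
  a <- tochar(seqI); b <- tochar(seqJ)
  if (length(a) != length(b)) stop("sequences must have equal length")
  m <- rbind(a, b)
  dm <- tn93Matrix(m, minSites = minSites, cap = cap)
  structure(dm@d[1L, 2L], valid = dm@valid[1L, 2L])
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via \code{ape::nj}). Negative branch
#' lengths are clamped to zero with the deficit added to the sibling branch.
#' The result is unrooted (basal trifurcation).
#'
#' @param dm a \code{DistanceMatrix} (all pairs must be valid) or a plain
#'   symmetric matrix.
#' @return an unrooted \code{phylo} object.
#' @export
njTree <- function(dm) {
  if (is(dm, "DistanceMatrix")) {
    bad <- which(!dm@valid & upper.tri(dm@valid), arr.ind = TRUE)
    if (nrow(bad)) {
      lab <- rownames(dm@d)
      pairs <- apply(bad, 1L, function(ij)
        paste0(lab[ij[1L]], "/", lab[ij[2L]]))
      stop("invalid (saturated or sparse) pairs: ",
           paste(pairs, collapse = ", "))
    }
    dm <- dm@d
  }
  if (nrow(dm) < 3L) stop("need at least three taxa")
  phy <- ape::nj(stats::as.dist(dm))
  .fixNegativeBranches(phy)
}

# clamp negative branch lengths at zero, moving the deficit to a sibling
.fixNegativeBranches <- function(phy) {
  repeat {
    neg <- which(phy$edge.length < -1e-14)
    if (!length(neg)) break
    i <- neg[which.min(phy$edge.length[neg])]
    parent <- phy$edge[i, 1L]
    sibs <- setdiff(which(phy$edge[, 1L] == parent), i)
    deficit <- -phy$edge.length[i]
    phy$edge.length[i] <- 0
    if (length(sibs)) {
      j <- sibs[which.min(phy$edge[sibs, 2L])]
      phy$edge.length[j] <- phy$edge.length[j] + deficit
    }
  }
  phy$edge.length[phy$edge.length < 0] <- 0
  phy
}

#' Neighbor-joining with nonparametric bootstrap supports
#'
#' Builds the point-estimate NJ tree from TN93 distances, then resamples
#' alignment columns with replacement (whole codons as the unit when the
#' site matrix carries codon structure, single sites otherwise), rebuilds
#' the NJ tree per replicate, and scores each internal edge of the point
#' tree by the percentage of replicates containing its bipartition.
#' Degenerate replicates (all sequences identical, or saturated pairs) are
#' skipped with a warning and the denominator adjusted. Deterministic given
#' \code{config@rngSeed}.
#'
#' @param sites character site matrix from \code{\link{selectCodonPositions}}.
#' @param config a \code{PipelineConfig} (\code{nBootstrap},
#'   \code{resampleUnit}, \code{rngSeed}).
#' @param speciesMap optional gene-to-species map for the resulting tree.
#' @return an unrooted \code{GeneTree} with supports in [0, 100].
#' @export
bootstrapSupport <- function(sites, config = pipelineConfig(),
                             speciesMap = NULL) {
  ind <- .baseIndicators(sites)
  point <- .tn93FromCounts(.tn93Counts(ind))
  if (!all(point$valid))
    stop("point-estimate distances contain invalid pairs")
  dpoint <- point$d
  dimnames(dpoint) <- list(rownames(sites), rownames(sites))
  ptree <- njTree(dpoint)

  codIdx <- attr(sites, "codonIndex")
  if (config@resampleUnit == "site" || is.null(codIdx))
    codIdx <- seq_len(ncol(sites))
  units <- unique(codIdx)
  nu <- length(units)

  oldseed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(oldseed)) assign(".Random.seed", oldseed, envir = globalenv())
  }, add = TRUE)
  set.seed(config@rngSeed)

  btrees <- vector("list", config@nBootstrap)
  skipped <- 0L
  for (b in seq_len(config@nBootstrap)) {
    cnt <- tabulate(sample.int(nu, nu, replace = TRUE), nbins = nu)
    w <- cnt[match(codIdx, units)]
    res <- .tn93FromCounts(.tn93Counts(ind, w = w))
    if (!all(res$valid) || all(res$d[upper.tri(res$d)] == 0)) {
      skipped <- skipped + 1L
      next
    }
    db <- res$d
    dimnames(db) <- dimnames(dpoint)
    btrees[[b]] <- njTree(db)
  }
  btrees <- Filter(Negate(is.null), btrees)
  if (skipped > 0L)
    warning(skipped, " degenerate bootstrap replicate(s) skipped")
  if (!length(btrees)) stop("all bootstrap replicates were degenerate")
  class(btrees) <- "multiPhylo"
  counts <- ape::prop.clades(ptree, btrees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  ntip <- length(ptree$tip.label)
  support <- rep(NA_real_, ntip + ptree$Nnode)
  support[ntip + seq_len(ptree$Nnode)] <- 100 * counts / length(btrees)
  support[ntip + 1L] <- NA_real_  # basal trifurcation: trivial split
  GeneTree(ptree, speciesMap = speciesMap, support = support,
           unrooted = TRUE)
}
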