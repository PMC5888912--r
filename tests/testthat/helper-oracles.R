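# Independent oracles and random-instance generators used across the suite.
# These deliberately avoid the package's internal algorithms: reconciliation
# costs are minimised by explicit enumeration of event histories, topology
# searches by explicit enumeration of resolutions, and TN93 values are
# cross-checked against ape's implementation.

# ---- species/gene tree instance generators --------------------------------

randomSpeciesTree <- function(nSpecies, branchLength = 1) {
  labels <- LETTERS[seq_len(nSpecies)]
  phy <- ape::rtree(nSpecies, tip.label = sample(labels))
  phy$edge.length <- rep(branchLength, nrow(phy$edge))
  SpeciesTree(phy, as.list(stats::setNames(labels, tolower(labels))))
}

randomGeneTreePhylo <- function(nGenes, speciesLabels) {
  sp <- sample(speciesLabels, nGenes, replace = TRUE)
  tips <- paste0(sp, "|g", seq_len(nGenes))
  ape::rtree(nGenes, tip.label = sample(tips))
}

# ---- brute-force duplication-loss cost over all event histories -----------

# tree tables for enumeration
.oracleStTables <- function(stPhylo) {
  n <- stPhylo$Nnode + length(stPhylo$tip.label)
  par <- integer(n)
  par[stPhylo$edge[, 2L]] <- stPhylo$edge[, 1L]
  depth <- integer(n)
  root <- length(stPhylo$tip.label) + 1L
  ord <- stPhylo$edge[order(stPhylo$edge[, 1L]), , drop = FALSE]
  # simple repeated relaxation (small trees)
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(stPhylo$edge))) {
      a <- stPhylo$edge[i, 1L]; b <- stPhylo$edge[i, 2L]
      if (depth[b] != depth[a] + 1L) { depth[b] <- depth[a] + 1L; changed <- TRUE }
    }
    if (!changed) break
  }
  anc <- matrix(FALSE, n, n)  # anc[i, j]: i ancestor-or-equal of j
  for (j in seq_len(n)) {
    v <- j
    repeat {
      anc[v, j] <- TRUE
      if (v == root) break
      v <- par[v]
    }
  }
  list(par = par, depth = depth, anc = anc, root = root, n = n)
}

.oracleLca <- function(tb, a, b) {
  while (a != b) {
    if (tb$depth[a] >= tb$depth[b]) a <- tb$par[a] else b <- tb$par[b]
  }
  a
}

# minimum D+L cost over all valid mappings of internal gene-tree nodes to
# species-tree nodes (each mapping corresponds to an event history: a node
# is a speciation iff it maps onto the join of its children's mappings with
# both children strictly below; every other node is a duplication; an edge
# into a child loses one species branch per step, minus one after a
# speciation)
oracleHistoryMinCost <- function(gtPhylo, map, stPhylo, dupCost = 1,
                                 lossCost = 1) {
  tb <- .oracleStTables(stPhylo)
  ntip <- length(gtPhylo$tip.label)
  n <- ntip + gtPhylo$Nnode
  kids <- vector("list", n)
  for (i in seq_len(nrow(gtPhylo$edge))) {
    a <- gtPhylo$edge[i, 1L]
    kids[[a]] <- c(kids[[a]], gtPhylo$edge[i, 2L])
  }
  tipSp <- match(map[gtPhylo$tip.label], stPhylo$tip.label)
  stopifnot(!anyNA(tipSp))

  internals <- setdiff(seq_len(n), seq_len(ntip))
  # species LCA of the tips below each gene node, by recursion
  lcaBelow <- integer(n)
  fillLca <- function(v) {
    if (v <= ntip) { lcaBelow[v] <<- tipSp[v]; return(lcaBelow[v]) }
    ms <- vapply(kids[[v]], fillLca, integer(1L))
    l <- ms[1L]
    for (m2 in ms[-1L]) l <- .oracleLca(tb, l, m2)
    lcaBelow[v] <<- l
    l
  }
  geneRoot <- ntip + 1L
  fillLca(geneRoot)
  cand <- vector("list", n)
  for (v in internals) cand[[v]] <- which(tb$anc[, lcaBelow[v]])

  # order internals so children are assigned before their parent, allowing
  # incremental validity checks and cost pruning
  gdepth <- integer(n)
  fillDepth <- function(v, d) {
    gdepth[v] <<- d
    for (k in kids[[v]]) fillDepth(k, d + 1L)
  }
  fillDepth(geneRoot, 0L)
  internalsOrdered <- internals[order(-gdepth[internals])]

  best <- Inf
  M <- integer(n)
  M[seq_len(ntip)] <- tipSp
  localCost <- function(v) {
    m <- M[v]
    ms <- M[kids[[v]]]
    if (!all(tb$anc[m, ms])) return(Inf)
    j <- .oracleLca(tb, ms[1L], ms[2L])
    spec <- (m == j) && all(ms != m)
    cost <- if (spec) 0 else dupCost
    for (mi in ms) {
      d <- tb$depth[mi] - tb$depth[m]
      cost <- cost + lossCost * max(0L, d - if (spec) 1L else 0L)
    }
    cost
  }
  recurse <- function(i, acc) {
    if (acc >= best) return(invisible())
    if (i > length(internalsOrdered)) {
      best <<- acc
      return(invisible())
    }
    v <- internalsOrdered[i]
    for (m in cand[[v]]) {
      M[v] <<- m
      lc <- localCost(v)
      if (is.finite(lc)) recurse(i + 1L, acc + lc)
    }
  }
  recurse(1L, 0)
  best
}

# minimum cost over all rootings of an unrooted (basal trifurcation) tree:
# every edge is made the root edge by re-orienting the adjacency and
# re-reading the resulting newick
oracleAllRootingsMinCost <- function(unrootedPhylo, map, stPhylo,
                                     dupCost = 1, lossCost = 1) {
  ntip <- length(unrootedPhylo$tip.label)
  edges <- unrootedPhylo$edge
  nb <- vector("list", max(edges))
  for (i in seq_len(nrow(edges))) {
    nb[[edges[i, 1L]]] <- c(nb[[edges[i, 1L]]], i)
    nb[[edges[i, 2L]]] <- c(nb[[edges[i, 2L]]], i)
  }
  fragFrom <- function(v, viaEdge) {
    sub <- character(0L)
    for (j in nb[[v]]) {
      if (j == viaEdge) next
      w <- if (edges[j, 1L] == v) edges[j, 2L] else edges[j, 1L]
      sub <- c(sub, fragFrom(w, j))
    }
    if (v <= ntip) return(unrootedPhylo$tip.label[v])
    paste0("(", paste(sub, collapse = ","), ")")
  }
  best <- Inf
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1L]; b <- edges[i, 2L]
    nwk <- paste0("(", fragFrom(a, i), ",", fragFrom(b, i), ");")
    rooted <- ape::read.tree(text = nwk)
    c <- oracleHistoryMinCost(rooted, map, stPhylo, dupCost, lossCost)
    if (c < best) best <- c
  }
  best
}

# ---- independent enumeration of rooted topologies over subtrees -----------

# all rooted binary topologies over a set of newick fragments, built by the
# split-into-two-parts recursion (different algorithm from the package's
# graft-based enumeration)
oracleAllRootedTrees <- function(parts) {
  if (length(parts) == 1L) return(parts)
  out <- character(0L)
  k <- length(parts)
  # first element always goes left to avoid duplicates
  for (mask in seq_len(2^(k - 1L)) - 1L) {
    left <- c(1L)
    right <- integer(0L)
    for (j in seq_len(k - 1L)) {
      if (bitwAnd(mask, bitwShiftL(1L, j - 1L))) left <- c(left, j + 1L)
      else right <- c(right, j + 1L)
    }
    if (!length(right)) next
    for (lt in oracleAllRootedTrees(parts[left])) {
      for (rt in oracleAllRootedTrees(parts[right])) {
        out <- c(out, paste0("(", lt, ",", rt, ")"))
      }
    }
  }
  unique(out)
}

# newick fragment of the clade below `node`, topology only
cladeFragment <- function(phy, node) {
  tips <- phy$tip.label
  kids <- vector("list", phy$Nnode + length(tips))
  for (i in seq_len(nrow(phy$edge))) {
    a <- phy$edge[i, 1L]
    kids[[a]] <- c(kids[[a]], phy$edge[i, 2L])
  }
  walk <- function(v) {
    if (v <= length(tips)) return(tips[v])
    paste0("(", paste(vapply(kids[[v]], walk, character(1L)),
                      collapse = ","), ")")
  }
  walk(node)
}

# ---- misc -----------------------------------------------------------------

# rooted clades (as sorted tip-label strings) of a phylo, excluding root
rootedCladeSet <- function(phy) {
  ntip <- length(phy$tip.label)
  kids <- vector("list", phy$Nnode + ntip)
  for (i in seq_len(nrow(phy$edge))) {
    a <- phy$edge[i, 1L]
    kids[[a]] <- c(kids[[a]], phy$edge[i, 2L])
  }
  tipsBelow <- function(v) {
    if (v <= ntip) return(phy$tip.label[v])
    unlist(lapply(kids[[v]], tipsBelow))
  }
  internal <- setdiff(seq_len(phy$Nnode + ntip), c(seq_len(ntip), ntip + 1L))
  sort(vapply(internal, function(v)
    paste(sort(tipsBelow(v)), collapse = "|"), character(1L)))
}

expectEqualNumeric <- function(x, y, tol = 1e-12) {
  testthat::expect_lt(max(abs(x - y)), tol)
}
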