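#' @include AllClasses.R AllGenerics.R phylo-core.R
NULL

# species-tree lookup tables reused across reconciliations
.stIndex <- function(st) {
  phy <- st@tree
  list(par = .parentVec(phy), depth = .depthVec(phy),
       tips = phy$tip.label, children = .childrenList(phy))
}

# LCA of two species nodes by walking up
.spLca <- function(idx, a, b) {
  while (a != b) {
    if (idx$depth[a] >= idx$depth[b]) a <- idx$par[a] else b <- idx$par[b]
  }
  a
}

#' LCA reconciliation of a rooted gene tree with the species tree
#'
#' Maps every gene-tree node to the species-tree MRCA of its descendants'
#' species. A node whose mapping equals that of at least one child is a
#' duplication; all other internal nodes are speciations. Losses accrue on
#' the species-tree branches skipped along each gene-tree edge: an edge from
#' \code{u} down to \code{v} loses the off-path species branch at every
#' intermediate node, plus the one at \code{M(u)} itself when \code{u} is a
#' duplication. With equal weights this reproduces the duplication-loss
#' parsimony optimum over event histories for the given rooted topology.
#'
#' @param gt a rooted, strictly binary \code{GeneTree} with all leaves
#'   mapped to species present in \code{st}.
#' @param st a \code{SpeciesTree}.
#' @param config a \code{PipelineConfig} (\code{dupCost}, \code{lossCost}).
#' @return a \code{ReconciliationResult}.
#' @export
lcaReconcile <- function(gt, st, config = pipelineConfig()) {
  phy <- gt@tree
  ntip <- length(phy$tip.label)
  n <- ntip + phy$Nnode
  nkids <- tabulate(phy$edge[, 1L], nbins = n)
  if (any(nkids[(ntip + 1L):n] != 2L))
    stop("gene tree is not strictly binary; call resolvePolytomies() first")
  idx <- .stIndex(st)
  sp <- gt@speciesMap[phy$tip.label]
  spi <- match(sp, idx$tips)
  if (anyNA(spi))
    stop("leaves mapped to species absent from the species tree: ",
         paste(phy$tip.label[is.na(spi)], collapse = ", "))

  M <- integer(n)
  M[seq_len(ntip)] <- spi
  po <- ape::postorder(phy)
  for (e in po) {
    a <- phy$edge[e, 1L]; b <- phy$edge[e, 2L]
    M[a] <- if (M[a] == 0L) M[b] else .spLca(idx, M[a], M[b])
  }

  events <- rep("leaf", n)
  ch <- .childrenList(phy)
  for (v in (ntip + 1L):n) {
    events[v] <- if (any(M[ch[[v]]] == M[v])) "duplication" else "speciation"
  }

  nsp <- length(idx$par)
  lossOnBranch <- integer(nsp)
  L <- 0L
  for (e in seq_len(nrow(phy$edge))) {
    u <- phy$edge[e, 1L]; v <- phy$edge[e, 2L]
    if (M[u] == M[v]) next
    # walk from M(v) up to M(u), collecting off-path child branches
    cur <- M[v]
    while (cur != M[u]) {
      parent <- idx$par[cur]
      if (parent != M[u] || events[u] == "duplication") {
        off <- setdiff(idx$children[[parent]], cur)
        lossOnBranch[off] <- lossOnBranch[off] + 1L
        L <- L + 1L
      }
      cur <- parent
    }
  }
  D <- sum(events == "duplication")
  names(lossOnBranch) <- as.character(seq_len(nsp))
  new("ReconciliationResult", geneTree = gt, mapping = M, events = events,
      branchLosses = lossOnBranch, D = as.integer(D), L = as.integer(L),
      cost = config@dupCost * D + config@lossCost * L)
}

#' Root an unrooted gene tree by duplication-loss parsimony
#'
#' Every edge of the unrooted tree is evaluated as a root position and the
#' rooting of minimal reconciliation cost is returned. Ties are broken by
#' (1) higher support on the root-adjacent edge, then (2) the
#' lexicographically smallest sorted leaf-label string of the smaller root
#' child. Deterministic.
#'
#' @param gt an unrooted \code{GeneTree} (basal trifurcation).
#' @param st a \code{SpeciesTree}.
#' @param config a \code{PipelineConfig}.
#' @return a rooted \code{GeneTree} with supports carried over (the split
#'   root edge's support appears on both root children).
#' @export
rootByDL <- function(gt, st, config = pipelineConfig()) {
  ut <- .phyloToUnrooted(gt@tree, gt@support)
  nEdge <- nrow(ut$edges)
  best <- NULL
  for (i in seq_len(nEdge)) {
    rep <- .rootOnEdge(ut, i)
    conv <- .repToPhylo(rep)
    cand <- new("GeneTree", tree = conv$tree, support = conv$support,
                speciesMap = gt@speciesMap,
                rearranged = conv$rearranged, unrooted = FALSE)
    cost <- lcaReconcile(cand, st, config)@cost
    sup <- ut$edges$support[i]
    if (is.na(sup)) sup <- -1
    kids <- .childrenList(conv$tree)[[.rootNode(conv$tree)]]
    tsets <- .tipDescList(conv$tree)
    sizes <- lengths(tsets[kids])
    small <- kids[order(sizes, vapply(kids, function(k)
      paste(sort(conv$tree$tip.label[tsets[[k]]]), collapse = "|"),
      character(1L)))][1L]
    key <- paste(sort(conv$tree$tip.label[tsets[[small]]]), collapse = "|")
    score <- list(cost = cost, sup = sup, key = key, cand = cand)
    if (is.null(best) ||
        cost < best$cost - 1e-12 ||
        (abs(cost - best$cost) <= 1e-12 &&
         (sup > best$sup + 1e-12 ||
          (abs(sup - best$sup) <= 1e-12 && key < best$key)))) {
      best <- score
    }
  }
  best$cand
}

#' Resolve polytomies into lexicographically ordered caterpillars
#'
#' Children of each multifurcating node are sorted by their smallest
#' descendant leaf label and folded left-deep; introduced edges carry
#' support 0 (and are therefore rearrangeable) and length 0.
#'
#' @param gt a \code{GeneTree}.
#' @return a strictly binary rooted \code{GeneTree}.
#' @export
resolvePolytomies <- function(gt) {
  if (ape::is.binary(gt@tree) && ape::is.rooted(gt@tree)) return(gt)
  rep <- .phyloToRep(gt@tree, gt@support, gt@rearranged)
  fix <- function(node) {
    if (.repIsTip(node)) return(node)
    node$children <- lapply(node$children, fix)
    while (length(node$children) > 2L) {
      keys <- vapply(node$children, function(k) min(.repTips(k)),
                     character(1L))
      ord <- order(keys)
      node$children <- node$children[ord]
      merged <- list(label = NA_character_, length = 0, support = 0,
                     rearranged = FALSE,
                     children = node$children[1:2])
      node$children <- c(list(merged), node$children[-(1:2)])
    }
    node
  }
  rep <- fix(rep)
  conv <- .repToPhylo(rep)
  new("GeneTree", tree = conv$tree, support = conv$support,
      speciesMap = gt@speciesMap, rearranged = conv$rearranged,
      unrooted = FALSE)
}

## ---- weak-node rearrangement ---------------------------------------------

# all rooted binary topologies over tokens (integers); each topology is a
# nested list of token ids
.enumRootedTopologies <- function(k) {
  topos <- list(1L)
  for (i in seq_len(k - 1L) + 1L) {
    nxt <- list()
    for (tp in topos) {
      nxt <- c(nxt, .graftEverywhere(tp, i))
    }
    topos <- nxt
  }
  topos
}

# graft token as a sibling of every node (including the root) of topo
.graftEverywhere <- function(topo, token) {
  out <- list(list(topo, token))
  if (!is.list(topo)) return(out)
  for (j in 1:2) {
    for (sub in .graftEverywhere(topo[[j]], token)) {
      tp <- topo
      tp[[j]] <- sub
      out <- c(out, list(tp))
    }
  }
  out
}

# nearest-neighbor interchanges of a token topology: for every internal
# edge (node -> list child), swap one grandchild with the node's other child
.nniNeighbors <- function(topo) {
  replaceAt <- function(root, path, newNode) {
    if (!length(path)) return(newNode)
    root[[path[1L]]] <- replaceAt(root[[path[1L]]], path[-1L], newNode)
    root
  }
  out <- list()
  recurse <- function(node, path) {
    if (!is.list(node)) return(invisible())
    for (j in 1:2) {
      child <- node[[j]]
      if (is.list(child)) {
        other <- node[[3L - j]]
        for (g in 1:2) {
          newChild <- child
          moved <- newChild[[g]]
          newChild[[g]] <- other
          newNode <- node
          newNode[[j]] <- newChild
          newNode[[3L - j]] <- moved
          out[[length(out) + 1L]] <<- replaceAt(topo, path, newNode)
        }
      }
      recurse(child, c(path, j))
    }
  }
  recurse(topo, integer(0L))
  out
}

# random rooted topology over k tokens (sequential random grafting)
.randomTopology <- function(k) {
  topo <- 1L
  for (i in seq_len(k - 1L) + 1L) {
    cands <- .graftEverywhere(topo, i)
    topo <- cands[[sample.int(length(cands), 1L)]]
  }
  topo
}

# recursive-rep search/replace by leaf set
.findRepByTips <- function(rep, leafSet) {
  if (setequal(.repTips(rep), leafSet)) return(rep)
  for (k in rep$children) {
    r <- .findRepByTips(k, leafSet)
    if (!is.null(r)) return(r)
  }
  NULL
}

.replaceRepByTips <- function(rep, leafSet, newSub) {
  if (setequal(.repTips(rep), leafSet)) {
    newSub$length <- rep$length
    newSub$support <- rep$support
    newSub$rearranged <- rep$rearranged
    return(newSub)
  }
  rep$children <- lapply(rep$children, .replaceRepByTips, leafSet = leafSet,
                         newSub = newSub)
  rep
}

# build the rep of a token topology with boundary subtree reps plugged in
.topoToRep <- function(topo, boundary) {
  if (!is.list(topo)) return(boundary[[topo]])
  kids <- lapply(topo, .topoToRep, boundary = boundary)
  list(label = NA_character_, length = 0, support = NA_real_,
       rearranged = TRUE, children = kids)
}

# extract the token topology of the current region resolution
.regionTopology <- function(rep, boundaryTipSets) {
  match1 <- function(node) {
    tips <- .repTips(node)
    for (j in seq_along(boundaryTipSets)) {
      if (setequal(tips, boundaryTipSets[[j]])) return(j)
    }
    stopifnot(!.repIsTip(node))
    lapply(node$children, match1)
  }
  match1(rep)
}

#' Rearrange weakly supported gene-tree regions to minimise D + L
#'
#' Internal edges with bootstrap support below \code{supportThreshold} (or
#' with no support value) form maximal connected weak regions. Within each
#' region, all alternative resolutions of the region's boundary subtrees are
#' explored (exhaustively when the region has at most
#' \code{exhaustiveLimit} boundary subtrees, by seeded greedy
#' nearest-neighbor-interchange hill climbing otherwise); strongly supported
#' edges are never altered. The returned tree minimises
#' \code{dupCost * D + lossCost * L} among explored trees and never exceeds
#' the input tree's cost; among cost optima the tree of minimal
#' Robinson-Foulds distance to the input is chosen, then the
#' lexicographically smallest. Edges created by rearrangement carry the
#' \code{rearranged} flag and no support value.
#'
#' @param gt a rooted binary \code{GeneTree} with supports on internal
#'   edges.
#' @param st a \code{SpeciesTree}.
#' @param config a \code{PipelineConfig}.
#' @return the rearranged rooted \code{GeneTree}.
#' @export
rearrangeWeakNodes <- function(gt, st, config = pipelineConfig()) {
  thr <- config@supportThreshold
  phy <- gt@tree
  ntip <- length(phy$tip.label)
  n <- ntip + phy$Nnode
  root <- .rootNode(phy)
  internal <- setdiff((ntip + 1L):n, root)
  if (length(internal) && all(is.na(gt@support[internal])) &&
      !any(gt@rearranged[internal]))
    stop("gene tree carries no support values")
  if (thr < 0 || thr > 100) stop("support threshold outside [0, 100]")

  isWeak <- function(v) {
    s <- gt@support[v]
    (is.na(s) && !gt@rearranged[v]) || (!is.na(s) && s < thr)
  }
  weakNodes <- internal[vapply(internal, isWeak, logical(1L))]
  if (!length(weakNodes)) return(gt)

  par <- .parentVec(phy)
  dep <- .depthVec(phy)
  tsets <- .tipDescList(phy)

  # connected components of weak edges (edge above each weak node)
  comp <- rep(NA_integer_, length(weakNodes))
  names(comp) <- as.character(weakNodes)
  cid <- 0L
  for (w in weakNodes) {
    if (!is.na(comp[as.character(w)])) next
    cid <- cid + 1L
    queue <- w
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      if (!is.na(comp[as.character(v)])) next
      comp[as.character(v)] <- cid
      touching <- weakNodes[vapply(weakNodes, function(x) {
        x != v && (par[x] == v || par[v] == x || par[x] == par[v])
      }, logical(1L))]
      queue <- c(queue, touching[is.na(comp[as.character(touching)])])
    }
  }

  regions <- lapply(seq_len(cid), function(k) {
    W <- weakNodes[comp == k]
    S <- unique(c(W, par[W]))
    t <- S[which.min(dep[S])]
    boundary <- list()
    for (u in S) {
      if (!u %in% c(W, t)) next
      kids <- which(par == u)
      for (c in kids) {
        if (c %in% W) next
        boundary <- c(boundary, list(phy$tip.label[tsets[[c]]]))
      }
    }
    list(topTips = phy$tip.label[tsets[[t]]], boundary = boundary,
         depth = dep[t])
  })
  regions <- regions[order(-vapply(regions, `[[`, numeric(1L), "depth"))]

  rep <- .phyloToRep(phy, gt@support, gt@rearranged)
  inputCanon <- .canonicalNewick(rep)

  oldseed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(oldseed)) assign(".Random.seed", oldseed, envir = globalenv())
  }, add = TRUE)
  set.seed(config@rngSeed + 1L)

  evalCost <- function(candRep) {
    conv <- .repToPhylo(candRep)
    cand <- new("GeneTree", tree = conv$tree, support = conv$support,
                speciesMap = gt@speciesMap, rearranged = conv$rearranged,
                unrooted = FALSE)
    list(gt = cand, cost = lcaReconcile(cand, st, config)@cost)
  }

  inputPhy <- phy
  for (rg in regions) {
    regionRep <- .findRepByTips(rep, rg$topTips)
    boundaryReps <- lapply(rg$boundary, function(ts)
      .findRepByTips(regionRep, ts))
    k <- length(boundaryReps)
    if (k < 2L) next
    curTopo <- .regionTopology(regionRep, rg$boundary)
    if (k <= config@exhaustiveLimit) {
      topos <- .enumRootedTopologies(k)
    } else {
      topos <- .greedyNniTopologies(curTopo, k, boundaryReps, rg, rep,
                                    evalCost)
    }
    cands <- vector("list", length(topos))
    costs <- numeric(length(topos))
    for (i in seq_along(topos)) {
      newSub <- .topoToRep(topos[[i]], boundaryReps)
      candRep <- .replaceRepByTips(rep, rg$topTips, newSub)
      ev <- evalCost(candRep)
      cands[[i]] <- list(rep = candRep, gt = ev$gt)
      costs[i] <- ev$cost
    }
    best <- which(costs <= min(costs) + 1e-12)
    if (length(best) > 1L) {
      rf <- vapply(best, function(i) {
        phangorn::RF.dist(ape::unroot(cands[[i]]$gt@tree),
                          ape::unroot(inputPhy))
      }, numeric(1L))
      best <- best[rf <= min(rf) + 1e-12]
    }
    if (length(best) > 1L) {
      keys <- vapply(best, function(i)
        .canonicalNewick(.phyloToRep(cands[[i]]$gt@tree,
                                     cands[[i]]$gt@support,
                                     cands[[i]]$gt@rearranged)),
        character(1L))
      best <- best[order(keys)]
    }
    chosenRep <- cands[[best[1L]]]$rep
    if (.canonicalNewick(chosenRep) != .canonicalNewick(rep)) {
      rep <- chosenRep
    }
    # else: region already optimal; keep the input resolution and supports
  }

  conv <- .repToPhylo(rep)
  new("GeneTree", tree = conv$tree, support = conv$support,
      speciesMap = gt@speciesMap, rearranged = conv$rearranged,
      unrooted = FALSE)
}

# greedy steepest-descent NNI over token topologies, with random restarts;
# returns the list of topologies visited as local optima (plus the start)
.greedyNniTopologies <- function(startTopo, k, boundaryReps, rg, rep,
                                 evalCost) {
  costOf <- function(topo) {
    newSub <- .topoToRep(topo, boundaryReps)
    evalCost(.replaceRepByTips(rep, rg$topTips, newSub))$cost
  }
  climb <- function(topo) {
    cur <- topo; curCost <- costOf(topo)
    repeat {
      nbs <- .nniNeighbors(cur)
      if (!length(nbs)) break
      ncosts <- vapply(nbs, costOf, numeric(1L))
      if (min(ncosts) < curCost - 1e-12) {
        i <- which.min(ncosts)
        cur <- nbs[[i]]; curCost <- ncosts[i]
      } else break
    }
    cur
  }
  out <- list(startTopo, climb(startTopo))
  for (r in 1:3) {
    out <- c(out, list(climb(.randomTopology(k))))
  }
  out
}
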