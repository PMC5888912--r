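# Internal helpers on ape "phylo" objects and on a lightweight recursive tree
# representation used for rooting and rearrangement surgery.

.nNodes <- function(phy) phy$Nnode + length(phy$tip.label)

.rootNode <- function(phy) length(phy$tip.label) + 1L

.parentVec <- function(phy) {
  p <- integer(.nNodes(phy))
  p[phy$edge[, 2L]] <- phy$edge[, 1L]
  p
}

.childrenList <- function(phy) {
  ch <- vector("list", .nNodes(phy))
  for (i in seq_len(nrow(phy$edge))) {
    a <- phy$edge[i, 1L]
    ch[[a]] <- c(ch[[a]], phy$edge[i, 2L])
  }
  ch
}

# depth in edges from the root (root = 0)
.depthVec <- function(phy) {
  d <- integer(.nNodes(phy))
  r <- .rootNode(phy)
  ch <- .childrenList(phy)
  stack <- r
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    for (c in ch[[v]]) {
      d[c] <- d[v] + 1L
      stack <- c(stack, c)
    }
  }
  d
}

# list of tip indices under each node (tips map to themselves)
.tipDescList <- function(phy) {
  n <- .nNodes(phy)
  ntip <- length(phy$tip.label)
  out <- vector("list", n)
  for (i in seq_len(ntip)) out[[i]] <- i
  ord <- rev(ape::postorder(phy))  # edges; process children before parents
  for (i in ape::postorder(phy)) {
    a <- phy$edge[i, 1L]; b <- phy$edge[i, 2L]
    out[[a]] <- c(out[[a]], out[[b]])
  }
  lapply(out, sort)
}

# MRCA of a set of node indices (usually tips); single element returns itself
.mrcaNode <- function(phy, nodes) {
  nodes <- unique(as.integer(nodes))
  if (length(nodes) == 1L) return(nodes)
  par <- .parentVec(phy)
  dep <- .depthVec(phy)
  cur <- nodes[1L]
  for (v in nodes[-1L]) {
    a <- cur; b <- v
    while (a != b) {
      if (dep[a] >= dep[b]) a <- par[a] else b <- par[b]
    }
    cur <- a
  }
  cur
}

# ancestors of a node up to the root, inclusive of the node itself
.ancestorsOf <- function(par, node) {
  out <- node
  while (par[node] != 0L) {
    node <- par[node]
    out <- c(out, node)
  }
  out
}

.isAncestorMat <- function(phy) {
  # anc[i, j] TRUE iff i is an ancestor-or-equal of j
  n <- .nNodes(phy)
  par <- .parentVec(phy)
  m <- matrix(FALSE, n, n)
  for (j in seq_len(n)) m[.ancestorsOf(par, j), j] <- TRUE
  m
}

## ---- recursive representation -------------------------------------------
## A node is list(label=, length=, support=, rearranged=, children=list())
## tips have label set and empty children.

.phyloToRep <- function(phy, support = NULL, rearranged = NULL) {
  n <- .nNodes(phy)
  if (is.null(support)) support <- rep(NA_real_, n)
  if (is.null(rearranged)) rearranged <- rep(FALSE, n)
  ch <- .childrenList(phy)
  el <- rep(NA_real_, n)
  if (!is.null(phy$edge.length)) el[phy$edge[, 2L]] <- phy$edge.length
  ntip <- length(phy$tip.label)
  build <- function(v) {
    kids <- lapply(ch[[v]], build)
    list(label = if (v <= ntip) phy$tip.label[v] else NA_character_,
         length = el[v], support = support[v],
         rearranged = rearranged[v], children = kids)
  }
  build(.rootNode(phy))
}

.repIsTip <- function(rep) length(rep$children) == 0L

.repTips <- function(rep) {
  if (.repIsTip(rep)) return(rep$label)
  unlist(lapply(rep$children, .repTips), use.names = FALSE)
}

.repCount <- function(rep) {
  if (.repIsTip(rep)) return(c(tips = 1L, nodes = 0L))
  k <- vapply(rep$children, .repCount, c(tips = 0L, nodes = 0L))
  c(tips = sum(k["tips", ]), nodes = 1L + sum(k["nodes", ]))
}

# convert recursive rep to phylo plus node-indexed support/rearranged vectors
.repToPhylo <- function(rep) {
  cnt <- .repCount(rep)
  ntip <- cnt[["tips"]]; nnode <- cnt[["nodes"]]
  n <- ntip + nnode
  edge <- matrix(0L, n - 1L, 2L)
  elen <- numeric(n - 1L)
  tips <- character(ntip)
  support <- rep(NA_real_, n)
  rearranged <- rep(FALSE, n)
  tipI <- 0L; nodeI <- ntip; edgeI <- 0L
  hasLen <- FALSE
  assign1 <- function(node) {
    if (.repIsTip(node)) {
      tipI <<- tipI + 1L
      tips[tipI] <<- node$label
      id <- tipI
    } else {
      nodeI <<- nodeI + 1L
      id <- nodeI
      myid <- id
      for (k in node$children) {
        cid <- assign1(k)
        edgeI <<- edgeI + 1L
        edge[edgeI, ] <<- c(myid, cid)
        elen[edgeI] <<- if (is.null(k$length) || is.na(k$length)) 0 else {
          hasLen <<- TRUE; k$length }
      }
    }
    support[id] <<- if (is.null(node$support)) NA_real_ else node$support
    rearranged[id] <<- isTRUE(node$rearranged)
    id
  }
  assign1(rep)
  phy <- list(edge = edge, tip.label = tips, Nnode = nnode,
              edge.length = elen)
  if (!hasLen) phy$edge.length <- NULL
  class(phy) <- "phylo"
  attr(phy, "order") <- NULL
  phy <- ape::reorder.phylo(phy, "cladewise")
  # reorder does not touch node numbering, only edge row order
  list(tree = phy, support = support, rearranged = rearranged)
}

# canonical newick (topology + labels only): children sorted by smallest tip
.canonicalNewick <- function(rep) {
  walk <- function(node) {
    if (.repIsTip(node)) return(node$label)
    parts <- vapply(node$children, walk, character(1L))
    parts <- parts[order(vapply(strsplit(gsub("[(),]", ",", parts), ","),
                                function(x) min(x[nzchar(x)]), character(1L)))]
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(walk(rep), ";")
}

## ---- unrooted adjacency representation -----------------------------------
## edges: data.frame(a, b, length, support, rearranged); vertex labels for tips

.phyloToUnrooted <- function(phy, support = NULL) {
  n <- .nNodes(phy)
  if (is.null(support)) support <- rep(NA_real_, n)
  el <- rep(NA_real_, n)
  if (!is.null(phy$edge.length)) el[phy$edge[, 2L]] <- phy$edge.length
  edges <- data.frame(a = phy$edge[, 1L], b = phy$edge[, 2L],
                      length = el[phy$edge[, 2L]],
                      support = support[phy$edge[, 2L]])
  root <- .rootNode(phy)
  deg <- tabulate(c(edges$a, edges$b), nbins = n)
  if (deg[root] == 2L) {
    # suppress a rooted-binary root into a single unrooted edge
    ri <- which(edges$a == root)
    e1 <- edges[ri[1L], ]; e2 <- edges[ri[2L], ]
    len <- sum(c(e1$length, e2$length), na.rm = !all(is.na(c(e1$length, e2$length))))
    sup <- suppressWarnings(max(c(e1$support, e2$support), na.rm = TRUE))
    if (!is.finite(sup)) sup <- NA_real_
    edges <- edges[-ri, ]
    edges <- rbind(edges, data.frame(a = e1$b, b = e2$b,
                                     length = len, support = sup))
  }
  list(edges = edges, tip.label = phy$tip.label, ntip = length(phy$tip.label))
}

# root the unrooted tree on edge i (midpoint); returns recursive rep
.rootOnEdge <- function(ut, i) {
  edges <- ut$edges
  ntip <- ut$ntip
  nb <- vector("list", max(c(edges$a, edges$b)))
  for (j in seq_len(nrow(edges))) {
    nb[[edges$a[j]]] <- c(nb[[edges$a[j]]], j)
    nb[[edges$b[j]]] <- c(nb[[edges$b[j]]], j)
  }
  grow <- function(v, viaEdge) {
    kids <- list()
    for (j in nb[[v]]) {
      if (j == viaEdge) next
      w <- if (edges$a[j] == v) edges$b[j] else edges$a[j]
      k <- grow(w, j)
      k$length <- edges$length[j]
      k$support <- edges$support[j]
      kids <- c(kids, list(k))
    }
    list(label = if (v <= ntip) ut$tip.label[v] else NA_character_,
         length = NA_real_, support = NA_real_, rearranged = FALSE,
         children = kids)
  }
  a <- edges$a[i]; b <- edges$b[i]
  half <- if (is.na(edges$length[i])) NA_real_ else edges$length[i] / 2
  ra <- grow(a, i); rb <- grow(b, i)
  ra$length <- half; rb$length <- half
  ra$support <- edges$support[i]; rb$support <- edges$support[i]
  list(label = NA_character_, length = NA_real_, support = NA_real_,
       rearranged = FALSE, children = list(ra, rb))
}
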