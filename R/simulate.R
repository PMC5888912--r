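#' @include AllClasses.R phylo-core.R homology-screen.R alignment-prep.R
NULL

#' Substitution parameters for the sequence simulator
#'
#' @param baseFreq stationary base frequencies (A, C, G, T).
#' @param alpha1 purine (A/G) transition rate.
#' @param alpha2 pyrimidine (C/T) transition rate.
#' @param beta transversion rate.
#' @param posRates relative rate multipliers for codon positions 1-3
#'   (second positions slowest, third fastest, as in coding sequence).
#' @return a \code{SubstitutionParams}.
#' @export
substitutionParams <- function(baseFreq = c(A = 0.30, C = 0.20,
                                            G = 0.20, T = 0.30),
                               alpha1 = 2, alpha2 = 2, beta = 1,
                               posRates = c(1, 0.5, 2.5)) {
  new("SubstitutionParams", baseFreq = baseFreq, alpha1 = alpha1,
      alpha2 = alpha2, beta = beta, posRates = posRates)
}

# TN93 rate matrix scaled to one expected substitution per unit time
.tn93Q <- function(params) {
  f <- params@baseFreq
  a1 <- params@alpha1; a2 <- params@alpha2; b <- params@beta
  Q <- matrix(0, 4, 4, dimnames = list(names(f), names(f)))
  bases <- names(f)
  for (i in bases) for (j in bases) {
    if (i == j) next
    rate <- if ((i == "A" && j == "G") || (i == "G" && j == "A")) a1
            else if ((i == "C" && j == "T") || (i == "T" && j == "C")) a2
            else b
    Q[i, j] <- rate * f[j]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(f * diag(Q))
  Q / mu
}

# transition probability matrix exp(Q t) via eigendecomposition of the
# symmetrised reversible generator
.tn93P <- function(Q, f, t) {
  if (t <= 0) return(diag(4))
  S <- diag(sqrt(f)) %*% Q %*% diag(1 / sqrt(f))
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  P <- diag(1 / sqrt(f)) %*% e$vectors %*% diag(exp(e$values * t)) %*%
    t(e$vectors) %*% diag(sqrt(f))
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Simulate a gene family by birth-death on the species tree
#'
#' A single ancestral copy enters the root of the species tree. Along each
#' branch every extant copy acquires duplications and losses as a Poisson
#' process with rates \code{lambda} and \code{mu} per copy per unit branch
#' length; duplicated copies evolve independently down the remaining tree.
#' The full event log is returned together with the gene tree of surviving
#' copies (unifurcations suppressed, branch lengths accumulated).
#' Deterministic given \code{seed}.
#'
#' @param st a \code{SpeciesTree} with branch lengths.
#' @param lambda duplication rate (events per copy per unit length).
#' @param mu loss rate.
#' @param seed integer RNG seed.
#' @return a \code{SimTruth}. When no copy survives, the gene tree is NULL
#'   and the species map empty.
#' @export
simulateGeneFamily <- function(st, lambda = 0.7, mu = 0, seed = 1L) {
  if (lambda < 0 || mu < 0) stop("rates must be non-negative")
  phy <- st@tree
  if (is.null(phy$edge.length)) stop("species tree must have branch lengths")
  ch <- .childrenList(phy)
  elen <- rep(NA_real_, .nNodes(phy))
  elen[phy$edge[, 2L]] <- phy$edge.length
  ntip <- length(phy$tip.label)

  oldseed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(oldseed)) assign(".Random.seed", oldseed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  events <- list()
  counters <- new.env()
  tipName <- function(node) {
    sp <- phy$tip.label[node]
    k <- get0(sp, envir = counters, inherits = FALSE, ifnotfound = 0L) + 1L
    assign(sp, k, envir = counters)
    paste0(sp, "|g", k)
  }

  # evolve one copy down the branch above `node`, starting at `offset`
  # along the branch; returns a rep node (or NULL if the copy dies)
  evolveBranch <- function(node, offset) {
    t <- elen[node]
    pos <- offset
    segStart <- offset
    repeat {
      wait <- if (lambda + mu > 0) stats::rexp(1L, lambda + mu) else Inf
      if (pos + wait >= t) break
      pos <- pos + wait
      isDup <- stats::runif(1L) < lambda / (lambda + mu)
      events[[length(events) + 1L]] <<- list(
        type = if (isDup) "duplication" else "loss",
        branch = node, time = pos)
      if (!isDup) return(NULL)
      left <- evolveBranch(node, pos)
      right <- evolveBranch(node, pos)
      # the duplication node sits at `pos`; its parent edge began at segStart
      if (is.null(left) && is.null(right)) return(NULL)
      if (is.null(left) || is.null(right)) {
        k <- if (is.null(left)) right else left
        k$length <- k$length + (pos - segStart)
        return(k)
      }
      dn <- list(label = NA_character_, length = pos - segStart,
                 support = NA_real_, rearranged = FALSE,
                 children = list(left, right))
      return(dn)
    }
    # reached the end of the branch without dying
    tailLen <- t - segStart
    k <- atNode(node)
    if (is.null(k)) return(NULL)
    k$length <- k$length + tailLen
    k
  }

  # copy present exactly at `node`: a leaf, or a speciation into children
  atNode <- function(node) {
    if (node <= ntip) {
      return(list(label = tipName(node), length = 0, support = NA_real_,
                  rearranged = FALSE, children = list()))
    }
    kids <- lapply(ch[[node]], evolveBranch, offset = 0)
    kids <- Filter(Negate(is.null), kids)
    if (!length(kids)) return(NULL)
    if (length(kids) == 1L) return(kids[[1L]])
    list(label = NA_character_, length = 0, support = NA_real_,
         rearranged = FALSE, children = kids)
  }

  rep <- atNode(.rootNode(phy))
  ev <- if (length(events)) {
    data.frame(type = vapply(events, `[[`, character(1L), "type"),
               branch = vapply(events, `[[`, integer(1L), "branch"),
               time = vapply(events, `[[`, numeric(1L), "time"))
  } else {
    data.frame(type = character(0L), branch = integer(0L),
               time = numeric(0L))
  }
  if (is.null(rep) || .repIsTip(rep)) {
    # extinct family, or a single surviving copy (no tree to build)
    map <- if (is.null(rep)) character(0L) else defaultSpeciesMap(rep$label)
    return(new("SimTruth", geneTree = NULL, speciesMap = map, events = ev,
               lambda = lambda, mu = mu, seed = as.integer(seed)))
  }
  conv <- .repToPhylo(rep)
  new("SimTruth", geneTree = conv$tree,
      speciesMap = defaultSpeciesMap(conv$tree$tip.label), events = ev,
      lambda = lambda, mu = mu, seed = as.integer(seed))
}

#' Simulate codon-structured sequences along a gene tree
#'
#' The root sequence is drawn from the stationary base frequencies; sites
#' evolve independently under the TN93 rate matrix scaled by codon-position
#' rate multipliers. Branch lengths are interpreted as expected
#' substitutions per site at the position-averaged rate. The output is the
#' true, gap-free codon alignment. Deterministic given \code{seed}.
#'
#' @param gt a \code{phylo} gene tree with branch lengths (e.g. from
#'   \code{\link{simulateGeneFamily}}).
#' @param params a \code{SubstitutionParams}.
#' @param nCodons number of codons (>= 1).
#' @param seed integer RNG seed.
#' @return a \code{CodonAlignment} (gap-free, all columns retained).
#' @export
simulateSequences <- function(gt, params = substitutionParams(),
                              nCodons = 3000L, seed = 1L) {
  if (nCodons < 1L) stop("nCodons must be >= 1")
  f <- params@baseFreq
  Q <- .tn93Q(params)
  posScale <- params@posRates / mean(params@posRates)
  nsite <- 3L * nCodons
  pos <- rep(1:3, nCodons)
  bases <- names(f)

  oldseed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(oldseed)) assign(".Random.seed", oldseed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  n <- .nNodes(gt)
  ntip <- length(gt$tip.label)
  elen <- rep(0, n)
  elen[gt$edge[, 2L]] <- gt$edge.length
  ch <- .childrenList(gt)

  states <- matrix(0L, n, nsite)  # 1..4 indexing into bases
  root <- .rootNode(gt)
  states[root, ] <- sample.int(4L, nsite, replace = TRUE, prob = f)

  evolveSites <- function(parentStates, t) {
    out <- parentStates
    for (p in 1:3) {
      P <- .tn93P(Q, f, t * posScale[p])
      cum <- t(apply(P, 1L, cumsum))
      sel <- which(pos == p)
      u <- stats::runif(length(sel))
      ps <- parentStates[sel]
      # vectorised categorical draw against the cumulative rows of P
      new <- integer(length(sel))
      for (s in 1:4) {
        idx <- ps == s
        if (!any(idx)) next
        new[idx] <- 1L + findInterval(u[idx], cum[s, ], left.open = TRUE)
      }
      new[new > 4L] <- 4L
      out[sel] <- new
    }
    out
  }

  # preorder traversal
  stack <- root
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    for (c in ch[[v]]) {
      states[c, ] <- evolveSites(states[v, ], elen[c])
      stack <- c(stack, c)
    }
  }
  seqs <- apply(states[seq_len(ntip), , drop = FALSE], 1L, function(s)
    paste(bases[s], collapse = ""))
  names(seqs) <- gt$tip.label
  new("CodonAlignment", seqs = Biostrings::DNAStringSet(seqs),
      retained = rep(TRUE, nCodons), queryId = gt$tip.label[1L],
      flagged = character(0L))
}

#' Write a complete synthetic pipeline fixture to disk
#'
#' Simulates \code{nFamilies} gene families on the species tree, evolves
#' codon sequences for each, and writes per-family CDS and protein FASTA,
#' a synthetic hit table (via \code{\link{kmerSimilaritySearch}}, flagged
#' synthetic by construction), a gene-to-species map, a truth log of
#' duplication and loss events, the species tree and a JSON manifest with
#' MD5 checksums of every file.
#'
#' @param st a \code{SpeciesTree}.
#' @param lambda,mu birth-death rates.
#' @param params a \code{SubstitutionParams}.
#' @param nFamilies number of families.
#' @param nCodons codons per family.
#' @param seed integer master seed (family f uses \code{seed + f} offsets).
#' @param dir output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return invisibly, the manifest as a list.
#' @export
makePipelineFixture <- function(st, lambda = 0.7, mu = 0,
                                params = substitutionParams(),
                                nFamilies = 5L, nCodons = 3000L, seed = 1L,
                                dir, overwrite = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !overwrite)
    stop("output directory exists and is not empty: ", dir)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0L)
  writeFasta <- function(x, path) {
    lines <- as.vector(rbind(paste0(">", names(x)), unname(x)))
    writeLines(lines, path)
    files <<- c(files, path)
  }
  stPath <- file.path(dir, "species_tree.nwk")
  writeLines(writeNewick(st), stPath)
  files <- c(files, stPath)

  truthAll <- list()
  for (f in seq_len(nFamilies)) {
    truth <- NULL
    bump <- 0L
    repeat {
      truth <- simulateGeneFamily(st, lambda, mu, seed = seed + 1000L * f + bump)
      if (!is.null(truth@geneTree) &&
          length(truth@geneTree$tip.label) >= 4L) break
      bump <- bump + 1L  # resimulate extinct/degenerate families
      if (bump > 50L) stop("family ", f, " failed to produce >= 4 genes")
    }
    aln <- simulateSequences(truth@geneTree, params, nCodons,
                             seed = seed + 1000L * f + 500L)
    cds <- stats::setNames(as.character(aln@seqs), names(aln@seqs))
    prot <- translateCodonAlignment(aln)
    fid <- sprintf("fam%03d", f)
    writeFasta(cds, file.path(dir, paste0(fid, "_cds.fasta")))
    writeFasta(prot, file.path(dir, paste0(fid, "_prot.fasta")))

    # synthetic hit table: query = first human gene if present, else first
    qs <- grep("^Homo_sapiens", names(prot), value = TRUE)
    qid <- if (length(qs)) qs[1L] else names(prot)[1L]
    hits <- kmerSimilaritySearch(stats::setNames(prot[qid], qid), prot,
                                 k = 5L)
    hp <- file.path(dir, paste0(fid, "_hits.tsv"))
    utils::write.table(
      data.frame(query_id = hits$query_id, subject_id = hits$subject_id,
                 pct_identity = NA, aln_len = hits$aln_len, mismatches = NA,
                 gapopens = NA, qstart = NA, qend = NA, sstart = NA,
                 send = NA, e_value = hits$e_value,
                 bit_score = hits$bit_score),
      hp, sep = "\t", row.names = FALSE, quote = FALSE)
    files <- c(files, hp)

    mp <- file.path(dir, paste0(fid, "_map.tsv"))
    utils::write.table(
      data.frame(gene_id = names(truth@speciesMap),
                 species_id = unname(truth@speciesMap)),
      mp, sep = "\t", row.names = FALSE, quote = FALSE)
    files <- c(files, mp)

    tp <- file.path(dir, paste0(fid, "_truth.tsv"))
    ev <- truth@events
    ev <- data.frame(family = rep(fid, nrow(ev)), ev)
    utils::write.table(ev, tp, sep = "\t", row.names = FALSE, quote = FALSE)
    files <- c(files, tp)
    truthAll[[fid]] <- truth
  }
  manifest <- list(
    n_families = nFamilies, lambda = lambda, mu = mu, seed = seed,
    n_codons = nCodons,
    families = sprintf("fam%03d", seq_len(nFamilies)),
    files = lapply(stats::setNames(files, basename(files)), function(p)
      unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(manifest = manifest, truth = truthAll))
}
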