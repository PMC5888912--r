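#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a GeneTree
#'
#' @param tree a rooted (or basally trifurcating) \code{phylo} object.
#' @param speciesMap named character vector mapping gene ids to species ids.
#'   If missing, the default mapping rule is applied: the prefix of the gene
#'   id before the first \code{"|"} is the species id (gene ids without a
#'   \code{"|"} map to themselves).
#' @param support numeric vector of per-node supports (edge above each node),
#'   or NULL for none.
#' @param unrooted logical; TRUE marks a tree represented with a basal
#'   trifurcation standing in for an unrooted topology.
#' @return a \code{GeneTree}.
#' @export
GeneTree <- function(tree, speciesMap = NULL, support = NULL,
                     unrooted = FALSE) {
  n <- tree$Nnode + length(tree$tip.label)
  if (is.null(support)) {
    support <- rep(NA_real_, n)
    if (!is.null(tree$node.label)) {
      lab <- tree$node.label
      num <- suppressWarnings(as.numeric(lab))
      support[length(tree$tip.label) + seq_len(tree$Nnode)] <- num
    }
  }
  if (is.null(speciesMap)) speciesMap <- defaultSpeciesMap(tree$tip.label)
  new("GeneTree", tree = tree, support = support, speciesMap = speciesMap,
      rearranged = rep(FALSE, n), unrooted = unrooted)
}

#' Default gene-to-species mapping rule
#'
#' The species id is the prefix of the gene id before the first \code{"|"};
#' ids without a separator map to themselves.
#'
#' @param geneIds character vector of gene identifiers.
#' @return named character vector (gene id -> species id).
#' @export
defaultSpeciesMap <- function(geneIds) {
  sp <- sub("\\|.*$", "", geneIds)
  names(sp) <- geneIds
  sp
}

#' Read a gene-to-species map from a two-column TSV (header required)
#'
#' @param path TSV file with columns \code{gene_id} and \code{species_id}.
#' @return named character vector (gene id -> species id).
#' @export
readSpeciesMap <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "species_id") %in% names(df)))
    stop("species map must have columns 'gene_id' and 'species_id'")
  stats::setNames(as.character(df$species_id), as.character(df$gene_id))
}

#' Parse a Newick string
#'
#' Internal-node labels that are numeric are interpreted as bootstrap
#' supports attached to the child edge of the labelled node (the dominant
#' dialect). The result round-trips losslessly through
#' \code{\link{writeNewick}}.
#'
#' @param text a Newick string.
#' @param rootedExpected logical; if TRUE, a basal trifurcation raises an
#'   error.
#' @param speciesMap optional named character vector; defaults to the prefix
#'   rule of \code{\link{defaultSpeciesMap}}.
#' @return a \code{GeneTree}.
#' @export
parseNewick <- function(text, rootedExpected = FALSE, speciesMap = NULL) {
  .checkNewickSyntax(text)
  phy <- ape::read.tree(text = text)
  if (is.null(phy)) stop("malformed Newick string")
  if (anyDuplicated(phy$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
               collapse = ", "))
  ch <- tabulate(phy$edge[, 1L], nbins = phy$Nnode + length(phy$tip.label))
  root <- length(phy$tip.label) + 1L
  trifurc <- ch[root] > 2L
  if (rootedExpected && trifurc)
    stop("expected a rooted tree but found a basal multifurcation")
  GeneTree(phy, speciesMap = speciesMap, unrooted = trifurc)
}

# minimal syntactic scan so malformed input reports a character offset
.checkNewickSyntax <- function(text) {
  if (!is.character(text) || length(text) != 1L)
    stop("Newick input must be a single string")
  chars <- strsplit(text, "")[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("Newick parse error at character ", i,
             ": unmatched ')'")
    }
    if (chars[i] == ";" && depth != 0L)
      stop("Newick parse error at character ", i,
           ": ';' inside unclosed '('")
  }
  if (depth != 0L)
    stop("Newick parse error at character ", length(chars),
         ": ", depth, " unclosed '('")
  if (!grepl(";", text))
    stop("Newick parse error at character ", nchar(text),
         ": missing terminal ';'")
  invisible(TRUE)
}

#' Write a tree as a Newick string with supports as internal-node labels
#'
#' @param x a \code{GeneTree}, \code{SpeciesTree} or \code{phylo}.
#' @param digits number of digits for branch lengths.
#' @return a Newick string.
#' @export
writeNewick <- function(x, digits = 10) {
  if (is(x, "SpeciesTree")) x <- x@tree
  if (is(x, "GeneTree")) {
    phy <- x@tree
    ntip <- length(phy$tip.label)
    sup <- x@support[ntip + seq_len(phy$Nnode)]
    lab <- ifelse(is.na(sup), "",
                  sub("\\.0+$", "", formatC(sup, format = "fg")))
    phy$node.label <- lab
    x <- phy
  }
  ape::write.tree(x, digits = digits)
}

#' The packaged deuterostome reference species tree
#'
#' A rooted binary tree of 13 deuterostome species (the five major lineages:
#' Hemichordata, Echinodermata, Cephalochordata, Urochordata, Vertebrata)
#' plus a protostome outgroup clade (Drosophila, Caenorhabditis), with
#' uniform placeholder branch lengths. Branches are classified as
#' \code{peripheral} (within a lineage crown group, terminals included) or
#' \code{ancestral} (lineage stems and deeper branches).
#'
#' @param outgroups character vector of outgroup species labels forming a
#'   clade sister to the deuterostomes.
#' @param branchLength uniform branch length (expected substitutions/site).
#' @return a \code{SpeciesTree}.
#' @export
speciesTreeFixture <- function(outgroups = c("Drosophila_melanogaster",
                                             "Caenorhabditis_elegans"),
                               branchLength = 0.1) {
  deut <- paste0(
    "((Saccoglossus_kowalevskii,Ptychodera_flava),",
    "(Strongylocentrotus_purpuratus,",
    "(Acanthaster_planci_OKI,Acanthaster_planci_GBR))),",
    "((Branchiostoma_belcheri,Branchiostoma_floridae),",
    "((Oikopleura_dioica,(Botryllus_schlosseri,",
    "(Ciona_savignyi,Ciona_intestinalis))),",
    "(Gallus_gallus,Homo_sapiens)))")
  og <- if (length(outgroups) == 1L) outgroups else
    paste0("(", paste(outgroups, collapse = ","), ")")
  nwk <- paste0("(", og, ",(", deut, "));")
  phy <- ape::read.tree(text = nwk)
  phy$edge.length <- rep(branchLength, nrow(phy$edge))
  lineages <- list(
    hemichordata = c("Saccoglossus_kowalevskii", "Ptychodera_flava"),
    echinodermata = c("Strongylocentrotus_purpuratus",
                      "Acanthaster_planci_OKI", "Acanthaster_planci_GBR"),
    cephalochordata = c("Branchiostoma_belcheri", "Branchiostoma_floridae"),
    urochordata = c("Oikopleura_dioica", "Botryllus_schlosseri",
                    "Ciona_savignyi", "Ciona_intestinalis"),
    vertebrata = c("Gallus_gallus", "Homo_sapiens"),
    outgroup = outgroups)
  SpeciesTree(phy, lineages)
}

#' Construct a SpeciesTree with lineage-labelled branches
#'
#' Branches whose descendant species all belong to one lineage are labelled
#' with it; the branch of the lineage MRCA is its (ancestral) stem, branches
#' strictly inside the crown group are peripheral. Deeper branches are
#' labelled with the sorted lineages they span and classified ancestral.
#'
#' @param tree a rooted binary \code{phylo} with unique tip labels.
#' @param lineages named list mapping lineage names to species vectors; must
#'   cover all tips.
#' @return a \code{SpeciesTree}.
#' @export
SpeciesTree <- function(tree, lineages) {
  tips <- tree$tip.label
  miss <- setdiff(tips, unlist(lineages))
  if (length(miss))
    stop("species not covered by any lineage: ", paste(miss, collapse = ", "))
  n <- tree$Nnode + length(tips)
  tipLin <- character(length(tips))
  for (ln in names(lineages)) tipLin[tips %in% lineages[[ln]]] <- ln
  desc <- .tipDescList(tree)
  lineage <- character(n)
  cls <- character(n)
  mrcas <- vapply(names(lineages), function(ln) {
    sp <- intersect(lineages[[ln]], tips)
    if (!length(sp)) return(NA_integer_)
    .mrcaNode(tree, match(sp, tips))
  }, integer(1L))
  for (v in seq_len(n)) {
    lns <- sort(unique(tipLin[desc[[v]]]))
    if (length(lns) == 1L) {
      lineage[v] <- lns
      cls[v] <- if (!is.na(mrcas[lns]) && v == mrcas[lns]) "ancestral"
                else "peripheral"
    } else {
      lineage[v] <- paste(lns, collapse = "+")
      cls[v] <- "ancestral"
    }
  }
  new("SpeciesTree", tree = tree, branchLineage = lineage,
      branchClass = cls, lineages = lineages)
}

#' @rdname mrca
#' @export
setMethod("mrca", "SpeciesTree", function(x, leaves) {
  mrca(x@tree, leaves)
})

#' @rdname mrca
#' @export
setMethod("mrca", "GeneTree", function(x, leaves) {
  mrca(x@tree, leaves)
})

#' @rdname mrca
#' @export
setMethod("mrca", "phylo", function(x, leaves) {
  if (length(leaves) == 0L) stop("leaf set must be non-empty")
  idx <- match(leaves, x$tip.label)
  if (anyNA(idx))
    stop("unknown leaf labels: ",
         paste(leaves[is.na(idx)], collapse = ", "))
  .mrcaNode(x, idx)
})

#' Bootstrap support of the clade spanned by a leaf set
#'
#' If \code{leaves} is exactly the leaf set of some node of the rooted gene
#' tree, the support of that node's subtending edge is returned; otherwise
#' \code{NA} ("not a clade").
#'
#' @param geneTree a rooted \code{GeneTree} with supports.
#' @param leaves character vector of gene ids (non-empty).
#' @return the support value, or \code{NA_real_} if the set is not a clade.
#' @export
cladeSupport <- function(geneTree, leaves) {
  if (length(leaves) == 0L) stop("leaf set must be non-empty")
  phy <- geneTree@tree
  idx <- match(leaves, phy$tip.label)
  if (anyNA(idx))
    stop("unknown leaf labels: ", paste(leaves[is.na(idx)], collapse = ", "))
  node <- .mrcaNode(phy, idx)
  tipset <- .tipDescList(phy)[[node]]
  if (!setequal(tipset, idx)) return(NA_real_)
  geneTree@support[node]
}
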