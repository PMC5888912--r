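#' @include AllClasses.R
NULL

#' Most recent common ancestor of a set of leaves
#'
#' @param x a \code{SpeciesTree}, \code{GeneTree} or \code{phylo} object.
#' @param leaves character vector of leaf labels (non-empty). The MRCA of a
#'   single leaf is that leaf.
#' @return the node id (integer) of the most recent common ancestor.
#' @export
setGeneric("mrca", function(x, leaves) standardGeneric("mrca"))

#' Extract the underlying phylo object
#' @param x a tree-carrying object.
#' @export
setGeneric("treeOf", function(x) standardGeneric("treeOf"))

#' Per-node bootstrap support values
#' @param x a \code{GeneTree}.
#' @export
setGeneric("supportValues", function(x) standardGeneric("supportValues"))

#' Gene-to-species map
#' @param x a \code{GeneTree} or \code{SimTruth}.
#' @export
setGeneric("speciesMap", function(x) standardGeneric("speciesMap"))

#' Per-species ortholog counts of an orthogroup
#' @param x an \code{Orthogroup} or \code{DuplicationCensus}.
#' @export
setGeneric("orthologCounts", function(x) standardGeneric("orthologCounts"))

#' Was the orthogroup accepted at the key node?
#' @param x an \code{Orthogroup}.
#' @export
setGeneric("isAccepted", function(x) standardGeneric("isAccepted"))

#' Duplication total of a reconciliation or census
#' @param x a \code{ReconciliationResult}.
#' @export
setGeneric("nDuplications", function(x) standardGeneric("nDuplications"))

#' Loss total of a reconciliation
#' @param x a \code{ReconciliationResult}.
#' @export
setGeneric("nLosses", function(x) standardGeneric("nLosses"))

#' Duplication-loss parsimony cost
#' @param x a \code{ReconciliationResult}.
#' @export
setGeneric("dlCost", function(x) standardGeneric("dlCost"))

setMethod("treeOf", "SpeciesTree", function(x) x@tree)
setMethod("treeOf", "GeneTree", function(x) x@tree)
setMethod("supportValues", "GeneTree", function(x) x@support)
setMethod("speciesMap", "GeneTree", function(x) x@speciesMap)
setMethod("speciesMap", "SimTruth", function(x) x@speciesMap)
setMethod("orthologCounts", "Orthogroup", function(x) x@counts)
setMethod("orthologCounts", "DuplicationCensus", function(x) x@orthologCounts)
setMethod("isAccepted", "Orthogroup", function(x) x@accepted)
setMethod("nDuplications", "ReconciliationResult", function(x) x@D)
setMethod("nLosses", "ReconciliationResult", function(x) x@L)
setMethod("dlCost", "ReconciliationResult", function(x) x@cost)

setMethod("show", "SpeciesTree", function(object) {
  cat("SpeciesTree with", length(object@tree$tip.label), "species and",
      length(object@lineages), "lineages\n")
  cat("  species:", paste(utils::head(object@tree$tip.label, 6L),
                          collapse = ", "),
      if (length(object@tree$tip.label) > 6L) "..." else "", "\n")
  cat("  lineages:", paste(names(object@lineages), collapse = ", "), "\n")
})

setMethod("show", "GeneTree", function(object) {
  cat("GeneTree with", length(object@tree$tip.label), "genes",
      if (object@unrooted) "(unrooted)" else "(rooted)", "\n")
  s <- object@support[!is.na(object@support)]
  if (length(s))
    cat("  supports: ", length(s), " edges, range [",
        min(s), ", ", max(s), "]\n", sep = "")
  cat("  species:", paste(unique(object@speciesMap), collapse = ", "), "\n")
})

setMethod("show", "CodonAlignment", function(object) {
  w <- if (length(object@seqs)) Biostrings::width(object@seqs)[1L] else 0L
  cat("CodonAlignment:", length(object@seqs), "sequences x",
      w %/% 3L, "codon columns (", sum(object@retained), "retained )\n")
  cat("  query:", object@queryId, "\n")
})

setMethod("show", "ReconciliationResult", function(object) {
  cat("ReconciliationResult: D =", object@D, ", L =", object@L,
      ", cost =", object@cost, "\n")
})

setMethod("show", "Orthogroup", function(object) {
  cat("Orthogroup", object@familyId, "with", length(object@members),
      "members; key-node support", object@keySupport,
      if (object@accepted) "(accepted)" else "(rejected)", "\n")
})

setMethod("show", "DuplicationCensus", function(object) {
  cat("DuplicationCensus:", nrow(object@orthologCounts), "families x",
      ncol(object@orthologCounts), "species;",
      sum(object@branchDuplications), "duplications placed\n")
})

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig: E <", object@eCutoff, "; length >=",
      object@lengthFraction, "x query;", object@nBootstrap,
      "bootstrap replicates;", object@codonMode,
      "; support threshold", object@supportThreshold, "\n")
})

setMethod("show", "SimTruth", function(object) {
  nd <- sum(object@events$type == "duplication")
  nl <- sum(object@events$type == "loss")
  cat("SimTruth:", length(object@geneTree$tip.label), "surviving genes;",
      nd, "duplications,", nl, "losses (lambda =", object@lambda,
      ", mu =", object@mu, ")\n")
})
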