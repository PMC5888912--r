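#' @import methods
NULL

setOldClass("phylo")

#' Reference species tree with lineage-labelled branches
#'
#' A rooted, strictly binary species phylogeny. Every branch (identified by
#' its child node) carries a lineage label and a class, either
#' \code{"peripheral"} (inside a lineage crown group, terminals included) or
#' \code{"ancestral"} (lineage stems and deeper internal branches).
#'
#' @slot tree a rooted binary \code{phylo} object with unique tip labels.
#' @slot branchLineage character vector indexed by node id; lineage label of
#'   the branch above each node (the root entry labels the root stem).
#' @slot branchClass character vector indexed by node id; \code{"peripheral"}
#'   or \code{"ancestral"}.
#' @slot lineages named list mapping each terminal lineage to its species.
#' @export
setClass("SpeciesTree", representation(
  tree = "ANY", branchLineage = "character", branchClass = "character",
  lineages = "list"))

setValidity("SpeciesTree", function(object) {
  phy <- object@tree
  if (!inherits(phy, "phylo")) return("tree must be a 'phylo' object")
  if (!ape::is.rooted(phy)) return("species tree must be rooted")
  if (!ape::is.binary(phy)) return("species tree must be strictly binary")
  if (anyDuplicated(phy$tip.label)) return("duplicate species labels")
  n <- phy$Nnode + length(phy$tip.label)
  if (length(object@branchLineage) != n || length(object@branchClass) != n)
    return("branch annotation length must equal the number of nodes")
  if (!all(object@branchClass %in% c("peripheral", "ancestral")))
    return("branch class must be 'peripheral' or 'ancestral'")
  TRUE
})

#' Gene tree with per-edge bootstrap supports and a gene-to-species map
#'
#' Trees are stored rooted; an unrooted tree is represented by a trifurcating
#' root node and \code{unrooted = TRUE}. The support of the edge above a node
#' is stored at that node's index (NA for tips and the root).
#'
#' @slot tree a \code{phylo} object.
#' @slot support numeric vector indexed by node id, values in [0, 100] or NA.
#' @slot speciesMap named character vector, gene id to species id.
#' @slot rearranged logical vector indexed by node id; TRUE marks edges
#'   created by weak-node rearrangement (they carry no support value).
#' @slot unrooted logical flag.
#' @export
setClass("GeneTree", representation(
  tree = "ANY", support = "numeric", speciesMap = "character",
  rearranged = "logical", unrooted = "logical"))

setValidity("GeneTree", function(object) {
  phy <- object@tree
  if (!inherits(phy, "phylo")) return("tree must be a 'phylo' object")
  n <- phy$Nnode + length(phy$tip.label)
  if (anyDuplicated(phy$tip.label)) return("duplicate gene labels")
  if (length(object@support) != n) return("support vector length mismatch")
  s <- object@support[!is.na(object@support)]
  if (length(s) && (any(s < 0) || any(s > 100)))
    return("supports must lie in [0, 100]")
  if (length(object@rearranged) != n)
    return("rearranged flag length mismatch")
  miss <- setdiff(phy$tip.label, names(object@speciesMap))
  if (length(miss))
    return(paste0("genes missing from species map: ",
                  paste(miss, collapse = ", ")))
  TRUE
})

#' Codon-structured nucleotide alignment
#'
#' Rows are aligned coding sequences; gaps occur in whole-codon triples and
#' column \code{i} has codon position \code{(i - 1) %% 3 + 1}. The
#' \code{retained} flag marks codon columns kept after trimming.
#'
#' @slot seqs a \code{DNAStringSet} of equal widths divisible by 3.
#' @slot retained logical vector, one entry per codon column.
#' @slot queryId id of the query sequence driving the relative-length filter.
#' @slot flagged ids of sequences with internal stop codons.
#' @export
setClass("CodonAlignment", representation(
  seqs = "ANY", retained = "logical", queryId = "character",
  flagged = "character"))

setValidity("CodonAlignment", function(object) {
  s <- object@seqs
  if (!inherits(s, "DNAStringSet")) return("seqs must be a DNAStringSet")
  w <- Biostrings::width(s)
  if (length(unique(w)) > 1L) return("all rows must have equal length")
  if (length(w) && w[1L] %% 3L != 0L)
    return("alignment length must be divisible by 3")
  if (length(w) && length(object@retained) != w[1L] %/% 3L)
    return("retained flags must have one entry per codon column")
  if (length(w) && w[1L] > 0L) {
    gaps <- as.matrix(s) == "-"
    for (i in seq_len(nrow(gaps))) {
      g <- gaps[i, ]
      dim(g) <- c(3L, w[1L] %/% 3L)
      if (any(!colSums(g) %in% c(0L, 3L)))
        return(paste0("gaps must occur in whole codons (row ",
                      names(s)[i], ")"))
    }
  }
  TRUE
})

#' Result of LCA reconciliation of a gene tree with the species tree
#'
#' @slot geneTree the rooted \code{GeneTree} that was reconciled.
#' @slot mapping integer vector, gene-tree node id to species-tree node id.
#' @slot events character vector per gene-tree node: \code{"leaf"},
#'   \code{"speciation"} or \code{"duplication"}.
#' @slot branchLosses named integer vector of losses per species-tree branch
#'   (named by the branch's child node id).
#' @slot D,L integer totals; \code{cost = dupCost * D + lossCost * L}.
#' @slot cost numeric reconciliation cost.
#' @export
setClass("ReconciliationResult", representation(
  geneTree = "GeneTree", mapping = "integer", events = "character",
  branchLosses = "integer", D = "integer", L = "integer", cost = "numeric"))

#' An accepted (or rejected) homologous gene clade
#'
#' @slot familyId family identifier.
#' @slot members gene ids in the orthogroup.
#' @slot keySupport bootstrap support of the key node (ingroup/outgroup
#'   separation), in [0, 100].
#' @slot accepted TRUE iff \code{keySupport >= supportThreshold}.
#' @slot counts named integer vector of per-species ortholog counts.
#' @export
setClass("Orthogroup", representation(
  familyId = "character", members = "character", keySupport = "numeric",
  accepted = "logical", counts = "integer"))

setValidity("Orthogroup", function(object) {
  if (length(object@counts) && sum(object@counts) != length(object@members))
    return("per-species counts must sum to the number of members")
  TRUE
})

#' Family-by-species ortholog counts plus per-branch duplication counts
#'
#' @slot orthologCounts integer matrix, families x species.
#' @slot branchDuplications integer matrix, families x species-tree branches
#'   (columns named by branch child node id; "root" is the root stem).
#' @slot familyLosses integer vector of per-family loss totals.
#' @export
setClass("DuplicationCensus", representation(
  orthologCounts = "matrix", branchDuplications = "matrix",
  familyLosses = "integer"))

#' Pipeline thresholds and switches
#'
#' Holds every tunable of the pipeline with its default: similarity screen
#' E-value cutoff (strict \code{<} 1e-3), relative-length filter fraction
#' (0.55), bootstrap support threshold (70), bootstrap replicate count (100),
#' codon-position mode (\code{"Exc3rd"} drops third positions), equal
#' duplication and loss costs, and the random seed.
#'
#' @export
setClass("PipelineConfig", representation(
  eCutoff = "numeric", lengthFraction = "numeric",
  supportThreshold = "numeric", nBootstrap = "integer",
  codonMode = "character", dupCost = "numeric", lossCost = "numeric",
  rngSeed = "integer", maxHits = "numeric", trimMethod = "character",
  maxGapFraction = "numeric", resampleUnit = "character",
  exhaustiveLimit = "integer"))

setValidity("PipelineConfig", function(object) {
  if (object@eCutoff <= 0) return("eCutoff must be positive")
  if (object@lengthFraction <= 0 || object@lengthFraction > 1)
    return("lengthFraction must lie in (0, 1]")
  if (object@supportThreshold < 0 || object@supportThreshold > 100)
    return("supportThreshold must lie in [0, 100]")
  if (object@nBootstrap < 1L) return("nBootstrap must be >= 1")
  if (!object@codonMode %in% c("Exc3rd", "Inc3rd"))
    return("codonMode must be 'Exc3rd' or 'Inc3rd'")
  if (object@dupCost <= 0 || object@lossCost <= 0)
    return("event costs must be positive")
  if (!object@trimMethod %in% c("gappyout", "maxgap"))
    return("trimMethod must be 'gappyout' or 'maxgap'")
  if (!object@resampleUnit %in% c("codon", "site"))
    return("resampleUnit must be 'codon' or 'site'")
  TRUE
})

#' TN93 distance matrix with per-pair validity flags
#'
#' @slot d symmetric numeric matrix of distances (substitutions/site).
#' @slot valid logical matrix; FALSE marks saturated pairs (distance capped)
#'   or pairs with fewer than \code{minSites} comparable sites.
#' @slot sites integer matrix of comparable (pairwise non-gap) site counts.
#' @export
setClass("DistanceMatrix", representation(
  d = "matrix", valid = "matrix", sites = "matrix"))

setValidity("DistanceMatrix", function(object) {
  d <- object@d
  if (nrow(d) != ncol(d)) return("distance matrix must be square")
  if (any(abs(diag(d)) > 1e-12)) return("diagonal must be zero")
  if (max(abs(d - t(d)), na.rm = TRUE) > 1e-9)
    return("distance matrix must be symmetric")
  if (any(d[object@valid] < 0)) return("valid distances must be >= 0")
  TRUE
})

#' Parameters of the TN93 substitution process used by the simulator
#'
#' @slot baseFreq stationary base frequencies (A, C, G, T), summing to 1.
#' @slot alpha1 purine (A/G) transition rate.
#' @slot alpha2 pyrimidine (C/T) transition rate.
#' @slot beta transversion rate.
#' @slot posRates relative rate multipliers for codon positions 1-3.
#' @export
setClass("SubstitutionParams", representation(
  baseFreq = "numeric", alpha1 = "numeric", alpha2 = "numeric",
  beta = "numeric", posRates = "numeric"))

setValidity("SubstitutionParams", function(object) {
  f <- object@baseFreq
  if (length(f) != 4L || any(f <= 0)) return("need 4 positive frequencies")
  if (abs(sum(f) - 1) > 1e-12) return("base frequencies must sum to 1")
  if (object@alpha1 <= 0 || object@alpha2 <= 0 || object@beta <= 0)
    return("rates must be positive")
  if (length(object@posRates) != 3L || any(object@posRates <= 0))
    return("need 3 positive codon-position rate multipliers")
  TRUE
})

#' Ground truth of one simulated gene family
#'
#' @slot geneTree \code{phylo}; the true gene tree of surviving copies.
#' @slot speciesMap named character vector, gene id to species id.
#' @slot events data.frame with columns \code{type} ("duplication"/"loss"),
#'   \code{branch} (species-tree child node id) and \code{time} along the
#'   branch.
#' @slot lambda,mu duplication and loss rates per copy per unit length.
#' @slot seed RNG seed used.
#' @export
setClass("SimTruth", representation(
  geneTree = "ANY", speciesMap = "character", events = "data.frame",
  lambda = "numeric", mu = "numeric", seed = "integer"))
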