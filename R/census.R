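#' @include AllClasses.R AllGenerics.R phylo-core.R reconciler.R
NULL

#' Bootstrap support of the key node separating two species sets
#'
#' The key node is the smallest clade containing every gene mapped to an
#' ingroup species and no gene mapped to an outgroup species (for orthogroup
#' acceptance: the separation of deuterostome from protostome genes). If no
#' such clade exists (the ingroup genes are paraphyletic with respect to the
#' outgroup genes), or if the key edge carries no support value (for
#' instance after rearrangement), 0 is returned.
#'
#' @param gt a rooted \code{GeneTree} with supports.
#' @param outgroupSpecies,ingroupSpecies non-empty character vectors of
#'   species ids.
#' @return the key-node support in [0, 100]; 0 when the criterion is unmet.
#' @export
keyNodeSupport <- function(gt, outgroupSpecies, ingroupSpecies) {
  if (!length(outgroupSpecies) || !length(ingroupSpecies))
    stop("outgroup and ingroup species sets must be non-empty")
  phy <- gt@tree
  sp <- gt@speciesMap[phy$tip.label]
  inGenes <- phy$tip.label[sp %in% ingroupSpecies]
  outGenes <- phy$tip.label[sp %in% outgroupSpecies]
  if (!length(inGenes) || !length(outGenes))
    stop("tree must contain at least one gene from each species set")
  node <- mrca(phy, inGenes)
  below <- phy$tip.label[.tipDescList(phy)[[node]]]
  if (any(outGenes %in% below)) return(0)
  s <- gt@support[node]
  if (is.na(s)) 0 else s
}

#' Accept or reject an orthogroup at the key node
#'
#' Acceptance is inclusive at the boundary: support exactly equal to the
#' threshold is accepted.
#'
#' @param support key-node support in [0, 100].
#' @param config a \code{PipelineConfig}.
#' @return logical.
#' @export
acceptOrthogroup <- function(support, config = pipelineConfig()) {
  if (support < 0 || support > 100) stop("support outside [0, 100]")
  support >= config@supportThreshold
}

#' Build an Orthogroup from a gene tree and its key-node support
#'
#' @param familyId family identifier.
#' @param members gene ids.
#' @param keySupport key-node support.
#' @param speciesMap named character vector covering the members.
#' @param config a \code{PipelineConfig}.
#' @return an \code{Orthogroup} (counts over the species present).
#' @export
Orthogroup <- function(familyId, members, keySupport, speciesMap,
                       config = pipelineConfig()) {
  sp <- speciesMap[members]
  counts <- table(sp)
  new("Orthogroup", familyId = familyId, members = members,
      keySupport = keySupport,
      accepted = acceptOrthogroup(keySupport, config),
      counts = stats::setNames(as.integer(counts), names(counts)))
}

#' Per-species ortholog counts of an orthogroup, zero-filled
#'
#' @param og an \code{Orthogroup}.
#' @param st a \code{SpeciesTree}; counts are reported for every species of
#'   the tree (zero for absent species).
#' @return named integer vector over the species-tree leaves.
#' @export
countOrthologs <- function(og, st) {
  species <- st@tree$tip.label
  unknown <- setdiff(names(og@counts), species)
  if (length(unknown))
    stop("members mapped to species absent from the species tree: ",
         paste(unknown, collapse = ", "))
  out <- stats::setNames(integer(length(species)), species)
  out[names(og@counts)] <- og@counts
  out
}

#' Place duplications on species-tree branches
#'
#' Each duplication node \code{v} of the reconciliation contributes one
#' count to the species-tree branch immediately above \code{M(v)} (the
#' branch is named by its child node id; duplications mapped to the root
#' fall on the \code{"root"} stem). The counts sum to \code{D}.
#'
#' @param rr a \code{ReconciliationResult}.
#' @param st the \code{SpeciesTree} used in the reconciliation.
#' @return named integer vector over species-tree branches.
#' @export
placeDuplications <- function(rr, st) {
  nsp <- st@tree$Nnode + length(st@tree$tip.label)
  out <- stats::setNames(integer(nsp), as.character(seq_len(nsp)))
  dups <- which(rr@events == "duplication")
  for (v in dups) {
    m <- rr@mapping[v]
    out[as.character(m)] <- out[as.character(m)] + 1L
  }
  root <- .rootNode(st@tree)
  names(out)[root] <- "root"
  out
}

#' Assemble a DuplicationCensus from orthogroups and reconciliations
#'
#' Only accepted orthogroups enter the census.
#'
#' @param orthogroups list of \code{Orthogroup} objects.
#' @param reconciliations list of \code{ReconciliationResult} objects,
#'   parallel to \code{orthogroups}.
#' @param st a \code{SpeciesTree}.
#' @return a \code{DuplicationCensus}.
#' @export
buildCensus <- function(orthogroups, reconciliations, st) {
  keep <- vapply(orthogroups, isAccepted, logical(1L))
  orthogroups <- orthogroups[keep]
  reconciliations <- reconciliations[keep]
  species <- st@tree$tip.label
  nsp <- st@tree$Nnode + length(species)
  branchNames <- as.character(seq_len(nsp))
  branchNames[.rootNode(st@tree)] <- "root"
  if (!length(orthogroups)) {
    return(new("DuplicationCensus",
               orthologCounts = matrix(0L, 0L, length(species),
                                       dimnames = list(NULL, species)),
               branchDuplications = matrix(0L, 0L, nsp,
                                           dimnames = list(NULL, branchNames)),
               familyLosses = integer(0L)))
  }
  fam <- vapply(orthogroups, function(o) o@familyId, character(1L))
  oc <- t(vapply(orthogroups, countOrthologs, st = st,
                 FUN.VALUE = stats::setNames(integer(length(species)),
                                             species)))
  bd <- t(vapply(reconciliations, placeDuplications, st = st,
                 FUN.VALUE = stats::setNames(integer(nsp), branchNames)))
  fl <- vapply(reconciliations, nLosses, integer(1L))
  rownames(oc) <- rownames(bd) <- fam
  new("DuplicationCensus", orthologCounts = oc, branchDuplications = bd,
      familyLosses = fl)
}

#' Census from an explicit family-by-species count matrix
#'
#' Used to analyse transcribed published count tables (no duplication
#' placements).
#'
#' @param counts integer matrix, families x species.
#' @return a \code{DuplicationCensus} with empty branch duplications.
#' @export
censusFromCounts <- function(counts) {
  new("DuplicationCensus", orthologCounts = as.matrix(counts),
      branchDuplications = matrix(0L, nrow(counts), 0L,
                                  dimnames = list(rownames(counts), NULL)),
      familyLosses = integer(nrow(counts)))
}

#' Aggregate a census by lineage
#'
#' Per-lineage ortholog averages are arithmetic means of the member
#' species' totals. Duplication counts are split into \code{peripheral}
#' (branches strictly inside a lineage crown group, terminals included) and
#' \code{ancestral} (the lineage stem and deeper branches, reported under
#' the label of the lineages they span). Both aggregation conventions for
#' per-lineage duplication figures are reported: the plain sum and the
#' per-family average (sum divided by the number of census families).
#'
#' @param census a \code{DuplicationCensus}.
#' @param st the \code{SpeciesTree}.
#' @param lineageMap named list: lineage name -> member species. Defaults to
#'   the terminal lineages of \code{st}. Composite lineages (e.g.
#'   ambulacrarians = hemichordates + echinoderms) may be included; ortholog
#'   averages are then taken over all member species.
#' @return a list with \code{speciesTotals}, \code{lineageAverages},
#'   \code{dupPeripheral}, \code{dupStem}, \code{dupDeep},
#'   \code{dupPerFamily} and \code{nFamilies}.
#' @export
lineageAggregate <- function(census, st, lineageMap = NULL) {
  if (is.null(lineageMap)) lineageMap <- st@lineages
  oc <- census@orthologCounts
  speciesTotals <- colSums(oc)
  missing <- setdiff(colnames(oc), unlist(lineageMap))
  if (length(missing))
    stop("species missing from the lineage map: ",
         paste(missing, collapse = ", "))
  lineageAverages <- vapply(lineageMap, function(sp) {
    sp <- intersect(sp, names(speciesTotals))
    if (!length(sp)) return(NA_real_)
    mean(speciesTotals[sp])
  }, numeric(1L))

  bd <- census@branchDuplications
  nfam <- nrow(oc)
  perBranch <- if (ncol(bd)) colSums(bd) else integer(0L)
  dupPeripheral <- stats::setNames(numeric(length(lineageMap)),
                                   names(lineageMap))
  dupStem <- dupPeripheral
  dupDeep <- numeric(0L)
  if (length(perBranch)) {
    lin <- st@branchLineage
    cls <- st@branchClass
    for (b in seq_along(perBranch)) {
      cnt <- perBranch[b]
      if (cnt == 0) next
      node <- if (names(perBranch)[b] == "root")
        .rootNode(st@tree) else as.integer(names(perBranch)[b])
      lb <- lin[node]
      if (cls[node] == "peripheral" && lb %in% names(dupPeripheral)) {
        dupPeripheral[lb] <- dupPeripheral[lb] + cnt
      } else if (lb %in% names(dupStem)) {
        dupStem[lb] <- dupStem[lb] + cnt
      } else {
        dupDeep[lb] <- sum(dupDeep[lb], cnt, na.rm = TRUE)
      }
    }
  }
  list(speciesTotals = speciesTotals,
       lineageAverages = lineageAverages,
       dupPeripheral = dupPeripheral,
       dupStem = dupStem,
       dupDeep = dupDeep,
       dupPerFamily = if (nfam) (dupPeripheral + dupStem) / nfam else
         dupPeripheral * NA_real_,
       nFamilies = nfam)
}

#' Transcribed published ortholog-count table for 16 paraxial-muscle gene
#' families across 13 deuterostome genomes
#'
#' The packaged family-by-species matrix of ortholog counts for 16
#' contractile-protein gene families (paraxial-type actin, skeletal myosin
#' heavy chain, tropomyosin, troponins I/T/C, tropomodulin, alpha-actinin,
#' calcineurins A/B, capping proteins alpha/beta, muscle LIM, FHL LIM,
#' titin, ryanodine receptor) across the 13 deuterostome species of the
#' reference tree. Row sums reproduce the published per-species totals.
#'
#' @return an integer matrix, species (rows) x families (columns).
#' @export
muscleOrthologTable <- function() {
  path <- system.file("extdata", "muscle_ortholog_counts.tsv",
                      package = "OrthoCensus", mustWork = TRUE)
  df <- utils::read.delim(path, header = TRUE, row.names = 1L,
                          check.names = FALSE)
  as.matrix(df)
}

#' Deuterostome lineage definitions used for census aggregation
#'
#' Terminal lineages plus the composite ambulacrarian (hemichordates +
#' echinoderms) and chordate (cephalochordates + urochordates +
#' vertebrates) groupings.
#'
#' @return named list of species vectors.
#' @export
deuterostomeLineages <- function() {
  st <- speciesTreeFixture()
  l <- st@lineages[setdiff(names(st@lineages), "outgroup")]
  c(l, list(
    ambulacraria = c(l$hemichordata, l$echinodermata),
    chordata = c(l$cephalochordata, l$urochordata, l$vertebrata)))
}
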