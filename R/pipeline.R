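#' @include AllClasses.R phylo-core.R homology-screen.R alignment-prep.R
#' @include nj-engine.R reconciler.R census.R
NULL

#' Import an externally inferred gene tree for rearrangement/reconciliation
#'
#' Reads a Newick gene tree (supports as internal-node labels, e.g. a
#' maximum-likelihood tree with bootstrap values) and a gene-to-species map,
#' and validates the pair. Trees without support values are accepted with a
#' warning; all their edges are then treated as weak (rearrangeable).
#'
#' @param newickPath Newick file path.
#' @param mapPath two-column TSV (\code{gene_id}, \code{species_id}, header
#'   required); NULL applies the default prefix mapping rule.
#' @return a \code{GeneTree}.
#' @export
importExternalTree <- function(newickPath, mapPath = NULL) {
  text <- paste(readLines(newickPath), collapse = "")
  map <- if (is.null(mapPath)) NULL else readSpeciesMap(mapPath)
  probe <- parseNewick(text)
  if (!is.null(map)) {
    unmapped <- setdiff(probe@tree$tip.label, names(map))
    if (length(unmapped))
      stop("leaves absent from the map: ", paste(unmapped, collapse = ", "))
  }
  gt <- parseNewick(text, speciesMap = map)
  ntip <- length(gt@tree$tip.label)
  internal <- ntip + seq_len(gt@tree$Nnode)[-1L]
  if (length(internal) && all(is.na(gt@support[internal])))
    warning("tree carries no support values; all edges treated as weak")
  gt
}

#' Run the two-step orthology-identification pipeline on a fixture directory
#'
#' Executes, for every family in the directory (as laid out by
#' \code{\link{makePipelineFixture}}): E-value screening of the hit table,
#' back-translation of the protein alignment onto the CDS, gap-based codon
#' column trimming, the relative-length filter, codon-position selection,
#' NJ/TN93 tree building with bootstrap supports, duplication-loss rooting,
#' weak-node rearrangement against the species tree, key-node orthogroup
#' acceptance, LCA reconciliation, and duplication placement. Stage errors
#' are recorded per family and the run continues. All randomness derives
#' from \code{config@rngSeed}.
#'
#' @param dir fixture directory containing \code{manifest.json},
#'   per-family \code{*_hits.tsv}, \code{*_prot.fasta}, \code{*_cds.fasta},
#'   \code{*_map.tsv} and \code{species_tree.nwk}.
#' @param st the reference \code{SpeciesTree}; defaults to the packaged
#'   deuterostome fixture.
#' @param config a \code{PipelineConfig}.
#' @param outgroupLineage name of the species-tree lineage whose species
#'   form the key-node outgroup (protostomes in the packaged fixture).
#' @param outDir optional directory for the JSON report and census TSVs.
#' @return a list (pipeline report): \code{families} (per-family stage
#'   outcomes), \code{census} (a \code{DuplicationCensus} over accepted
#'   families), \code{config}, \code{seed} and \code{nAccepted}.
#' @export
runPipeline <- function(dir, st = speciesTreeFixture(),
                        config = pipelineConfig(),
                        outgroupLineage = "outgroup", outDir = NULL) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  famIds <- unlist(manifest$families)
  outSp <- st@lineages[[outgroupLineage]]
  if (is.null(outSp)) stop("unknown outgroup lineage: ", outgroupLineage)
  inSp <- setdiff(st@tree$tip.label, outSp)

  orthogroups <- list()
  reconciliations <- list()
  famReports <- list()
  for (fi in seq_along(famIds)) {
    fid <- famIds[fi]
    famConfig <- config
    famConfig@rngSeed <-
      as.integer((as.numeric(config@rngSeed) + 7919 * fi) %% 2147483647)
    rec <- list(family = fid, status = "ok", reason = NA_character_)
    res <- tryCatch({
      hits <- readHits(file.path(dir, paste0(fid, "_hits.tsv")))
      keep <- filterHits(hits, famConfig)
      qid <- hits$query_id[1L]
      keep <- union(qid, keep)
      rec$screened <- length(keep)

      prot <- .readFastaFlat(file.path(dir, paste0(fid, "_prot.fasta")))
      cds <- .readFastaFlat(file.path(dir, paste0(fid, "_cds.fasta")))
      map <- readSpeciesMap(file.path(dir, paste0(fid, "_map.tsv")))
      prot <- prot[intersect(names(prot), keep)]
      if (length(unique(nchar(prot))) != 1L)
        stop("protein rows are not aligned (unequal widths)")

      ca <- withCallingHandlers(
        backtranslate(prot, cds, queryId = qid),
        warning = function(w) {
          rec$warnings <<- c(rec$warnings, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      ca <- trimGappyColumns(ca, famConfig)
      ca <- applyLengthFilter(ca, famConfig)
      rec$retained <- length(ca@seqs)
      if (length(ca@seqs) < 4L)
        stop("fewer than four sequences after filtering")

      sites <- selectCodonPositions(ca, famConfig@codonMode)
      gt <- withCallingHandlers(
        bootstrapSupport(sites, famConfig,
                         speciesMap = map[rownames(sites)]),
        warning = function(w) {
          rec$warnings <<- c(rec$warnings, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      rooted <- rootByDL(gt, st, famConfig)
      rearr <- rearrangeWeakNodes(rooted, st, famConfig)
      ks <- keyNodeSupport(rearr, outSp, inSp)
      rec$keySupport <- ks

      rr <- lcaReconcile(rearr, st, famConfig)
      rec$D <- rr@D; rec$L <- rr@L; rec$cost <- rr@cost

      # orthogroup = the key-node clade (deuterostome genes)
      sp <- rearr@speciesMap[rearr@tree$tip.label]
      members <- rearr@tree$tip.label[sp %in% inSp]
      og <- Orthogroup(fid, members, ks, rearr@speciesMap, famConfig)
      rec$accepted <- og@accepted
      list(og = og, rr = rr)
    }, error = function(e) {
      rec$status <<- "error"
      rec$reason <<- conditionMessage(e)
      rec$accepted <<- FALSE
      NULL
    })
    if (!is.null(res)) {
      orthogroups[[fid]] <- res$og
      reconciliations[[fid]] <- res$rr
    }
    famReports[[fid]] <- rec
  }

  census <- buildCensus(orthogroups, reconciliations, st)
  nAccepted <- sum(vapply(famReports, function(r) isTRUE(r$accepted),
                          logical(1L)))
  report <- list(families = famReports, census = census,
                 config = config, seed = config@rngSeed,
                 nAccepted = nAccepted)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(census@orthologCounts,
                       file.path(outDir, "ortholog_counts.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    utils::write.table(census@branchDuplications,
                       file.path(outDir, "branch_duplications.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    jsonlite::write_json(
      list(seed = config@rngSeed, n_accepted = nAccepted,
           families = famReports),
      file.path(outDir, "report.json"), auto_unbox = TRUE, pretty = TRUE,
      force = TRUE)
  }
  if (length(famIds) && nAccepted == 0L)
    warning("no family passed the key-node acceptance criterion")
  report
}

#' End-to-end duplication-recovery study on simulated gene families
#'
#' Simulates \code{nFamilies} gene families on the reference species tree,
#' runs the full pipeline on the generated fixture, and compares the
#' census duplication count of each family with the true number of
#' duplication events in the simulation log. Families whose pipeline run
#' fails are reported with \code{censusD = NA} (they count as
#' non-recoveries).
#'
#' @param nFamilies number of families.
#' @param lambda,mu birth-death rates per copy per unit branch length.
#' @param nCodons codons per family.
#' @param seed master seed for simulation and pipeline.
#' @param st the reference \code{SpeciesTree}.
#' @param config a \code{PipelineConfig}.
#' @param dir scratch directory for the fixture (a temporary directory by
#'   default, removed afterwards).
#' @return data.frame with columns \code{family}, \code{trueD},
#'   \code{censusD}, \code{accepted} and \code{status}.
#' @export
duplicationRecoveryStudy <- function(nFamilies = 200L, lambda = 0.7,
                                     mu = 0, nCodons = 3000L, seed = 1L,
                                     st = speciesTreeFixture(),
                                     config = pipelineConfig(rngSeed = seed),
                                     dir = NULL) {
  cleanup <- is.null(dir)
  if (is.null(dir)) dir <- tempfile("recovery_fixture_")
  fx <- makePipelineFixture(st, lambda = lambda, mu = mu,
                            nFamilies = nFamilies, nCodons = nCodons,
                            seed = seed, dir = dir, overwrite = TRUE)
  on.exit(if (cleanup) unlink(dir, recursive = TRUE), add = TRUE)
  res <- suppressWarnings(runPipeline(dir, st, config))
  fam <- names(fx$truth)
  trueD <- vapply(fx$truth, function(t)
    sum(t@events$type == "duplication"), integer(1L))
  censusD <- rep(NA_integer_, length(fam))
  names(censusD) <- fam
  bd <- res$census@branchDuplications
  for (f in intersect(fam, rownames(bd))) censusD[f] <- sum(bd[f, ])
  status <- vapply(res$families[fam], function(r) r$status, character(1L))
  accepted <- vapply(res$families[fam], function(r) isTRUE(r$accepted),
                     logical(1L))
  data.frame(family = fam, trueD = unname(trueD),
             censusD = unname(censusD), accepted = unname(accepted),
             status = unname(status), row.names = NULL)
}

#' Read a pipeline configuration from a declarative YAML file
#'
#' Unknown keys raise an error; missing keys take the package defaults
#' (see \code{\link{pipelineConfig}}).
#'
#' @param path YAML file path.
#' @return a \code{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(pipelineConfig))
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  do.call(pipelineConfig, vals)
}

# minimal single-line FASTA reader (fixture files are written single-line);
# multi-line records are concatenated
.readFastaFlat <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  id <- sub("^>", "", lines[hdr])
  id <- sub("\\s.*$", "", id)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, character(1L),
                 collapse = "")
  stats::setNames(unname(seqs), id)
}
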