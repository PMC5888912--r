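#' @include AllClasses.R
NULL

#' Pipeline configuration constructor
#'
#' @param eCutoff E-value screen cutoff; hits are retained when their E-value
#'   is strictly below this value.
#' @param lengthFraction relative-length filter: sequences covering fewer
#'   than this fraction of the query's residues over retained columns are
#'   removed (a ratio exactly equal survives).
#' @param supportThreshold bootstrap percentage below which an edge is
#'   rearrangeable, and at-or-above which an orthogroup key node is accepted.
#' @param nBootstrap number of bootstrap replicates.
#' @param codonMode \code{"Exc3rd"} (drop third codon positions) or
#'   \code{"Inc3rd"} (keep all positions).
#' @param dupCost,lossCost duplication-loss parsimony weights (equal by
#'   default).
#' @param rngSeed integer seed controlling every stochastic step.
#' @param maxHits optional cap on the number of screened hits per query.
#' @param trimMethod \code{"gappyout"} (slope heuristic on the gap-score
#'   distribution) or \code{"maxgap"} (simple gap-fraction cutoff).
#' @param maxGapFraction cutoff used by the \code{"maxgap"} trim method.
#' @param resampleUnit bootstrap resampling unit: \code{"codon"} (whole
#'   codons, the default for codon-structured alignments) or \code{"site"}.
#' @param exhaustiveLimit weak regions with at most this many boundary
#'   subtrees are rearranged by exhaustive enumeration; larger regions use
#'   greedy nearest-neighbor-interchange hill climbing.
#' @return a \code{PipelineConfig}.
#' @export
pipelineConfig <- function(eCutoff = 1e-3, lengthFraction = 0.55,
                           supportThreshold = 70, nBootstrap = 100L,
                           codonMode = "Exc3rd", dupCost = 1, lossCost = 1,
                           rngSeed = 1L, maxHits = Inf,
                           trimMethod = "gappyout", maxGapFraction = 0.8,
                           resampleUnit = "codon", exhaustiveLimit = 7L) {
  new("PipelineConfig", eCutoff = eCutoff, lengthFraction = lengthFraction,
      supportThreshold = supportThreshold,
      nBootstrap = as.integer(nBootstrap), codonMode = codonMode,
      dupCost = dupCost, lossCost = lossCost, rngSeed = as.integer(rngSeed),
      maxHits = maxHits, trimMethod = trimMethod,
      maxGapFraction = maxGapFraction, resampleUnit = resampleUnit,
      exhaustiveLimit = as.integer(exhaustiveLimit))
}

#' Read a similarity hit table (BLAST outfmt-6 column order)
#'
#' Columns: query_id, subject_id, pct_identity, aln_len, mismatches,
#' gapopens, qstart, qend, sstart, send, e_value, bit_score. A header line
#' starting with \code{query_id} is tolerated and skipped.
#'
#' @param path TSV file path.
#' @return a data.frame of hit records.
#' @export
readHits <- function(path) {
  first <- readLines(path, n = 1L)
  hasHeader <- grepl("^query_id", first)
  cols <- c("query_id", "subject_id", "pct_identity", "aln_len",
            "mismatches", "gapopens", "qstart", "qend", "sstart", "send",
            "e_value", "bit_score")
  df <- utils::read.delim(path, header = hasHeader,
                          stringsAsFactors = FALSE)
  if (!hasHeader) names(df) <- cols[seq_len(ncol(df))]
  df
}

#' Screen similarity hits by E-value
#'
#' Subjects with an E-value strictly below the cutoff are retained (the
#' comparison is strict \code{<}); duplicates are collapsed, preserving the
#' order of first appearance. If \code{maxHits} is finite, only the first
#' \code{maxHits} rows (by increasing E-value, ties by input order) enter
#' the screen.
#'
#' @param hits data.frame with at least \code{subject_id} and \code{e_value}.
#' @param config a \code{PipelineConfig}.
#' @return character vector of retained subject ids.
#' @export
filterHits <- function(hits, config = pipelineConfig()) {
  if (NROW(hits) == 0L) return(character(0L))
  if (!all(c("subject_id", "e_value") %in% names(hits)))
    stop("hits must have columns 'subject_id' and 'e_value'")
  if (any(hits$e_value < 0)) stop("negative E-values are invalid")
  if (any(!nzchar(hits$subject_id))) stop("empty subject ids are invalid")
  if (is.finite(config@maxHits)) {
    ord <- order(hits$e_value)
    hits <- hits[ord[seq_len(min(length(ord), config@maxHits))], ]
  }
  keep <- hits$subject_id[hits$e_value < config@eCutoff]
  unique(keep)
}

#' Keep the longest transcript variant per locus
#'
#' Ties are broken by the lexicographically smaller transcript id.
#'
#' @param geneRecords data.frame with columns \code{locus_id},
#'   \code{transcript_id} and \code{cds_length}.
#' @return named character vector: locus id -> selected transcript id.
#' @export
selectLongestVariant <- function(geneRecords) {
  stopifnot(all(c("locus_id", "transcript_id", "cds_length") %in%
                  names(geneRecords)))
  if (any(geneRecords$cds_length <= 0))
    stop("cds_length must be positive")
  sel <- vapply(split(geneRecords, geneRecords$locus_id), function(g) {
    g <- g[order(-g$cds_length, g$transcript_id), ]
    as.character(g$transcript_id[1L])
  }, character(1L))
  sel
}

#' Naive shared-k-mer similarity search (synthetic stand-in)
#'
#' A deterministic ranking of database proteins by the number of distinct
#' k-mers shared with the query. The emitted \code{e_value} is a monotone
#' transform of the shared-k-mer count (\code{10^-shared}) and is synthetic:
#' it exists only so that end-to-end runs on simulated data need no external
#' search binary. Ties are broken by Jaccard similarity of the k-mer sets
#' (so a sequence identical to the query ranks first), then by subject id.
#'
#' @param query a protein sequence (character string or \code{AAString}).
#' @param database a named character vector or \code{AAStringSet}.
#' @param k k-mer length (>= 2, not longer than the query).
#' @return a data.frame of hit records in rank order, with columns
#'   \code{query_id}, \code{subject_id}, \code{e_value}, \code{bit_score}
#'   and \code{aln_len}.
#' @export
kmerSimilaritySearch <- function(query, database, k = 5L) {
  qid <- "query"
  if (inherits(query, "AAString")) query <- as.character(query)
  if (!is.null(names(query))) qid <- names(query)[1L]
  query <- as.character(query)[1L]
  if (inherits(database, "AAStringSet")) {
    database <- stats::setNames(as.character(database), names(database))
  }
  if (k < 2L) stop("k must be >= 2")
  if (nchar(query) < k) stop("k is longer than the query sequence")
  if (length(database) == 0L)
    return(data.frame(query_id = character(0L), subject_id = character(0L),
                      e_value = numeric(0L), bit_score = numeric(0L),
                      aln_len = integer(0L)))
  short <- nchar(database) < k
  if (any(short))
    stop("database sequences shorter than k: ",
         paste(names(database)[short], collapse = ", "))
  kmers <- function(s) {
    n <- nchar(s)
    unique(substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
  }
  qk <- kmers(query)
  shared <- numeric(length(database))
  jac <- numeric(length(database))
  for (i in seq_along(database)) {
    sk <- kmers(database[[i]])
    s <- length(intersect(qk, sk))
    shared[i] <- s
    jac[i] <- s / length(union(qk, sk))
  }
  ord <- order(-shared, -jac, names(database))
  data.frame(query_id = qid,
             subject_id = names(database)[ord],
             e_value = 10^(-shared[ord]),
             bit_score = shared[ord],
             aln_len = nchar(database)[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}
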