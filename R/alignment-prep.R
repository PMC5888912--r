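#' @include AllClasses.R
NULL

.STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Force CDS sequences onto a protein alignment (back-translation)
#'
#' Each aligned amino acid is replaced by its codon from the corresponding
#' CDS; each protein gap becomes \code{"---"}. A single trailing stop codon
#' on a CDS is trimmed before the length check. Internal stop codons are
#' tolerated: the sequence is flagged and a warning names it.
#'
#' @param pa an \code{AAStringSet} (or named character vector) of aligned
#'   protein sequences of equal width, gaps as \code{"-"}.
#' @param cds a \code{DNAStringSet} (or named character vector) of unaligned
#'   coding sequences covering all alignment rows.
#' @param queryId id of the query row (stored on the result; defaults to the
#'   first row).
#' @return a \code{CodonAlignment} with all codon columns retained.
#' @export
backtranslate <- function(pa, cds, queryId = NULL) {
  if (inherits(pa, "AAStringSet")) pa <- stats::setNames(as.character(pa), names(pa))
  if (inherits(cds, "DNAStringSet")) cds <- stats::setNames(as.character(cds), names(cds))
  if (is.null(names(pa))) stop("protein alignment rows must be named")
  if (length(unique(nchar(pa))) > 1L)
    stop("protein alignment rows must have equal length")
  miss <- setdiff(names(pa), names(cds))
  if (length(miss))
    stop("CDS missing for: ", paste(miss, collapse = ", "))
  out <- character(length(pa))
  flagged <- character(0L)
  for (i in seq_along(pa)) {
    id <- names(pa)[i]
    aa <- strsplit(pa[[i]], "")[[1L]]
    n_aa <- sum(aa != "-")
    dna <- toupper(cds[[id]])
    if (nchar(dna) %% 3L != 0L)
      stop("CDS length of '", id, "' is not a multiple of 3")
    ncod <- nchar(dna) %/% 3L
    codons <- substring(dna, 3L * seq_len(ncod) - 2L, 3L * seq_len(ncod))
    if (ncod == n_aa + 1L && codons[ncod] %in% .STOP_CODONS) {
      codons <- codons[-ncod]
      ncod <- ncod - 1L
    }
    if (ncod != n_aa)
      stop("CDS of '", id, "' has ", ncod,
           " codons but the aligned protein has ", n_aa, " residues")
    if (any(codons %in% .STOP_CODONS)) flagged <- c(flagged, id)
    row <- rep("---", length(aa))
    row[aa != "-"] <- codons
    out[i] <- paste(row, collapse = "")
  }
  if (length(flagged))
    warning("internal stop codon(s) in: ", paste(flagged, collapse = ", "))
  names(out) <- names(pa)
  if (is.null(queryId)) queryId <- names(pa)[1L]
  ncol <- if (length(out)) nchar(out[[1L]]) %/% 3L else 0L
  new("CodonAlignment", seqs = Biostrings::DNAStringSet(out),
      retained = rep(TRUE, ncol), queryId = queryId, flagged = flagged)
}

#' Translate the rows of a codon alignment back to proteins
#'
#' Gap codons become \code{"-"}; stop codons become \code{"X"}.
#'
#' @param ca a \code{CodonAlignment}.
#' @param retainedOnly translate retained codon columns only.
#' @return named character vector of aligned protein sequences.
#' @export
translateCodonAlignment <- function(ca, retainedOnly = FALSE) {
  m <- .codonMatrix(ca)
  if (retainedOnly) m <- m[, ca@retained, drop = FALSE]
  code <- Biostrings::GENETIC_CODE
  tr <- apply(m, 1L, function(cod) {
    aa <- ifelse(cod == "---", "-", {
      v <- code[cod]
      v[is.na(v)] <- "X"
      v
    })
    aa[aa == "*"] <- "X"
    paste(aa, collapse = "")
  })
  stats::setNames(tr, names(ca@seqs))
}

# rows x codon-columns matrix of codon strings
.codonMatrix <- function(ca) {
  ch <- as.matrix(ca@seqs)
  ncod <- ncol(ch) %/% 3L
  m <- matrix("", nrow(ch), ncod, dimnames = list(names(ca@seqs), NULL))
  for (j in seq_len(ncod)) {
    m[, j] <- paste0(ch[, 3L * j - 2L], ch[, 3L * j - 1L], ch[, 3L * j])
  }
  m
}

#' Trim gap-rich codon columns
#'
#' The default method is a gappyout-style heuristic evaluated at whole-codon
#' granularity: codon columns are scored by their gap fraction, the distinct
#' gap fractions define points on the gap-score distribution, and the cut is
#' placed at the steepest slope of that distribution (the largest drop in
#' gap fraction per column mass); columns with a gap fraction above the cut
#' are dropped. The decision is computed from all columns, so trimming is
#' idempotent. The \code{"maxgap"} fallback drops columns whose gap fraction
#' exceeds \code{maxGapFraction}.
#'
#' @param ca a \code{CodonAlignment} with at least two rows.
#' @param config a \code{PipelineConfig} (fields \code{trimMethod} and
#'   \code{maxGapFraction}).
#' @return the \code{CodonAlignment} with updated retained flags.
#' @export
trimGappyColumns <- function(ca, config = pipelineConfig()) {
  if (length(ca@seqs) < 2L) stop("need at least two rows to trim")
  m <- .codonMatrix(ca)
  gapFrac <- colMeans(m == "---")
  retained <- if (config@trimMethod == "maxgap") {
    gapFrac <= config@maxGapFraction
  } else {
    .gappyoutRetained(gapFrac)
  }
  if (!any(retained)) stop("alignment eliminated by trimming")
  ca@retained <- retained
  ca
}

# slope heuristic: distinct gap fractions descending define points
# (cumulative column fraction, gap fraction); cut below the steepest drop
.gappyoutRetained <- function(gapFrac) {
  u <- sort(unique(gapFrac), decreasing = TRUE)
  if (length(u) == 1L) return(rep(TRUE, length(gapFrac)))
  ncols <- length(gapFrac)
  cum <- vapply(u, function(v) sum(gapFrac >= v), numeric(1L)) / ncols
  slope <- (u[-length(u)] - u[-1L]) / (cum[-1L] - cum[-length(u)])
  cut <- u[which.max(slope) + 1L]
  gapFrac <= cut
}

#' Remove sequences much shorter than the query (relative-length filter)
#'
#' A row is removed when its non-gap residue count over the retained
#' (unambiguously aligned) columns is strictly below
#' \code{lengthFraction} times the query's count; a ratio exactly equal to
#' the fraction survives. The query row itself always survives.
#'
#' @param ca a \code{CodonAlignment} with retained flags set.
#' @param config a \code{PipelineConfig}.
#' @return the filtered \code{CodonAlignment}.
#' @export
applyLengthFilter <- function(ca, config = pipelineConfig()) {
  ids <- names(ca@seqs)
  if (!ca@queryId %in% ids)
    stop("query id '", ca@queryId, "' not present in the alignment")
  m <- .codonMatrix(ca)[, ca@retained, drop = FALSE]
  cov <- rowSums(m != "---")
  qcov <- cov[[ca@queryId]]
  # tolerance so a ratio exactly at the boundary survives despite floating
  # point (e.g. 0.55 * 100 > 55 in binary)
  keep <- cov >= config@lengthFraction * qcov - 1e-9
  keep[[ca@queryId]] <- TRUE
  ca@seqs <- ca@seqs[keep]
  ca@flagged <- intersect(ca@flagged, ids[keep])
  ca
}

#' Select codon positions from the retained columns
#'
#' \code{"Exc3rd"} returns the first and second position of every retained
#' codon column; \code{"Inc3rd"} returns all three. Column order is
#' preserved; the result is a plain character site matrix (rows = sequences)
#' with attributes \code{codonIndex} (retained-codon index of each column,
#' the bootstrap resampling unit) and \code{codonPos} (position 1-3).
#'
#' @param ca a \code{CodonAlignment} with retained flags set.
#' @param mode \code{"Exc3rd"} or \code{"Inc3rd"}.
#' @return a character matrix of selected sites.
#' @export
selectCodonPositions <- function(ca, mode = c("Exc3rd", "Inc3rd")) {
  mode <- match.arg(mode)
  ch <- as.matrix(ca@seqs)
  ncod <- ncol(ch) %/% 3L
  keepCodon <- which(ca@retained)
  pos <- rep(1:3, times = length(keepCodon))
  cols <- as.vector(rbind(3L * keepCodon - 2L, 3L * keepCodon - 1L,
                          3L * keepCodon))
  codIdx <- rep(seq_along(keepCodon), each = 3L)
  if (mode == "Exc3rd") {
    sel <- pos != 3L
    cols <- cols[sel]; pos <- pos[sel]; codIdx <- codIdx[sel]
  }
  out <- ch[, cols, drop = FALSE]
  rownames(out) <- names(ca@seqs)
  attr(out, "codonIndex") <- codIdx
  attr(out, "codonPos") <- pos
  out
}

#' Write the retained-column mask as a sidecar TSV
#'
#' @param ca a \code{CodonAlignment}.
#' @param path output TSV path (columns: column_index, codon_position,
#'   retained; one row per nucleotide column).
#' @export
writeRetainedMask <- function(ca, path) {
  ncod <- length(ca@retained)
  df <- data.frame(column_index = seq_len(3L * ncod),
                   codon_position = rep(1:3, ncod),
                   retained = rep(ca@retained, each = 3L))
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
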