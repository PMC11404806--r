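#' Parse a per-residue score export from an external predictor
#'
#' Reads a TSV/CSV table with columns \code{position}, \code{residue},
#' \code{score} (1-based positions) into a \linkS4class{ResidueProfile}
#' aligned to the given sequence. The residue column is cross-checked
#' against the sequence; gaps, duplicates, or mismatches raise an error
#' naming the position. Reading is gzip-transparent.
#'
#' @param path TSV (or CSV) file.
#' @param algorithm algorithm name to record.
#' @param seq the sequence the scores refer to (string or AAString(Set)).
#' @param seqId sequence identifier.
#' @param threshold calling threshold to record in the profile.
#' @param sep field separator; \code{"\t"} by default, use \code{","} for CSV.
#' @return \linkS4class{ResidueProfile}.
#' @export
parseResidueScores <- function(path, algorithm, seq, seqId = "seq",
                               threshold = 0, sep = "\t") {
  if (is(seq, "AAStringSet")) { seqId <- names(seq)[1]; seq <- as.character(seq[[1]]) }
  seq <- toupper(as.character(seq))
  tab <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("position", "residue", "score")
  if (!all(need %in% names(tab)))
    stop("expected columns position, residue, score; got: ",
         paste(names(tab), collapse = ", "))
  tab <- tab[order(tab$position), ]
  n <- nchar(seq)
  if (anyDuplicated(tab$position))
    stop("duplicate position(s): ",
         paste(unique(tab$position[duplicated(tab$position)]), collapse = ", "))
  if (!identical(as.integer(tab$position), seq_len(n)))
    stop("positions must cover 1..", n, " without gaps; first problem at position ",
         setdiff(seq_len(n), tab$position)[1])
  obs <- toupper(tab$residue)
  expd <- strsplit(seq, "")[[1]]
  bad <- which(obs != expd)
  if (length(bad) > 0)
    stop("residue mismatch at position ", bad[1],
         ": table has '", obs[bad[1]], "', sequence has '", expd[bad[1]], "'")
  new("ResidueProfile", seqId = seqId, algorithm = algorithm,
      residues = seq, scores = as.numeric(tab$score), threshold = threshold)
}

#' Parse a per-window (peptide) prediction export
#'
#' Reads a TSV table with columns \code{start}, \code{peptide}, \code{score}
#' into an \linkS4class{EpitopeSet}, validating each peptide against the
#' sequence at its stated start. With \code{dedupe = TRUE}, overlapping
#' predictions are reduced to the highest-scoring one per transitive overlap
#' cluster (ties broken by smaller start, then shorter length), emulating
#' manual "one epitope per region" selection.
#'
#' @inheritParams parseResidueScores
#' @param dedupe collapse overlapping predictions (default \code{FALSE}).
#' @return \linkS4class{EpitopeSet}.
#' @export
parsePeptidePredictions <- function(path, algorithm, seq, seqId = "seq",
                                    dedupe = FALSE, sep = "\t") {
  if (is(seq, "AAStringSet")) { seqId <- names(seq)[1]; seq <- as.character(seq[[1]]) }
  seq <- toupper(as.character(seq))
  tab <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("start", "peptide", "score")
  if (!all(need %in% names(tab)))
    stop("expected columns start, peptide, score; got: ",
         paste(names(tab), collapse = ", "))
  tab$peptide <- toupper(tab$peptide)
  tab$start <- as.integer(tab$start)
  tab$end <- tab$start + nchar(tab$peptide) - 1L
  if (nrow(tab) > 0) {
    if (any(tab$start < 1L) || any(tab$end > nchar(seq)))
      stop("prediction interval outside sequence bounds")
    claim <- substring(seq, tab$start, tab$end)
    bad <- which(claim != tab$peptide)
    if (length(bad) > 0)
      stop("peptide/sequence mismatch at start ", tab$start[bad[1]],
           ": table has '", tab$peptide[bad[1]], "', sequence has '",
           claim[bad[1]], "'")
  }
  p <- data.frame(seq_id = seqId, algorithm = algorithm,
                  start = tab$start, end = tab$end,
                  peptide = tab$peptide, score = as.numeric(tab$score),
                  stringsAsFactors = FALSE)
  es <- new("EpitopeSet", predictions = p)
  if (dedupe) dedupeOverlaps(es) else es
}

#' Reduce overlapping predictions to one per overlap cluster
#'
#' Clusters are transitive interval overlaps computed per sequence and per
#' algorithm; within each cluster the highest-scoring prediction wins, with
#' ties broken by smaller start, then shorter length. Idempotent.
#'
#' @param es \linkS4class{EpitopeSet}.
#' @return deduplicated \linkS4class{EpitopeSet}.
#' @export
dedupeOverlaps <- function(es) {
  p <- predictions(es)
  if (nrow(p) == 0) return(es)
  keep <- logical(0)
  out <- lapply(split(p, list(p$seq_id, p$algorithm), drop = TRUE), function(g) {
    ir <- IRanges::IRanges(start = g$start, end = g$end)
    cl <- S4Vectors::subjectHits(IRanges::findOverlaps(
      ir, IRanges::reduce(ir, min.gapwidth = 0L), select = "all"))
    picked <- lapply(split(seq_len(nrow(g)), cl), function(idx) {
      gg <- g[idx, ]
      o <- order(-gg$score, gg$start, gg$end - gg$start)
      gg[o[1], , drop = FALSE]
    })
    do.call(rbind, picked)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$seq_id, res$algorithm, res$start), ]
  rownames(res) <- NULL
  new("EpitopeSet", predictions = res)
}

#' Export an EpitopeSet as TSV
#'
#' Written with all six columns so that \code{\link{readEpitopeSet}}
#' round-trips exactly.
#'
#' @param es \linkS4class{EpitopeSet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeEpitopeSet <- function(es, path) {
  write.table(predictions(es), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an EpitopeSet written by \code{\link{writeEpitopeSet}}
#'
#' @param path TSV path.
#' @return \linkS4class{EpitopeSet}.
#' @export
readEpitopeSet <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(seq_id = "character", algorithm = "character",
                                   peptide = "character"))
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  new("EpitopeSet", predictions = tab)
}
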