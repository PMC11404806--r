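#' Read protein sequences from a FASTA file
#'
#' Validating FASTA reader for protein sequences. Residues are upper-cased,
#' trailing \code{*} terminators are stripped, and any character outside the
#' 20 standard one-letter codes plus \code{X} raises an error naming the
#' offending line. Returns a \link[Biostrings]{AAStringSet} so downstream
#' Biostrings machinery applies directly.
#'
#' @param path path to a FASTA file.
#' @return \link[Biostrings]{AAStringSet}, one element per record; names are
#'   the first whitespace-delimited token of each header.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "MKV"), tf)
#' readFasta(tf)
readFasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*$", lines)
  idx <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("empty FASTA file: ", path)
  if (!startsWith(lines[1], ">"))
    stop("malformed FASTA: line ", idx[1], " does not start a record header")
  hdr <- startsWith(lines, ">")
  ids <- character(0)
  seqs <- character(0)
  cur <- NULL
  for (k in seq_along(lines)) {
    ln <- lines[k]
    if (hdr[k]) {
      id <- sub("^>\\s*", "", ln)
      id <- strsplit(id, "\\s+")[[1]][1]
      if (is.na(id) || !nzchar(id))
        stop("malformed FASTA header at line ", idx[k])
      ids <- c(ids, id)
      seqs <- c(seqs, "")
      cur <- length(seqs)
    } else {
      chunk <- toupper(gsub("\\s", "", ln))
      chunk <- sub("\\*$", "", chunk)
      bad <- setdiff(strsplit(chunk, "")[[1]], AA_ALLOWED)
      if (length(bad) > 0)
        stop("illegal residue character(s) ", paste(bad, collapse = ""),
             " at line ", idx[k])
      seqs[cur] <- paste0(seqs[cur], chunk)
    }
  }
  if (any(!nzchar(seqs)))
    stop("record(s) with empty sequence: ", paste(ids[!nzchar(seqs)], collapse = ", "))
  Biostrings::AAStringSet(setNames(seqs, ids))
}

#' Write protein sequences to FASTA
#'
#' @param x \link[Biostrings]{AAStringSet} or named character vector.
#' @param path output path.
#' @param width line wrap width.
#' @return \code{path}, invisibly.
#' @export
writeFasta <- function(x, path, width = 60L) {
  if (is.character(x)) x <- Biostrings::AAStringSet(x)
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

#' Read a multiple sequence alignment
#'
#' Reads an aligned-FASTA or Clustal alignment into a
#' \link[Biostrings]{AAMultipleAlignment}. Rows must all have the same
#' length; ragged alignments raise an error listing the offending ids.
#'
#' @param path alignment file.
#' @param dialect \code{"fasta"} or \code{"clustal"}.
#' @return \link[Biostrings]{AAMultipleAlignment}.
#' @export
readAlignment <- function(path, dialect = c("fasta", "clustal")) {
  dialect <- match.arg(dialect)
  if (dialect == "clustal") {
    aln <- Biostrings::readAAMultipleAlignment(path, format = "clustal")
    return(aln)
  }
  lines <- readLines(path)
  keep <- !grepl("^\\s*$", lines)
  lines <- lines[keep]
  hdr <- startsWith(lines, ">")
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1), 1L)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), function(z)
    toupper(gsub("\\s", "", paste(z, collapse = ""))), character(1))
  names(seqs) <- ids
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    off <- ids[lens != max(lens)]
    stop("ragged alignment; offending id(s): ", paste(off, collapse = ", "))
  }
  Biostrings::AAMultipleAlignment(Biostrings::AAStringSet(seqs))
}

#' Build an alignment from already-aligned strings
#'
#' @param x named character vector of equal-length gapped strings.
#' @return \link[Biostrings]{AAMultipleAlignment}.
#' @export
asAlignment <- function(x) {
  stopifnot(is.character(x), !is.null(names(x)))
  if (length(unique(nchar(x))) > 1L)
    stop("ragged alignment; offending id(s): ",
         paste(names(x)[nchar(x) != max(nchar(x))], collapse = ", "))
  Biostrings::AAMultipleAlignment(Biostrings::AAStringSet(toupper(x)))
}

# character matrix view of an alignment (rows = members, cols = columns)
alnMatrix <- function(aln) {
  ss <- Biostrings::unmasked(aln)
  m <- do.call(rbind, strsplit(as.character(ss), ""))
  rownames(m) <- names(ss)
  m
}

alnIds <- function(aln) {
  ids <- rownames(aln)
  if (is.null(ids)) ids <- names(Biostrings::unmasked(aln))
  ids
}

#' Remove gaps from one alignment member
#'
#' @param aln \link[Biostrings]{AAMultipleAlignment}.
#' @param seqId member identifier.
#' @return ungapped residue string.
#' @export
degap <- function(aln, seqId) {
  ids <- alnIds(aln)
  if (!(seqId %in% ids)) stop("unknown alignment member: ", seqId)
  row <- as.character(Biostrings::unmasked(aln)[[match(seqId, ids)]])
  gsub("-", "", row)
}

#' Map residue positions to alignment columns and back
#'
#' For one alignment member, builds the bidirectional mapping between 1-based
#' residue positions on the ungapped sequence and 1-based alignment columns.
#'
#' @param aln \link[Biostrings]{AAMultipleAlignment}.
#' @param seqId member identifier.
#' @return list with \code{posToCol} (integer vector, one entry per residue)
#'   and \code{colToPos} (integer vector, one entry per column, \code{NA} at
#'   this member's gap columns).
#' @export
columnMap <- function(aln, seqId) {
  ids <- alnIds(aln)
  if (!(seqId %in% ids)) stop("unknown alignment member: ", seqId)
  row <- strsplit(as.character(Biostrings::unmasked(aln)[[match(seqId, ids)]]), "")[[1]]
  nongap <- row != "-"
  posToCol <- which(nongap)
  colToPos <- rep(NA_integer_, length(row))
  colToPos[nongap] <- seq_len(sum(nongap))
  list(posToCol = as.integer(posToCol), colToPos = colToPos)
}

#' Write a phylogenetic tree as plain Newick
#'
#' Branch lengths are rounded to 6 decimal places before writing.
#'
#' @param tree \link[ape]{phylo} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeNewick <- function(tree, path) {
  if (!is.null(tree$edge.length))
    tree$edge.length <- round(tree$edge.length, 6)
  ape::write.tree(tree, file = path)
  invisible(path)
}
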