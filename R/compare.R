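# Global pairwise alignment and epitope-vs-reference comparison.
#
# Two scoring schemes are provided. "simple" is textbook Needleman-Wunsch
# with a linear gap penalty and end gaps charged; it is the scheme checked
# against the exhaustive-enumeration oracle. "needle" reproduces EMBOSS
# Needle defaults (BLOSUM62, gap open 10 / extend 0.5, end gaps free) and is
# the default for short-epitope-vs-full-chain identity, where a linear
# zero-mismatch scheme degenerates (all no-insertion alignments carry the
# same gap count, so matches scatter arbitrarily).

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Global alignment of two protein sequences
#'
#' @param query,target non-empty residue strings.
#' @param scheme \code{"needle"} (EMBOSS-style: BLOSUM62, affine gap open
#'   10 / extend 0.5 with a gap's first residue costing \code{gapOpen} and
#'   each further residue \code{gapExtend}, end gaps free) or
#'   \code{"simple"} (linear gap; match/mismatch/gap scores; end gaps
#'   charged; deterministic traceback preferring diagonal, then up, then
#'   left).
#' @param match,mismatch,gap scores for the simple scheme.
#' @param gapOpen,gapExtend positive penalties for the needle scheme.
#' @return \linkS4class{AlignmentResult}. Identity is exact residue matches
#'   divided by the query length, computed after trimming the target to the
#'   aligned span of the query; \code{X} never matches.
#' @export
needlemanWunsch <- function(query, target, scheme = c("needle", "simple"),
                            match = 1, mismatch = 0, gap = -1,
                            gapOpen = 10, gapExtend = 0.5) {
  scheme <- match.arg(scheme)
  query <- toupper(as.character(query)); target <- toupper(as.character(target))
  if (nchar(query) < 1L || nchar(target) < 1L)
    stop("query and target must be non-empty")
  if (scheme == "simple")
    nwSimple(query, target, match, mismatch, gap)
  else
    nwNeedle(query, target, gapOpen, gapExtend)
}

finishAlignment <- function(query, aq, at, score) {
  qa <- strsplit(aq, "")[[1]]; ta <- strsplit(at, "")[[1]]
  qpos <- which(qa != "-")
  first <- min(qpos); last <- max(qpos)
  win <- first:last
  m <- sum(qa[win] == ta[win] & qa[win] != "-" & qa[win] != "X")
  tcum <- cumsum(ta != "-")
  tstart <- if (tcum[first] == 0) {
    if (any(ta[win] != "-")) which(tcum == 1)[1] else NA_integer_
  } else tcum[first]
  tend <- tcum[last]
  if (is.na(tstart) || tend < tstart) { tstart <- NA_integer_; tend <- NA_integer_ }
  new("AlignmentResult", alignedQuery = aq, alignedTarget = at,
      score = score, matches = as.integer(m),
      identity = m / nchar(query),
      targetStart = if (is.na(tstart)) 0L else as.integer(tstart),
      targetEnd = if (is.na(tend)) 0L else as.integer(tend))
}

nwSimple <- function(query, target, match, mismatch, gap) {
  q <- strsplit(query, "")[[1]]; t <- strsplit(target, "")[[1]]
  n <- length(q); m <- length(t)
  H <- matrix(0, n + 1L, m + 1L)
  H[, 1] <- gap * (0:n)
  H[1, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    sub <- ifelse(t == q[i] & q[i] != "X" & t != "X", match, mismatch)
    row_prev <- H[i, ]; row_cur <- H[i + 1L, ]
    for (j in seq_len(m)) {
      row_cur[j + 1L] <- max(row_prev[j] + sub[j], row_prev[j + 1L] + gap,
                             row_cur[j] + gap)
    }
    H[i + 1L, ] <- row_cur
  }
  # traceback: diagonal > up > left
  i <- n; j <- m; aq <- character(0); at <- character(0)
  while (i > 0 || j > 0) {
    sij <- if (i > 0 && j > 0) {
      if (q[i] == t[j] && q[i] != "X" && t[j] != "X") match else mismatch
    } else NA
    if (i > 0 && j > 0 && H[i + 1L, j + 1L] == H[i, j] + sij) {
      aq <- c(q[i], aq); at <- c(t[j], at); i <- i - 1L; j <- j - 1L
    } else if (i > 0 && H[i + 1L, j + 1L] == H[i, j + 1L] + gap) {
      aq <- c(q[i], aq); at <- c("-", at); i <- i - 1L
    } else {
      aq <- c("-", aq); at <- c(t[j], at); j <- j - 1L
    }
  }
  finishAlignment(query, paste(aq, collapse = ""), paste(at, collapse = ""),
                  H[n + 1L, m + 1L])
}

nwNeedle <- function(query, target, gapOpen, gapExtend) {
  q <- strsplit(query, "")[[1]]; t <- strsplit(target, "")[[1]]
  n <- length(q); m <- length(t)
  B <- blosum62()
  qx <- ifelse(q %in% rownames(B), q, "X")
  tx <- ifelse(t %in% rownames(B), t, "X")
  S <- B[qx, tx, drop = FALSE]      # n x m substitution scores
  NEG <- -1e9
  H <- matrix(0, n + 1L, m + 1L)    # ends-free: zero first row/col
  D <- matrix(NEG, n + 1L, m + 1L)  # gap consuming query (vertical)
  I <- matrix(NEG, n + 1L, m + 1L)  # gap consuming target (horizontal)
  for (i in seq_len(n)) {
    Hp <- H[i, ]; Hc <- H[i + 1L, ]; Dp <- D[i, ]; Dc <- D[i + 1L, ]
    Ic <- I[i + 1L, ]
    Si <- S[i, ]
    for (j in seq_len(m)) {
      Dc[j + 1L] <- max(Hp[j + 1L] - gapOpen, Dp[j + 1L] - gapExtend)
      Ic[j + 1L] <- max(Hc[j] - gapOpen, Ic[j] - gapExtend)
      Hc[j + 1L] <- max(Hp[j] + Si[j], Dc[j + 1L], Ic[j + 1L])
    }
    H[i + 1L, ] <- Hc; D[i + 1L, ] <- Dc; I[i + 1L, ] <- Ic
  }
  # best cell on last row / last column (trailing end gaps free);
  # ties: prefer the last row, then the largest index
  lastRow <- H[n + 1L, ]; lastCol <- H[, m + 1L]
  bestRowJ <- which(lastRow == max(lastRow)); bestRowJ <- bestRowJ[length(bestRowJ)]
  bestColI <- which(lastCol == max(lastCol)); bestColI <- bestColI[length(bestColI)]
  if (max(lastRow) >= max(lastCol)) { i <- n; j <- bestRowJ - 1L } else {
    i <- bestColI - 1L; j <- m }
  score <- H[i + 1L, j + 1L]
  aq <- if (i < n) q[(i + 1L):n] else character(0)
  at <- if (i < n) rep("-", n - i) else character(0)
  aq <- c(if (j < m) rep("-", m - j) else character(0), aq)
  at <- c(if (j < m) t[(j + 1L):m] else character(0), at)
  state <- "H"
  while (i > 0 && j > 0) {
    if (state == "H") {
      h <- H[i + 1L, j + 1L]
      if (h == H[i, j] + S[i, j]) {
        aq <- c(q[i], aq); at <- c(t[j], at); i <- i - 1L; j <- j - 1L
      } else if (h == D[i + 1L, j + 1L]) state <- "D"
      else state <- "I"
    } else if (state == "D") {
      aq <- c(q[i], aq); at <- c("-", at)
      if (D[i + 1L, j + 1L] == H[i, j + 1L] - gapOpen) state <- "H"
      i <- i - 1L
    } else {
      aq <- c("-", aq); at <- c(t[j], at)
      if (I[i + 1L, j + 1L] == H[i + 1L, j] - gapOpen) state <- "H"
      j <- j - 1L
    }
  }
  if (i > 0) { aq <- c(q[seq_len(i)], aq); at <- c(rep("-", i), at) }
  if (j > 0) { aq <- c(rep("-", j), aq); at <- c(t[seq_len(j)], at) }
  finishAlignment(query, paste(aq, collapse = ""), paste(at, collapse = ""), score)
}

#' Identity of each epitope against each reference chain
#'
#' @param epitopes character vector of epitope peptides (names used as ids if
#'   present), or a list of \linkS4class{ConsensusEpitope}.
#' @param references \link[Biostrings]{AAStringSet} of reference chains.
#' @param ... passed to \code{\link{needlemanWunsch}}.
#' @return data.frame with columns epitope, reference, identity,
#'   target_start, target_end.
#' @export
epitopeIdentityTable <- function(epitopes, references, ...) {
  if (is.list(epitopes)) {
    peps <- vapply(epitopes, peptide, character(1))
  } else peps <- epitopes
  if (is.null(names(peps)) || any(!nzchar(names(peps)))) names(peps) <- peps
  if (length(references) == 0) stop("references must be non-empty")
  rows <- list()
  for (k in seq_along(peps)) for (r in seq_along(references)) {
    res <- needlemanWunsch(peps[[k]], as.character(references[[r]]), ...)
    rows[[length(rows) + 1L]] <- data.frame(
      epitope = names(peps)[k], reference = names(references)[r],
      identity = res@identity,
      target_start = res@targetStart, target_end = res@targetEnd,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Read a reference epitope table
#'
#' TSV with columns id, peptide, start, end (1-based inclusive positions on
#' the reference chain). If \code{refChain} is given each peptide is
#' validated against it.
#'
#' @param path TSV path.
#' @param refChain optional reference chain residues.
#' @return data.frame id, peptide, start, end.
#' @export
readReferenceEpitopes <- function(path, refChain = NULL) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "peptide", "start", "end")
  if (!all(need %in% names(tab)))
    stop("expected columns id, peptide, start, end")
  tab$start <- as.integer(tab$start); tab$end <- as.integer(tab$end)
  if (!is.null(refChain) && nrow(tab) > 0) {
    refChain <- toupper(as.character(refChain))
    claim <- substring(refChain, tab$start, tab$end)
    bad <- which(claim != toupper(tab$peptide))
    if (length(bad) > 0)
      stop("reference epitope '", tab$id[bad[1]], "' does not match the chain")
  }
  tab
}

#' Shared-amino-acid similarity summary against a reference epitope set
#'
#' For a query epitope mapped to a span on the reference chain, counts for
#' each reference epitope the number of shared positions (interval
#' intersection size). Returns the mode of the nonzero counts (ties:
#' smallest), their min-max range, and the number of reference epitopes
#' sharing at least one position.
#'
#' @param spanStart,spanEnd the query epitope's span on the reference chain
#'   (from \code{\link{epitopeIdentityTable}}).
#' @param refEpitopes data.frame from \code{\link{readReferenceEpitopes}}.
#' @param queryLength epitope (query) length L, used for the k/L rendering.
#' @param requireResidueIdentity if \code{TRUE}, only positions where the
#'   query peptide residue equals the reference chain residue count as
#'   shared; needs \code{queryPeptide} and \code{refChain}.
#' @param queryPeptide,refChain residues, only used when
#'   \code{requireResidueIdentity} is \code{TRUE}.
#' @return list with \code{M} (mode count, NA when no overlap), \code{Rmin},
#'   \code{Rmax}, \code{nMatching}, \code{L}, and display strings
#'   \code{modeLabel} ("k/L") and \code{rangeLabel}.
#' @export
sharedAASummary <- function(spanStart, spanEnd, refEpitopes, queryLength,
                            requireResidueIdentity = FALSE,
                            queryPeptide = NULL, refChain = NULL) {
  if (nrow(refEpitopes) == 0 || is.na(spanStart)) {
    return(list(M = NA_integer_, Rmin = NA_integer_, Rmax = NA_integer_,
                nMatching = 0L, L = queryLength,
                modeLabel = "-", rangeLabel = "-"))
  }
  shared <- integer(nrow(refEpitopes))
  for (k in seq_len(nrow(refEpitopes))) {
    lo <- max(spanStart, refEpitopes$start[k])
    hi <- min(spanEnd, refEpitopes$end[k])
    if (hi < lo) next
    if (requireResidueIdentity) {
      stopifnot(!is.null(queryPeptide), !is.null(refChain))
      qres <- strsplit(toupper(queryPeptide), "")[[1]]
      # align query residues to span positions left to right
      pos <- lo:hi
      off <- pos - spanStart + 1L
      off <- off[off >= 1L & off <= length(qres)]
      pos <- pos[seq_along(off)]
      rres <- strsplit(substring(toupper(refChain), min(pos), max(pos)), "")[[1]]
      shared[k] <- sum(qres[off] == rres & qres[off] != "X")
    } else {
      shared[k] <- hi - lo + 1L
    }
  }
  nz <- shared[shared >= 1L]
  if (length(nz) == 0) {
    return(list(M = NA_integer_, Rmin = NA_integer_, Rmax = NA_integer_,
                nMatching = 0L, L = queryLength,
                modeLabel = "-", rangeLabel = "-"))
  }
  tab <- table(nz)
  M <- as.integer(names(tab)[which.max(tab)])  # ties -> smallest (table sorted)
  Rmin <- min(nz); Rmax <- max(nz)
  list(M = M, Rmin = as.integer(Rmin), Rmax = as.integer(Rmax),
       nMatching = length(nz), L = queryLength,
       modeLabel = sprintf("%d/%d", M, queryLength),
       rangeLabel = if (Rmin == Rmax) sprintf("%d/%d", Rmin, queryLength) else
         sprintf("%d/%d-%d/%d", Rmin, queryLength, Rmax, queryLength))
}
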