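# Core consensus machinery. All consensus epitopes live in alignment-column
# coordinates; member predictions are lifted there via columnMap().

alnMaps <- function(aln) {
  ids <- alnIds(aln)
  setNames(lapply(ids, function(m) columnMap(aln, m)), ids)
}

# coverage[[algorithm]][[member]] = logical vector over alignment columns:
# TRUE where that member has a prediction by that algorithm and a residue.
coverageByColumn <- function(es, aln, maps = alnMaps(aln)) {
  mat <- alnMatrix(aln)
  members <- rownames(mat)
  ncol_aln <- ncol(mat)
  p <- predictions(es)
  res <- list()
  for (alg in unique(p$algorithm)) {
    res[[alg]] <- list()
    for (m in members) {
      cov <- rep(FALSE, ncol_aln)
      rows <- p[p$algorithm == alg & p$seq_id == m, , drop = FALSE]
      if (nrow(rows) > 0) {
        nres <- length(maps[[m]]$posToCol)
        if (any(rows$end > nres))
          stop("prediction interval outside member length for '", m, "'")
        for (r in seq_len(nrow(rows)))
          cov[maps[[m]]$posToCol[rows$start[r]:rows$end[r]]] <- TRUE
      }
      res[[alg]][[m]] <- cov
    }
  }
  res
}

# majority residue per column among a subset mask (members x columns logical);
# ties broken alphabetically; returns NA where no member is selected.
majorityResidue <- function(mat, mask) {
  vapply(seq_len(ncol(mat)), function(cc) {
    rs <- mat[mask[, cc], cc]
    rs <- rs[rs != "-"]
    if (length(rs) == 0) return(NA_character_)
    tab <- table(rs)
    names(tab)[which.max(tab)][1]  # table() is alphabetical; which.max takes first
  }, character(1))
}

#' Intra-algorithm consensus epitopes
#'
#' For one algorithm, lifts every member's predictions onto alignment
#' columns and computes, per column, the support: the number of members
#' whose prediction covers the column \emph{and} whose residue equals the
#' column's majority residue among predicted members (ties alphabetical;
#' \code{X} never matches). Maximal runs of columns with support at or above
#' \code{minSupport}, of length at least \code{minLength}, become consensus
#' epitopes.
#'
#' @param es \linkS4class{EpitopeSet} (only rows of \code{algorithm} are used).
#' @param aln \link[Biostrings]{AAMultipleAlignment} tying the members together.
#' @param algorithm algorithm name to extract.
#' @param minSupport minimum member support per column (default 3).
#' @param minLength minimum consensus length in columns (default 5).
#' @return list of \linkS4class{ConsensusEpitope}.
#' @export
intraAlgorithmConsensus <- function(es, aln, algorithm,
                                    minSupport = 3L, minLength = 5L) {
  mat <- alnMatrix(aln)
  members <- rownames(mat)
  if (minSupport > length(members))
    stop("minSupport exceeds the number of alignment members")
  p <- predictions(es)
  p <- p[p$algorithm == algorithm, , drop = FALSE]
  sub <- new("EpitopeSet", predictions = p)
  if (nrow(p) == 0) return(list())
  cov <- coverageByColumn(sub, aln)[[algorithm]]
  covmat <- do.call(rbind, cov[members])          # members x columns
  maj <- majorityResidue(mat, covmat)
  match_mat <- covmat & sweep(mat, 2, maj, "==") & mat != "X"
  support <- colSums(match_mat)
  runs <- rle(support >= minSupport)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  out <- list()
  for (k in which(runs$values & runs$lengths >= minLength)) {
    cs <- starts[k]; ce <- ends[k]
    cols <- cs:ce
    pep <- paste(maj[cols], collapse = "")
    supp_members <- members[rowSums(covmat[, cols, drop = FALSE]) > 0]
    out[[length(out) + 1L]] <- new("ConsensusEpitope",
      peptide = pep, colStart = as.integer(cs), colEnd = as.integer(ce),
      domainLabel = NA_character_,
      supportingSequences = supp_members,
      supportingAlgorithms = algorithm,
      perPositionSupport = as.integer(support[cols]))
  }
  out
}

#' Inter-algorithm consensus epitopes
#'
#' Given per-algorithm lists of intra-algorithm consensus epitopes sharing
#' one alignment coordinate system, counts per column the number of distinct
#' algorithms whose epitopes cover the column, and emits maximal runs
#' covered by at least \code{minAlgorithms} algorithms (and at least
#' \code{minLength} columns long) as final consensus epitopes.
#'
#' @param perAlgorithm named list: algorithm name -> list of
#'   \linkS4class{ConsensusEpitope}.
#' @param aln the shared \link[Biostrings]{AAMultipleAlignment}.
#' @param minAlgorithms minimum number of distinct algorithms (default 3).
#' @param minLength minimum consensus length in columns (default 5).
#' @return list of \linkS4class{ConsensusEpitope}.
#' @export
interAlgorithmConsensus <- function(perAlgorithm, aln,
                                    minAlgorithms = 3L, minLength = 5L) {
  mat <- alnMatrix(aln)
  ncol_aln <- ncol(mat)
  algs <- names(perAlgorithm)
  algcov <- matrix(FALSE, nrow = length(algs), ncol = ncol_aln,
                   dimnames = list(algs, NULL))
  for (a in algs) for (ep in perAlgorithm[[a]])
    algcov[a, ep@colStart:ep@colEnd] <- TRUE
  covcount <- colSums(algcov)
  runs <- rle(covcount >= minAlgorithms)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  out <- list()
  for (k in which(runs$values & runs$lengths >= minLength)) {
    cs <- starts[k]; ce <- ends[k]
    cols <- cs:ce
    supp_algs <- algs[rowSums(algcov[, cols, drop = FALSE]) > 0]
    supp_members <- sort(unique(unlist(lapply(supp_algs, function(a)
      unlist(lapply(perAlgorithm[[a]], function(ep)
        if (ep@colEnd >= cs && ep@colStart <= ce) ep@supportingSequences))))))
    mask <- matrix(TRUE, nrow = nrow(mat), ncol = ncol(mat))
    if (length(supp_members) > 0)
      mask <- matrix(rownames(mat) %in% supp_members, nrow = nrow(mat),
                     ncol = ncol(mat))
    maj <- majorityResidue(mat, mask)
    pep <- paste(ifelse(is.na(maj[cols]), "X", maj[cols]), collapse = "")
    out[[length(out) + 1L]] <- new("ConsensusEpitope",
      peptide = pep, colStart = as.integer(cs), colEnd = as.integer(ce),
      domainLabel = NA_character_,
      supportingSequences = supp_members,
      supportingAlgorithms = sort(supp_algs),
      perPositionSupport = as.integer(covcount[cols]))
  }
  out
}

#' Project a consensus epitope onto one alignment member
#'
#' @param epitope \linkS4class{ConsensusEpitope}.
#' @param aln \link[Biostrings]{AAMultipleAlignment}.
#' @param memberId member to project onto.
#' @return list with \code{start}, \code{end} (1-based residue positions on
#'   the ungapped member; \code{NA} if the member is all-gap there) and
#'   \code{peptide} (the member's residues over the span).
#' @export
epitopeOnMember <- function(epitope, aln, memberId) {
  cm <- columnMap(aln, memberId)
  pos <- cm$colToPos[epitope@colStart:epitope@colEnd]
  pos <- pos[!is.na(pos)]
  if (length(pos) == 0)
    return(list(start = NA_integer_, end = NA_integer_, peptide = ""))
  res <- degap(aln, memberId)
  list(start = min(pos), end = max(pos),
       peptide = substr(res, min(pos), max(pos)))
}

# ---- conservation index ----

# per-epitope mean algorithm score, min-max normalized per algorithm
epitopeScoreComponent <- function(epitope, es, aln, maps = alnMaps(aln)) {
  p <- predictions(es)
  cols <- epitope@colStart:epitope@colEnd
  vals <- c()
  for (a in epitope@supportingAlgorithms) {
    pa <- p[p$algorithm == a, , drop = FALSE]
    if (nrow(pa) == 0) next
    ov <- logical(nrow(pa))
    for (r in seq_len(nrow(pa))) {
      # contiguous residue runs map to monotone column sets: a range test
      # against the run's first and last column suffices
      ptc <- maps[[pa$seq_id[r]]]$posToCol
      ov[r] <- ptc[pa$end[r]] >= cols[1] && ptc[pa$start[r]] <= cols[length(cols)]
    }
    if (!any(ov)) next
    v <- mean(pa$score[ov])
    rng <- range(pa$score)
    vals <- c(vals, if (diff(rng) < .Machine$double.eps) 1 else
      (v - rng[1]) / (rng[2] - rng[1]))
  }
  if (length(vals) == 0) 0 else mean(vals)
}

#' Conservation reports for a set of consensus epitopes
#'
#' Computes the six-component 0-1 conservation index for each epitope:
#' \describe{
#'   \item{presence}{fraction of member sequences containing the epitope
#'     (a member contains it when its predictions, any algorithm, cover at
#'     least half of the epitope's columns).}
#'   \item{position}{mean over columns of (members covered by a prediction
#'     whose residue matches the column majority) / (number of members);
#'     mismatched residues and unpredicted members contribute 0.}
#'   \item{score}{mean over supporting algorithms of the epitope's mean
#'     prediction score, min-max normalized by that algorithm's observed
#'     score range.}
#'   \item{iqr}{0.25/0.5/0.75/1 by the quartile (inclusive, linearly
#'     interpolated convention) of the epitope's score component within the
#'     distribution over all epitopes scored together.}
#'   \item{algorithms}{supporting algorithms / algorithms run.}
#'   \item{agreement}{mean over columns of (algorithms covering the column)
#'     / (algorithms run).}
#' }
#' The index is the arithmetic mean of the six.
#'
#' @param epitopes list of \linkS4class{ConsensusEpitope}.
#' @param es \linkS4class{EpitopeSet} with all per-sequence predictions.
#' @param aln \link[Biostrings]{AAMultipleAlignment}.
#' @param nAlgorithms number of algorithms run (default: distinct algorithms
#'   in \code{es}).
#' @return list of \linkS4class{ConservationReport}, parallel to
#'   \code{epitopes}.
#' @export
conservationReports <- function(epitopes, es, aln,
                                nAlgorithms = length(algorithms(es))) {
  if (length(epitopes) == 0) return(list())
  mat <- alnMatrix(aln)
  members <- rownames(mat)
  nm <- length(members)
  maps <- alnMaps(aln)
  cov <- coverageByColumn(es, aln, maps)
  algs_run <- names(cov)
  sscore <- vapply(epitopes, epitopeScoreComponent, numeric(1),
                   es = es, aln = aln, maps = maps)
  q <- quantile(sscore, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  siqr <- vapply(sscore, function(v)
    if (v <= q[1]) 0.25 else if (v <= q[2]) 0.5 else if (v <= q[3]) 0.75 else 1.0,
    numeric(1))
  out <- vector("list", length(epitopes))
  for (i in seq_along(epitopes)) {
    ep <- epitopes[[i]]
    cols <- ep@colStart:ep@colEnd
    ncols <- length(cols)
    # any-algorithm coverage per member per epitope column
    anyCov <- matrix(FALSE, nrow = nm, ncol = ncols, dimnames = list(members, NULL))
    for (a in algs_run) for (m in members)
      anyCov[m, ] <- anyCov[m, ] | cov[[a]][[m]][cols]
    presence <- mean(rowSums(anyCov) >= ncols / 2)
    maj <- strsplit(ep@peptide, "")[[1]]
    submat <- mat[, cols, drop = FALSE]
    matchm <- anyCov & sweep(submat, 2, maj, "==") & submat != "X"
    position <- mean(colSums(matchm) / nm)
    algcols <- vapply(algs_run, function(a)
      vapply(seq_along(cols), function(j)
        any(vapply(members, function(m) cov[[a]][[m]][cols[j]], logical(1))),
        logical(1)), logical(ncols))
    if (is.null(dim(algcols))) algcols <- matrix(algcols, nrow = 1)
    agreement <- mean(rowSums(algcols) / nAlgorithms)
    salg <- length(ep@supportingAlgorithms) / nAlgorithms
    comp <- c(presence, position, sscore[i], siqr[i], salg, agreement)
    out[[i]] <- new("ConservationReport", epitope = ep,
                    sPresence = presence, sPosition = position,
                    sScore = sscore[i], sIqr = siqr[i],
                    sAlgorithms = salg, sAgreement = agreement,
                    index = mean(comp))
  }
  out
}

#' Read a BED-like domain annotation
#'
#' BED conventions: 0-based half-open intervals on the reference member;
#' columns chrom (member id), start, end, name (domain label). Converted to
#' 1-based inclusive internally.
#'
#' @param path BED file (tab-separated, no header).
#' @return data.frame with seq_id, start, end, domain (1-based inclusive).
#' @export
readDomainsBed <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 4) stop("BED domain file needs 4 columns: id, start, end, name")
  data.frame(seq_id = tab[[1]], start = as.integer(tab[[2]]) + 1L,
             end = as.integer(tab[[3]]), domain = tab[[4]],
             stringsAsFactors = FALSE)
}

#' Assign domain labels to consensus epitopes
#'
#' Each epitope is projected onto the reference member and labelled with the
#' domain interval it overlaps most (ties: first domain in file order).
#'
#' @param epitopes list of \linkS4class{ConsensusEpitope}.
#' @param aln alignment.
#' @param refId reference member id (must match the BED's first column).
#' @param domains data.frame from \code{\link{readDomainsBed}}.
#' @return the input list with \code{domainLabel} slots filled.
#' @export
assignDomains <- function(epitopes, aln, refId, domains) {
  dom <- domains[domains$seq_id == refId, , drop = FALSE]
  lapply(epitopes, function(ep) {
    span <- epitopeOnMember(ep, aln, refId)
    if (is.na(span$start)) return(ep)
    ov <- pmin(dom$end, span$end) - pmax(dom$start, span$start) + 1L
    ov[ov < 0] <- 0L
    if (all(ov == 0)) return(ep)
    ep@domainLabel <- dom$domain[which.max(ov)]
    ep
  })
}
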