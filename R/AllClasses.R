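#' @import methods
#' @importFrom stats quantile rbinom rpois runif rnorm sd setNames wilcox.test as.dist
#' @importFrom utils read.delim write.table head tail
NULL

AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_ALLOWED <- c(AA_ALPHABET20, "X")

#' EpitopeSet: a set of per-sequence epitope predictions
#'
#' Container for linear B-cell epitope predictions, one row per predicted
#' epitope on one sequence by one algorithm. Coordinates are 1-based inclusive
#' residue positions on the ungapped sequence.
#'
#' @slot predictions data.frame with columns \code{seq_id}, \code{algorithm},
#'   \code{start}, \code{end}, \code{peptide}, \code{score}.
#' @exportClass EpitopeSet
setClass("EpitopeSet", representation(predictions = "data.frame"))

setValidity("EpitopeSet", function(object) {
  p <- object@predictions
  need <- c("seq_id", "algorithm", "start", "end", "peptide", "score")
  if (!all(need %in% names(p)))
    return(paste("missing columns:", paste(setdiff(need, names(p)), collapse = ", ")))
  if (nrow(p) == 0) return(TRUE)
  if (any(p$start < 1L) || any(p$end < p$start))
    return("intervals must satisfy 1 <= start <= end")
  if (any(nchar(p$peptide) != p$end - p$start + 1L))
    return("peptide length must equal end - start + 1")
  if (any(!is.finite(p$score))) return("scores must be finite")
  TRUE
})

#' ResidueProfile: per-residue scores for one sequence and one algorithm
#'
#' @slot seqId sequence identifier.
#' @slot algorithm algorithm name.
#' @slot residues the scored residue string (same length as \code{scores}).
#' @slot scores numeric vector, one score per residue.
#' @slot threshold numeric calling threshold on the profile's own scale.
#' @exportClass ResidueProfile
setClass("ResidueProfile", representation(
  seqId = "character", algorithm = "character", residues = "character",
  scores = "numeric", threshold = "numeric"))

setValidity("ResidueProfile", function(object) {
  if (length(object@seqId) != 1L) return("seqId must be length 1")
  if (length(object@scores) < 1L) return("scores must be non-empty")
  if (any(!is.finite(object@scores))) return("scores must be finite")
  if (nchar(object@residues) != length(object@scores))
    return("residues must have one character per score")
  TRUE
})

#' PropensityScale: a published per-residue physicochemical scale
#'
#' @slot name scale name (e.g. \code{"hydrophilicity"}).
#' @slot values named numeric vector over the 20 standard residues.
#' @slot window odd positive smoothing window width.
#' @slot defaultThreshold default calling threshold on the normalized
#'   [-3, +3] scale.
#' @exportClass PropensityScale
setClass("PropensityScale", representation(
  name = "character", values = "numeric",
  window = "integer", defaultThreshold = "numeric"))

setValidity("PropensityScale", function(object) {
  if (!all(AA_ALPHABET20 %in% names(object@values)))
    return("values must cover all 20 standard residues")
  if (length(object@window) != 1L || object@window < 1L || object@window %% 2L == 0L)
    return("window must be a positive odd integer")
  TRUE
})

#' ConsensusEpitope: a consensus peptide in alignment-column coordinates
#'
#' The central product of the two-level consensus procedure: a run of
#' alignment columns called by enough member sequences (intra-algorithm level)
#' or enough algorithms (inter-algorithm level), with the majority residue per
#' column as consensus peptide.
#'
#' @slot peptide consensus residues (majority residue per column).
#' @slot colStart,colEnd 1-based inclusive alignment-column interval.
#' @slot domainLabel optional domain annotation (e.g. VH/CH1/CH2/CH3).
#' @slot supportingSequences ids of member sequences supporting the epitope.
#' @slot supportingAlgorithms names of algorithms supporting the epitope.
#' @slot perPositionSupport integer support count per column.
#' @exportClass ConsensusEpitope
setClass("ConsensusEpitope", representation(
  peptide = "character", colStart = "integer", colEnd = "integer",
  domainLabel = "character", supportingSequences = "character",
  supportingAlgorithms = "character", perPositionSupport = "integer"))

setValidity("ConsensusEpitope", function(object) {
  if (object@colStart < 1L || object@colEnd < object@colStart)
    return("column interval must satisfy 1 <= colStart <= colEnd")
  n <- object@colEnd - object@colStart + 1L
  if (nchar(object@peptide) != n) return("peptide length must equal column span")
  if (length(object@perPositionSupport) != n)
    return("perPositionSupport length must equal peptide length")
  TRUE
})

#' ConservationReport: the six-component 0-1 conservation index
#'
#' @slot epitope the scored \linkS4class{ConsensusEpitope}.
#' @slot sPresence fraction of member sequences containing the epitope.
#' @slot sPosition mean per-position residue conservation (mismatches score 0).
#' @slot sScore normalized mean algorithm score.
#' @slot sIqr quartile-localization score in {0.25, 0.5, 0.75, 1}.
#' @slot sAlgorithms fraction of algorithms predicting the epitope.
#' @slot sAgreement mean cross-algorithm per-position agreement.
#' @slot index arithmetic mean of the six components, in [0, 1].
#' @exportClass ConservationReport
setClass("ConservationReport", representation(
  epitope = "ConsensusEpitope",
  sPresence = "numeric", sPosition = "numeric", sScore = "numeric",
  sIqr = "numeric", sAlgorithms = "numeric", sAgreement = "numeric",
  index = "numeric"))

setValidity("ConservationReport", function(object) {
  comp <- c(object@sPresence, object@sPosition, object@sScore,
            object@sIqr, object@sAlgorithms, object@sAgreement, object@index)
  if (any(comp < -1e-9) || any(comp > 1 + 1e-9))
    return("all components and the index must lie in [0, 1]")
  m <- mean(c(object@sPresence, object@sPosition, object@sScore,
              object@sIqr, object@sAlgorithms, object@sAgreement))
  if (abs(m - object@index) > 1e-9)
    return("index must be the arithmetic mean of the six components")
  TRUE
})

#' AlignmentResult: a global pairwise alignment with trimmed identity
#'
#' @slot alignedQuery,alignedTarget gapped aligned strings.
#' @slot score alignment score under the scheme used.
#' @slot matches number of exact residue matches within the query span.
#' @slot identity matches / query length, in [0, 1].
#' @slot targetStart,targetEnd 1-based span of the query on the ungapped
#'   target (the "trimmed" target region).
#' @exportClass AlignmentResult
setClass("AlignmentResult", representation(
  alignedQuery = "character", alignedTarget = "character",
  score = "numeric", matches = "integer", identity = "numeric",
  targetStart = "integer", targetEnd = "integer"))

setValidity("AlignmentResult", function(object) {
  if (object@identity < -1e-12 || object@identity > 1 + 1e-12)
    return("identity must lie in [0, 1]")
  if (nchar(object@alignedQuery) != nchar(object@alignedTarget))
    return("aligned strings must have equal length")
  TRUE
})

#' SuperpositionResult: RMSD and TM-score of matched coordinate sets
#'
#' @slot rmsd root-mean-square deviation (Angstrom) after optimal
#'   superposition.
#' @slot tmScore TM-score normalized by the target length.
#' @slot tmScoreQuery TM-score normalized by the query (mobile) length.
#' @slot rotation 3x3 proper rotation matrix applied to the mobile set.
#' @slot translation length-3 translation applied after rotation.
#' @slot nMatched number of matched coordinate pairs.
#' @slot targetLength target chain length used for TM normalization.
#' @slot distances per-pair distances (Angstrom) after superposition.
#' @exportClass SuperpositionResult
setClass("SuperpositionResult", representation(
  rmsd = "numeric", tmScore = "numeric", tmScoreQuery = "numeric",
  rotation = "matrix", translation = "numeric",
  nMatched = "integer", targetLength = "integer", distances = "numeric"))

setValidity("SuperpositionResult", function(object) {
  if (object@rmsd < 0) return("rmsd must be nonnegative")
  if (object@tmScore > 1 + 1e-12) return("tmScore must not exceed 1")
  TRUE
})
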