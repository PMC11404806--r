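#' Accessors for epicons classes
#'
#' @param x an epicons S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("predictions", function(x) standardGeneric("predictions"))

#' @rdname accessors
#' @export
setGeneric("algorithms", function(x) standardGeneric("algorithms"))

#' @rdname accessors
#' @export
setGeneric("seqIds", function(x) standardGeneric("seqIds"))

#' @rdname accessors
#' @export
setGeneric("peptide", function(x) standardGeneric("peptide"))

#' @rdname accessors
#' @export
setGeneric("columnRange", function(x) standardGeneric("columnRange"))

#' @rdname accessors
#' @export
setGeneric("supportingSequences", function(x) standardGeneric("supportingSequences"))

#' @rdname accessors
#' @export
setGeneric("supportingAlgorithms", function(x) standardGeneric("supportingAlgorithms"))

#' @rdname accessors
#' @export
setGeneric("perPositionSupport", function(x) standardGeneric("perPositionSupport"))

#' @rdname accessors
#' @export
setGeneric("domainLabel", function(x) standardGeneric("domainLabel"))

#' @rdname accessors
#' @export
setGeneric("conservationIndex", function(x) standardGeneric("conservationIndex"))

#' @rdname accessors
#' @export
setGeneric("components", function(x) standardGeneric("components"))

#' @rdname accessors
#' @export
setGeneric("pidentity", function(x) standardGeneric("pidentity"))

#' @rdname accessors
#' @export
setGeneric("rmsd", function(x) standardGeneric("rmsd"))

#' @rdname accessors
#' @export
setGeneric("tmScore", function(x) standardGeneric("tmScore"))

# ---- methods ----

#' @describeIn accessors prediction table of an EpitopeSet
#' @export
setMethod("predictions", "EpitopeSet", function(x) x@predictions)

#' @describeIn accessors algorithm names present in an EpitopeSet
#' @export
setMethod("algorithms", "EpitopeSet", function(x) sort(unique(x@predictions$algorithm)))

#' @describeIn accessors sequence ids present in an EpitopeSet
#' @export
setMethod("seqIds", "EpitopeSet", function(x) sort(unique(x@predictions$seq_id)))

#' @export
setMethod("length", "EpitopeSet", function(x) nrow(x@predictions))

#' @describeIn accessors consensus peptide string
#' @export
setMethod("peptide", "ConsensusEpitope", function(x) x@peptide)

#' @describeIn accessors alignment-column interval (start, end) of a consensus epitope
#' @export
setMethod("columnRange", "ConsensusEpitope",
          function(x) c(start = x@colStart, end = x@colEnd))

#' @describeIn accessors member ids supporting a consensus epitope
#' @export
setMethod("supportingSequences", "ConsensusEpitope", function(x) x@supportingSequences)

#' @describeIn accessors algorithms supporting a consensus epitope
#' @export
setMethod("supportingAlgorithms", "ConsensusEpitope", function(x) x@supportingAlgorithms)

#' @describeIn accessors per-column support counts
#' @export
setMethod("perPositionSupport", "ConsensusEpitope", function(x) x@perPositionSupport)

#' @describeIn accessors domain label (possibly NA)
#' @export
setMethod("domainLabel", "ConsensusEpitope", function(x) x@domainLabel)

#' @describeIn accessors final 0-1 conservation index
#' @export
setMethod("conservationIndex", "ConservationReport", function(x) x@index)

#' @describeIn accessors named vector of the six index components
#' @export
setMethod("components", "ConservationReport", function(x)
  c(presence = x@sPresence, position = x@sPosition, score = x@sScore,
    iqr = x@sIqr, algorithms = x@sAlgorithms, agreement = x@sAgreement))

#' @describeIn accessors identity fraction of an AlignmentResult
#' @export
setMethod("pidentity", "AlignmentResult", function(x) x@identity)

#' @describeIn accessors RMSD (Angstrom) of a superposition
#' @export
setMethod("rmsd", "SuperpositionResult", function(x) x@rmsd)

#' @describeIn accessors target-normalized TM-score of a superposition
#' @export
setMethod("tmScore", "SuperpositionResult", function(x) x@tmScore)

# ---- show methods ----

setMethod("show", "EpitopeSet", function(object) {
  p <- object@predictions
  cat(sprintf("EpitopeSet with %d prediction(s): %d sequence(s), %d algorithm(s)\n",
              nrow(p), length(unique(p$seq_id)), length(unique(p$algorithm))))
  if (nrow(p) > 0) print(head(p, 6))
  if (nrow(p) > 6) cat(sprintf("... and %d more rows\n", nrow(p) - 6L))
})

setMethod("show", "ConsensusEpitope", function(object) {
  cat(sprintf("ConsensusEpitope '%s' columns %d-%d (%d seqs, %d algorithms)\n",
              object@peptide, object@colStart, object@colEnd,
              length(object@supportingSequences),
              length(object@supportingAlgorithms)))
})

setMethod("show", "ConservationReport", function(object) {
  cat(sprintf("ConservationReport '%s': index %.4f\n",
              object@epitope@peptide, object@index))
  print(round(components(object), 4))
})

setMethod("show", "AlignmentResult", function(object) {
  cat(sprintf("AlignmentResult: score %.1f, identity %.3f (%d matches), target span %d-%d\n",
              object@score, object@identity, object@matches,
              object@targetStart, object@targetEnd))
})

setMethod("show", "SuperpositionResult", function(object) {
  cat(sprintf("SuperpositionResult: rmsd %.3f A, TM (target) %.4f, TM (query) %.4f, n = %d\n",
              object@rmsd, object@tmScore, object@tmScoreQuery, object@nMatched))
})
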