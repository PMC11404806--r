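#' Reconstructed human IgA heavy-chain constant regions
#'
#' Returns the two human IgA heavy-chain constant-region sequences used as
#' reference chains for epitope identity comparisons: IGHA1 (353 aa) and
#' IGHA2 (340 aa).
#'
#' These are \emph{synthetic reconstructions} written from model knowledge
#' of the corresponding UniProt entries (P01876, P01877), shipped under
#' \code{inst/extdata/human_iga_constant_synthetic.fasta} because the
#' package builds and tests fully offline. They reproduce most, but not
#' necessarily all, positions of the database entries; identity values
#' computed against them should be treated accordingly, and users with
#' network access should substitute the actual UniProt FASTA records.
#'
#' @return \link[Biostrings]{AAStringSet} with elements \code{IGHA1} and
#'   \code{IGHA2}.
#' @export
humanIgAChains <- function() {
  readFasta(system.file("extdata", "human_iga_constant_synthetic.fasta",
                        package = "epicons", mustWork = TRUE))
}

#' The thirteen consensus epitope peptides of the manatee IgA study design
#'
#' Consensus linear B-cell epitopes on Florida manatee IgA, as published,
#' with their heavy-chain domain assignments. These peptides serve as the
#' canonical worked example for the identity and similarity stages.
#'
#' @return named character vector (names = domain labels).
#' @export
manateeConsensusEpitopes <- function() {
  c(VH = "DTSKS", VH = "VNSEDT",
    CH1 = "LVTVSSEPETSPRVFP", CH1 = "NHSGENVTV", CH1 = "DQCPDN",
    CH1 = "HNSSSQEAKVP",
    CH2 = "APERDS", CH2 = "EPWKSGNK", CH2 = "GTQSATISKNSGN",
    CH3 = "HLLPPPAEEL", CH3 = "QLPQNN", CH3 = "PRQEPG", CH3 = "QTWKWGD")
}
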