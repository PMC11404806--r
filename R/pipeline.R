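# End-to-end orchestration: from sequences + per-algorithm predictions (real
# or simulated) to a joined conservation / identity / similarity report.
# A thin command-line wrapper over these functions ships in
# inst/scripts/epicons.

#' Run the consensus-epitope pipeline
#'
#' Orchestrates: input loading (or simulation), intra- and inter-algorithm
#' consensus, conservation scoring, identity and shared-amino-acid
#' comparison against reference chains, neighbor-joining tree construction,
#' and a joined report. Every output lands in \code{outDir}; a machine
#' readable manifest (config hash, package version, seed) is written next
#' to them. Outputs are deterministic given identical inputs and config.
#'
#' @param config configuration list, or path to a YAML file containing one.
#'   Recognized fields: \code{seed}; \code{simulate} (list of
#'   \code{\link{simConfig}} overrides; when present the family and
#'   predictions are simulated); \code{fasta}, \code{alignment} (input
#'   paths when not simulating); \code{predictions} (list of
#'   \code{list(algorithm=, file=, type="peptide"|"residue", seq_id=,
#'   threshold=, dedupe=)} entries); \code{min_support},
#'   \code{min_algorithms}, \code{min_length}; \code{scheme}
#'   (\code{"needle"} or \code{"simple"}); \code{references} (FASTA of
#'   reference chains); \code{reference_epitopes} (named list: reference
#'   chain id -> epitope TSV); \code{domains} (BED path) with
#'   \code{domain_ref} (member id); \code{tree} (logical).
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with the report data.frame and the
#'   intermediate objects.
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config) && length(config) == 1L) {
    cfgPath <- config
    config <- yaml::read_yaml(config)
  } else cfgPath <- NULL
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  minSupport <- config$min_support %||% 3L
  minAlgorithms <- config$min_algorithms %||% 3L
  minLength <- config$min_length %||% 5L
  scheme <- config$scheme %||% "needle"

  # ---- inputs ----
  if (!is.null(config$simulate)) {
    simArgs <- config$simulate
    simArgs$seed <- simArgs$seed %||% seed
    cfg <- do.call(simConfig, simArgs)
    family <- simulateFamily(cfg)
    es <- simulatePredictions(family, cfg)
    aln <- family$alignment
    seqs <- family$sequences
    writeFasta(seqs, file.path(outDir, "sequences.fasta"))
  } else {
    if (is.null(config$alignment)) stop("stage 'ingest': no alignment input")
    aln <- readAlignment(config$alignment,
                         dialect = config$alignment_dialect %||% "fasta")
    seqs <- Biostrings::AAStringSet(vapply(alnIds(aln), function(id)
      degap(aln, id), character(1)))
    sets <- lapply(config$predictions, function(p) {
      seq <- as.character(seqs[[p$seq_id]])
      if ((p$type %||% "peptide") == "residue") {
        prof <- parseResidueScores(p$file, p$algorithm, seq, seqId = p$seq_id,
                                   threshold = p$threshold %||% 0)
        callEpitopes(prof, minLength = minLength)
      } else {
        parsePeptidePredictions(p$file, p$algorithm, seq, seqId = p$seq_id,
                                dedupe = isTRUE(p$dedupe))
      }
    })
    es <- combineEpitopeSets(sets)
  }
  writeEpitopeSet(es, file.path(outDir, "predictions.tsv"))

  # ---- consensus ----
  perAlg <- lapply(setNames(nm = algorithms(es)), function(a)
    intraAlgorithmConsensus(es, aln, a, minSupport = minSupport,
                            minLength = minLength))
  final <- interAlgorithmConsensus(perAlg, aln,
                                   minAlgorithms = minAlgorithms,
                                   minLength = minLength)
  if (!is.null(config$domains)) {
    doms <- readDomainsBed(config$domains)
    final <- assignDomains(final, aln, config$domain_ref, doms)
  }

  # ---- conservation ----
  reports <- conservationReports(final, es, aln)
  consTab <- data.frame(
    epitope = vapply(final, peptide, character(1)),
    domain = vapply(final, domainLabel, character(1)),
    col_start = vapply(final, function(e) e@colStart, integer(1)),
    col_end = vapply(final, function(e) e@colEnd, integer(1)),
    n_sequences = vapply(final, function(e) length(e@supportingSequences), integer(1)),
    n_algorithms = vapply(final, function(e) length(e@supportingAlgorithms), integer(1)),
    conservation = vapply(reports, conservationIndex, numeric(1)),
    stringsAsFactors = FALSE)
  writeReportTsv(consTab, file.path(outDir, "conservation.tsv"))

  # ---- compare ----
  report <- consTab
  if (!is.null(config$references) && nrow(consTab) > 0) {
    refs <- readFasta(config$references)
    idt <- epitopeIdentityTable(setNames(consTab$epitope, consTab$epitope),
                                refs, scheme = scheme)
    writeReportTsv(idt, file.path(outDir, "identity.tsv"))
    for (rn in names(refs)) {
      sub <- idt[idt$reference == rn, ]
      report[[paste0("identity_", rn)]] <-
        round(sub$identity[match(report$epitope, sub$epitope)], 2)
    }
    for (rn in names(config$reference_epitopes %||% list())) {
      refEp <- readReferenceEpitopes(config$reference_epitopes[[rn]])
      sub <- idt[idt$reference == rn, ]
      summ <- lapply(seq_len(nrow(report)), function(k) {
        row <- sub[match(report$epitope[k], sub$epitope), ]
        sharedAASummary(row$target_start, row$target_end, refEp,
                        queryLength = nchar(report$epitope[k]))
      })
      report[[paste0("M_", rn)]] <- vapply(summ, function(s) s$modeLabel, character(1))
      report[[paste0("R_", rn)]] <- vapply(summ, function(s) s$rangeLabel, character(1))
      report[[paste0("n_", rn)]] <- vapply(summ, function(s) s$nMatching, integer(1))
    }
  }
  writeReportTsv(report, file.path(outDir, "report.tsv"))

  # ---- tree ----
  tree <- NULL
  if (isTRUE(config$tree %||% TRUE) && length(seqs) >= 3) {
    tree <- buildNJTree(aln)
    writeNewick(tree, file.path(outDir, "tree.nwk"))
  }

  # ---- manifest ----
  cfgNorm <- config[order(names(config))]
  hash <- substr(paste(
    tools::md5sum(writeTempYaml(cfgNorm))[[1]]), 1, 32)
  manifest <- list(package = "epicons",
                   version = as.character(utils::packageVersion("epicons")),
                   seed = seed, config_md5 = hash,
                   config_file = cfgPath %||% NA,
                   n_consensus_epitopes = nrow(consTab))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(report = report, conservation = reports, consensus = final,
                 perAlgorithm = perAlg, predictions = es, alignment = aln,
                 sequences = seqs, tree = tree))
}

writeTempYaml <- function(x) {
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(x, f)
  f
}

writeReportTsv <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "-")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate pipeline output against simulation truth
#'
#' Matches final consensus epitopes to planted intervals by interval
#' Jaccard on a chosen member's coordinates (the simulated alignment is
#' ungapped, so columns equal positions), and contrasts conservation
#' indices of intra-algorithm consensus epitopes overlapping planted
#' regions against decoys.
#'
#' @param pipelineResult value of \code{\link{runPipeline}} on a simulated
#'   config.
#' @param truth planted-interval data.frame from
#'   \code{\link{simulateFamily}}.
#' @param jaccardMin minimum interval Jaccard to count a planted epitope as
#'   recovered (default 0.5).
#' @return list: \code{recovery} (fraction of planted epitopes recovered),
#'   \code{plantedIdx}/\code{decoyIdx} (conservation indices of
#'   intra-level consensus epitopes overlapping planted regions or not),
#'   and \code{pValue} of the one-sided Mann-Whitney test that planted
#'   epitopes score higher.
#' @export
evaluateRecovery <- function(pipelineResult, truth, jaccardMin = 0.5) {
  final <- pipelineResult$consensus
  recovered <- vapply(seq_len(nrow(truth)), function(k)
    any(vapply(final, function(ep)
      intervalJaccard(ep@colStart, ep@colEnd, truth$start[k], truth$end[k]) >=
        jaccardMin, logical(1))), logical(1))
  intra <- unlist(pipelineResult$perAlgorithm, recursive = FALSE)
  idx <- numeric(0); planted <- logical(0)
  if (length(intra) > 0) {
    reps <- conservationReports(intra, pipelineResult$predictions,
                                pipelineResult$alignment)
    idx <- vapply(reps, conservationIndex, numeric(1))
    planted <- vapply(intra, function(ep)
      any(vapply(seq_len(nrow(truth)), function(k)
        intervalJaccard(ep@colStart, ep@colEnd,
                        truth$start[k], truth$end[k]) >= jaccardMin,
        logical(1))), logical(1))
  }
  p <- if (any(planted) && any(!planted))
    wilcox.test(idx[planted], idx[!planted], alternative = "greater",
                exact = FALSE)$p.value else NA_real_
  list(recovery = mean(recovered), plantedIdx = idx[planted],
       decoyIdx = idx[!planted], pValue = p)
}
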