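# Synthetic data generator. Emulates the study conditions the pipeline
# assumes: a family of K homologous sequences diverged from a common
# ancestor with conserved (planted) epitope regions, noisy per-algorithm
# epitope predictions with controlled inter-algorithm agreement, and a
# reference-epitope set planted on a target chain. A single integer seed
# drives every draw, so all fixtures are bitwise reproducible.

#' Simulation configuration
#'
#' Defaults mirror the study design the pipeline targets: five homologous
#' sequences scored by ten algorithms.
#'
#' @param seed integer seed driving all draws.
#' @param nMembers number of homologous sequences (default 5).
#' @param ancestorLength ancestor length in residues.
#' @param substitutionProb per-site substitution probability outside planted
#'   epitopes; inside planted epitopes sites mutate at one tenth this rate.
#' @param nPlantedEpitopes number of planted (conserved) epitope regions.
#' @param epitopeLengthRange length-2 integer range of planted epitope
#'   lengths.
#' @param nAlgorithms number of emulated prediction algorithms (default 10).
#' @param algorithmAgreement probability that an algorithm recovers a
#'   planted epitope.
#' @param scoreNoiseSd Gaussian noise SD added to prediction scores.
#' @param decoyRate expected decoys per algorithm per 100 residues.
#' @param plantedScore,decoyScore base prediction scores for planted and
#'   decoy epitopes.
#' @return validated configuration list of class \code{SimConfig}.
#' @export
simConfig <- function(seed = 1L, nMembers = 5L, ancestorLength = 400L,
                      substitutionProb = 0.05, nPlantedEpitopes = 3L,
                      epitopeLengthRange = c(8L, 15L), nAlgorithms = 10L,
                      algorithmAgreement = 0.9, scoreNoiseSd = 0.1,
                      decoyRate = 0.5, plantedScore = 0.8, decoyScore = 0.5) {
  stopifnot(substitutionProb >= 0, substitutionProb <= 1,
            algorithmAgreement >= 0, algorithmAgreement <= 1,
            ancestorLength >= 1, nMembers >= 1, nAlgorithms >= 1,
            epitopeLengthRange[1] >= 1,
            epitopeLengthRange[2] >= epitopeLengthRange[1])
  if (epitopeLengthRange[2] > ancestorLength)
    stop("planted epitopes cannot be longer than the ancestor")
  structure(list(
    seed = as.integer(seed), nMembers = as.integer(nMembers),
    ancestorLength = as.integer(ancestorLength),
    substitutionProb = substitutionProb,
    nPlantedEpitopes = as.integer(nPlantedEpitopes),
    epitopeLengthRange = as.integer(epitopeLengthRange),
    nAlgorithms = as.integer(nAlgorithms),
    algorithmAgreement = algorithmAgreement,
    scoreNoiseSd = scoreNoiseSd, decoyRate = decoyRate,
    plantedScore = plantedScore, decoyScore = decoyScore),
    class = "SimConfig")
}

# non-overlapping interval placement with a minimum spacer, uniform over
# feasible arrangements (stars-and-bars allocation of the slack)
placeIntervals <- function(n, lens, total, minGap = 2L) {
  if (n == 0) return(data.frame(start = integer(), end = integer()))
  need <- sum(lens) + (n - 1L) * minGap
  if (need > total)
    stop("cannot place ", n, " non-overlapping epitopes on length ", total)
  free <- total - need
  cuts <- if (n > 0 && free > 0) sort(sample.int(free + n, n)) else seq_len(n)
  gaps <- diff(c(0L, cuts, free + n + 1L)) - 1L   # n+1 nonneg parts summing to free
  starts <- integer(n); pos <- 0L
  for (k in seq_len(n)) {
    pos <- pos + gaps[k] + if (k > 1L) minGap else 0L
    starts[k] <- pos + 1L
    pos <- pos + lens[k]
  }
  data.frame(start = starts, end = starts + lens - 1L)
}

#' Simulate a family of homologous sequences with planted epitopes
#'
#' The ancestor is drawn uniformly over the 20 standard residues. Each
#' member mutates independently per site with the configured probability;
#' sites inside planted epitope regions mutate at one tenth that rate
#' (conserved regions). The alignment is the trivial ungapped one.
#'
#' @param cfg \code{\link{simConfig}}.
#' @return list with \code{alignment}
#'   (\link[Biostrings]{AAMultipleAlignment}), \code{sequences}
#'   (\link[Biostrings]{AAStringSet}), \code{truth} (data.frame of planted
#'   start/end, identical in residue and column coordinates here), and
#'   \code{ancestor}.
#' @export
simulateFamily <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  L <- cfg$ancestorLength
  anc <- sample(AA_ALPHABET20, L, replace = TRUE)
  lens <- if (cfg$nPlantedEpitopes > 0)
    sample(seq(cfg$epitopeLengthRange[1], cfg$epitopeLengthRange[2]),
           cfg$nPlantedEpitopes, replace = TRUE) else integer(0)
  truth <- placeIntervals(cfg$nPlantedEpitopes, lens, L)
  inEpitope <- rep(FALSE, L)
  for (k in seq_len(nrow(truth))) inEpitope[truth$start[k]:truth$end[k]] <- TRUE
  rate <- ifelse(inEpitope, cfg$substitutionProb / 10, cfg$substitutionProb)
  members <- vapply(seq_len(cfg$nMembers), function(m) {
    mut <- runif(L) < rate
    res <- anc
    if (any(mut))
      res[mut] <- vapply(res[mut], function(r)
        sample(setdiff(AA_ALPHABET20, r), 1L), character(1))
    paste(res, collapse = "")
  }, character(1))
  names(members) <- sprintf("member%02d", seq_len(cfg$nMembers))
  seqs <- Biostrings::AAStringSet(members)
  list(alignment = asAlignment(members), sequences = seqs,
       truth = truth, ancestor = paste(anc, collapse = ""))
}

#' Simulate per-algorithm epitope predictions for a family
#'
#' Each algorithm recovers each planted epitope with probability
#' \code{algorithmAgreement}; a recovered epitope is emitted on every member
#' (emulating a deterministic tool applied to near-identical homologs) with
#' a shared start jitter of -1/0/+1. Each algorithm additionally emits
#' Poisson-distributed decoy epitopes at random positions, also on every
#' member. Scores are a base value plus Gaussian noise.
#'
#' @param family result of \code{\link{simulateFamily}}.
#' @param cfg the same \code{\link{simConfig}}.
#' @return \linkS4class{EpitopeSet} covering all algorithms and members.
#' @export
simulatePredictions <- function(family, cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed + 1L)
  seqs <- family$sequences
  L <- nchar(as.character(seqs[[1]]))
  truth <- family$truth
  rows <- list()
  emit <- function(alg, s, e, base) {
    for (m in names(seqs)) {
      sc <- base + rnorm(1, sd = cfg$scoreNoiseSd)
      rows[[length(rows) + 1L]] <<- data.frame(
        seq_id = m, algorithm = alg, start = s, end = e,
        peptide = substr(as.character(seqs[[m]]), s, e),
        score = sc, stringsAsFactors = FALSE)
    }
  }
  for (a in seq_len(cfg$nAlgorithms)) {
    alg <- sprintf("alg%02d", a)
    for (k in seq_len(nrow(truth))) {
      if (runif(1) < cfg$algorithmAgreement) {
        jit <- sample(-1:1, 1L)
        s <- max(1L, truth$start[k] + jit)
        e <- min(L, truth$end[k] + jit)
        emit(alg, s, e, cfg$plantedScore)
      }
    }
    nDecoys <- rpois(1, cfg$decoyRate * L / 100)
    for (d in seq_len(nDecoys)) {
      len <- sample(seq(cfg$epitopeLengthRange[1], cfg$epitopeLengthRange[2]), 1L)
      s <- sample.int(L - len + 1L, 1L)
      emit(alg, s, s + len - 1L, cfg$decoyScore)
    }
  }
  emptyish <- data.frame(seq_id = character(), algorithm = character(),
                         start = integer(), end = integer(),
                         peptide = character(), score = numeric(),
                         stringsAsFactors = FALSE)
  new("EpitopeSet", predictions = if (length(rows)) do.call(rbind, rows) else emptyish)
}

#' Simulate a reference epitope set on a target chain
#'
#' Uniformly placed intervals of uniformly drawn lengths, reproducible from
#' the seed. Stands in for experimentally confirmed epitope tables.
#'
#' @param chainLength reference chain length.
#' @param n number of reference epitopes.
#' @param lengthRange length-2 range of epitope lengths.
#' @param seed integer seed.
#' @param refChain optional chain residues; when given, peptides are cut
#'   from it, otherwise placeholder \code{X} peptides are used.
#' @return data.frame id, peptide, start, end.
#' @export
simulateReferenceEpitopes <- function(chainLength, n, lengthRange = c(6L, 15L),
                                      seed = 1L, refChain = NULL) {
  if (lengthRange[2] > chainLength)
    stop("reference epitopes cannot be longer than the chain")
  set.seed(seed)
  if (n == 0)
    return(data.frame(id = character(), peptide = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  lens <- sample(seq(lengthRange[1], lengthRange[2]), n, replace = TRUE)
  starts <- vapply(lens, function(l) sample.int(chainLength - l + 1L, 1L),
                   integer(1))
  ends <- starts + lens - 1L
  peps <- if (is.null(refChain)) strrep("X", lens) else
    substring(toupper(as.character(refChain)), starts, ends)
  data.frame(id = sprintf("ref%04d", seq_len(n)), peptide = peps,
             start = starts, end = ends, stringsAsFactors = FALSE)
}

#' Jaccard overlap of two 1-based inclusive intervals
#'
#' @param s1,e1,s2,e2 interval bounds.
#' @return intersection / union, in [0, 1].
#' @export
intervalJaccard <- function(s1, e1, s2, e2) {
  inter <- max(0L, min(e1, e2) - max(s1, s2) + 1L)
  union <- (e1 - s1 + 1L) + (e2 - s2 + 1L) - inter
  inter / union
}
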