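#' The seven packaged propensity scales
#'
#' Per-residue physicochemical scales used for sliding-window linear B-cell
#' epitope propensity profiles: Parker hydrophilicity, Karplus-Schulz
#' flexibility, Emini surface accessibility, Chou-Fasman beta-turn
#' propensity, an exposed-surface preference (Janin transfer free energy,
#' sign-flipped so larger means more exposed), Grantham polarity, and
#' Kolaskar-Tongaonkar antigenic propensity. Tables ship as TSV under
#' \code{inst/extdata/scales}.
#'
#' @return character vector of scale names.
#' @export
propensityScaleNames <- function() {
  c("hydrophilicity", "flexibility", "accessibility", "turns",
    "exposed_surface", "polarity", "antigenic_propensity")
}

#' Load one propensity scale
#'
#' @param name one of \code{propensityScaleNames()}.
#' @param window odd smoothing window width (default 7 for every scale).
#' @param defaultThreshold calling threshold on the normalized [-3, +3]
#'   scale (default 0).
#' @return \linkS4class{PropensityScale}.
#' @export
propensityScale <- function(name, window = 7L, defaultThreshold = 0) {
  name <- match.arg(name, propensityScaleNames())
  path <- system.file("extdata", "scales", paste0(name, ".tsv"),
                      package = "epicons", mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  vals <- setNames(tab$value, tab$residue)
  new("PropensityScale", name = name, values = vals,
      window = as.integer(window), defaultThreshold = defaultThreshold)
}

#' Load all seven propensity scales
#'
#' @inheritParams propensityScale
#' @return named list of \linkS4class{PropensityScale} objects.
#' @export
propensityScales <- function(window = 7L, defaultThreshold = 0) {
  scales <- lapply(propensityScaleNames(), propensityScale,
                   window = window, defaultThreshold = defaultThreshold)
  setNames(scales, propensityScaleNames())
}

#' Sliding-window propensity profile, rescaled to [-3, +3]
#'
#' Computes the window mean of the raw scale values centered at each residue
#' (windows overhanging a terminus are truncated), then rescales the profile
#' per sequence so that its minimum maps to -3 and its maximum to +3.
#' A constant profile maps to 0 everywhere. \code{X} residues take the mean
#' of the 20 scale values.
#'
#' @param seq residue string, \link[Biostrings]{AAString}, or a length-1
#'   \link[Biostrings]{AAStringSet}.
#' @param scale \linkS4class{PropensityScale}.
#' @param seqId identifier recorded in the profile (defaults to the name of
#'   \code{seq} if present, else \code{"seq"}).
#' @return \linkS4class{ResidueProfile} whose algorithm name is
#'   \code{"propensity:<scale name>"}.
#' @export
propensityProfile <- function(seq, scale, seqId = NULL) {
  stopifnot(is(scale, "PropensityScale"))
  if (is(seq, "AAStringSet")) {
    if (is.null(seqId)) seqId <- names(seq)[1]
    seq <- as.character(seq[[1]])
  }
  seq <- toupper(as.character(seq))
  if (is.null(seqId)) seqId <- "seq"
  n <- nchar(seq)
  if (n < 1L) stop("sequence must be non-empty")
  chars <- strsplit(seq, "")[[1]]
  bad <- setdiff(chars, AA_ALLOWED)
  if (length(bad) > 0)
    stop("illegal residue character(s): ", paste(unique(bad), collapse = ""))
  vals <- scale@values[chars]
  vals[chars == "X"] <- mean(scale@values[AA_ALPHABET20])
  half <- (scale@window - 1L) %/% 2L
  raw <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(vals[lo:hi])
  }, numeric(1))
  rng <- range(raw)
  if (diff(rng) < .Machine$double.eps * max(1, abs(rng[2]))) {
    scores <- rep(0, n)
  } else {
    scores <- -3 + 6 * (raw - rng[1]) / (rng[2] - rng[1])
  }
  new("ResidueProfile", seqId = seqId,
      algorithm = paste0("propensity:", scale@name),
      residues = seq, scores = scores, threshold = scale@defaultThreshold)
}

#' Call epitopes from a residue profile by thresholding
#'
#' Maximal runs of consecutive positions with score at or above the
#' threshold, of length at least \code{minLength}, become predictions whose
#' score is the run mean.
#'
#' @param profile \linkS4class{ResidueProfile}.
#' @param threshold calling threshold (default: the profile's own).
#' @param minLength minimum epitope length (default 5).
#' @return \linkS4class{EpitopeSet} (possibly empty).
#' @export
callEpitopes <- function(profile, threshold = profile@threshold, minLength = 5L) {
  stopifnot(is(profile, "ResidueProfile"), minLength >= 1L)
  above <- profile@scores >= threshold
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= minLength
  rows <- lapply(which(keep), function(k) {
    s <- starts[k]; e <- ends[k]
    data.frame(seq_id = profile@seqId, algorithm = profile@algorithm,
               start = s, end = e,
               peptide = substr(profile@residues, s, e),
               score = mean(profile@scores[s:e]),
               stringsAsFactors = FALSE)
  })
  emptyish <- data.frame(seq_id = character(), algorithm = character(),
                         start = integer(), end = integer(),
                         peptide = character(), score = numeric(),
                         stringsAsFactors = FALSE)
  new("EpitopeSet", predictions = if (length(rows)) do.call(rbind, rows) else emptyish)
}

#' Run all propensity scales on a set of sequences
#'
#' Convenience wrapper: computes a profile per sequence per scale and calls
#' epitopes with each scale's default threshold.
#'
#' @param seqs \link[Biostrings]{AAStringSet} (or named character vector).
#' @param scales list of \linkS4class{PropensityScale} objects
#'   (default: all seven).
#' @param minLength minimum epitope length.
#' @return \linkS4class{EpitopeSet} combining all calls.
#' @export
predictPropensityEpitopes <- function(seqs, scales = propensityScales(),
                                      minLength = 5L) {
  if (is.character(seqs)) seqs <- Biostrings::AAStringSet(seqs)
  sets <- list()
  for (i in seq_along(seqs)) {
    for (sc in scales) {
      prof <- propensityProfile(as.character(seqs[[i]]), sc,
                                seqId = names(seqs)[i])
      sets[[length(sets) + 1L]] <- callEpitopes(prof, minLength = minLength)
    }
  }
  combineEpitopeSets(sets)
}

#' Combine several EpitopeSets into one
#'
#' @param sets list of \linkS4class{EpitopeSet} objects.
#' @return \linkS4class{EpitopeSet}.
#' @export
combineEpitopeSets <- function(sets) {
  tabs <- lapply(sets, predictions)
  new("EpitopeSet", predictions = do.call(rbind, tabs))
}

#' Export a residue profile as TSV
#'
#' Columns: seq_id, pos, residue, score, above_threshold.
#'
#' @param profile \linkS4class{ResidueProfile}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeProfile <- function(profile, path) {
  tab <- data.frame(
    seq_id = profile@seqId,
    pos = seq_along(profile@scores),
    residue = strsplit(profile@residues, "")[[1]],
    score = profile@scores,
    above_threshold = profile@scores >= profile@threshold)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
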