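# Structural overlap metrics on residue-matched C-alpha coordinate sets:
# Kabsch least-squares superposition (SVD, proper rotation enforced) and the
# TM-score. bio3d handles PDB parsing; the metrics themselves are authored
# here and cross-checked against bio3d's fitting in the tests.

#' Read C-alpha coordinates from a PDB file
#'
#' Extracts the C-alpha atoms of ATOM records (altloc \code{'A'} or blank
#' preferred); insertion codes are preserved in the residue labels.
#'
#' @param path PDB file.
#' @param chain optional chain identifier to restrict to.
#' @return numeric matrix n x 3 with residue labels
#'   ("chain:resno[insert]") as rownames.
#' @export
readCAlpha <- function(path, chain = NULL) {
  pdb <- bio3d::read.pdb(path)
  sel <- pdb$atom$elety == "CA" & pdb$atom$type == "ATOM"
  if (!is.null(chain)) sel <- sel & pdb$atom$chain %in% chain
  alt <- pdb$atom$alt
  sel <- sel & (is.na(alt) | alt == "" | alt == "A")
  at <- pdb$atom[sel, , drop = FALSE]
  if (nrow(at) < 1L) stop("no C-alpha ATOM records in ", path)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  ins <- ifelse(is.na(at$insert) | at$insert == "", "", at$insert)
  rownames(xyz) <- paste0(at$chain, ":", at$resno, ins)
  xyz
}

#' Write a coordinate set as a minimal C-alpha-only PDB
#'
#' @param xyz n x 3 coordinate matrix.
#' @param path output path.
#' @param chain chain identifier to write.
#' @return \code{path}, invisibly.
#' @export
writeCAlpha <- function(xyz, path, chain = "A") {
  lines <- vapply(seq_len(nrow(xyz)), function(i)
    sprintf("ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, chain, i, xyz[i, 1], xyz[i, 2], xyz[i, 3]), character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Optimal rigid superposition of two matched coordinate sets
#'
#' Kabsch algorithm: centers both sets, computes the SVD of the covariance,
#' and enforces a proper rotation (determinant +1). Returns the RMSD over
#' matched pairs and TM-scores under both normalizations.
#'
#' @param a mobile coordinate set (n x 3), superposed onto \code{b}.
#' @param b fixed coordinate set (n x 3); rows are matched pairs.
#' @param targetLength chain length used for target-normalized TM-score
#'   (default: number of matched pairs).
#' @param queryLength chain length for query-normalized TM-score
#'   (default: number of matched pairs).
#' @return \linkS4class{SuperpositionResult}.
#' @export
kabschSuperpose <- function(a, b, targetLength = nrow(b), queryLength = nrow(a)) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("coordinate sets must have matching sizes")
  if (nrow(a) < 3L) stop("need at least 3 matched points")
  if (any(!is.finite(a)) || any(!is.finite(b))) stop("coordinates must be finite")
  ca <- colMeans(a); cb <- colMeans(b)
  A <- sweep(a, 2, ca); B <- sweep(b, 2, cb)
  H <- t(A) %*% B
  sv <- svd(H)
  dsign <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, dsign)) %*% t(sv$u)
  rot <- A %*% t(R)
  dif <- rot - B
  dists <- sqrt(rowSums(dif^2))
  rmsd <- sqrt(mean(dists^2))
  trans <- cb - as.numeric(R %*% ca)
  new("SuperpositionResult",
      rmsd = rmsd,
      tmScore = tmScoreFromDistances(dists, targetLength),
      tmScoreQuery = tmScoreFromDistances(dists, queryLength),
      rotation = R, translation = trans,
      nMatched = nrow(a), targetLength = as.integer(targetLength),
      distances = dists)
}

#' TM-score from per-pair distances
#'
#' \deqn{TM = (1/L) \sum_i 1 / (1 + (d_i/d_0)^2)} with
#' \eqn{d_0 = 1.24 (L - 15)^{1/3} - 1.8}, floored at 0.5 Angstrom for short
#' chains, and \eqn{L} the normalization length.
#'
#' @param distances nonnegative per-pair distances (Angstrom).
#' @param normLength normalization length L (> 0).
#' @return TM-score in (0, 1].
#' @export
tmScoreFromDistances <- function(distances, normLength) {
  if (normLength <= 0) stop("normalization length must be positive")
  if (any(distances < 0)) stop("distances must be nonnegative")
  d0 <- max(1.24 * (max(normLength - 15, 0))^(1 / 3) - 1.8, 0.5)
  sum(1 / (1 + (distances / d0)^2)) / normLength
}

#' d0 distance scale used by the TM-score
#'
#' @param normLength normalization length.
#' @return d0 in Angstrom (floored at 0.5).
#' @export
tmD0 <- function(normLength) {
  max(1.24 * (max(normLength - 15, 0))^(1 / 3) - 1.8, 0.5)
}

#' Apply a superposition's transform to coordinates
#'
#' @param xyz n x 3 matrix.
#' @param sup \linkS4class{SuperpositionResult}.
#' @return transformed n x 3 matrix.
#' @export
applySuperposition <- function(xyz, sup) {
  sweep(as.matrix(xyz) %*% t(sup@rotation), 2, sup@translation, "+")
}
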