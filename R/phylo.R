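# Distance-based tree stage: p-distance from a protein MSA and a
# neighbor-joining tree. NJ itself is delegated to ape::nj (Saitou-Nei, as
# implemented throughout the field); this module owns the distance model and
# the branch-length hygiene around it.

#' Pairwise p-distance matrix from a protein alignment
#'
#' \code{d[i, j]} = mismatches / compared sites. With
#' \code{mode = "pairwise_deletion"} a site is compared for a pair when
#' neither member has a gap or \code{X} there; with
#' \code{mode = "complete_deletion"} only columns free of gaps and \code{X}
#' in every member are used for all pairs.
#'
#' @param aln \link[Biostrings]{AAMultipleAlignment} with at least 2 members.
#' @param mode \code{"pairwise_deletion"} (default) or
#'   \code{"complete_deletion"}.
#' @return symmetric numeric matrix with zero diagonal, labelled by member id.
#' @export
pDistance <- function(aln, mode = c("pairwise_deletion", "complete_deletion")) {
  mode <- match.arg(mode)
  mat <- alnMatrix(aln)
  if (nrow(mat) < 2L) stop("need at least 2 alignment members")
  ok <- mat != "-" & mat != "X"
  if (mode == "complete_deletion") {
    keep <- colSums(ok) == nrow(mat)
    mat <- mat[, keep, drop = FALSE]
    ok <- ok[, keep, drop = FALSE]
  }
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    comp <- ok[i, ] & ok[j, ]
    if (!any(comp))
      stop("no comparable sites for pair ", rownames(mat)[i], " / ",
           rownames(mat)[j])
    d[i, j] <- d[j, i] <- mean(mat[i, comp] != mat[j, comp])
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via \code{\link[ape]{nj}}). Negative branch
#' lengths, which NJ can produce on non-additive matrices, are clamped to
#' zero with a warning.
#'
#' @param d symmetric distance matrix with at least 3 labelled taxa.
#' @return \link[ape]{phylo} tree (unrooted).
#' @export
neighborJoining <- function(d) {
  if (!isSymmetric(unname(d))) stop("distance matrix must be symmetric")
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 taxa")
  tree <- ape::nj(as.dist(d))
  if (any(tree$edge.length < 0)) {
    warning("negative NJ branch length(s) clamped to zero")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Neighbor-joining tree straight from an alignment
#'
#' Convenience composition of \code{\link{pDistance}} and
#' \code{\link{neighborJoining}}.
#'
#' @inheritParams pDistance
#' @return \link[ape]{phylo}.
#' @export
buildNJTree <- function(aln, mode = "pairwise_deletion") {
  neighborJoining(pDistance(aln, mode = mode))
}

#' Write a labelled square distance matrix as TSV
#'
#' @param d matrix from \code{\link{pDistance}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeDistanceMatrix <- function(d, path) {
  write.table(data.frame(id = rownames(d), d, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
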