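# Shared fixtures and independent oracles used across the suite.

# tiny alignment builder
mkAln <- function(...) {
  v <- c(...)
  epicons::asAlignment(v)
}

# EpitopeSet builder from (seq_id, algorithm, start, end) rows against a
# named character vector of sequences
mkEpitopes <- function(seqs, rows, score = 1) {
  tab <- do.call(rbind, lapply(rows, function(r) {
    data.frame(seq_id = r[[1]], algorithm = r[[2]],
               start = as.integer(r[[3]]), end = as.integer(r[[4]]),
               peptide = substr(seqs[[r[[1]]]], r[[3]], r[[4]]),
               score = if (length(r) >= 5) r[[5]] else score,
               stringsAsFactors = FALSE)
  }))
  new("EpitopeSet", predictions = tab)
}

# exhaustive-enumeration oracle for global alignment score under the simple
# linear-gap scheme: walks every monotone lattice path, independent of the
# DP implementation it checks
enumNWScore <- function(q, t, match = 1, mismatch = 0, gap = -1) {
  qc <- strsplit(q, "")[[1]]; tc <- strsplit(t, "")[[1]]
  best <- -Inf
  rec <- function(i, j, acc) {
    if (i == 0 && j == 0) {
      if (acc > best) best <<- acc
      return(invisible())
    }
    if (i > 0 && j > 0) {
      s <- if (qc[i] == tc[j] && qc[i] != "X") match else mismatch
      rec(i - 1, j - 1, acc + s)
    }
    if (i > 0) rec(i - 1, j, acc + gap)
    if (j > 0) rec(i, j - 1, acc + gap)
  }
  rec(length(qc), length(tc), 0)
  best
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# random residue string
randSeq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# random proper rotation (QR of a random matrix, sign-fixed)
randRotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

refChainsPath <- function() {
  system.file("extdata", "human_iga_constant_synthetic.fasta",
              package = "epicons", mustWork = TRUE)
}
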