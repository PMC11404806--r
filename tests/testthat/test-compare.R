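test_that("self-alignment is gapless with identity 1", {
  r <- needlemanWunsch("PEPTIDE", "PEPTIDE", scheme = "simple")
  expect_equal(r@alignedQuery, "PEPTIDE")
  expect_equal(r@alignedTarget, "PEPTIDE")
  expect_equal(r@identity, 1.0)
  r2 <- needlemanWunsch("PEPTIDE", "PEPTIDE", scheme = "needle")
  expect_equal(r2@identity, 1.0)
})

test_that("the AC/AGC textbook case aligns as A-C with full query identity", {
  # oracle: among all global alignments of AC/AGC under +1/0/-1 the best
  # keeps both matches through one target insertion
  r <- needlemanWunsch("AC", "AGC", scheme = "simple")
  expect_equal(r@alignedQuery, "A-C")
  expect_equal(r@alignedTarget, "AGC")
  expect_equal(r@matches, 2L)
  expect_equal(r@identity, 1.0)
  expect_equal(r@score, enumNWScore("AC", "AGC"))
})

test_that("DP scores equal the exhaustive-enumeration oracle on random pairs", {
  withr::with_seed(42, {
    for (k in 1:200) {
      q <- randSeq(sample(1:6, 1))
      t <- randSeq(sample(1:6, 1))
      r <- needlemanWunsch(q, t, scheme = "simple")
      expect_equal(r@score, enumNWScore(q, t),
                   info = paste(q, t))
    }
  })
})

test_that("simple-scheme alignments are valid and degap to their inputs", {
  withr::with_seed(17, {
    for (k in 1:50) {
      q <- randSeq(sample(1:8, 1), AA20)
      t <- randSeq(sample(1:8, 1), AA20)
      r <- needlemanWunsch(q, t, scheme = "simple")
      expect_equal(gsub("-", "", r@alignedQuery), q)
      expect_equal(gsub("-", "", r@alignedTarget), t)
    }
  })
})

test_that("needle scheme agrees with Biostrings overlap alignment scores", {
  # independent route: Biostrings pairwiseAlignment with BLOSUM62 and
  # ends-free ("overlap") mode, same open/extend convention
  withr::with_seed(99, {
    for (k in 1:25) {
      q <- randSeq(sample(4:10, 1), AA20)
      t <- randSeq(sample(10:40, 1), AA20)
      mine <- needlemanWunsch(q, t, scheme = "needle")
      ref <- Biostrings::pairwiseAlignment(
        q, t, type = "overlap", substitutionMatrix = "BLOSUM62",
        gapOpening = 9.5, gapExtension = 0.5)
      expect_equal(mine@score, Biostrings::score(ref), info = paste(q, t))
    }
  })
})

test_that("identity is invariant when the target extends outside the span", {
  r1 <- needlemanWunsch("KVDEW", "AKVDEWRA")
  r2 <- needlemanWunsch("KVDEW", paste0("MMMM", "AKVDEWRA", "TTTT"))
  expect_equal(r1@identity, r2@identity)
  expect_equal(r1@identity, 1.0)
})

test_that("X never matches anything", {
  r <- needlemanWunsch("XXXX", "AKVD", scheme = "simple")
  expect_equal(r@identity, 0)
  refs <- Biostrings::AAStringSet(c(ref = "AKVDEWRACL"))
  tab <- epitopeIdentityTable(c("XXXX"), refs, scheme = "simple")
  expect_equal(tab$identity, 0)
})

test_that("epitope identity table covers every epitope-reference pair", {
  refs <- Biostrings::AAStringSet(c(r1 = "AKVDEWRACL", r2 = "AKVDEFRACL"))
  tab <- epitopeIdentityTable(c(ep1 = "KVDEW", ep2 = "RACL"), refs)
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$identity[tab$epitope == "ep2"], c(1, 1))
  self <- epitopeIdentityTable(c(e = "AKVDEWRACL"), refs["r1"])
  expect_equal(self$identity, 1.0)
})

test_that("shared amino acid summaries match brute-force intersection counts", {
  refs <- data.frame(id = c("r1", "r2", "r3"),
                     peptide = c("XXXX", "XXXX", "XXXX"),
                     start = c(1L, 3L, 5L), end = c(4L, 6L, 8L))
  # query span 3..8 (length 6); oracle by hand: overlaps 2, 4, 4
  s <- sharedAASummary(3, 8, refs, queryLength = 6)
  expect_equal(s$M, 4L)            # mode of {2,4,4}
  expect_equal(c(s$Rmin, s$Rmax), c(2L, 4L))
  expect_equal(s$nMatching, 3L)
  expect_equal(s$modeLabel, "4/6")
  expect_equal(s$rangeLabel, "2/6-4/6")

  # uniform overlap: three references each sharing exactly 4 positions
  refs2 <- data.frame(id = paste0("r", 1:3), peptide = "XXXX",
                      start = c(1L, 1L, 1L), end = c(4L, 4L, 4L))
  s2 <- sharedAASummary(1, 6, refs2, queryLength = 6)
  expect_equal(s2$M, 4L); expect_equal(s2$nMatching, 3L)
  expect_equal(s2$rangeLabel, "4/6")

  # empty reference set
  s3 <- sharedAASummary(1, 6, refs[0, ], queryLength = 6)
  expect_equal(s3$nMatching, 0L)
  expect_true(is.na(s3$M))
})

test_that("shared counts are invariant to reference ordering and match brute force", {
  withr::with_seed(7, {
    for (k in 1:20) {
      n <- sample(1:12, 1)
      starts <- sample(1:40, n, replace = TRUE)
      ends <- starts + sample(0:10, n, replace = TRUE)
      refs <- data.frame(id = paste0("r", 1:n), peptide = "X",
                         start = starts, end = ends)
      qs <- sample(1:40, 1); qe <- qs + sample(2:12, 1)
      s <- sharedAASummary(qs, qe, refs, queryLength = qe - qs + 1)
      sPerm <- sharedAASummary(qs, qe, refs[sample(n), ], queryLength = qe - qs + 1)
      expect_equal(s[c("M", "Rmin", "Rmax", "nMatching")],
                   sPerm[c("M", "Rmin", "Rmax", "nMatching")])
      # brute force
      ov <- pmax(0, pmin(ends, qe) - pmax(starts, qs) + 1)
      nz <- ov[ov > 0]
      expect_equal(s$nMatching, length(nz))
      if (length(nz) > 0) {
        expect_equal(c(s$Rmin, s$Rmax), range(nz))
        tb <- table(nz)
        expect_equal(s$M, as.integer(sort(names(tb)[tb == max(tb)])[1]))
      }
    }
  })
})

test_that("reference epitope tables validate against the chain", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(id = "e1", peptide = "KVDE", start = 2, end = 5),
              tf, sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- readReferenceEpitopes(tf, refChain = "AKVDEWRACL")
  expect_equal(tab$peptide, "KVDE")
  expect_error(readReferenceEpitopes(tf, refChain = "AKVFEWRACL"), "match")
})
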