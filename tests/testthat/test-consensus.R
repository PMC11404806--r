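# helpers for building consensus inputs ------------------------------------

identicalFamily <- function(n = 5, seq = "MKVDEWRACLTT") {
  v <- setNames(rep(seq, n), sprintf("m%d", seq_len(n)))
  v
}

consEpitope <- function(cs, ce, alg, pep = strrep("A", ce - cs + 1),
                        seqs = c("m1", "m2", "m3")) {
  new("ConsensusEpitope", peptide = pep, colStart = as.integer(cs),
      colEnd = as.integer(ce), domainLabel = NA_character_,
      supportingSequences = seqs, supportingAlgorithms = alg,
      perPositionSupport = rep(3L, ce - cs + 1))
}

test_that("identical members with identical predictions give full support", {
  fam <- identicalFamily()
  aln <- mkAln(fam)
  es <- mkEpitopes(fam, lapply(names(fam), function(m) list(m, "alg1", 3, 9)))
  out <- intraAlgorithmConsensus(es, aln, "alg1", minSupport = 3, minLength = 5)
  expect_length(out, 1L)
  expect_equal(unname(columnRange(out[[1]])), c(3L, 9L))
  expect_equal(perPositionSupport(out[[1]]), rep(5L, 7L))
  expect_equal(peptide(out[[1]]), substr(fam[[1]], 3, 9))
  expect_setequal(supportingSequences(out[[1]]), names(fam))
})

test_that("predictions in fewer members than minSupport yield nothing", {
  fam <- identicalFamily()
  aln <- mkAln(fam)
  es <- mkEpitopes(fam, list(list("m1", "alg1", 3, 9), list("m2", "alg1", 3, 9)))
  expect_length(intraAlgorithmConsensus(es, aln, "alg1", minSupport = 3), 0L)
  expect_error(intraAlgorithmConsensus(es, aln, "alg1", minSupport = 9),
               "minSupport")
})

test_that("staggered gapped predictions match a per-column brute force", {
  fam <- c(m1 = "MKVDEWRACLTT", m2 = "MKVDEWRACLTT", m3 = "MKVDE-WRACLT",
           m4 = "MKVDEFRACLTT", m5 = "MKVDEWRACLTT")
  aln <- mkAln(fam)
  # residue-coordinate predictions per member
  preds <- list(m1 = c(2, 9), m2 = c(3, 10), m3 = c(4, 10), m4 = c(2, 8),
                m5 = c(5, 12))
  seqs <- vapply(names(fam), function(m) gsub("-", "", fam[[m]]), character(1))
  es <- mkEpitopes(seqs, lapply(names(preds), function(m)
    list(m, "alg1", preds[[m]][1], preds[[m]][2])))

  # oracle: explicit per-column support count
  ncols <- nchar(fam[[1]])
  support <- integer(ncols)
  for (cc in seq_len(ncols)) {
    covered <- character(0); residues <- character(0)
    for (m in names(fam)) {
      row <- strsplit(fam[[m]], "")[[1]]
      if (row[cc] == "-") next
      pos <- sum(row[seq_len(cc)] != "-")
      if (pos >= preds[[m]][1] && pos <= preds[[m]][2]) {
        covered <- c(covered, m); residues <- c(residues, row[cc])
      }
    }
    if (length(covered) == 0) next
    tab <- table(residues)
    maj <- sort(names(tab)[tab == max(tab)])[1]
    support[cc] <- sum(residues == maj & residues != "X")
  }
  runs <- rle(support >= 3)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  keep <- which(runs$values & runs$lengths >= 3)

  out <- intraAlgorithmConsensus(es, aln, "alg1", minSupport = 3, minLength = 3)
  expect_length(out, length(keep))
  for (k in seq_along(keep)) {
    expect_equal(unname(columnRange(out[[k]])),
                 c(starts[keep[k]], ends[keep[k]]))
    expect_equal(perPositionSupport(out[[k]]),
                 support[starts[keep[k]]:ends[keep[k]]])
  }
})

test_that("single member with minSupport 1 returns its predictions unchanged", {
  fam <- c(solo = "MKVDEWRACLTT")
  aln <- mkAln(fam)
  es <- mkEpitopes(fam, list(list("solo", "alg1", 2, 5),
                             list("solo", "alg1", 8, 11)))
  out <- intraAlgorithmConsensus(es, aln, "alg1", minSupport = 1, minLength = 1)
  expect_length(out, 2L)
  expect_equal(unname(columnRange(out[[1]])), c(2L, 5L))
  expect_equal(unname(columnRange(out[[2]])), c(8L, 11L))
  expect_equal(peptide(out[[1]]), "KVDE")
})

test_that("member order never changes consensus output", {
  fam <- c(m1 = "MKVDEWRACLTT", m2 = "MKVDEWRACLTT", m3 = "MKVDEFRACLTT",
           m4 = "MKVDEWRACLTT", m5 = "MKVDEWRACLTT")
  es <- mkEpitopes(fam, lapply(names(fam), function(m) list(m, "alg1", 3, 10)))
  out1 <- intraAlgorithmConsensus(es, mkAln(fam), "alg1")
  perm <- fam[c(4, 2, 5, 1, 3)]
  out2 <- intraAlgorithmConsensus(es, mkAln(perm), "alg1")
  expect_equal(length(out1), length(out2))
  expect_equal(peptide(out1[[1]]), peptide(out2[[1]]))
  expect_equal(perPositionSupport(out1[[1]]), perPositionSupport(out2[[1]]))
})

test_that("inter-algorithm consensus applies the three-algorithm rule", {
  fam <- identicalFamily()
  aln <- mkAln(fam)
  same <- lapply(setNames(nm = c("a1", "a2", "a3")), function(a)
    list(consEpitope(3, 9, a)))
  out <- interAlgorithmConsensus(same, aln, minAlgorithms = 3, minLength = 5)
  expect_length(out, 1L)
  expect_equal(unname(columnRange(out[[1]])), c(3L, 9L))
  expect_setequal(supportingAlgorithms(out[[1]]), c("a1", "a2", "a3"))

  two <- same[1:2]
  expect_length(interAlgorithmConsensus(two, aln, minAlgorithms = 3), 0L)
})

test_that("partially overlapping algorithms reduce to the >=3 coverage set", {
  fam <- identicalFamily()
  aln <- mkAln(fam)
  per <- list(a1 = list(consEpitope(2, 8, "a1")),
              a2 = list(consEpitope(4, 10, "a2")),
              a3 = list(consEpitope(6, 12, "a3")))
  # coverage oracle: count algorithms per column
  cov <- sapply(1:12, function(cc)
    sum(c(cc >= 2 & cc <= 8, cc >= 4 & cc <= 10, cc >= 6 & cc <= 12)))
  expected <- range(which(cov >= 3))
  out <- interAlgorithmConsensus(per, aln, minAlgorithms = 3, minLength = 1)
  expect_length(out, 1L)
  expect_equal(unname(columnRange(out[[1]])), expected)
  expect_equal(perPositionSupport(out[[1]]), cov[cov >= 3])
})

# ---- conservation index ---------------------------------------------------

perfectScenario <- function() {
  fam <- identicalFamily()
  aln <- mkAln(fam)
  algs <- sprintf("a%d", 1:4)
  rows <- list()
  for (a in algs) for (m in names(fam)) rows[[length(rows) + 1L]] <-
    list(m, a, 2, 8, 1.0)
  # a weaker, non-adjacent second epitope so the perfect one sits above the
  # third quartile of the score distribution
  for (a in algs[1:3]) for (m in names(fam)[1:3]) rows[[length(rows) + 1L]] <-
    list(m, a, 10, 12, 0.2)
  es <- mkEpitopes(fam, rows)
  per <- lapply(setNames(nm = algs), function(a)
    intraAlgorithmConsensus(es, aln, a, minSupport = 3, minLength = 3))
  final <- interAlgorithmConsensus(per, aln, minAlgorithms = 3, minLength = 3)
  list(fam = fam, aln = aln, es = es, final = final)
}

test_that("a universally supported epitope with top scores reaches index 1", {
  sc <- perfectScenario()
  expect_length(sc$final, 2L)
  reps <- conservationReports(sc$final, sc$es, sc$aln)
  main <- reps[[which.max(vapply(reps, conservationIndex, numeric(1)))]]
  expect_equal(unname(components(main)), rep(1, 6))
  expect_equal(conservationIndex(main), 1.0)
  # ... and the index is 1 only because every component is 1
  other <- reps[[which.min(vapply(reps, conservationIndex, numeric(1)))]]
  expect_lt(conservationIndex(other), 1.0)
  expect_true(any(components(other) < 1))
})

test_that("conservation components match an independent hand computation", {
  fam <- c(m1 = "MKVDEWRACLTT", m2 = "MKVDEWRACLTT", m3 = "MKVDEFRACLTT",
           m4 = "MKVDEWRACLTT", m5 = "MKVDEWRACLTT")
  aln <- mkAln(fam)
  # epitope columns 3..9; algorithms a1 (3 members), a2 (3 members);
  # a3 runs but never predicts here
  rows <- list(list("m1", "a1", 3, 9, 0.9), list("m2", "a1", 3, 9, 0.7),
               list("m3", "a1", 3, 9, 0.5),
               list("m1", "a2", 3, 9, 0.4), list("m2", "a2", 3, 9, 0.4),
               list("m4", "a2", 3, 9, 0.4),
               list("m5", "a3", 1, 2, 0.3))
  es <- mkEpitopes(fam, rows)
  ep <- new("ConsensusEpitope", peptide = substr(fam[["m1"]], 3, 9),
            colStart = 3L, colEnd = 9L, domainLabel = NA_character_,
            supportingSequences = c("m1", "m2", "m3", "m4"),
            supportingAlgorithms = c("a1", "a2"),
            perPositionSupport = rep(3L, 7L))
  rep1 <- conservationReports(list(ep), es, aln, nAlgorithms = 3)[[1]]
  comp <- components(rep1)

  # presence: m1, m2, m3, m4 covered over all columns; m5 nowhere -> 4/5
  expect_equal(unname(comp["presence"]), 4 / 5)
  # position: columns 3..5 and 7..9: members m1..m4 covered & matching -> 4/5;
  # column 6: majority among covered (m1 W, m2 W, m3 F, m4 W) is W -> 3/5
  expect_equal(unname(comp["position"]), mean(c(rep(4 / 5, 3), 3 / 5, rep(4 / 5, 3))))
  # score: a1 mean 0.7 of range [0.5, 0.9] -> 0.5; a2 constant range -> 1
  expect_equal(unname(comp["score"]), mean(c(0.5, 1)))
  # single epitope: its score sits at every quartile boundary -> 0.25
  expect_equal(unname(comp["iqr"]), 0.25)
  # algorithms: 2 of 3 run
  expect_equal(unname(comp["algorithms"]), 2 / 3)
  # agreement: a1 and a2 cover every epitope column, a3 none -> 2/3
  expect_equal(unname(comp["agreement"]), 2 / 3)
  expect_equal(conservationIndex(rep1), mean(comp))
})

test_that("removing a supporting algorithm never raises support components", {
  sc <- perfectScenario()
  nAlg <- length(algorithms(sc$es))
  repsFull <- conservationReports(sc$final, sc$es, sc$aln, nAlgorithms = nAlg)
  dropped <- new("EpitopeSet",
                 predictions = predictions(sc$es)[predictions(sc$es)$algorithm != "a4", ])
  finalDropped <- lapply(sc$final, function(ep) {
    ep@supportingAlgorithms <- setdiff(ep@supportingAlgorithms, "a4")
    ep
  })
  repsDrop <- conservationReports(finalDropped, dropped, sc$aln, nAlgorithms = nAlg)
  for (k in seq_along(repsFull)) {
    expect_lte(components(repsDrop[[k]])["algorithms"],
               components(repsFull[[k]])["algorithms"])
    expect_lte(components(repsDrop[[k]])["agreement"],
               components(repsFull[[k]])["agreement"])
  }
})

test_that("domain labels come from the BED annotation via the reference member", {
  fam <- identicalFamily()
  aln <- mkAln(fam)
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("m1\t0\t6\tVH", "m1\t6\t12\tCH1"), bed)
  doms <- readDomainsBed(bed)
  expect_equal(doms$start, c(1L, 7L))
  expect_equal(doms$end, c(6L, 12L))
  eps <- list(consEpitope(2, 5, "a1", seqs = "m1"),
              consEpitope(8, 12, "a1", seqs = "m1"))
  lab <- assignDomains(eps, aln, "m1", doms)
  expect_equal(domainLabel(lab[[1]]), "VH")
  expect_equal(domainLabel(lab[[2]]), "CH1")
})
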