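test_that("zero substitution rate reproduces the ancestor in every member", {
  cfg <- simConfig(seed = 2, substitutionProb = 0, ancestorLength = 120,
                   nPlantedEpitopes = 2)
  fam <- simulateFamily(cfg)
  seqs <- as.character(fam$sequences)
  expect_true(all(seqs == fam$ancestor))
})

test_that("the same seed reproduces family and predictions bit for bit", {
  cfg <- simConfig(seed = 9, ancestorLength = 150, nPlantedEpitopes = 2)
  f1 <- simulateFamily(cfg); f2 <- simulateFamily(cfg)
  expect_identical(as.character(f1$sequences), as.character(f2$sequences))
  expect_identical(f1$truth, f2$truth)
  p1 <- predictions(simulatePredictions(f1, cfg))
  p2 <- predictions(simulatePredictions(f2, cfg))
  expect_identical(p1, p2)
})

test_that("observed mismatch fraction tracks the substitution probability", {
  p <- 0.1; L <- 10000L
  cfg <- simConfig(seed = 4, nMembers = 1, ancestorLength = L,
                   substitutionProb = p, nPlantedEpitopes = 0)
  fam <- simulateFamily(cfg)
  obs <- mean(strsplit(as.character(fam$sequences[[1]]), "")[[1]] !=
                strsplit(fam$ancestor, "")[[1]])
  se <- sqrt(p * (1 - p) / L)
  expect_lt(abs(obs - p), 3 * se)
})

test_that("planted regions mutate at a tenth of the background rate", {
  cfg <- simConfig(seed = 6, nMembers = 20, ancestorLength = 2000,
                   substitutionProb = 0.2, nPlantedEpitopes = 10,
                   epitopeLengthRange = c(20L, 30L))
  fam <- simulateFamily(cfg)
  anc <- strsplit(fam$ancestor, "")[[1]]
  inEp <- rep(FALSE, length(anc))
  for (k in seq_len(nrow(fam$truth)))
    inEp[fam$truth$start[k]:fam$truth$end[k]] <- TRUE
  mism <- sapply(as.character(fam$sequences), function(s)
    strsplit(s, "")[[1]] != anc)
  rateIn <- mean(mism[inEp, ]); rateOut <- mean(mism[!inEp, ])
  expect_lt(rateIn, rateOut / 5)   # ~10x separation, generous slack
})

test_that("full agreement with no decoys reports exactly the planted epitopes", {
  cfg <- simConfig(seed = 8, algorithmAgreement = 1, decoyRate = 0,
                   ancestorLength = 200, nPlantedEpitopes = 3,
                   scoreNoiseSd = 0)
  fam <- simulateFamily(cfg)
  es <- simulatePredictions(fam, cfg)
  p <- predictions(es)
  # every algorithm x member x planted epitope appears exactly once
  expect_equal(nrow(p), cfg$nAlgorithms * cfg$nMembers * nrow(fam$truth))
  # each reported interval sits within +-1 of a planted interval
  for (k in seq_len(nrow(p))) {
    expect_true(any(abs(p$start[k] - fam$truth$start) <= 1))
  }
})

test_that("zero agreement emits only decoys", {
  cfg <- simConfig(seed = 12, algorithmAgreement = 0, decoyRate = 2,
                   ancestorLength = 300, nPlantedEpitopes = 3,
                   plantedScore = 10)
  fam <- simulateFamily(cfg)
  p <- predictions(simulatePredictions(fam, cfg))
  expect_true(all(p$score < 5))   # no planted-score emissions
})

test_that("recovery by three or more algorithms follows the binomial tail", {
  # 50 planted epitopes, agreement 0.8, 10 algorithms
  cfg <- simConfig(seed = 21, ancestorLength = 5000, nPlantedEpitopes = 50,
                   epitopeLengthRange = c(8L, 12L), algorithmAgreement = 0.8,
                   decoyRate = 0)
  fam <- simulateFamily(cfg)
  p <- predictions(simulatePredictions(fam, cfg))
  perEpitope <- vapply(seq_len(nrow(fam$truth)), function(k) {
    hits <- p$seq_id == "member01" &
      abs(p$start - fam$truth$start[k]) <= 1 & p$score > 0.65
    length(unique(p$algorithm[hits]))
  }, integer(1))
  frac <- mean(perEpitope >= 3)
  expected <- 1 - pbinom(2, 10, 0.8)
  se <- sqrt(expected * (1 - expected) / 50)
  expect_lt(abs(frac - expected), 3 * se + 1e-9)
})

test_that("reference epitope simulation respects bounds and reproducibility", {
  r0 <- simulateReferenceEpitopes(100, 0, seed = 5)
  expect_equal(nrow(r0), 0L)
  r1 <- simulateReferenceEpitopes(100, 40, c(6L, 15L), seed = 5)
  r2 <- simulateReferenceEpitopes(100, 40, c(6L, 15L), seed = 5)
  expect_identical(r1, r2)
  expect_true(all(r1$start >= 1L & r1$end <= 100L & r1$start <= r1$end))
  expect_true(all(r1$end - r1$start + 1L >= 6L))
  expect_true(all(r1$end - r1$start + 1L <= 15L))
  expect_error(simulateReferenceEpitopes(10, 5, c(11L, 12L)), "longer")
})

test_that("interval Jaccard behaves at its extremes", {
  expect_equal(intervalJaccard(1, 10, 1, 10), 1)
  expect_equal(intervalJaccard(1, 5, 6, 10), 0)
  expect_equal(intervalJaccard(1, 6, 4, 9), 3 / 9)
})
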