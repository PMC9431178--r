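meta <- AcquisitionMeta("DMF-d7", 298, 500)
ban <- bananamideSWRI103()

test_that("composite distance has the standard CSP closed form", {
  p <- c(deltaH = 4.2, deltaC = 55)
  expect_equal(compositeDelta(p, p), 0)
  expect_equal(compositeDelta(p, c(deltaH = 4.23, deltaC = 55)), 0.03)
  expect_equal(compositeDelta(p, c(deltaH = 4.2, deltaC = 55.2), wC = 0.25),
               0.05)
  ## symmetric by construction
  q <- c(deltaH = 4.31, deltaC = 54.2)
  expect_equal(compositeDelta(p, q), compositeDelta(q, p))
})

test_that("self-pairing is total and invariant under peak permutation", {
  fp <- simulateFingerprint(ban$sequence, meta = meta)
  pr <- pairPeaks(fp, fp)
  expect_equal(nrow(pr$pairs), nrow(peaks(fp)))
  expect_equal(nrow(pr$unmatchedQuery), 0L)
  set.seed(3)
  shuf <- Fingerprint(peaks(fp)[sample(nrow(peaks(fp))), ], acquisition(fp),
                      region = fp@region)
  pr2 <- pairPeaks(fp, shuf)
  expect_equal(pr2$pairs[order(pr2$pairs$label), ],
               pr$pairs[order(pr$pairs$label), ], ignore_attr = TRUE)
})

test_that("unlabeled assignment attains the exhaustive-permutation minimum", {
  set.seed(41)
  for (i in 1:25) {
    n <- sample(2:7, 1L)
    q <- unlabeledFingerprint(runif(n, 3.8, 4.8), runif(n, 50, 65))
    r <- unlabeledFingerprint(peaks(q)$deltaH + rnorm(n, 0, 0.1),
                              peaks(q)$deltaC + rnorm(n, 0, 0.5))
    pr <- pairPeaks(q, r, wC = 0.25)
    got <- sum(sqrt((pr$pairs$qDeltaH - pr$pairs$rDeltaH)^2 +
                      (0.25 * (pr$pairs$qDeltaC - pr$pairs$rDeltaC))^2))
    cost <- outer(seq_len(n), seq_len(n), function(a, b)
      sqrt((peaks(q)$deltaH[a] - peaks(r)$deltaH[b])^2 +
             (0.25 * (peaks(q)$deltaC[a] - peaks(r)$deltaC[b]))^2))
    expect_equal(got, bruteForceAssignmentCost(cost), tolerance = 1e-9)
  }
})

test_that("unequal unlabeled peak counts leave the excess unmatched", {
  q <- unlabeledFingerprint(c(4.1, 4.3, 4.5), c(55, 57, 59))
  r <- unlabeledFingerprint(c(4.11, 4.29), c(55.1, 57.2))
  pr <- pairPeaks(q, r)
  expect_equal(nrow(pr$pairs), 2L)
  expect_equal(nrow(pr$unmatchedQuery), 1L)
  expect_equal(pr$unmatchedQuery$deltaH, 4.5)
})

test_that("matching a fingerprint against itself is a perfect match", {
  fp <- simulateFingerprint(ban$sequence, meta = meta)
  rep <- scoreMatch(fp, fp)
  expect_equal(rmsd(rep), 0)
  expect_equal(rep@maxDev, 0)
  expect_equal(rep@nOver, 0L)
  expect_equal(rep@coverage, 1)
  expect_equal(verdict(rep), "match")
})

test_that("match scoring is symmetric in its summary statistics", {
  model <- ShiftModel()
  a <- simulateFingerprint(ban$sequence, model, noiseSeed = 1, meta = meta)
  b <- simulateFingerprint(ban$sequence, model, noiseSeed = 2, meta = meta)
  r1 <- scoreMatch(a, b); r2 <- scoreMatch(b, a)
  expect_equal(rmsd(r1), rmsd(r2))
  expect_equal(r1@maxDev, r2@maxDev)
  expect_equal(r1@nOver, r2@nOver)
  expect_equal(verdict(r1), verdict(r2))
})

test_that("a single displaced peak drives maxDev, nOver and the verdict", {
  fp <- simulateFingerprint(ban$sequence, meta = meta)
  pk <- peaks(fp)
  pk$deltaH[4] <- pk$deltaH[4] + 0.10   # composite displacement 0.10 ppm
  moved <- Fingerprint(pk, acquisition(fp), region = fp@region)
  rep <- scoreMatch(fp, moved, matchParams(threshold = 0.025))
  expect_equal(rep@nOver, 1L)
  expect_equal(rep@maxDev, 0.10, tolerance = 1e-9)
  expect_equal(verdict(rep), "mismatch")  # default mismatchMinPeaks = 1
  ## with a higher mismatch requirement the verdict degrades to ambiguous
  rep2 <- scoreMatch(fp, moved, matchParams(mismatchMinPeaks = 3))
  expect_equal(verdict(rep2), "ambiguous")
})

test_that("incompatible acquisition conditions yield 'incomparable', not an error", {
  fp <- simulateFingerprint(ban$sequence, meta = AcquisitionMeta("DMSO-d6", 298))
  fp2 <- simulateFingerprint(ban$sequence, meta = AcquisitionMeta("DMF-d7", 298))
  rep <- scoreMatch(fp, fp2)
  expect_equal(verdict(rep), "incomparable")
  expect_false(rep@conditionsCompatible)
  expect_match(paste(rep@params$conditionNotes, collapse = " "), "solvent")
  ## temperature beyond tolerance triggers the same path
  warm <- simulateFingerprint(ban$sequence, meta = AcquisitionMeta("DMSO-d6", 310))
  expect_equal(verdict(scoreMatch(fp, warm)), "incomparable")
  ## within tolerance is fine
  near <- simulateFingerprint(ban$sequence, meta = AcquisitionMeta("DMSO-d6", 299.5))
  expect_equal(verdict(scoreMatch(fp, near)), "match")
})

test_that("region mismatch is a hard error", {
  fp <- simulateFingerprint(ban$sequence, meta = meta)
  full <- Fingerprint(peaks(fp), meta, region = "full")
  expect_error(pairPeaks(fp, full), "region mismatch")
})

test_that("global offset correction absorbs a referencing discrepancy", {
  fp <- simulateFingerprint(ban$sequence, meta = meta)
  pk <- peaks(fp)
  pk$deltaH <- pk$deltaH + 0.05  # systematic referencing offset
  pk$deltaC <- pk$deltaC + 0.30
  shifted <- Fingerprint(pk, acquisition(fp), region = fp@region)
  plain <- scoreMatch(fp, shifted)
  corrected <- scoreMatch(fp, shifted, matchParams(offsetCorrect = TRUE))
  expect_equal(verdict(plain), "mismatch")
  expect_equal(verdict(corrected), "match")
  expect_equal(unname(corrected@offsets["H"]), -0.05, tolerance = 1e-9)
  expect_equal(unname(corrected@offsets["C"]), -0.30, tolerance = 1e-9)
})
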