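# Rarefaction, alpha/beta diversity, bootstrap summaries, k-mers, PCoA.

test_that("alpha diversity matches hand-computed values (base-2 Shannon)", {
  expect_identical(alphaDiversity(c(1, 1, 1, 1), "shannon"), 2)
  expect_identical(alphaDiversity(c(3, 0, 1), "observed_features"), 2L)
  expect_equal(alphaDiversity(c(2, 1, 1), "shannon"), 1.5)
  expect_identical(alphaDiversity(c(0, 0), "observed_features"), 0L)
  expect_warning(z <- alphaDiversity(c(0, 0), "shannon"), "all-zero")
  expect_identical(z, 0)
})

test_that("rarefaction conserves depth and drops shallow samples", {
  m <- matrix(c(500L, 0L, 200L, 300L, 100L, 50L), nrow = 2,
              dimnames = list(c("f1", "f2"), c("s1", "s2", "s3")))
  tab <- FeatureTable(m)
  # a sample already exactly at depth passes through unchanged
  expect_message(r <- rarefyTable(tab, 500), "dropping")
  expect_identical(counts(r)[, "s1"], c(f1 = 500L, f2 = 0L))
  expect_identical(sampleIDs(r), c("s1", "s2"))
  expect_true(all(sampleTotals(r) == 500))
  # with replacement nothing with >= 1 read is dropped
  rb <- rarefyTable(tab, 500, withReplacement = TRUE, seed = 1)
  expect_identical(sampleIDs(rb), c("s1", "s2", "s3"))
  expect_true(all(sampleTotals(rb) == 500))
  expect_error(rarefyTable(tab, 0), "depth")
  expect_error(rarefyTable(FeatureTable(matrix(1L, 1, 1,
    dimnames = list("f", "s"))), 500), "no samples")
  # conservation on random tables, both modes
  for (seed in 1:3) {
    ft <- randomTable(nFeatures = 12, nSamples = 4, lambda = 50,
                      seed = seed)
    expect_true(all(sampleTotals(
      rarefyTable(ft, 100, withReplacement = TRUE, seed = seed)) == 100))
    expect_true(all(sampleTotals(
      rarefyTable(ft, 100, withReplacement = FALSE, seed = seed)) == 100))
  }
})

test_that("with-replacement rarefaction has the multinomial expectation", {
  tab <- FeatureTable(matrix(c(9000L, 1000L), 2, 1,
                             dimnames = list(c("f1", "f2"), "s1")))
  nRep <- 2000
  f2 <- vapply(seq_len(nRep), function(i) {
    counts(rarefyTable(tab, 500, withReplacement = TRUE, seed = i))[2, 1]
  }, integer(1))
  # E[f2] = 500 * 0.1 = 50, per-draw sd = sqrt(500 * .1 * .9)
  se <- sqrt(500 * 0.1 * 0.9) / sqrt(nRep)
  expect_lt(abs(mean(f2) - 50), 3 * se)
})

test_that("bootstrap alpha reduces to a single rarefaction at nBoot = 1", {
  ft <- randomTable(nFeatures = 10, nSamples = 3, lambda = 80, seed = 4)
  one <- bootstrapAlpha(ft, "shannon", depth = 100, nBoot = 1, seed = 99)
  direct <- rarefyTable(ft, 100, withReplacement = TRUE, seed = 99)
  expected <- apply(counts(direct), 2, alphaDiversity, metric = "shannon")
  expect_equal(as.numeric(one), unname(expected))
})

test_that("bootstrap alpha medians converge to analytic entropy", {
  # one-taxon community: Shannon 0 regardless of bootstrapping
  single <- FeatureTable(matrix(c(400L, 0L), 2, 1,
                                dimnames = list(c("f1", "f2"), "s1")))
  expect_identical(as.numeric(
    bootstrapAlpha(single, "shannon", depth = 100, nBoot = 5, seed = 1)), 0)
  # uniform 4-taxon community at depth 5000: close to log2(4) = 2 bits
  unif <- FeatureTable(matrix(rep(50000L, 4), 4, 1,
                              dimnames = list(paste0("f", 1:4), "s1")))
  med <- bootstrapAlpha(unif, "shannon", depth = 5000, nBoot = 10, seed = 2)
  expect_lt(abs(as.numeric(med) - 2), 0.01)
})

test_that("beta diversity matches the set and count formulas", {
  m <- matrix(c(1L, 1L, 0L, 1L, 3L, 0L), nrow = 3,
              dimnames = list(paste0("f", 1:3), c("u", "v")))
  d <- as.matrix(betaDiversity(FeatureTable(m), "bray_curtis"))
  expect_equal(d["u", "v"], 2 / 6)
  expect_equal(as.matrix(betaDiversity(FeatureTable(m), "jaccard"))["u", "v"],
               0)  # same support
  ident <- FeatureTable(matrix(c(2L, 3L, 2L, 3L), 2, 2,
                               dimnames = list(c("f1", "f2"), c("a", "b"))))
  expect_equal(as.matrix(betaDiversity(ident, "jaccard"))["a", "b"], 0)
  expect_equal(as.matrix(betaDiversity(ident, "bray_curtis"))["a", "b"], 0)
  disjoint <- FeatureTable(matrix(c(2L, 0L, 0L, 3L), 2, 2,
                                  dimnames = list(c("f1", "f2"),
                                                  c("a", "b"))))
  expect_equal(as.matrix(betaDiversity(disjoint, "jaccard"))["a", "b"], 1)
  expect_equal(as.matrix(betaDiversity(disjoint, "bray_curtis"))["a", "b"], 1)
  expect_error(betaDiversity(FeatureTable(matrix(1L, 1, 1,
    dimnames = list("f", "s"))), "jaccard"), "two samples")
})

test_that("beta diversity agrees with vegan and stays in [0, 1]", {
  skip_if_not_installed("vegan")
  for (seed in 1:3) {
    ft <- randomTable(nFeatures = 15, nSamples = 6, lambda = 5, seed = seed)
    x <- t(counts(ft))
    bc <- as.matrix(betaDiversity(ft, "bray_curtis"))
    expect_equal(bc, as.matrix(vegan::vegdist(x, "bray")),
                 tolerance = 1e-12, ignore_attr = TRUE)
    jc <- as.matrix(betaDiversity(ft, "jaccard"))
    expect_equal(jc,
                 as.matrix(vegan::vegdist(x, "jaccard", binary = TRUE)),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_true(all(bc >= 0 & bc <= 1) && all(jc >= 0 & jc <= 1))
    expect_equal(bc, t(bc))
    expect_true(all(diag(bc) == 0))
  }
})

test_that("all-zero sample pairs get distance 0 with a message", {
  m <- matrix(c(0L, 0L, 0L, 0L, 1L, 2L), nrow = 2,
              dimnames = list(c("f1", "f2"), c("z1", "z2", "ok")))
  expect_message(d <- betaDiversity(FeatureTable(m), "bray_curtis"),
                 "all-zero")
  expect_equal(as.matrix(d)["z1", "z2"], 0)
})

test_that("the bootstrap beta summary is the medoid of the bootstrap set", {
  # medoid of {X, X, Y} is one of the identical pair
  x <- as.matrix(randomPointDist(4, seed = 1)$dist)
  y <- as.matrix(randomPointDist(4, seed = 2)$dist)
  expect_identical(medoidIndex(list(x, x, y)), 1L)
  expect_identical(medoidIndex(list(y, x, x)), 2L)  # lowest-index tie-break
  expect_identical(medoidIndex(list(x)), 1L)

  ft <- randomTable(nFeatures = 12, nSamples = 5, lambda = 60, seed = 7)
  bb <- bootstrapBeta(ft, "bray_curtis", depth = 100, nBoot = 5, seed = 3)
  idx <- attr(bb, "medoidIndex")
  expect_true(idx %in% 1:5)
  # medoid is an element of the bootstrap set
  set.seed(3)
  boots2 <- lapply(1:5, function(i)
    betaDiversity(rarefyTable(ft, 100, withReplacement = TRUE),
                  "bray_curtis"))
  expect_equal(as.matrix(bb), as.matrix(boots2[[idx]]), ignore_attr = TRUE)
})

test_that("k-mer decomposition expands counts by sequence multiplicity", {
  tab1 <- FeatureTable(matrix(5L, 1, 1, dimnames = list("a", "s1")))
  seqs <- Biostrings::DNAStringSet(c(a = "ACGTA"))
  k1 <- kmerizeTable(tab1, seqs, k = 3)
  expect_identical(counts(k1)[c("ACG", "CGT", "GTA"), "s1"],
                   c(ACG = 5L, CGT = 5L, GTA = 5L))

  tab2 <- FeatureTable(matrix(c(2L, 3L), 2, 1,
                              dimnames = list(c("a", "b"), "s1")))
  seqs2 <- Biostrings::DNAStringSet(c(a = "ACGT", b = "CGTT"))
  k2 <- kmerizeTable(tab2, seqs2, k = 3)
  expect_identical(counts(k2)[c("ACG", "CGT", "GTT"), "s1"],
                   c(ACG = 2L, CGT = 5L, GTT = 3L))

  # conservation: equal-length N-free sequences, total = (L - k + 1) * reads
  ds <- simulateDataset(simulationConfig(nSites = 1, nRows = 2,
                                         vinesPerRow = 3, nTaxaCore = 8,
                                         nTaxaRare = 0, nContaminants = 0,
                                         depth = 300, seqLength = 60,
                                         seed = 13))
  kt <- kmerizeTable(ds$table, ds$sequences, k = 16)
  expect_equal(unname(sampleTotals(kt)),
               unname((60 - 16 + 1) * sampleTotals(ds$table)))

  # N-containing k-mers are skipped; missing sequences are named
  seqsN <- Biostrings::DNAStringSet(c(a = "ACNTA"))
  expect_warning(kN <- kmerizeTable(tab1, seqsN, k = 3), "contains N")
  expect_identical(nrow(kN), 0L)
  expect_identical(sampleIDs(kN), "s1")
  expect_error(kmerizeTable(tab2, seqs, k = 3), "b")
  expect_error(kmerizeTable(tab1, seqs, k = 10), "exceeds")
})

test_that("PCoA recovers Euclidean configurations exactly", {
  # collinear 1-D points 0, 1, 3
  x <- matrix(c(0, 1, 3), dimnames = list(c("a", "b", "c"), NULL))
  res <- ordinatePCoA(dist(x))
  pos <- res$eigenvalues > 1e-9
  expect_identical(sum(pos), 1L)
  rec <- as.matrix(dist(res$coordinates[, 1]))
  expect_lt(max(abs(rec - as.matrix(dist(x)))), 1e-9)

  # random planar points: first axes reproduce all pairwise distances
  for (d in 2:3) {
    rp <- randomPointDist(8, d = d, seed = d)
    res <- ordinatePCoA(rp$dist)
    rec <- as.matrix(dist(res$coordinates))
    expect_lt(max(abs(rec - as.matrix(rp$dist))), 1e-9)
  }

  zero <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  rz <- ordinatePCoA(zero)
  expect_true(all(abs(rz$coordinates) < 1e-12))
  expect_true(all(abs(rz$eigenvalues) < 1e-12))
  expect_error(ordinatePCoA(dist(matrix(c(0, 1), 2, 1))), "3 samples")
})

test_that("PCoA eigenvalues agree with ape::pcoa", {
  skip_if_not_installed("ape")
  rp <- randomPointDist(7, seed = 42)
  mine <- ordinatePCoA(rp$dist)
  ref <- ape::pcoa(rp$dist)
  k <- length(ref$values$Eigenvalues)
  expect_equal(mine$eigenvalues[seq_len(k)], ref$values$Eigenvalues,
               tolerance = 1e-8)
})
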