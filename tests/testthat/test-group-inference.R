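# PERMANOVA family, ANOVA on alpha diversity, Spearman trends, letters.

twoClusterDist <- function(nPer = 4, sep = 1) {
  n <- 2 * nPer
  m <- matrix(sep, n, n)
  m[seq_len(nPer), seq_len(nPer)] <- 0
  m[nPer + seq_len(nPer), nPer + seq_len(nPer)] <- 0
  diag(m) <- 0
  dimnames(m) <- list(paste0("s", 1:n), paste0("s", 1:n))
  m
}

test_that("perfect separation yields R2 = 1 at the minimum p", {
  d <- twoClusterDist()
  g <- rep(c("A", "B"), each = 4)
  res <- permanova(d, g, permutations = 99, seed = 1)
  expect_equal(res$R2, 1)
  expect_lte(res$pValue, 0.05)
  expect_error(permanova(d, rep("A", 8)), "2 groups")
  expect_error(permanova(d, c("A", rep("B", 7))), "singleton")
})

test_that("PERMANOVA decomposition and statistics match vegan::adonis2", {
  skip_if_not_installed("vegan")
  for (seed in 1:3) {
    rp <- randomPointDist(12, seed = seed)
    g <- rep(c("A", "B", "C"), each = 4)
    mine <- permanova(rp$dist, g, permutations = 49, seed = seed)
    ref <- as.data.frame(vegan::adonis2(rp$dist ~ g,
                                        data = data.frame(g = g),
                                        permutations = 9))
    expect_equal(mine$pseudoF, ref$F[1], tolerance = 1e-9)
    expect_equal(mine$R2, ref$R2[1], tolerance = 1e-9)
  }
})

test_that("exhaustive PERMANOVA p equals the assignment-enumeration oracle", {
  for (seed in c(2, 9)) {
    rp <- randomPointDist(6, seed = seed)
    g <- rep(c("A", "B"), each = 3)
    res <- permanova(rp$dist, g, permutations = "exhaustive")
    expect_equal(res$pValue, oraclePermanovaP(rp$dist, g))
  }
})

test_that("PERMANOVA pseudo-F equals classical ANOVA F on 1-D data", {
  for (seed in 1:5) {
    set.seed(seed)
    y <- rnorm(15)
    g <- factor(rep(c("A", "B", "C"), each = 5))
    pf <- permanova(dist(y), g, permutations = 9, seed = seed)$pseudoF
    af <- summary(aov(y ~ g))[[1]]$`F value`[1]
    expect_equal(pf, af, tolerance = 1e-9)
  }
})

test_that("stratified PERMANOVA detects confounding and stays calibrated", {
  d <- as.matrix(randomPointDist(12, seed = 5)$dist)
  strata <- rep(c("V1", "V2"), each = 6)
  expect_error(permanovaStratified(d, strata, strata), "confounding")
  f <- rep(rep(c("zin", "car"), each = 3), 2)
  res <- permanovaStratified(d, f, strata, permutations = 99, seed = 2)
  expect_true(res$pseudoF >= 0)
  expect_true(res$R2 >= 0 && res$R2 <= 1)
  expect_gte(res$pValue, 1 / 100)
})

test_that("a null cultivar effect is rarely declared significant", {
  # generator with zero cultivar effect: stratified test of cultivar
  # within site should reject at roughly the nominal rate only
  rejections <- 0L
  for (rep in 1:10) {
    ds <- simulateDataset(simulationConfig(
      nSites = 2, nRows = 3, vinesPerRow = 6, nTaxaCore = 30,
      nTaxaRare = 0, nContaminants = 0, depth = 500,
      sigmaCultivar = 0, seed = 400 + rep))
    md <- ds$metadata
    b <- betaDiversity(ds$table, "bray_curtis")
    res <- permanovaStratified(b, setNames(md$cultivar, rownames(md)),
                               setNames(md$vineyard, rownames(md)),
                               permutations = 199, seed = rep)
    if (res$pValue <= 0.05) rejections <- rejections + 1L
  }
  expect_lte(rejections, 2L)
})

test_that("one-way and two-way ANOVA match textbook computations", {
  y <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  g <- factor(rep(c("a", "b", "c"), each = 3))
  res <- anovaAlpha(y, g)
  grand <- mean(y)
  ssb <- 3 * sum((tapply(y, g, mean) - grand)^2)
  ssw <- sum((y - rep(tapply(y, g, mean), each = 3))^2)
  fHand <- (ssb / 2) / (ssw / 6)
  expect_equal(res$F, fHand, tolerance = 1e-12)

  sep <- anovaAlpha(c(1, 1, 1, 5, 5, 5), factor(rep(c("a", "b"), each = 3)))
  expect_lt(sep$p, 1e-10)
  flat <- anovaAlpha(rep(2, 6), factor(rep(c("a", "b"), each = 3)))
  expect_identical(flat$F, 0)

  set.seed(3)
  y2 <- rnorm(12)
  f1 <- factor(rep(c("a", "b"), 6))
  f2 <- factor(rep(c("x", "y", "z"), each = 4))
  two <- anovaAlpha(y2, f1, f2)
  expect_identical(two$term, c("factor1", "factor2"))
  expect_true(all(two$F >= 0))
  f2bad <- factor(c(rep("x", 6), rep("y", 6)))
  f1bad <- factor(c(rep("a", 6), rep("b", 6)))
  expect_error(anovaAlpha(y2, f1bad, f2bad), "empty")
})

test_that("Spearman trend tests match exhaustive enumeration at n = 5", {
  expect_equal(spearmanTrend(1:6, c(2, 4, 5, 7, 8, 11))$rho, 1)
  expect_equal(spearmanTrend(1:6, rev(c(2, 4, 5, 7, 8, 11)))$rho, -1)
  expect_error(spearmanTrend(1:6, rep(1, 6)), "constant")
  expect_error(spearmanTrend(1:3, 1:3), "at least 4")

  set.seed(4)
  y <- sample(c(3.2, 1.5, 9.9, 0.4, 7.7))
  res <- spearmanTrend(1:5, y)
  rhoOf <- function(p) cor(1:5, y[p], method = "spearman")
  rhos <- apply(permEnum(5), 1, rhoOf)
  pOracle <- mean(abs(rhos) >= abs(rhoOf(1:5)) - 1e-12)
  expect_equal(res$pValue, pOracle)
})

test_that("compact letters encode the significance graph", {
  sig <- matrix(TRUE, 3, 3, dimnames = list(c("A", "B", "C"),
                                            c("A", "B", "C")))
  diag(sig) <- FALSE
  expect_identical(unname(compactLetters(sig)), c("a", "b", "c"))

  none <- matrix(FALSE, 3, 3, dimnames = dimnames(sig))
  expect_identical(unname(compactLetters(none)), c("a", "a", "a"))

  ac <- none
  ac["A", "C"] <- ac["C", "A"] <- TRUE
  expect_identical(unname(compactLetters(ac)), c("a", "ab", "b"))

  # property: on random graphs, groups share a letter iff not significant
  set.seed(5)
  for (rep in 1:20) {
    k <- 5
    sigR <- matrix(FALSE, k, k, dimnames = list(letters[1:k], letters[1:k]))
    pairs <- which(upper.tri(sigR), arr.ind = TRUE)
    on <- runif(nrow(pairs)) < 0.4
    for (idx in which(on)) {
      sigR[pairs[idx, 1], pairs[idx, 2]] <- TRUE
      sigR[pairs[idx, 2], pairs[idx, 1]] <- TRUE
    }
    lets <- compactLetters(sigR)
    for (idx in seq_len(nrow(pairs))) {
      i <- pairs[idx, 1]; j <- pairs[idx, 2]
      share <- length(intersect(strsplit(lets[i], "")[[1]],
                                strsplit(lets[j], "")[[1]])) > 0
      expect_identical(share, !sigR[i, j])
    }
  }
})

test_that("pairwise PERMANOVA letters reflect the adjusted p matrix", {
  # three groups: A and B overlap, C is far from both
  set.seed(6)
  x <- rbind(matrix(rnorm(10, 0), 5, 2), matrix(rnorm(10, 0.1), 5, 2),
             matrix(rnorm(10, 50), 5, 2))
  rownames(x) <- paste0("s", 1:15)
  g <- rep(c("A", "B", "C"), each = 5)
  res <- permanovaPairwise(dist(x), g, permutations = 199, seed = 3)
  expect_identical(nrow(res$table), 3L)
  expect_true(all(res$table$q >= res$table$p - 1e-15))
  lets <- res$letters
  shared <- function(a, b) length(intersect(strsplit(lets[a], "")[[1]],
                                            strsplit(lets[b], "")[[1]])) > 0
  for (k in seq_len(nrow(res$table))) {
    expect_identical(shared(res$table$group_a[k], res$table$group_b[k]),
                     res$table$q[k] > res$alpha)
  }
  expect_true(shared("A", "B"))
  expect_false(shared("A", "C"))
})

test_that("permutation tests are seed-reproducible bit-exactly", {
  rp <- randomPointDist(10, seed = 7)
  g <- rep(c("A", "B"), each = 5)
  r1 <- permanova(rp$dist, g, permutations = 99, seed = 11)
  r2 <- permanova(rp$dist, g, permutations = 99, seed = 11)
  expect_identical(r1, r2)
  b <- randomPointDist(10, seed = 8)$dist
  m1 <- mantelTest(rp$dist, b, permutations = 99, seed = 12)
  m2 <- mantelTest(rp$dist, b, permutations = 99, seed = 12)
  expect_identical(m1, m2)
})
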