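# Shared fixtures and independent oracles used across the suite.

# A small deterministic count table.
toyTable <- function() {
  m <- matrix(c(10L, 0L, 3L, 5L, 2L, 0L, 0L, 7L, 1L, 4L, 6L, 2L),
              nrow = 4,
              dimnames = list(paste0("f", 1:4), paste0("s", 1:3)))
  FeatureTable(m)
}

# Random count table with a fixed seed.
randomTable <- function(nFeatures = 8, nSamples = 5, lambda = 20,
                        seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(nFeatures * nSamples, lambda), nFeatures, nSamples,
              dimnames = list(paste0("f", seq_len(nFeatures)),
                              paste0("s", seq_len(nSamples))))
  FeatureTable(m)
}

# Exhaustive permutation enumerator, written differently from the package
# internals (iterative Heap-style growth by insertion) so oracle and
# implementation cannot share a bug.
permEnum <- function(n) {
  perms <- list(1L)
  for (k in 2:n) {
    perms <- unlist(lapply(perms, function(p) {
      lapply(seq_len(k), function(pos) append(p, k, after = pos - 1L))
    }), recursive = FALSE)
  }
  do.call(rbind, perms)
}

# Oracle Mantel p-value: enumerate all orderings, Spearman via cor().
oracleMantelP <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  n <- nrow(a)
  va <- a[upper.tri(a)]
  rhoOf <- function(p) {
    bp <- b[p, p]
    suppressWarnings(cor(va, bp[upper.tri(bp)], method = "spearman"))
  }
  obs <- abs(rhoOf(seq_len(n)))
  rhos <- abs(apply(permEnum(n), 1, rhoOf))
  mean(rhos >= obs - 1e-12)
}

# Oracle PERMANOVA p-value for 2 groups via vegan::adonis2 F statistics
# over every distinct label assignment.
oraclePermanovaP <- function(d, grouping) {
  skip_if_not_installed("vegan")
  m <- as.matrix(d)
  n <- nrow(m)
  g <- factor(grouping)
  k <- sum(g == levels(g)[1])
  fOf <- function(idx) {
    gg <- factor(ifelse(seq_len(n) %in% idx, "A", "B"))
    df <- data.frame(gg = gg)
    as.data.frame(vegan::adonis2(as.dist(m) ~ gg, data = df,
                                 permutations = 1))$F[1]
  }
  obs <- fOf(which(g == levels(g)[1]))
  fs <- apply(combn(n, k), 2, fOf)
  mean(fs >= obs - 1e-12)
}

# Equally spaced metadata on a line of vines, for spatial tests.
lineMetadata <- function(n, spacingM = 10, lat0 = 38.5, lon0 = -122.8) {
  lat <- lat0 + (seq_len(n) - 1) * spacingM / 6371008.8 * 180 / pi
  data.frame(sample_id = paste0("s", seq_len(n)),
             vineyard = "V1", cultivar = "Zinfandel",
             latitude = lat, longitude = lon0,
             row.names = paste0("s", seq_len(n)))
}

# Euclidean dist of random planar points, labelled.
randomPointDist <- function(n, d = 2, seed = 1) {
  set.seed(seed)
  x <- matrix(runif(n * d, 0, 100), n, d)
  rownames(x) <- paste0("s", seq_len(n))
  list(points = x, dist = dist(x))
}
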