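# Bootstrapped rarefaction, alpha/beta diversity, k-mer decomposition, PCoA.
#
# Conventions fixed here and documented throughout: Shannon entropy is in
# bits (log base 2); bootstrap rarefaction resamples WITH replacement at
# fixed depth; bootstrap alpha is summarised by the per-sample median and
# bootstrap beta by the medoid matrix (minimum summed Frobenius distance).

#' Rarefy a feature table to even depth
#'
#' Subsamples every sample to exactly `depth` reads. Without replacement
#' (plain rarefaction) samples with fewer than `depth` reads are dropped
#' (reported via a message); with replacement (the bootstrap mode) any
#' sample with at least one read is resampled from its relative abundances
#' via a multinomial draw and never dropped.
#'
#' @param table a [FeatureTable-class].
#' @param depth target reads per sample (>= 1).
#' @param withReplacement logical; TRUE is the bootstrap mode.
#' @param seed optional integer seed (local to this call).
#' @return a rarefied [FeatureTable-class]; every column sums to `depth`.
#' @export
rarefyTable <- function(table, depth = 500, withReplacement = FALSE,
                        seed = NULL) {
  stopifnot(is(table, "FeatureTable"))
  if (depth < 1) stop("depth must be >= 1")
  m <- counts(table)
  tot <- colSums(m)
  keep <- if (withReplacement) tot >= 1 else tot >= depth
  if (!any(keep)) stop("no samples survive rarefaction at this depth")
  if (any(!keep)) {
    message(sprintf("dropping %d sample(s) below depth %d: %s",
                    sum(!keep), depth,
                    paste(colnames(m)[!keep], collapse = ", ")))
  }
  m <- m[, keep, drop = FALSE]
  out <- .withSeed(seed, {
    vapply(seq_len(ncol(m)), function(j) {
      x <- m[, j]
      if (withReplacement) {
        drop(rmultinom(1L, depth, x))
      } else if (sum(x) == depth) {
        as.integer(x)
      } else {
        pool <- rep.int(seq_along(x), x)
        tabulate(pool[sample.int(length(pool), depth)], nbins = length(x))
      }
    }, integer(nrow(m)))
  })
  out <- matrix(out, nrow = nrow(m),
                dimnames = list(rownames(m), colnames(m)))
  FeatureTable(out, sampleData = as.data.frame(colData(table))[keep, ,
                                                               drop = FALSE],
               taxonomy = as.data.frame(rowData(table)))
}

#' Alpha diversity of one sample
#'
#' `observed_features` is the number of features with positive count;
#' `shannon` is the Shannon entropy in bits, \eqn{-\sum p_i \log_2 p_i}
#' over features with positive proportion. An all-zero vector has richness
#' 0; its Shannon entropy is returned as 0 with a warning.
#'
#' @param x non-negative count vector for one sample.
#' @param metric "observed_features" or "shannon".
#' @return a single number.
#' @examples
#' alphaDiversity(c(1, 1, 1, 1), "shannon")  # log2(4) = 2 bits
#' alphaDiversity(c(2, 1, 1), "shannon")     # 1.5 bits
#' @export
alphaDiversity <- function(x, metric = c("observed_features", "shannon")) {
  metric <- match.arg(metric)
  if (any(x < 0)) stop("negative counts")
  if (metric == "observed_features") return(sum(x > 0))
  tot <- sum(x)
  if (tot == 0) {
    warning("Shannon entropy undefined for an all-zero sample; returning 0")
    return(0)
  }
  p <- x[x > 0] / tot
  -sum(p * log2(p))
}

# Alpha metric for every sample of a count matrix (features x samples).
.alphaAll <- function(m, metric) {
  apply(m, 2L, alphaDiversity, metric = metric)
}

#' Bootstrapped alpha diversity (median over bootstraps)
#'
#' For each of `nBoot` with-replacement rarefactions at `depth`, computes
#' the alpha metric per sample; returns the elementwise median, the robust
#' summary used for bootstrapped diversity estimation.
#'
#' @inheritParams rarefyTable
#' @param metric "observed_features" or "shannon".
#' @param nBoot number of bootstrap rarefactions (default 10).
#' @return named numeric vector (one value per retained sample) with
#'   attributes `metric`, `depth`, `nBoot`.
#' @export
bootstrapAlpha <- function(table, metric = c("observed_features", "shannon"),
                           depth = 500, nBoot = 10, seed = NULL) {
  metric <- match.arg(metric)
  stopifnot(nBoot >= 1)
  kept <- sampleIDs(table)[sampleTotals(table) >= 1]
  vals <- .withSeed(seed, {
    vapply(seq_len(nBoot), function(b) {
      r <- rarefyTable(table, depth, withReplacement = TRUE)
      .alphaAll(counts(r), metric)
    }, numeric(length(kept)))
  })
  vals <- matrix(vals, nrow = length(kept), dimnames = list(kept, NULL))
  out <- apply(vals, 1L, median)
  structure(out, metric = metric, depth = depth, nBoot = nBoot)
}

#' Beta diversity distance matrix
#'
#' Jaccard distance on presence/absence, \eqn{1 - |A \cap B| / |A \cup B|};
#' Bray-Curtis dissimilarity on counts,
#' \eqn{\sum_i |u_i - v_i| / \sum_i (u_i + v_i)}. Pairs of all-zero samples
#' are assigned distance 0 by convention (reported via a message) so that
#' downstream permutation tests never see NaN.
#'
#' @param table a [FeatureTable-class] with at least two samples.
#' @param metric "jaccard" or "bray_curtis".
#' @return a `dist` object labelled by sample id.
#' @export
betaDiversity <- function(table, metric = c("jaccard", "bray_curtis")) {
  metric <- match.arg(metric)
  stopifnot(is(table, "FeatureTable"))
  m <- counts(table)
  if (ncol(m) < 2L) stop("beta diversity needs at least two samples")
  if (metric == "jaccard") {
    inc <- t(m > 0) * 1
    inter <- tcrossprod(inc)
    n1 <- rowSums(inc)
    union <- outer(n1, n1, "+") - inter
    d <- 1 - inter / union
    zero <- union == 0
  } else {
    num <- as.matrix(dist(t(m), method = "manhattan"))
    tot <- colSums(m)
    den <- outer(tot, tot, "+")
    d <- num / den
    zero <- den == 0
  }
  if (any(zero)) {
    message(sprintf(
      "%d all-zero sample pair(s) assigned distance 0 by convention",
      sum(zero[upper.tri(zero)])))
    d[zero] <- 0
  }
  diag(d) <- 0
  dimnames(d) <- list(colnames(m), colnames(m))
  as.dist(d)
}

#' Bootstrapped beta diversity (medoid over bootstraps)
#'
#' Computes the beta-diversity matrix on each of `nBoot` with-replacement
#' rarefactions and returns the medoid: the bootstrap matrix with minimum
#' summed Frobenius distance to the others (ties broken by lowest bootstrap
#' index), so the summary is always an actually observed matrix.
#'
#' @inheritParams bootstrapAlpha
#' @param metric "jaccard" or "bray_curtis".
#' @return a `dist` object with attribute `medoidIndex`.
#' @export
bootstrapBeta <- function(table, metric = c("jaccard", "bray_curtis"),
                          depth = 500, nBoot = 10, seed = NULL) {
  metric <- match.arg(metric)
  stopifnot(nBoot >= 1)
  mats <- .withSeed(seed, {
    lapply(seq_len(nBoot), function(b) {
      betaDiversity(rarefyTable(table, depth, withReplacement = TRUE), metric)
    })
  })
  idx <- medoidIndex(mats)
  structure(mats[[idx]], medoidIndex = idx)
}

#' Medoid of a set of distance matrices
#'
#' @param mats list of `dist` objects (or matrices) over the same samples.
#' @return index of the matrix minimising the sum of Frobenius distances to
#'   all others; ties broken by lowest index.
#' @export
medoidIndex <- function(mats) {
  stopifnot(length(mats) >= 1L)
  vecs <- vapply(mats, function(m) as.numeric(as.matrix(m)),
                 numeric(length(as.matrix(mats[[1L]]))))
  n <- length(mats)
  frob <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i) frob[i, j] <- frob[j, i] <- sqrt(sum((vecs[, i] - vecs[, j])^2))
    }
  }
  which.min(rowSums(frob))
}

#' Decompose a feature table into k-mer space
#'
#' Replaces the ASV feature space by the space of all k-mers observed across
#' the ASV sequences: the count of k-mer m in sample s is the sum over
#' features of `count(s, f) * occurrences(m, seq(f))` (overlapping
#' occurrences counted). K-mers containing N are skipped. This yields the
#' "genetic similarity" feature representation used alongside ASVs.
#'
#' @param table a [FeatureTable-class].
#' @param sequences a named [Biostrings::DNAStringSet] covering every
#'   feature of `table`.
#' @param k k-mer length (default 16); must not exceed the shortest
#'   sequence.
#' @return a [FeatureTable-class] with k-mers as features.
#' @export
kmerizeTable <- function(table, sequences, k = 16) {
  stopifnot(is(table, "FeatureTable"), k >= 1)
  miss <- setdiff(featureIDs(table), names(sequences))
  if (length(miss)) {
    stop(sprintf("no sequence for feature(s): %s",
                 paste(miss, collapse = ", ")))
  }
  seqs <- as.character(sequences[featureIDs(table)])
  if (k > min(nchar(seqs))) {
    stop(sprintf("k = %d exceeds shortest sequence length %d",
                 k, min(nchar(seqs))))
  }
  # per-feature k-mer multiplicity, skipping k-mers containing N
  kmerCounts <- lapply(seqs, function(s) {
    n <- nchar(s)
    km <- substring(s, seq_len(n - k + 1L), k:n)
    km <- km[!grepl("N", km, fixed = TRUE)]
    if (!length(km)) return(integer(0L))
    table(km)
  })
  allKmers <- sort(unique(unlist(lapply(kmerCounts, names))))
  if (!length(allKmers)) {
    warning("no valid k-mers (every k-mer contains N); returning an empty table")
    empty <- matrix(0L, 0L, ncol(table),
                    dimnames = list(character(0L), sampleIDs(table)))
    return(FeatureTable(empty, sampleData = as.data.frame(colData(table))))
  }
  # sparse-by-construction expansion matrix: kmers x features
  expand <- matrix(0, length(allKmers), nrow(table),
                   dimnames = list(allKmers, featureIDs(table)))
  for (i in seq_along(kmerCounts)) {
    tc <- kmerCounts[[i]]
    if (length(tc)) expand[names(tc), i] <- as.numeric(tc)
  }
  FeatureTable(expand %*% counts(table),
               sampleData = as.data.frame(colData(table)))
}

#' Principal coordinates analysis (classical metric MDS)
#'
#' Double-centres \eqn{-D^2/2} and eigendecomposes it. Coordinates use
#' eigenvectors scaled by the square root of positive eigenvalues only;
#' negative eigenvalues (non-Euclidean input) are reported but excluded
#' from the coordinates, and `proportionExplained` uses the sum of positive
#' eigenvalues as denominator.
#'
#' @param d a `dist` or square distance matrix over at least 3 samples.
#' @return list of class "pcoa" with `coordinates` (samples x axes),
#'   `eigenvalues` (all, descending), `proportionExplained` (positive axes).
#' @export
ordinatePCoA <- function(d) {
  m <- .asDistanceMatrix(d)
  n <- nrow(m)
  if (n < 3L) stop("PCoA needs at least 3 samples")
  a <- -0.5 * m^2
  centered <- a - matrix(rowMeans(a), n, n) -
    matrix(colMeans(a), n, n, byrow = TRUE) + mean(a)
  e <- eigen(centered, symmetric = TRUE)
  pos <- e$values > max(e$values, 0) * 1e-12
  coords <- if (any(pos)) {
    e$vectors[, pos, drop = FALSE] %*%
      diag(sqrt(e$values[pos]), nrow = sum(pos))
  } else {
    matrix(0, n, 1L)
  }
  rownames(coords) <- rownames(m)
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  denom <- sum(e$values[pos])
  structure(list(
    coordinates = coords,
    eigenvalues = e$values,
    proportionExplained = if (denom > 0) e$values[pos] / denom
                          else rep(0, ncol(coords))),
    class = "pcoa")
}

#' @export
print.pcoa <- function(x, ...) {
  cat(sprintf("PCoA: %d samples, %d positive axes\n",
              nrow(x$coordinates), ncol(x$coordinates)))
  pe <- head(x$proportionExplained, 3L)
  cat("  proportion explained:",
      paste(sprintf("%.1f%%", 100 * pe), collapse = ", "), "\n")
  invisible(x)
}
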