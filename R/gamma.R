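# Gamma diversity (pooled over samples) and sample-accumulation curves.

#' Pooled (gamma) diversity of a sample set
#'
#' Sums counts across the subset into one pooled community vector and
#' computes the alpha metric on it: gamma richness is the total observed
#' richness of the set, gamma Shannon the entropy of the pooled counts
#' (not the mean of per-sample entropies).
#'
#' @param table a [FeatureTable-class].
#' @param samples character vector of sample ids (default: all).
#' @param metric "observed_features" or "shannon".
#' @return a single number.
#' @export
pooledGamma <- function(table, samples = sampleIDs(table),
                        metric = c("observed_features", "shannon")) {
  metric <- match.arg(metric)
  stopifnot(is(table, "FeatureTable"))
  if (!length(samples)) stop("empty sample subset")
  miss <- setdiff(samples, sampleIDs(table))
  if (length(miss)) {
    stop(sprintf("unknown sample(s): %s", paste(miss, collapse = ", ")))
  }
  pooled <- rowSums(counts(table)[, samples, drop = FALSE])
  alphaDiversity(pooled, metric)
}

#' Gamma-diversity sample-accumulation curves
#'
#' For each site and each sampling density x, draws x samples from the
#' site (with replacement by default) `nIter` times, computes the pooled
#' gamma diversity of each draw, and reports the mean with a t-based 95
#' percent confidence interval across iterations. The table is expected to
#' be pre-rarefied to even depth (a warning is raised if sample totals
#' differ).
#'
#' @param table a [FeatureTable-class], ideally rarefied to even depth.
#' @param siteGrouping site label per sample (named vectors are matched by
#'   sample id).
#' @param densities integer vector of sampling densities; default 1..n
#'   samples per site.
#' @param nIter Monte-Carlo iterations per density (default 10; >= 2 for a
#'   CI).
#' @param metric "observed_features" or "shannon".
#' @param withReplacement draw samples with replacement (default TRUE);
#'   without replacement, densities above the site size are skipped.
#' @param conf confidence level (default 0.95).
#' @param seed optional integer seed.
#' @return data.frame of class "accumulationCurve": site, density, mean,
#'   lower, upper, metric, n_iterations.
#' @export
accumulationCurve <- function(table, siteGrouping, densities = NULL,
                              nIter = 10,
                              metric = c("observed_features", "shannon"),
                              withReplacement = TRUE, conf = 0.95,
                              seed = NULL) {
  metric <- match.arg(metric)
  stopifnot(is(table, "FeatureTable"))
  if (nIter < 2L) stop("nIter must be >= 2 to form a confidence interval")
  g <- .alignGrouping(siteGrouping, sampleIDs(table))
  tot <- sampleTotals(table)
  if (length(unique(tot[tot > 0])) > 1L) {
    warning("sample totals are uneven; rarefy to even depth first")
  }
  m <- counts(table)
  tcrit <- qt(1 - (1 - conf) / 2, df = nIter - 1L)
  out <- .withSeed(seed, {
    res <- list()
    for (site in levels(g)) {
      ids <- sampleIDs(table)[g == site]
      dens <- if (is.null(densities)) seq_along(ids) else
        sort(unique(as.integer(densities)))
      if (!withReplacement) dens <- dens[dens <= length(ids)]
      dens <- dens[dens >= 1L]
      for (x in dens) {
        vals <- vapply(seq_len(nIter), function(i) {
          pick <- sample(ids, x, replace = withReplacement)
          alphaDiversity(rowSums(m[, pick, drop = FALSE]), metric)
        }, numeric(1L))
        mu <- mean(vals)
        half <- tcrit * sd(vals) / sqrt(nIter)
        res[[length(res) + 1L]] <- data.frame(
          site = site, density = x, mean = mu,
          lower = mu - half, upper = mu + half,
          metric = metric, n_iterations = nIter)
      }
    }
    do.call(rbind, res)
  })
  structure(out, class = c("accumulationCurve", "data.frame"))
}
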