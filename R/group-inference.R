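# Permutation and classical tests for group differences in diversity:
# one-way PERMANOVA, pairwise PERMANOVA with compact letter display,
# stratified (two-way) PERMANOVA with restricted permutations, ANOVA on
# alpha diversity, and Spearman trend tests.

# Sum-of-squares decomposition of a squared-distance matrix under a
# grouping: SS_total = sum_{i<j} d2 / n, SS_within = per-group analogue.
.permanovaSS <- function(d2, groups) {
  n <- nrow(d2)
  ssTotal <- sum(d2) / (2 * n)
  ssWithin <- 0
  for (idx in split(seq_len(n), groups)) {
    if (length(idx) > 1L) {
      ssWithin <- ssWithin + sum(d2[idx, idx]) / (2 * length(idx))
    }
  }
  c(total = ssTotal, within = ssWithin, among = ssTotal - ssWithin)
}

.permanovaF <- function(d2, groups, dfA, dfW) {
  ss <- .permanovaSS(d2, groups)
  (ss[["among"]] / dfA) / (ss[["within"]] / dfW)
}

#' One-way PERMANOVA
#'
#' Permutational multivariate analysis of variance on a distance matrix:
#' pseudo-F from the among/within squared-distance decomposition,
#' significance by permutation of the group labels with the
#' (1 + x) / (1 + N) estimator. The effect size reported as `R2` is
#' SS_among / SS_total. Set `permutations = "exhaustive"` (n <= 7) to
#' enumerate all label orderings.
#'
#' @param d `dist` or square distance matrix.
#' @param grouping factor-like group labels, one per sample (named vectors
#'   are reordered to match `d`); at least 2 groups of at least 2 samples.
#' @param permutations integer (default 999) or "exhaustive".
#' @param seed optional integer seed.
#' @return list of class "permanova": `pseudoF`, `R2`, `pValue`,
#'   `nPermutations`, `groupSizes`, `df`.
#' @export
permanova <- function(d, grouping, permutations = 999, seed = NULL) {
  m <- .asDistanceMatrix(d)
  grouping <- .alignGrouping(grouping, rownames(m))
  sizes <- table(grouping)
  if (length(sizes) < 2L) stop("PERMANOVA needs at least 2 groups")
  if (any(sizes < 2L)) {
    stop(sprintf("singleton group(s): %s",
                 paste(names(sizes)[sizes < 2L], collapse = ", ")))
  }
  n <- nrow(m)
  a <- length(sizes)
  dfA <- a - 1L
  dfW <- n - a
  d2 <- m^2
  ss <- .permanovaSS(d2, grouping)
  fObs <- (ss[["among"]] / dfA) / (ss[["within"]] / dfW)
  r2 <- ss[["among"]] / ss[["total"]]
  if (identical(permutations, "exhaustive")) {
    if (n > 7L) stop("exhaustive enumeration limited to n <= 7")
    perms <- .allPermutations(n)
    fs <- apply(perms, 1L, function(p)
      .permanovaF(d2, grouping[p], dfA, dfW))
    p <- mean(fs >= fObs - 1e-12)
    nPerm <- nrow(perms) - 1L
  } else {
    nPerm <- as.integer(permutations)
    stopifnot(nPerm >= 1L)
    fs <- .withSeed(seed, {
      vapply(seq_len(nPerm), function(i)
        .permanovaF(d2, grouping[sample.int(n)], dfA, dfW), numeric(1L))
    })
    p <- (1 + sum(fs >= fObs - 1e-12)) / (1 + nPerm)
  }
  structure(list(pseudoF = unname(fObs), R2 = unname(r2), pValue = p,
                 nPermutations = nPerm,
                 groupSizes = as.integer(sizes),
                 groups = names(sizes), df = c(among = dfA, within = dfW)),
            class = "permanova")
}

.alignGrouping <- function(grouping, ids) {
  if (!is.null(names(grouping))) {
    miss <- setdiff(ids, names(grouping))
    if (length(miss)) {
      stop(sprintf("grouping missing sample(s): %s",
                   paste(miss, collapse = ", ")))
    }
    grouping <- grouping[ids]
  } else if (length(grouping) != length(ids)) {
    stop("grouping length does not match the distance matrix")
  }
  factor(as.character(grouping))
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA: pseudo-F = %.4f, R2 = %.4f, p = %.4g (%d permutations)\n",
    x$pseudoF, x$R2, x$pValue, x$nPermutations))
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s (n=%d)", x$groups, x$groupSizes),
                    collapse = ", ")))
  invisible(x)
}

#' Pairwise PERMANOVA with compact letter display
#'
#' Runs [permanova()] on every pair of groups, adjusts p-values
#' (Benjamini-Hochberg by default) and summarises the significance graph as
#' compact letters by insert-and-absorb: groups sharing no letter differ
#' significantly (adjusted p <= alpha); groups sharing a letter do not.
#'
#' @inheritParams permanova
#' @param alpha significance level for the letter display (default 0.05).
#' @param pAdjust "BH" or "none".
#' @return list of class "permanovaPairwise": `table` (one row per pair
#'   with F, R2, p, q), `letters` (named per group), `alpha`.
#' @export
permanovaPairwise <- function(d, grouping, permutations = 999, alpha = 0.05,
                              pAdjust = c("BH", "none"), seed = NULL) {
  pAdjust <- match.arg(pAdjust)
  m <- .asDistanceMatrix(d)
  grouping <- .alignGrouping(grouping, rownames(m))
  levs <- levels(grouping)
  if (length(levs) < 2L) stop("need at least 2 groups")
  pairs <- combn(levs, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1L, k]; g2 <- pairs[2L, k]
    sel <- grouping %in% c(g1, g2)
    res <- permanova(m[sel, sel, drop = FALSE], droplevels(grouping[sel]),
                     permutations = permutations,
                     seed = if (is.null(seed)) NULL else seed + k)
    data.frame(group_a = g1, group_b = g2, pseudoF = res$pseudoF,
               R2 = res$R2, p = res$pValue)
  })
  tab <- do.call(rbind, rows)
  tab$q <- if (pAdjust == "BH") p.adjust(tab$p, "BH") else tab$p
  sig <- matrix(FALSE, length(levs), length(levs),
                dimnames = list(levs, levs))
  for (k in seq_len(nrow(tab))) {
    s <- tab$q[k] <= alpha
    sig[tab$group_a[k], tab$group_b[k]] <- s
    sig[tab$group_b[k], tab$group_a[k]] <- s
  }
  structure(list(table = tab, letters = compactLetters(sig), alpha = alpha),
            class = "permanovaPairwise")
}

#' @export
print.permanovaPairwise <- function(x, ...) {
  cat(sprintf("Pairwise PERMANOVA (alpha = %g):\n", x$alpha))
  print(x$table, row.names = FALSE)
  cat("  letters:",
      paste(sprintf("%s = %s", names(x$letters), x$letters),
            collapse = ", "), "\n")
  invisible(x)
}

#' Compact letter display from a significance matrix
#'
#' Insert-and-absorb algorithm: start with one letter covering all groups;
#' for each significantly different pair contained in a letter set, split
#' that set into two sets excluding one member each, then absorb sets
#' contained in others. Guarantees that two groups share a letter iff they
#' are not significantly different.
#'
#' @param sig square logical matrix (TRUE = significantly different),
#'   dimnames = group names.
#' @return named character vector of letter strings.
#' @export
compactLetters <- function(sig) {
  stopifnot(is.matrix(sig), nrow(sig) == ncol(sig))
  groups <- rownames(sig)
  sets <- list(groups)
  pairs <- which(upper.tri(sig) & sig, arr.ind = TRUE)
  for (k in seq_len(nrow(pairs))) {
    g1 <- groups[pairs[k, 1L]]; g2 <- groups[pairs[k, 2L]]
    newSets <- list()
    for (s in sets) {
      if (all(c(g1, g2) %in% s)) {
        newSets <- c(newSets, list(setdiff(s, g1)), list(setdiff(s, g2)))
      } else {
        newSets <- c(newSets, list(s))
      }
    }
    # absorb: drop any set contained in another (duplicates keep first)
    keep <- rep(TRUE, length(newSets))
    for (i in seq_along(newSets)) {
      for (j in seq_along(newSets)) {
        if (i == j || !keep[i] || !keep[j]) next
        if (all(newSets[[i]] %in% newSets[[j]]) &&
            (!setequal(newSets[[i]], newSets[[j]]) || i > j)) {
          keep[i] <- FALSE
          break
        }
      }
    }
    sets <- newSets[keep]
  }
  sets <- sets[vapply(sets, length, integer(1L)) > 0L]
  # assign letters in group order so the first group always carries "a"
  sets <- sets[order(vapply(sets, function(s) min(match(s, groups)),
                            numeric(1L)))]
  out <- setNames(rep("", length(groups)), groups)
  for (i in seq_along(sets)) {
    for (g in sets[[i]]) out[g] <- paste0(out[g], letters[i])
  }
  out
}

#' Stratified (two-way) PERMANOVA
#'
#' Tests a factor (e.g. cultivar) after accounting for a stratifying
#' variable (e.g. vineyard site): sums of squares are decomposed within
#' each stratum and pooled, and permutations shuffle factor labels only
#' within strata, so between-stratum structure can never generate
#' significance.
#'
#' @inheritParams permanova
#' @param factor factor-like labels to test.
#' @param strata factor-like stratum labels (permutation blocks).
#' @return list of class "permanova" (with `stratified = TRUE`).
#' @export
permanovaStratified <- function(d, factor, strata, permutations = 999,
                                seed = NULL) {
  m <- .asDistanceMatrix(d)
  f <- .alignGrouping(factor, rownames(m))
  s <- .alignGrouping(strata, rownames(m))
  varies <- vapply(split(f, s), function(x) length(unique(x)) > 1L,
                   logical(1L))
  if (!any(varies)) {
    stop("factor is constant within every stratum: unresolvable confounding")
  }
  d2 <- m^2
  strataIdx <- split(seq_len(nrow(m)), s)
  pooled <- function(fLabels) {
    ssA <- 0; ssW <- 0; dfA <- 0L; cells <- 0L
    for (idx in strataIdx) {
      ss <- .permanovaSS(d2[idx, idx, drop = FALSE], fLabels[idx])
      aS <- length(unique(fLabels[idx]))
      ssA <- ssA + ss[["among"]]
      ssW <- ssW + ss[["within"]]
      dfA <- dfA + (aS - 1L)
      cells <- cells + aS
    }
    list(ssA = ssA, ssW = ssW, dfA = dfA, dfW = nrow(m) - cells)
  }
  obs <- pooled(f)
  if (obs$dfA < 1L || obs$dfW < 1L) stop("insufficient degrees of freedom")
  fObs <- (obs$ssA / obs$dfA) / (obs$ssW / obs$dfW)
  r2 <- obs$ssA / (obs$ssA + obs$ssW)
  nPerm <- as.integer(permutations)
  stopifnot(nPerm >= 1L)
  fs <- .withSeed(seed, {
    vapply(seq_len(nPerm), function(i) {
      fp <- f
      for (idx in strataIdx) fp[idx] <- f[idx][sample.int(length(idx))]
      pb <- pooled(fp)
      (pb$ssA / pb$dfA) / (pb$ssW / pb$dfW)
    }, numeric(1L))
  })
  p <- (1 + sum(fs >= fObs - 1e-12)) / (1 + nPerm)
  sizes <- table(f)
  structure(list(pseudoF = fObs, R2 = r2, pValue = p,
                 nPermutations = nPerm, groupSizes = as.integer(sizes),
                 groups = names(sizes),
                 df = c(among = obs$dfA, within = obs$dfW),
                 stratified = TRUE),
            class = "permanova")
}

#' ANOVA on alpha diversity
#'
#' One-way F-test, or two-way main-effects ANOVA (type II sums of squares,
#' no interaction) when two factors are given. Two-way designs need every
#' factor-level combination observed; empty cells raise an error suggesting
#' a one-way analysis.
#'
#' @param values numeric alpha-diversity values (named vectors are matched
#'   to factor names if present).
#' @param factor1 first grouping.
#' @param factor2 optional second grouping.
#' @return data.frame of class "anovaAlpha" with one row per factor: term,
#'   df, F, p.
#' @export
anovaAlpha <- function(values, factor1, factor2 = NULL) {
  f1 <- factor(as.character(factor1))
  stopifnot(length(f1) == length(values))
  if (nlevels(f1) < 2L) stop("factor1 needs at least 2 groups")
  if (var(values) == 0) {
    # no variation at all: F = 0 by convention (0/0 otherwise)
    terms <- if (is.null(factor2)) "factor1" else c("factor1", "factor2")
    return(structure(data.frame(term = terms, df = NA_integer_, F = 0,
                                p = 1),
                     class = c("anovaAlpha", "data.frame")))
  }
  if (is.null(factor2)) {
    fit <- aov(values ~ f1)
    s <- summary(fit)[[1L]]
    out <- data.frame(term = "factor1", df = s$Df[1L],
                      F = s$`F value`[1L], p = s$`Pr(>F)`[1L])
  } else {
    f2 <- factor(as.character(factor2))
    if (nlevels(f2) < 2L) stop("factor2 needs at least 2 groups")
    cells <- table(f1, f2)
    if (any(cells == 0L)) {
      stop(paste("empty factor combination cell(s); consider one-way",
                 "ANOVA per factor"))
    }
    fit <- lm(values ~ f1 + f2)
    a2 <- car::Anova(fit, type = 2)
    out <- data.frame(term = c("factor1", "factor2"),
                      df = a2$Df[1:2],
                      F = a2$`F value`[1:2], p = a2$`Pr(>F)`[1:2])
  }
  structure(out, class = c("anovaAlpha", "data.frame"))
}

#' Spearman trend test
#'
#' Rank correlation (average ranks for ties) of a response against an
#' ordered covariate such as vineyard row number. Exact two-sided p for
#' n <= 9 without ties, t-approximation otherwise.
#'
#' @param x ordered covariate.
#' @param y response values.
#' @return list of class "spearmanTrend": `rho`, `pValue`, `n`.
#' @export
spearmanTrend <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stop("Spearman trend test needs at least 4 pairs")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop("constant covariate or response: rho undefined")
  }
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  exact <- length(x) <= 9L && !ties
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = exact))
  structure(list(rho = unname(ct$estimate), pValue = ct$p.value,
                 n = length(x)),
            class = "spearmanTrend")
}

#' @export
print.spearmanTrend <- function(x, ...) {
  cat(sprintf("Spearman trend: rho = %.4f, p = %.4g (n = %d)\n",
              x$rho, x$pValue, x$n))
  invisible(x)
}
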