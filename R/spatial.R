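# Geodesic distances, local planar projection, Mantel distance-decay tests,
# pair classification and taxon-vs-coordinate screening.

.EARTH_RADIUS_M <- 6371008.8  # mean Earth radius, metres

#' Haversine great-circle distance
#'
#' @param lat1,lon1,lat2,lon2 decimal degrees (vectorised).
#' @param radius sphere radius in metres (default: mean Earth radius
#'   6 371 008.8 m).
#' @return distance(s) in metres.
#' @export
haversine <- function(lat1, lon1, lat2, lon2, radius = .EARTH_RADIUS_M) {
  toRad <- pi / 180
  dlat <- (lat2 - lat1) * toRad
  dlon <- (lon2 - lon1) * toRad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * toRad) * cos(lat2 * toRad) * sin(dlon / 2)^2
  2 * radius * asin(pmin(1, sqrt(a)))
}

#' Geodesic distance matrix between samples
#'
#' Haversine great-circle distances, in metres, between all sample pairs.
#' Within-vineyard extents are tiny relative to the Earth radius, so the
#' spherical approximation errs well under 0.5 percent.
#'
#' @param metadata data.frame with `latitude` and `longitude` columns and
#'   sample ids as rownames; rows with missing coordinates raise an error
#'   naming the sample.
#' @return a `dist` object in metres.
#' @export
geodesicMatrix <- function(metadata) {
  metadata <- .checkMetadata(metadata, c("latitude", "longitude"))
  lat <- metadata$latitude
  lon <- metadata$longitude
  n <- nrow(metadata)
  m <- matrix(0, n, n, dimnames = list(rownames(metadata), rownames(metadata)))
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    m[i, j] <- m[j, i] <- haversine(lat[i], lon[i], lat[j], lon[j])
  }
  as.dist(m)
}

#' Project coordinates to local planar metres
#'
#' Equirectangular projection about a reference point (default: the
#' centroid): x = R cos(lat0) dlon, y = R dlat, in metres. Adequate for
#' vineyard-scale extents, and the projection used for all kriging.
#'
#' @param metadata data.frame with `latitude`/`longitude`, or a 2-column
#'   matrix (lat, lon).
#' @param origin optional c(lat, lon) reference; default centroid.
#' @return matrix with columns `x`, `y` (metres) and attribute `origin`.
#' @export
projectCoords <- function(metadata, origin = NULL) {
  if (is.matrix(metadata)) {
    lat <- metadata[, 1L]; lon <- metadata[, 2L]
    ids <- rownames(metadata)
  } else {
    metadata <- .checkMetadata(metadata, c("latitude", "longitude"))
    lat <- metadata$latitude; lon <- metadata$longitude
    ids <- rownames(metadata)
  }
  if (is.null(origin)) origin <- c(mean(lat), mean(lon))
  toRad <- pi / 180
  x <- .EARTH_RADIUS_M * cos(origin[1L] * toRad) * (lon - origin[2L]) * toRad
  y <- .EARTH_RADIUS_M * (lat - origin[1L]) * toRad
  structure(cbind(x = x, y = y), dimnames = list(ids, c("x", "y")),
            origin = origin)
}

# Inverse of projectCoords: planar metres about origin -> lat/lon degrees.
.unprojectCoords <- function(xy, origin) {
  toDeg <- 180 / pi
  lat <- origin[1L] + (xy[, 2L] / .EARTH_RADIUS_M) * toDeg
  lon <- origin[2L] +
    (xy[, 1L] / (.EARTH_RADIUS_M * cos(origin[1L] * pi / 180))) * toDeg
  cbind(latitude = lat, longitude = lon)
}

# Core permutation machinery shared by mantelTest: returns observed rho and
# the permutation distribution of rho under row/column relabelling of b.
.mantelStatistics <- function(a, b, permutations, seed) {
  va <- .upperTri(a)
  vb <- .upperTri(b)
  if (length(unique(va)) < 2L || length(unique(vb)) < 2L) {
    stop("constant distance vector: Spearman rho undefined")
  }
  ra <- rank(va)
  rho <- .rhoFromRanks(ra, rank(vb))
  n <- nrow(a)
  permRho <- function(p) {
    .rhoFromRanks(ra, rank(.upperTri(b[p, p])))
  }
  if (identical(permutations, "exhaustive")) {
    if (n > 7L) stop("exhaustive enumeration limited to n <= 7")
    perms <- .allPermutations(n)
    rhos <- apply(perms, 1L, permRho)
    # identity row included: p is the exact proportion of orderings at
    # least as extreme, identical to the (1+x)/(1+N) estimator here.
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    nPerm <- nrow(perms) - 1L
  } else {
    nPerm <- as.integer(permutations)
    stopifnot(nPerm >= 1L)
    rhos <- .withSeed(seed, {
      vapply(seq_len(nPerm), function(i) permRho(sample.int(n)), numeric(1L))
    })
    p <- (1 + sum(abs(rhos) >= abs(rho) - 1e-12)) / (1 + nPerm)
  }
  list(rho = rho, p = p, nPerm = nPerm, nPairs = length(va))
}

#' Mantel test between two distance matrices
#'
#' Spearman correlation of the upper-triangle entries (average ranks for
#' ties), with significance by simultaneous row/column permutation of the
#' second matrix's sample labels. Two-sided on |rho|; the p-value uses the
#' (1 + x) / (1 + N) estimator and so is never zero. Set
#' `permutations = "exhaustive"` (n <= 7) to enumerate all orderings.
#'
#' @param dmA,dmB `dist` objects or square matrices over the same samples
#'   (dmB is reordered to match dmA).
#' @param permutations integer (default 999) or "exhaustive".
#' @param seed optional integer seed.
#' @return list of class "mantel": `rho`, `pValue`, `nPermutations`,
#'   `nPairs`.
#' @export
mantelTest <- function(dmA, dmB, permutations = 999, seed = NULL) {
  pair <- .alignDistancePair(dmA, dmB)
  if (nrow(pair$a) < 4L) stop("Mantel test needs at least 4 samples")
  st <- .mantelStatistics(pair$a, pair$b, permutations, seed)
  structure(list(rho = st$rho, pValue = st$p, nPermutations = st$nPerm,
                 nPairs = st$nPairs),
            class = "mantel")
}

#' @export
print.mantel <- function(x, ...) {
  cat(sprintf("Mantel test: rho = %.4f, p = %.4g (%d permutations, %d pairs)\n",
              x$rho, x$pValue, x$nPermutations, x$nPairs))
  invisible(x)
}

#' Distance-decay analysis
#'
#' Relates community dissimilarity to geodesic distance over sample pairs:
#' a Mantel test (Spearman, permutation inference) plus a descriptive
#' ordinary-least-squares fit of community distance on geodesic distance
#' with a 95 percent CI on the slope. Pairs are not independent, so the
#' regression is descriptive only; inference comes from the Mantel test.
#'
#' @param dmCommunity community `dist` (e.g. Bray-Curtis).
#' @param dmGeo geodesic `dist` in metres over the same samples.
#' @inheritParams mantelTest
#' @return list of class "distanceDecay": `mantel`, `slope`, `intercept`,
#'   `slopeCI` (95%), and `pairs` (data.frame geo/community for plotting).
#' @export
distanceDecay <- function(dmCommunity, dmGeo, permutations = 999,
                          seed = NULL) {
  pair <- .alignDistancePair(dmGeo, dmCommunity)
  # a constant community-distance vector leaves rho undefined but the
  # descriptive regression (slope 0) still meaningful
  mt <- tryCatch(mantelTest(pair$a, pair$b, permutations, seed),
                 error = function(e) {
                   if (grepl("constant distance", conditionMessage(e))) {
                     warning("constant distances: Mantel rho undefined, ",
                             "reporting the OLS fit only")
                     NULL
                   } else stop(e)
                 })
  geo <- .upperTri(pair$a)
  com <- .upperTri(pair$b)
  fit <- lm(com ~ geo)
  ci <- suppressWarnings(confint(fit, "geo", level = 0.95))
  structure(list(mantel = mt,
                 slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 slopeCI = c(lower = ci[1L], upper = ci[2L]),
                 pairs = data.frame(geo = geo, community = com)),
            class = "distanceDecay")
}

#' @export
print.distanceDecay <- function(x, ...) {
  if (is.null(x$mantel)) cat("Mantel: undefined (constant distances)\n")
  else print(x$mantel)
  cat(sprintf("  OLS (descriptive): community = %.4g + %.4g * metres; ",
              x$intercept, x$slope))
  cat(sprintf("slope 95%% CI [%.4g, %.4g]\n", x$slopeCI[1L], x$slopeCI[2L]))
  invisible(x)
}

#' Label sample pairs by spatial relationship
#'
#' Classifies every unordered sample pair as `within_vine` (same non-missing
#' `vine_group`, e.g. clusters of one oversampled vine), `within_vineyard`
#' (same vineyard, different vine) or `between_vineyard`, and attaches the
#' pair distances, giving the distance distributions compared across
#' organisational scales.
#'
#' @param d `dist` over the samples.
#' @param metadata data.frame with `vineyard` and optional `vine_group`,
#'   rownames = sample ids.
#' @return data.frame with columns `sample_a`, `sample_b`, `class`,
#'   `distance`.
#' @export
pairClassDistances <- function(d, metadata) {
  m <- .asDistanceMatrix(d)
  metadata <- .checkMetadata(metadata, "vineyard")
  ids <- rownames(m)
  miss <- setdiff(ids, rownames(metadata))
  if (length(miss)) {
    stop(sprintf("metadata missing sample(s): %s", paste(miss, collapse = ", ")))
  }
  md <- metadata[ids, , drop = FALSE]
  vg <- if ("vine_group" %in% colnames(md)) as.character(md$vine_group)
        else rep(NA_character_, nrow(md))
  pairs <- which(upper.tri(m), arr.ind = TRUE)
  i <- pairs[, 1L]; j <- pairs[, 2L]
  sameGroup <- !is.na(vg[i]) & !is.na(vg[j]) & vg[i] == vg[j]
  sameVineyard <- as.character(md$vineyard)[i] == as.character(md$vineyard)[j]
  cls <- ifelse(sameGroup, "within_vine",
                ifelse(sameVineyard, "within_vineyard", "between_vineyard"))
  data.frame(sample_a = ids[i], sample_b = ids[j],
             class = factor(cls, levels = c("within_vine", "within_vineyard",
                                            "between_vineyard")),
             distance = m[pairs])
}

#' Screen taxa for latitude/longitude abundance trends
#'
#' Converts the table to relative abundances, keeps taxa present in at
#' least `minPrevalence` of samples, and computes Spearman rho and p-values
#' of each taxon's relative abundance against latitude and against
#' longitude. Benjamini-Hochberg adjustment (default) is applied across all
#' tests in the screen; `correction = "none"` reports raw p-values as
#' q-values.
#'
#' @param table a [FeatureTable-class].
#' @param metadata data.frame with coordinates, rownames = sample ids.
#' @param minPrevalence minimum fraction of samples with a positive count
#'   (default 0.1).
#' @param correction "bh" or "none".
#' @return data.frame of class "taxonScreen" with one row per taxon:
#'   rho/p/q for latitude and longitude.
#' @export
taxonCoordinateScreen <- function(table, metadata, minPrevalence = 0.1,
                                  correction = c("bh", "none")) {
  correction <- match.arg(correction)
  stopifnot(is(table, "FeatureTable"))
  metadata <- .checkMetadata(metadata, c("latitude", "longitude"))
  ids <- intersect(sampleIDs(table), rownames(metadata))
  if (length(ids) < 4L) stop("need at least 4 samples with coordinates")
  m <- counts(table)[, ids, drop = FALSE]
  tot <- colSums(m)
  tot[tot == 0] <- 1
  rel <- sweep(m, 2L, tot, "/")
  prev <- rowMeans(m > 0)
  keep <- prev >= minPrevalence
  if (!any(keep)) {
    warning("no taxon passes the prevalence filter")
    return(structure(data.frame(), class = c("taxonScreen", "data.frame")))
  }
  rel <- rel[keep, , drop = FALSE]
  lat <- metadata[ids, "latitude"]
  lon <- metadata[ids, "longitude"]
  one <- function(y, x) {
    if (length(unique(y)) < 2L || length(unique(x)) < 2L) {
      return(c(rho = NA_real_, p = NA_real_))
    }
    ct <- suppressWarnings(cor.test(y, x, method = "spearman",
                                    exact = FALSE))
    c(rho = unname(ct$estimate), p = ct$p.value)
  }
  resLat <- t(apply(rel, 1L, one, x = lat))
  resLon <- t(apply(rel, 1L, one, x = lon))
  ps <- c(resLat[, "p"], resLon[, "p"])
  qs <- if (correction == "bh") p.adjust(ps, "BH") else ps
  k <- nrow(rel)
  out <- data.frame(
    feature_id = rownames(rel),
    prevalence = prev[keep],
    rho_latitude = resLat[, "rho"], p_latitude = resLat[, "p"],
    q_latitude = qs[seq_len(k)],
    rho_longitude = resLon[, "rho"], p_longitude = resLon[, "p"],
    q_longitude = qs[k + seq_len(k)],
    row.names = NULL)
  structure(out, class = c("taxonScreen", "data.frame"))
}
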