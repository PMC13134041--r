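# Synthetic vineyard community generator: georeferenced vine grids with
# spatially autocorrelated, site- and cultivar-structured multinomial count
# data, localized rare taxa, an edge-gradient taxon, and contaminant
# features for filter testing. Defaults emulate a densely sampled
# California vineyard block (rows of vines a few metres apart, two nearby
# sites, 500-5000 reads per sample).

#' Simulation configuration for the synthetic vineyard generator
#'
#' Returns a validated configuration list with defaults chosen to mirror a
#' densely gridded vineyard survey: 5 rows x 12 vines per site at 3 m row
#' and 2 m vine spacing, two sites 3 km apart, 60 core taxa plus 15
#' localized rare taxa, multinomial depth 5000, log-scale effect sizes
#' sigma_site = 1, sigma_cultivar = 0.5, sigma_spatial = 1 with a 30 m
#' correlation length, residual noise 0.3, and a powdery-mildew-like
#' gradient taxon increasing along longitude.
#'
#' @param nRows rows of vines per site.
#' @param vinesPerRow vines per row.
#' @param rowSpacing,vineSpacing metres between rows / between vines.
#' @param origin c(lat, lon) of the first site's grid origin, degrees.
#' @param orientation degrees clockwise from north of the within-row
#'   direction (0 = rows run north-south).
#' @param nSites number of vineyard sites.
#' @param siteOffset metres (eastward) between successive sites.
#' @param nTaxaCore,nTaxaRare core and rare taxon pool sizes.
#' @param depth multinomial reads per sample.
#' @param sigmaSite,sigmaCultivar,sigmaSpatial,sigmaNoise,sigmaTaxon
#'   log-scale effect standard deviations (site, cultivar, spatial GRF
#'   loading scale, residual, between-taxon baseline unevenness).
#' @param lengthScale metres; exponential correlation length of the GRFs.
#' @param cultivarLayout "interplanted" or "monoclonal".
#' @param cultivarProportions named proportions for interplanted layouts
#'   (sums to 1).
#' @param rareRadius metres; a rare taxon occurs only within this radius of
#'   its focal vine.
#' @param rareLevel log-propensity of a rare taxon inside its radius.
#' @param gradientAxis "lon" or "lat"; axis of the edge-gradient taxon.
#' @param gradientSlope log-propensity change per metre along the axis.
#' @param nContaminants contaminant features (chloroplast / mitochondria /
#'   class-unassigned lineages) included for filter testing.
#' @param seqLength nucleotides per synthetic ASV sequence.
#' @param seed integer seed making the whole dataset reproducible.
#' @return list of class "SimulationConfig".
#' @export
simulationConfig <- function(nRows = 5, vinesPerRow = 12,
                             rowSpacing = 3, vineSpacing = 2,
                             origin = c(38.53, -121.75),
                             orientation = 0,
                             nSites = 2, siteOffset = 3000,
                             nTaxaCore = 60, nTaxaRare = 15,
                             depth = 5000,
                             sigmaSite = 1, sigmaCultivar = 0.5,
                             sigmaSpatial = 1, lengthScale = 30,
                             sigmaNoise = 0.3, sigmaTaxon = 1,
                             cultivarLayout = c("interplanted",
                                                "monoclonal"),
                             cultivarProportions = c(Zinfandel = 0.6,
                                                     Carignan = 0.4),
                             rareRadius = 5, rareLevel = -1,
                             gradientAxis = c("lon", "lat"),
                             gradientSlope = 0.15,
                             nContaminants = 3,
                             seqLength = 150,
                             seed = 42) {
  cfg <- list(nRows = nRows, vinesPerRow = vinesPerRow,
              rowSpacing = rowSpacing, vineSpacing = vineSpacing,
              origin = origin, orientation = orientation,
              nSites = nSites, siteOffset = siteOffset,
              nTaxaCore = nTaxaCore, nTaxaRare = nTaxaRare, depth = depth,
              sigmaSite = sigmaSite, sigmaCultivar = sigmaCultivar,
              sigmaSpatial = sigmaSpatial, lengthScale = lengthScale,
              sigmaNoise = sigmaNoise, sigmaTaxon = sigmaTaxon,
              cultivarLayout = match.arg(cultivarLayout),
              cultivarProportions = cultivarProportions,
              rareRadius = rareRadius, rareLevel = rareLevel,
              gradientAxis = match.arg(gradientAxis),
              gradientSlope = gradientSlope,
              nContaminants = nContaminants,
              seqLength = seqLength, seed = seed)
  with(cfg, {
    stopifnot(nRows >= 1, vinesPerRow >= 1, rowSpacing > 0, vineSpacing > 0,
              nSites >= 1, nTaxaCore >= 1, nTaxaRare >= 0, depth >= 1,
              sigmaSite >= 0, sigmaCultivar >= 0, sigmaSpatial >= 0,
              sigmaNoise >= 0, sigmaTaxon >= 0, lengthScale > 0,
              rareRadius > 0, seqLength >= 20, nContaminants >= 0)
    stopifnot(abs(sum(cultivarProportions) - 1) < 1e-9)
  })
  structure(cfg, class = "SimulationConfig")
}

#' Lay out vines and assign cultivars
#'
#' Places a regular grid of vines per site (rotated by `orientation`,
#' sites offset eastward), converts planar metre positions to WGS84
#' lat/lon by the inverse equirectangular projection about `origin`, and
#' assigns cultivars (monoclonal, or randomly interplanted at the
#' configured proportions using the config seed).
#'
#' @param config a [simulationConfig()] object.
#' @return data.frame of per-vine metadata: sample_id, vineyard, cultivar,
#'   latitude, longitude, row, vine; planar metres as attribute `xy`.
#' @export
makeLayout <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  c0 <- config
  nVines <- c0$nRows * c0$vinesPerRow
  if (nVines < 1L) stop("layout has zero vines")
  theta <- c0$orientation * pi / 180
  vineDir <- c(sin(theta), cos(theta))   # within-row direction (east, north)
  rowDir <- c(cos(theta), -sin(theta))   # across-row direction
  rows <- list()
  for (s in seq_len(c0$nSites)) {
    for (i in seq_len(c0$nRows)) {
      for (j in seq_len(c0$vinesPerRow)) {
        pos <- (i - 1) * c0$rowSpacing * rowDir +
          (j - 1) * c0$vineSpacing * vineDir +
          c((s - 1) * c0$siteOffset, 0)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("site%d_r%02d_v%02d", s, i, j),
          vineyard = sprintf("V%d", s), row = i, vine = j,
          x = pos[1L], y = pos[2L])
      }
    }
  }
  md <- do.call(rbind, rows)
  ll <- .unprojectCoords(as.matrix(md[, c("x", "y")]), c0$origin)
  md$latitude <- ll[, "latitude"]
  md$longitude <- ll[, "longitude"]
  md$cultivar <- if (c0$cultivarLayout == "monoclonal") {
    "Chardonnay"
  } else {
    .withSeed(c0$seed, {
      sample(names(c0$cultivarProportions), nrow(md), replace = TRUE,
             prob = c0$cultivarProportions)
    })
  }
  md$vine_group <- NA_character_
  rownames(md) <- md$sample_id
  xy <- as.matrix(md[, c("x", "y")])
  md$x <- NULL; md$y <- NULL
  md <- md[, c("sample_id", "vineyard", "cultivar", "latitude", "longitude",
               "row", "vine", "vine_group")]
  attr(md, "xy") <- xy
  md
}

#' Draw a Gaussian random field at given coordinates
#'
#' Zero-mean draw from an exponential-covariance process,
#' C(d) = variance * exp(-d / lengthScale), via Cholesky factorisation of
#' the covariance matrix (jitter 1e-10 on the diagonal).
#'
#' @param coords n x 2 planar coordinates (metres).
#' @param lengthScale correlation length, metres (> 0).
#' @param variance marginal variance (>= 0; 0 returns zeros).
#' @param seed optional integer seed.
#' @param nDraws number of independent fields (default 1).
#' @return numeric vector (nDraws = 1) or n x nDraws matrix.
#' @export
sampleGRF <- function(coords, lengthScale, variance, seed = NULL,
                      nDraws = 1) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(n >= 1L, lengthScale > 0, variance >= 0, nDraws >= 1)
  if (variance == 0) {
    z <- matrix(0, n, nDraws)
    return(if (nDraws == 1) drop(z) else z)
  }
  d <- as.matrix(dist(coords))
  covm <- variance * exp(-d / lengthScale)
  diag(covm) <- diag(covm) + 1e-10
  ch <- tryCatch(chol(covm), error = function(e)
    stop("covariance not positive definite after jitter"))
  z <- .withSeed(seed, matrix(rnorm(n * nDraws), n, nDraws))
  out <- crossprod(ch, z)
  if (nDraws == 1) drop(out) else out
}

.randomSequences <- function(n, len, prefix = "asv") {
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1L))
  setNames(seqs, sprintf("%s%03d", prefix, seq_len(n)))
}

.syntheticLineage <- function(i, genus = NULL) {
  g <- if (is.null(genus)) sprintf("Genus%03d", i) else genus
  sprintf(paste0("d__Bacteria; p__Phylum%02d; c__Class%02d; o__Order%02d; ",
                 "f__Family%03d; g__%s; s__%s_sp%03d"),
          (i - 1L) %% 12L + 1L, (i - 1L) %% 20L + 1L, (i - 1L) %% 25L + 1L,
          i, g, g, i)
}

#' Simulate a complete synthetic vineyard dataset
#'
#' Generates a georeferenced multi-site vineyard community with the
#' structure the spatial analyses assume. For each core taxon t and vine v
#' the log-propensity is
#' \deqn{\eta(t, v) = b_t + site(t, s(v)) + cultivar(t, c(v)) +
#'   w_t G_t(v) + \epsilon(t, v)}
#' with taxon baselines b_t ~ N(0, sigmaTaxon^2), site and cultivar effects
#' N(0, sigmaSite^2) / N(0, sigmaCultivar^2), independent exponential-
#' covariance Gaussian random fields G_t with log-normal loadings w_t
#' scaled by sigmaSpatial, and residual noise N(0, sigmaNoise^2). Rare taxa
#' are present (at `rareLevel`) only within `rareRadius` of a random focal
#' vine; one gradient taxon has propensity linear in latitude or longitude
#' (metres); contaminant features carry organelle/unassigned lineages for
#' filter testing. Relative abundances are the softmax over taxa within
#' each vine and counts a multinomial draw at `depth`, so sample totals
#' equal `depth` exactly.
#'
#' @param config a [simulationConfig()].
#' @return list: `table` ([FeatureTable-class] with metadata and taxonomy
#'   attached), `sequences` (DNAStringSet), `taxonomy`, `metadata`
#'   (data.frames), and `truth` (all generated effects, for recovery
#'   tests).
#' @export
simulateDataset <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  c0 <- config
  md <- makeLayout(c0)
  xy <- attr(md, "xy")
  n <- nrow(md)
  .withSeed(c0$seed + 1L, {
    site <- factor(md$vineyard)
    cult <- factor(md$cultivar)
    nCore <- c0$nTaxaCore
    baseline <- rnorm(nCore, 0, c0$sigmaTaxon)
    siteEff <- matrix(rnorm(nCore * nlevels(site), 0, c0$sigmaSite),
                      nCore, nlevels(site),
                      dimnames = list(NULL, levels(site)))
    cultEff <- matrix(rnorm(nCore * nlevels(cult), 0, c0$sigmaCultivar),
                      nCore, nlevels(cult),
                      dimnames = list(NULL, levels(cult)))
    w <- c0$sigmaSpatial * rlnorm(nCore, meanlog = -0.125, sdlog = 0.5)
    grf <- if (c0$sigmaSpatial > 0) {
      sampleGRF(xy, c0$lengthScale, 1, nDraws = nCore)
    } else {
      matrix(0, n, nCore)
    }
    eps <- matrix(rnorm(n * nCore, 0, c0$sigmaNoise), n, nCore)
    # vines x taxa log-propensities
    eta <- matrix(baseline, n, nCore, byrow = TRUE) +
      t(siteEff[, as.integer(site), drop = FALSE]) +
      t(cultEff[, as.integer(cult), drop = FALSE]) +
      sweep(grf, 2L, w, "*") + eps

    # rare taxa: present only within rareRadius of a focal vine
    nRare <- c0$nTaxaRare
    focal <- if (nRare > 0) sample.int(n, nRare, replace = TRUE) else integer(0)
    if (nRare > 0) {
      dmat <- as.matrix(dist(xy))
      etaRare <- matrix(-Inf, n, nRare)
      for (r in seq_len(nRare)) {
        near <- dmat[, focal[r]] <= c0$rareRadius
        etaRare[near, r] <- c0$rareLevel
      }
      eta <- cbind(eta, etaRare)
    }

    # gradient taxon: linear in the chosen axis within each site (an
    # edge gradient per vineyard, not a global trend across sites)
    axisVal <- if (c0$gradientAxis == "lon") xy[, "x"] else xy[, "y"]
    etaGrad <- numeric(n)
    for (sv in levels(site)) {
      idx <- site == sv
      etaGrad[idx] <- c0$gradientSlope * (axisVal[idx] - min(axisVal[idx]))
    }
    eta <- cbind(eta, etaGrad)

    # contaminants: moderate constant propensity, organelle lineages
    nCon <- c0$nContaminants
    if (nCon > 0) eta <- cbind(eta, matrix(-1, n, nCon))

    nTaxa <- ncol(eta)
    ids <- sprintf("asv%03d", seq_len(nTaxa))
    probs <- exp(eta - apply(eta, 1L, max))
    probs <- probs / rowSums(probs)
    countsM <- matrix(0L, nTaxa, n, dimnames = list(ids, md$sample_id))
    for (v in seq_len(n)) {
      countsM[, v] <- drop(rmultinom(1L, c0$depth, probs[v, ]))
    }

    seqs <- .randomSequences(nTaxa, c0$seqLength)
    names(seqs) <- ids
    conLineages <- c(
      "d__Bacteria; p__Cyanobacteria; c__Cyanobacteriia; o__Chloroplast; f__Chloroplast; g__Chloroplast; s__Chloroplast",
      "d__Bacteria; p__Proteobacteria; c__Alphaproteobacteria; o__Rickettsiales; f__Mitochondria; g__Mitochondria; s__Mitochondria",
      "d__Bacteria; p__Unclassified")
    lineage <- character(nTaxa)
    lineage[seq_len(nCore)] <- vapply(seq_len(nCore), .syntheticLineage,
                                      character(1L))
    if (nRare > 0) {
      lineage[nCore + seq_len(nRare)] <-
        vapply(nCore + seq_len(nRare), .syntheticLineage, character(1L))
    }
    gradIdx <- nCore + nRare + 1L
    lineage[gradIdx] <- .syntheticLineage(gradIdx, genus = "Erysiphe")
    if (nCon > 0) {
      lineage[gradIdx + seq_len(nCon)] <-
        rep_len(conLineages, nCon)
    }
    taxonomy <- data.frame(feature_id = ids, lineage = lineage,
                           confidence = 1, row.names = ids)
    metadata <- md
    attr(metadata, "xy") <- xy
    table <- FeatureTable(countsM, sampleData = metadata,
                          taxonomy = taxonomy)
    truth <- list(baseline = baseline, siteEffects = siteEff,
                  cultivarEffects = cultEff, spatialLoadings = w,
                  grf = grf, rareFocal = focal,
                  gradientFeature = ids[gradIdx],
                  gradientAxis = c0$gradientAxis,
                  gradientEta = etaGrad, eta = eta, probs = probs,
                  xy = xy)
    list(table = table, sequences = DNAStringSet(seqs),
         taxonomy = taxonomy, metadata = metadata, truth = truth)
  })
}

#' Write a simulated dataset to disk
#'
#' Emits the TSV/FASTA dialects consumed by [readFeatureTable()],
#' [readTaxonomy()], [readSampleMetadata()] and [readSequences()]:
#' `table.tsv`, `taxonomy.tsv`, `metadata.tsv`, `sequences.fasta`.
#'
#' @param dataset result of [simulateDataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeDataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeFeatureTable(dataset$table, file.path(dir, "table.tsv"))
  write.table(dataset$taxonomy, file.path(dir, "taxonomy.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  md <- dataset$metadata
  attr(md, "xy") <- NULL
  write.table(md, file.path(dir, "metadata.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeXStringSet(dataset$sequences, file.path(dir, "sequences.fasta"))
  invisible(dir)
}
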