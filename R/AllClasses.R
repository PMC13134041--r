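#' FeatureTable: a validated amplicon count matrix
#'
#' An S4 container for sample-by-feature marker-gene count data, extending
#' [SummarizedExperiment::SummarizedExperiment]. Following Bioconductor
#' convention, features (ASVs or k-mers) are rows and samples are columns;
#' the single assay is named `"counts"` and holds non-negative integers.
#' Per-sample metadata (vineyard, cultivar, latitude, longitude, row, vine,
#' vine_group) lives in `colData`, per-feature taxonomy in `rowData`.
#'
#' @slot .. inherited from SummarizedExperiment.
#' @export
setClass("FeatureTable", contains = "SummarizedExperiment")

.validFeatureTable <- function(object) {
  msg <- character()
  if (!"counts" %in% names(assays(object))) {
    msg <- c(msg, "assay 'counts' is required")
  } else {
    m <- assay(object, "counts")
    if ((nrow(m) > 0L && is.null(rownames(m))) ||
        (ncol(m) > 0L && is.null(colnames(m)))) {
      msg <- c(msg, "counts must have feature (row) and sample (column) names")
    } else {
      if (anyDuplicated(rownames(m))) msg <- c(msg, "duplicate feature ids")
      if (anyDuplicated(colnames(m))) msg <- c(msg, "duplicate sample ids")
    }
    if (any(!is.finite(m))) msg <- c(msg, "counts contain non-finite values")
    else {
      if (any(m < 0)) msg <- c(msg, "counts contain negative values")
      if (any(m != round(m))) msg <- c(msg, "counts contain non-integer values")
    }
  }
  if (length(msg)) msg else TRUE
}

setValidity("FeatureTable", .validFeatureTable)

#' Construct a FeatureTable
#'
#' @param counts numeric matrix of non-negative integer counts, features as
#'   rows and samples as columns, both dimensions named. Use `transpose = TRUE`
#'   when your matrix has samples as rows (the orientation some exports use).
#' @param sampleData optional data.frame of per-sample metadata, rownames =
#'   sample ids (or a `sample_id` column).
#' @param taxonomy optional data.frame of per-feature annotations, rownames =
#'   feature ids (or a `feature_id` column).
#' @param transpose logical; set TRUE if `counts` is samples x features.
#' @return a validated [FeatureTable-class] object.
#' @examples
#' m <- matrix(c(3L, 1L, 0L, 2L), 2, 2,
#'             dimnames = list(c("asv1", "asv2"), c("s1", "s2")))
#' ft <- FeatureTable(m)
#' counts(ft)
#' @export
FeatureTable <- function(counts, sampleData = NULL, taxonomy = NULL,
                         transpose = FALSE) {
  counts <- as.matrix(counts)
  if (transpose) counts <- t(counts)
  storage.mode(counts) <- "double"
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be finite non-negative integers")
  }
  storage.mode(counts) <- "integer"
  cd <- if (is.null(sampleData)) {
    DataFrame(row.names = colnames(counts))
  } else {
    sampleData <- as.data.frame(sampleData)
    if ("sample_id" %in% colnames(sampleData)) {
      rownames(sampleData) <- sampleData$sample_id
    }
    extra <- setdiff(colnames(counts), rownames(sampleData))
    if (length(extra)) {
      stop(sprintf("sampleData is missing sample(s): %s",
                   paste(extra, collapse = ", ")))
    }
    DataFrame(sampleData[colnames(counts), , drop = FALSE])
  }
  rd <- if (is.null(taxonomy)) {
    DataFrame(row.names = rownames(counts))
  } else {
    taxonomy <- as.data.frame(taxonomy)
    if ("feature_id" %in% colnames(taxonomy)) {
      rownames(taxonomy) <- taxonomy$feature_id
    }
    extra <- setdiff(rownames(counts), rownames(taxonomy))
    if (length(extra)) {
      stop(sprintf("taxonomy is missing feature(s): %s",
                   paste(extra, collapse = ", ")))
    }
    DataFrame(taxonomy[rownames(counts), , drop = FALSE])
  }
  se <- SummarizedExperiment(assays = list(counts = counts),
                             colData = cd, rowData = rd)
  new("FeatureTable", se)
}

#' @describeIn FeatureTable sample identifiers (column names).
#' @param x a FeatureTable.
#' @export
sampleIDs <- function(x) colnames(x)

#' @describeIn FeatureTable feature identifiers (row names).
#' @export
featureIDs <- function(x) rownames(x)

#' @rdname FeatureTable
#' @param object a FeatureTable.
#' @aliases counts,FeatureTable-method
#' @export
setMethod("counts", "FeatureTable", function(object) {
  assay(object, "counts")
})

#' Per-sample total read counts
#' @param x a FeatureTable.
#' @return named integer vector of column sums.
#' @export
sampleTotals <- function(x) colSums(counts(x))

setMethod("show", "FeatureTable", function(object) {
  cat(sprintf("FeatureTable: %d features x %d samples, %s total reads\n",
              nrow(object), ncol(object),
              format(sum(as.numeric(counts(object))), big.mark = ",")))
  callNextMethod()
})

#' KrigingModel: fitted Gaussian-process spatial interpolator
#'
#' Holds a Matern-kernel Gaussian process fitted by maximising the log
#' marginal likelihood over (length scale, amplitude, noise variance) with
#' multi-start optimisation. Values are standardised internally; the stored
#' mean/sd de-standardise predictions. See [fitKrige()] and
#' [predictKrige()].
#'
#' @slot lengthScale kernel length scale, metres.
#' @slot amplitude kernel standard deviation (standardised-value scale).
#' @slot noiseVar white-noise variance (standardised-value scale).
#' @slot nu Matern smoothness (0.5, 1.5 or 2.5).
#' @slot coords training coordinates (n x 2, planar metres).
#' @slot y standardised training values.
#' @slot yMean,ySd de-standardisation constants.
#' @slot alpha cached K^-1 y.
#' @slot L cached upper Cholesky factor of K.
#' @slot logLik best log marginal likelihood.
#' @slot trace data.frame with one row per optimiser start.
#' @export
setClass("KrigingModel", representation(
  lengthScale = "numeric", amplitude = "numeric", noiseVar = "numeric",
  nu = "numeric", coords = "matrix", y = "numeric",
  yMean = "numeric", ySd = "numeric", alpha = "numeric", L = "matrix",
  logLik = "numeric", trace = "data.frame"))

setValidity("KrigingModel", function(object) {
  msg <- character()
  if (object@lengthScale <= 0) msg <- c(msg, "lengthScale must be > 0")
  if (object@noiseVar < 0) msg <- c(msg, "noiseVar must be >= 0")
  if (!object@nu %in% c(0.5, 1.5, 2.5)) {
    msg <- c(msg, "nu must be one of 0.5, 1.5, 2.5")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "KrigingModel", function(object) {
  cat(sprintf(
    paste0("KrigingModel (Matern nu = %.1f)\n",
           "  length scale : %.2f m\n  amplitude    : %.4f (standardised)\n",
           "  noise var    : %.3g (standardised)\n",
           "  n training   : %d\n  log marginal likelihood: %.3f\n"),
    object@nu, object@lengthScale, object@amplitude, object@noiseVar,
    nrow(object@coords), object@logLik))
})
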