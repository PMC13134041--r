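# Feature-table, taxonomy, metadata and sequence I/O plus the standard
# amplicon feature-filtering rules applied before diversity analysis.

#' Read a feature table from TSV or BIOM
#'
#' The canonical TSV dialect has features as rows and samples as columns,
#' first column the feature id (the usual amplicon-export layout). Use
#' `transpose = TRUE` for samples-as-rows files. BIOM (2.1) reading is
#' available when the `biomformat` package is installed.
#'
#' @param path file path.
#' @param format "tsv" or "biom".
#' @param transpose logical, TSV only: TRUE if samples are rows.
#' @return a [FeatureTable-class].
#' @export
readFeatureTable <- function(path, format = c("tsv", "biom"),
                             transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("BIOM support requires the 'biomformat' package")
    }
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))
    return(FeatureTable(m))
  }
  raw <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", comment.char = "",
                    quote = "")
  if (ncol(raw) < 2L) stop("feature table needs an id column plus counts")
  ids <- raw[[1L]]
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate %s id(s): %s",
                 if (transpose) "sample" else "feature",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (anyDuplicated(colnames(raw)[-1L])) {
    stop(sprintf("duplicate %s id(s) in header: %s",
                 if (transpose) "feature" else "sample",
                 paste(unique(colnames(raw)[-1L][duplicated(colnames(raw)[-1L])]),
                       collapse = ", ")))
  }
  num <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw))))
  num <- matrix(num, nrow = nrow(raw),
                dimnames = list(ids, colnames(raw)[-1L]))
  if (any(is.na(num))) stop("non-numeric count cell(s) in table")
  if (any(num != round(num))) stop("non-integer count cell(s) in table")
  if (any(num < 0)) stop("negative count cell(s) in table")
  FeatureTable(num, transpose = transpose)
}

#' Write a feature table as TSV
#'
#' Features as rows, samples as columns, first column `feature_id`.
#' [readFeatureTable()] of the written file reproduces the table exactly.
#'
#' @param x a [FeatureTable-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeFeatureTable <- function(x, path) {
  stopifnot(is(x, "FeatureTable"))
  df <- data.frame(feature_id = featureIDs(x), counts(x),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy annotation table
#'
#' Expects a TSV with header and at least two columns: feature id and a
#' rank-delimited lineage string (e.g. `d__Bacteria; p__...; c__...`), with
#' an optional numeric confidence column in `[0, 1]`.
#'
#' @param path file path.
#' @return data.frame with columns `feature_id`, `lineage`, and `confidence`
#'   (NA when absent), rownames = feature ids.
#' @export
readTaxonomy <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", comment.char = "", quote = "")
  if (ncol(raw) < 2L) stop("taxonomy table needs feature id and lineage")
  out <- data.frame(feature_id = raw[[1L]], lineage = raw[[2L]],
                    confidence = if (ncol(raw) >= 3L)
                      suppressWarnings(as.numeric(raw[[3L]])) else NA_real_,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$feature_id)) stop("duplicate feature ids in taxonomy")
  rownames(out) <- out$feature_id
  out
}

#' Read per-sample metadata
#'
#' TSV with header; first column is the sample id. Recognised columns:
#' `vineyard`, `cultivar`, `latitude`, `longitude`, `row`, `vine`,
#' `vine_group`. Coordinates are validated as WGS84 decimal degrees.
#'
#' @param path file path.
#' @return data.frame, rownames = sample ids.
#' @export
readSampleMetadata <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  md <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   comment.char = "", quote = "", stringsAsFactors = FALSE)
  if (anyDuplicated(md[[1L]])) stop("duplicate sample ids in metadata")
  rownames(md) <- md[[1L]]
  colnames(md)[1L] <- "sample_id"
  for (col in c("latitude", "longitude")) {
    if (col %in% colnames(md)) {
      md[[col]] <- as.numeric(md[[col]])
      lim <- if (col == "latitude") 90 else 180
      bad <- !is.na(md[[col]]) & abs(md[[col]]) > lim
      if (any(bad)) {
        stop(sprintf("%s out of range for sample(s): %s", col,
                     paste(rownames(md)[bad], collapse = ", ")))
      }
    }
  }
  md
}

#' Read ASV sequences from FASTA
#'
#' @param path FASTA file.
#' @return a [Biostrings::DNAStringSet] named by feature id.
#' @export
readSequences <- function(path) {
  seqs <- readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) stop("duplicate sequence ids in FASTA")
  if (any(width(seqs) == 0L)) stop("empty sequence(s) in FASTA")
  seqs
}

# Rank-prefix letters used by SILVA (d__) and UNITE (k__) style lineages.
.rankPrefixes <- c(domain = "d", kingdom = "k", phylum = "p", class = "c",
                   order = "o", family = "f", genus = "g", species = "s")

#' Parse a lineage string into named ranks
#'
#' Splits on `;`, trims whitespace, strips `x__` prefixes. Rank names come
#' from the prefix letter where present (so SILVA `d__` and UNITE `k__`
#' strings both parse); prefix-free lineages are assigned ranks positionally
#' (domain, phylum, class, order, family, genus, species). A rank is
#' unassigned when absent or empty after its prefix.
#'
#' @param lineage character vector of lineage strings.
#' @return list of named character vectors (one per input).
#' @export
parseLineage <- function(lineage) {
  positional <- c("domain", "phylum", "class", "order", "family", "genus",
                  "species")
  lapply(lineage, function(s) {
    parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1L]])
    n <- length(parts)
    if (n == 0L) return(setNames(character(0L), character(0L)))
    has.prefix <- grepl("^[a-zA-Z]__", parts)
    vals <- trimws(ifelse(has.prefix, substring(parts, 4L), parts))
    nms <- rep(NA_character_, n)
    pm <- match(tolower(substring(parts, 1L, 1L)), .rankPrefixes)
    nms[has.prefix] <- names(.rankPrefixes)[pm[has.prefix]]
    fill <- is.na(nms)
    nms[fill] <- positional[pmin(seq_len(n), 7L)][fill]
    setNames(vals, nms)
  })
}

# TRUE where the lineage has a non-empty value at `rank` ("class" etc.;
# "domain" also satisfied by a kingdom-level assignment and vice versa).
.assignedAtRank <- function(lineage, rank) {
  parsed <- parseLineage(lineage)
  rank <- tolower(rank)
  eq <- if (rank %in% c("domain", "kingdom")) c("domain", "kingdom") else rank
  vapply(parsed, function(v) {
    any(names(v) %in% eq & nzchar(v[names(v) %in% eq]))
  }, logical(1L))
}

#' Default lineage exclusion terms
#'
#' Host- and organelle-derived reads removed from amplicon surveys:
#' chloroplast, mitochondria, Viridiplantae, Metazoa; 16S mode additionally
#' excludes features whose domain is Eukaryota.
#' @export
defaultExcludeTerms <- function() {
  c("chloroplast", "mitochondria", "viridiplantae", "metazoa")
}

#' Filter features by taxonomy and abundance
#'
#' Applies the standard amplicon QC rules: remove features (i) not assigned
#' at `requireRank` (default class), (ii) with total count across samples
#' below `minReads` (default 2, i.e. singletons removed), and (iii) whose
#' lineage contains any of `excludeTerms` as a case-insensitive substring.
#' In `mode = "16S"`, features whose domain rank is Eukaryota are also
#' removed. Samples left with zero reads are retained and reported via a
#' message so that depth decisions stay separate from filtering.
#'
#' @param table a [FeatureTable-class].
#' @param taxonomy data.frame as from [readTaxonomy()]; every feature of
#'   `table` must be present.
#' @param minReads minimum total count across samples (features strictly
#'   below are removed); `>= 0`.
#' @param excludeTerms character vector of lineage substrings; `character(0)`
#'   disables.
#' @param requireRank rank name that must be assigned, or `NA` to disable.
#' @param mode `"16S"` (adds the Eukaryota domain exclusion) or `"ITS"`.
#' @return the filtered [FeatureTable-class] (same samples).
#' @export
filterFeatures <- function(table, taxonomy,
                           minReads = 2,
                           excludeTerms = defaultExcludeTerms(),
                           requireRank = "class",
                           mode = c("16S", "ITS")) {
  stopifnot(is(table, "FeatureTable"), minReads >= 0)
  mode <- match.arg(mode)
  taxonomy <- as.data.frame(taxonomy)
  if (!"lineage" %in% colnames(taxonomy)) {
    stop("taxonomy must have a 'lineage' column")
  }
  if ("feature_id" %in% colnames(taxonomy)) {
    rownames(taxonomy) <- taxonomy$feature_id
  }
  miss <- setdiff(featureIDs(table), rownames(taxonomy))
  if (length(miss)) {
    stop(sprintf("feature(s) missing from taxonomy: %s",
                 paste(miss, collapse = ", ")))
  }
  lin <- taxonomy[featureIDs(table), "lineage"]
  keep <- rep(TRUE, nrow(table))
  if (!is.na(requireRank) && nzchar(requireRank)) {
    keep <- keep & .assignedAtRank(lin, requireRank)
  }
  keep <- keep & rowSums(counts(table)) >= minReads
  if (length(excludeTerms)) {
    low <- tolower(lin)
    hit <- Reduce(`|`, lapply(tolower(excludeTerms),
                              function(t) grepl(t, low, fixed = TRUE)))
    keep <- keep & !hit
  }
  if (mode == "16S") {
    dom <- vapply(parseLineage(lin), function(v) {
      d <- v[names(v) %in% c("domain", "kingdom")]
      if (length(d)) tolower(d[[1L]]) else ""
    }, character(1L))
    keep <- keep & dom != "eukaryota"
  }
  out <- table[keep, ]
  if (nrow(out) == 0L) warning("all features removed by filtering")
  empty <- sampleTotals(out) == 0
  if (any(empty)) {
    message(sprintf("%d sample(s) left with zero reads after filtering: %s",
                    sum(empty),
                    paste(sampleIDs(out)[empty], collapse = ", ")))
  }
  out
}

#' Merge two feature tables over their shared samples
#'
#' Used to combine ASV and k-mer representations: feature spaces must be
#' disjoint (or are namespaced via `prefixes`); the merged table covers the
#' intersection of the two sample sets with the union of features.
#'
#' @param a,b [FeatureTable-class] objects.
#' @param prefixes optional character(2); when given, feature ids are
#'   prefixed (`prefixes[1]` for `a`, `prefixes[2]` for `b`) before merging.
#' @return merged [FeatureTable-class].
#' @export
mergeTables <- function(a, b, prefixes = NULL) {
  stopifnot(is(a, "FeatureTable"), is(b, "FeatureTable"))
  ma <- counts(a); mb <- counts(b)
  if (!is.null(prefixes)) {
    stopifnot(length(prefixes) == 2L)
    rownames(ma) <- paste0(prefixes[1L], rownames(ma))
    rownames(mb) <- paste0(prefixes[2L], rownames(mb))
  }
  overlap <- intersect(rownames(ma), rownames(mb))
  if (length(overlap)) {
    stop(sprintf(
      "overlapping feature ids (%s%s); pass 'prefixes' to namespace them",
      paste(head(overlap, 3L), collapse = ", "),
      if (length(overlap) > 3L) ", ..." else ""))
  }
  shared <- intersect(colnames(ma), colnames(mb))
  if (!length(shared)) stop("tables share no samples")
  FeatureTable(rbind(ma[, shared, drop = FALSE], mb[, shared, drop = FALSE]))
}

#' Serialise a distance matrix as square TSV
#'
#' Writes the full square matrix (both triangles) with ids as header row and
#' first column.
#' @param d a `dist` or square symmetric matrix.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeDistanceMatrix <- function(d, path) {
  m <- .asDistanceMatrix(d)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square TSV distance matrix
#' @param path file path as written by [writeDistanceMatrix()].
#' @return a `dist` object with sample labels.
#' @export
readDistanceMatrix <- function(path) {
  raw <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    comment.char = "", quote = "")
  m <- as.matrix(raw[, -1L, drop = FALSE])
  rownames(m) <- raw[[1L]]
  as.dist(.asDistanceMatrix(m))
}
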