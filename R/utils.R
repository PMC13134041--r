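# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs expr on the current stream.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# All permutations of seq_len(n), one per row (n! rows). Used for exhaustive
# permutation tests at small n; guarded so nobody asks for n! explosion.
.allPermutations <- function(n) {
  stopifnot(n >= 1L, n <= 8L)
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .allPermutations(n - 1L)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}

# Coerce a DistanceMatrix-like input (dist or square matrix) to a validated
# square symmetric hollow matrix with sample ids as dimnames.
.asDistanceMatrix <- function(d, arg = "d") {
  m <- if (inherits(d, "dist")) as.matrix(d) else as.matrix(d)
  if (nrow(m) != ncol(m)) {
    stop(sprintf("'%s' must be square, got %d x %d", arg, nrow(m), ncol(m)))
  }
  if (any(!is.finite(m))) stop(sprintf("'%s' contains non-finite values", arg))
  if (any(abs(m - t(m)) > 1e-12)) {
    stop(sprintf("'%s' is not symmetric (tolerance 1e-12)", arg))
  }
  if (any(abs(diag(m)) > 1e-12)) {
    stop(sprintf("'%s' has a nonzero diagonal", arg))
  }
  if (any(m < 0)) stop(sprintf("'%s' has negative entries", arg))
  if (is.null(rownames(m))) {
    rownames(m) <- colnames(m) <- paste0("s", seq_len(nrow(m)))
  } else {
    colnames(m) <- rownames(m)
  }
  m
}

.upperTri <- function(m) m[upper.tri(m)]

# Align dm_b's samples to dm_a's order; error if the sets differ.
.alignDistancePair <- function(a, b) {
  a <- .asDistanceMatrix(a, "dm_a")
  b <- .asDistanceMatrix(b, "dm_b")
  if (!setequal(rownames(a), rownames(b))) {
    stop("the two distance matrices cover different sample sets")
  }
  b <- b[rownames(a), rownames(a)]
  list(a = a, b = b)
}

# Spearman rho via Pearson correlation of (pre-computed) average ranks.
.rhoFromRanks <- function(ra, rb) {
  suppressWarnings(cor(ra, rb))
}

.checkMetadata <- function(metadata, need = character(), context = "metadata") {
  if (!is.data.frame(metadata)) metadata <- as.data.frame(metadata)
  missing <- setdiff(need, colnames(metadata))
  if (length(missing)) {
    stop(sprintf("%s lacks required column(s): %s", context,
                 paste(missing, collapse = ", ")))
  }
  if ("latitude" %in% need) {
    lat <- metadata$latitude
    lon <- metadata$longitude
    bad <- !is.finite(lat) | !is.finite(lon) | abs(lat) > 90 | abs(lon) > 180
    if (any(bad)) {
      ids <- rownames(metadata)
      if (is.null(ids)) ids <- as.character(seq_len(nrow(metadata)))
      stop(sprintf("invalid or missing coordinates for sample(s): %s",
                   paste(ids[bad], collapse = ", ")))
    }
  }
  metadata
}
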