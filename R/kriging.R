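# Gaussian-process (kriging) spatial interpolation with a Matern kernel
# plus white noise, fitted by multi-start maximisation of the log marginal
# likelihood. Values are standardised internally; predictions are
# de-standardised on the way out.

# Matern covariance for nu in {0.5, 1.5, 2.5}; d is a distance matrix.
.maternCov <- function(d, lengthScale, amplitude, nu) {
  r <- d / lengthScale
  k <- switch(as.character(nu),
    "0.5" = exp(-r),
    "1.5" = (1 + sqrt(3) * r) * exp(-sqrt(3) * r),
    "2.5" = (1 + sqrt(5) * r + 5 * r^2 / 3) * exp(-sqrt(5) * r),
    stop("nu must be 0.5, 1.5 or 2.5"))
  amplitude^2 * k
}

# Negative log marginal likelihood; theta = log(lengthScale, amplitude,
# sdNoise). Returns a large value on Cholesky failure so optim can recover.
.gpNegLML <- function(theta, d, y, nu) {
  ell <- exp(theta[1L]); amp <- exp(theta[2L]); noise <- exp(theta[3L])^2
  k <- .maternCov(d, ell, amp, nu)
  diag(k) <- diag(k) + noise + 1e-10
  ch <- tryCatch(chol(k), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  alpha <- backsolve(ch, forwardsolve(t(ch), y))
  0.5 * sum(y * alpha) + sum(log(diag(ch))) + 0.5 * length(y) * log(2 * pi)
}

#' Fit a Gaussian-process spatial model (kriging)
#'
#' Standardises `values`, then maximises the log marginal likelihood of a
#' Matern(nu) + white-noise GP over (length scale, amplitude, noise sd) by
#' L-BFGS-B from `nRestarts` random log-uniform starts plus one heuristic
#' start at the median inter-point distance. Hyperparameter bounds: length
#' scale in [0.1 x min, 10 x max inter-point distance]; amplitude and noise
#' sd in [1e-8, 10] on the standardised scale (noise bounds overridable via
#' `noiseBounds`, e.g. `c(1e-10, 1e-8)` for near-interpolating fits).
#'
#' @param coords n x 2 matrix of planar coordinates in metres (see
#'   [projectCoords()]); n >= 5.
#' @param values numeric response at each coordinate (finite).
#' @param nu Matern smoothness: 0.5, 1.5 (default) or 2.5.
#' @param nRestarts random optimiser restarts (default 10).
#' @param noiseBounds length-2 bounds for the noise *sd* on the
#'   standardised scale.
#' @param seed optional integer seed for the random starts.
#' @return a [KrigingModel-class].
#' @export
fitKrige <- function(coords, values, nu = 1.5, nRestarts = 10,
                     noiseBounds = c(1e-8, 10), seed = NULL) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2L)
  if (nrow(coords) < 5L) stop("kriging needs at least 5 points")
  if (any(!is.finite(values)) || length(values) != nrow(coords)) {
    stop("values must be finite, one per coordinate")
  }
  d <- as.matrix(dist(coords))
  offDiag <- d[upper.tri(d)]
  posD <- offDiag[offDiag > 0]
  if (!length(posD)) stop("all coordinates identical")
  yMean <- mean(values)
  ySd <- sd(values)
  if (!is.finite(ySd) || ySd < 1e-12) ySd <- 1  # constant response
  y <- (values - yMean) / ySd

  lower <- log(c(0.1 * min(posD), 1e-8, noiseBounds[1L]))
  upper <- log(c(10 * max(posD), 10, noiseBounds[2L]))
  heuristic <- pmin(pmax(log(c(median(posD), 1, 0.1)), lower), upper)
  starts <- .withSeed(seed, {
    rbind(heuristic,
          matrix(runif(3L * nRestarts, rep(lower, each = nRestarts),
                       rep(upper, each = nRestarts)),
                 nrow = nRestarts))
  })
  fits <- lapply(seq_len(nrow(starts)), function(i) {
    tryCatch(
      optim(starts[i, ], .gpNegLML, d = d, y = y, nu = nu,
            method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 200)),
      error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, logical(1L))
  if (!any(ok)) stop("GP optimisation failed from every start")
  nll <- vapply(fits, function(f) if (is.null(f)) Inf else f$value,
                numeric(1L))
  best <- fits[[which.min(nll)]]
  ell <- exp(best$par[1L]); amp <- exp(best$par[2L])
  noiseVar <- exp(best$par[3L])^2
  k <- .maternCov(d, ell, amp, nu)
  diag(k) <- diag(k) + noiseVar + 1e-10
  ch <- chol(k)
  alpha <- backsolve(ch, forwardsolve(t(ch), y))
  trace <- data.frame(
    start = seq_len(nrow(starts)),
    logLik = -nll,
    converged = vapply(fits, function(f)
      if (is.null(f)) FALSE else f$convergence == 0, logical(1L)))
  new("KrigingModel", lengthScale = ell, amplitude = amp,
      noiseVar = noiseVar, nu = nu, coords = coords, y = y,
      yMean = yMean, ySd = ySd, alpha = as.numeric(alpha), L = ch,
      logLik = -best$value, trace = trace)
}

#' Predict from a fitted kriging model
#'
#' Posterior mean and standard deviation of the latent field at query
#' coordinates, de-standardised to the original value scale. The sd is for
#' the noise-free field: ~0 at a training point when the fitted noise is
#' ~0, and approaching the prior amplitude far from all training points.
#'
#' @param model a [KrigingModel-class].
#' @param coords m x 2 matrix of planar coordinates (metres, same
#'   projection as the training coordinates).
#' @return data.frame with columns `mean` and `sd`.
#' @export
predictKrige <- function(model, coords) {
  if (!is(model, "KrigingModel")) stop("model must be a fitted KrigingModel")
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2L)
  crossD <- sqrt(pmax(outer(rowSums(coords^2), rowSums(model@coords^2),
                            "+") - 2 * tcrossprod(coords, model@coords), 0))
  ks <- .maternCov(crossD, model@lengthScale, model@amplitude, model@nu)
  mu <- as.numeric(ks %*% model@alpha)
  v <- forwardsolve(t(model@L), t(ks))
  varLatent <- pmax(0, model@amplitude^2 - colSums(v^2))
  data.frame(mean = model@yMean + model@ySd * mu,
             sd = model@ySd * sqrt(varLatent))
}

#' Krige a diversity surface over vine positions
#'
#' Convenience wrapper: projects sample and query coordinates to a shared
#' local planar frame, fits the GP to the observed values and predicts at
#' the query vines, returning a tidy table ready for plotting or TSV
#' export (id, lon, lat, observed, predicted, sd).
#'
#' @param metadata data.frame with `latitude`/`longitude` for the observed
#'   samples, rownames = ids.
#' @param values named numeric (alpha diversity, PCoA axis, relative
#'   abundance, ...) for the observed samples.
#' @param queryMetadata optional data.frame of positions to interpolate at
#'   (default: the observed positions).
#' @inheritParams fitKrige
#' @return list of class "krigedSurface": `model` and `surface` data.frame.
#' @export
krigeSurface <- function(metadata, values, queryMetadata = NULL, nu = 1.5,
                         nRestarts = 10, seed = NULL) {
  metadata <- .checkMetadata(metadata, c("latitude", "longitude"))
  if (is.null(queryMetadata)) queryMetadata <- metadata
  queryMetadata <- .checkMetadata(queryMetadata, c("latitude", "longitude"))
  if (!is.null(names(values))) {
    values <- values[rownames(metadata)]
  }
  xy <- projectCoords(metadata)
  origin <- attr(xy, "origin")
  qxy <- projectCoords(queryMetadata, origin = origin)
  model <- fitKrige(xy, values, nu = nu, nRestarts = nRestarts, seed = seed)
  pred <- predictKrige(model, qxy)
  obs <- values[match(rownames(queryMetadata), rownames(metadata))]
  surface <- data.frame(
    id = rownames(queryMetadata),
    longitude = queryMetadata$longitude,
    latitude = queryMetadata$latitude,
    observed = obs,
    predicted = pred$mean,
    sd = pred$sd,
    row.names = NULL)
  structure(list(model = model, surface = surface), class = "krigedSurface")
}

#' @export
print.krigedSurface <- function(x, ...) {
  show(x$model)
  cat(sprintf("  surface: %d predicted position(s)\n", nrow(x$surface)))
  invisible(x)
}
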