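#' Calibration maps between assay chips
#'
#' `LinearMap` is a line fitted by orthogonal (total least squares)
#' regression between ladder EC50 values on two chips.
#' `PiecewiseVectorMap` is the two-parameter map between expression
#' vectors: identity up to an inflection point `c`, then linear with
#' slope `s` (continuous at `c`, invertible iff `s > 0`); it models a
#' soft ceiling where one expression vector saturates.
#'
#' @slot slope,intercept parameters of the line (slope must be nonzero).
#' @aliases PiecewiseVectorMap-class
#' @export
setClass("LinearMap", representation(slope = "numeric",
                                     intercept = "numeric"))

setValidity("LinearMap", function(object) {
  if (length(object@slope) != 1L || object@slope == 0)
    return("slope must be a single nonzero value")
  TRUE
})

#' @slot inflection the inflection point `c`.
#' @slot upperSlope the slope `s` above the inflection.
#' @slot flatFit flag raised when no curvature was detected (s ~ 1).
#' @rdname LinearMap-class
#' @export
setClass("PiecewiseVectorMap",
  representation(inflection = "numeric", upperSlope = "numeric",
                 flatFit = "logical"))

setMethod("show", "LinearMap", function(object) {
  cat(sprintf("LinearMap: y = %.6g x + %.6g\n",
              object@slope, object@intercept))
})

setMethod("show", "PiecewiseVectorMap", function(object) {
  cat(sprintf(
    "PiecewiseVectorMap: identity below c = %.6g, slope %.6g above%s\n",
    object@inflection, object@upperSlope,
    if (object@flatFit) " (flat fit: no curvature detected)" else ""))
})

#' Apply or invert a calibration map
#'
#' `applyMap` evaluates the map at `x`; `invertMap` evaluates the exact
#' functional inverse at `y` (for a `PiecewiseVectorMap` this requires
#' `upperSlope > 0`). `invertMap(m, applyMap(m, x)) == x`.
#'
#' @param map a `LinearMap` or `PiecewiseVectorMap`.
#' @param x,y numeric vectors.
#' @return Numeric vector of mapped values.
#' @export
setGeneric("applyMap", function(map, x) standardGeneric("applyMap"))

#' @rdname applyMap
#' @export
setGeneric("invertMap", function(map, y) standardGeneric("invertMap"))

#' @rdname applyMap
#' @export
setMethod("applyMap", "LinearMap", function(map, x)
  map@intercept + map@slope * x)

#' @rdname applyMap
#' @export
setMethod("invertMap", "LinearMap", function(map, y)
  (y - map@intercept) / map@slope)

#' @rdname applyMap
#' @export
setMethod("applyMap", "PiecewiseVectorMap", function(map, x) {
  ifelse(x <= map@inflection, x,
         map@inflection + map@upperSlope * (x - map@inflection))
})

#' @rdname applyMap
#' @export
setMethod("invertMap", "PiecewiseVectorMap", function(map, y) {
  if (map@upperSlope <= 0) {
    stop("map is not invertible (upper slope <= 0)", call. = FALSE)
  }
  ifelse(y <= map@inflection, y,
         map@inflection + (y - map@inflection) / map@upperSlope)
})

#' Orthogonal (total least squares) regression
#'
#' Fits the line minimising summed squared perpendicular distances
#' (Deming regression with error-variance ratio `varRatio`, default 1),
#' the appropriate fit when both axes carry comparable measurement error,
#' as between EC50 values of ladder proteins on two chips.
#'
#' @param x,y paired numeric vectors (n >= 3, nonzero spread in both).
#' @param varRatio assumed ratio of y-error variance to x-error variance.
#' @return A [LinearMap-class].
#' @examples
#' fitOrthogonal(1:5, 2 * (1:5) + 1)   # slope 2, intercept 1
#' @export
fitOrthogonal <- function(x, y, varRatio = 1) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 paired points", call. = FALSE)
  sxx <- stats::var(x); syy <- stats::var(y); sxy <- stats::cov(x, y)
  if (sxx < .Machine$double.eps || syy < .Machine$double.eps) {
    stop("degenerate spread in x or y", call. = FALSE)
  }
  d <- varRatio
  if (abs(sxy) < .Machine$double.eps) {
    stop("no covariance between x and y: orthogonal slope undefined",
         call. = FALSE)
  }
  slope <- (syy - d * sxx + sqrt((syy - d * sxx)^2 + 4 * d * sxy^2)) /
    (2 * sxy)
  new("LinearMap", slope = slope, intercept = mean(y) - slope * mean(x))
}

#' Piecewise-linear orthogonal regression between expression vectors
#'
#' Fits the two-parameter map whose lower segment is constrained to lie
#' along `y = x` up to a best-fit inflection point `c` and whose upper
#' segment has free slope `s` (continuous at `c`), by minimising summed
#' squared orthogonal distances to the two-segment curve. The search is a
#' grid over candidate inflections (x-quantiles) with an inner
#' one-dimensional slope optimisation, followed by a Nelder-Mead polish,
#' which makes the fit reproducible and exact on noiseless data. If the
#' fitted upper slope is within `flatTol` of 1 no curvature is detectable:
#' `c` is reported as `max(x)` and the `flatFit` flag is raised.
#'
#' @param x,y paired numeric vectors (n >= 10), `x` spanning both sides
#'   of the eventual inflection.
#' @param flatTol half-width of the "no curvature" band around s = 1.
#' @return A [PiecewiseVectorMap-class].
#' @export
fitPiecewiseVectorMap <- function(x, y, flatTol = 0.05) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 10L) stop("need at least 10 paired points", call. = FALSE)

  objective <- function(cc, ss) {
    dLower <- (y - x)^2 / 2
    dUpper <- (y - cc - ss * (x - cc))^2 / (1 + ss^2)
    sum(pmin(dLower, dUpper))
  }
  # coarse 2-D grid first: the profile over s can have flat plateaus
  # (all points falling back to the identity segment), so a 1-D line
  # search is unreliable
  cGrid <- stats::quantile(x, probs = seq(0.05, 0.95, length.out = 40),
                           names = FALSE)
  sGrid <- seq(0.05, 2.5, by = 0.05)
  best <- list(val = Inf)
  for (cc in cGrid) {
    vals <- vapply(sGrid, function(ss) objective(cc, ss), numeric(1))
    k <- which.min(vals)
    if (vals[k] < best$val) best <- list(c = cc, s = sGrid[k],
                                         val = vals[k])
  }
  polish <- stats::optim(c(best$c, best$s),
                         function(p) objective(p[1L], p[2L]),
                         method = "Nelder-Mead",
                         control = list(reltol = 1e-14, maxit = 2000))
  cc <- polish$par[1L]; ss <- polish$par[2L]
  if (abs(ss - 1) < flatTol) {
    return(new("PiecewiseVectorMap", inflection = max(x), upperSlope = 1,
               flatFit = TRUE))
  }
  new("PiecewiseVectorMap", inflection = cc, upperSlope = ss,
      flatFit = FALSE)
}

#' Calibrate a new chip onto the reference EC50 scale
#'
#' Applies, per protease, the optional inverse of a
#' [PiecewiseVectorMap-class] (mapping data from a new expression vector
#' back into the original vector's space) and then a ladder-fitted
#' [LinearMap-class] (orthogonal regression of this chip's ladder EC50s
#' onto their reference-chip values), returning the calibrated table plus
#' a calibration report.
#'
#' @param newChip data.frame with columns `id`, `ec50_trypsin`,
#'   `ec50_chymotrypsin`.
#' @param ladder data.frame with columns `id`, `ref_trypsin`,
#'   `ref_chymotrypsin`: reference-chip EC50s of the ladder designs
#'   (which must appear on the new chip).
#' @param vectorMap optional [PiecewiseVectorMap-class], or a named list
#'   with one map per protease.
#' @return A list with `table` (calibrated data.frame) and `report`
#'   (per-protease fit parameters and ladder residuals).
#' @export
reconcileChip <- function(newChip, ladder, vectorMap = NULL) {
  stopifnot(all(c("id", "ec50_trypsin", "ec50_chymotrypsin")
                %in% names(newChip)))
  idx <- match(ladder$id, newChip$id)
  if (sum(!is.na(idx)) < 3L) {
    stop("need at least 3 ladder designs present on the new chip",
         call. = FALSE)
  }
  out <- newChip
  report <- list()
  for (p in .PROTEASES) {
    col <- paste0("ec50_", p)
    vals <- newChip[[col]]
    vm <- if (is(vectorMap, "PiecewiseVectorMap")) vectorMap
          else vectorMap[[p]]
    if (!is.null(vm)) vals <- invertMap(vm, vals)
    lx <- vals[idx]
    ly <- ladder[[paste0("ref_", p)]]
    lmap <- fitOrthogonal(lx, ly)
    out[[col]] <- applyMap(lmap, vals)
    report[[p]] <- list(slope = lmap@slope, intercept = lmap@intercept,
                        nLadder = sum(!is.na(idx)),
                        residuals = applyMap(lmap, lx) - ly)
  }
  list(table = out, report = report)
}
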