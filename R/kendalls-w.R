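# The core statistic: tie-corrected Kendall's coefficient of concordance
# (Kendall's W) per vertex neighborhood, yielding surface regional
# homogeneity (2dReHo) maps and their global mean.

# Tie-correction term for one ranked series: sum over tie groups of
# (t^3 - t), where t is the size of each group of tied values.
tieTerm <- function(x) {
  tb <- tabulate(match(x, unique(x)))
  sum(tb^3 - tb)
}

#' Kendall's coefficient of concordance (Kendall's W) with tie correction
#'
#' Measures the agreement of `m` series (rows, the "judges") in ranking `n`
#' timepoints (columns, the "objects"). Ranks are midranks within each
#' series; with column rank sums R_t,
#' \deqn{W = \frac{12 \sum_t (R_t - m(n+1)/2)^2}{m^2 (n^3 - n) - m \sum_j T_j},}
#' where \eqn{T_j = \sum_g (t_g^3 - t_g)} corrects for tie groups of size
#' \eqn{t_g} in series j. W is 1 for identical rank orders and has
#' expectation 1/m for independent series.
#'
#' @param series numeric matrix, m x n, rows = series, columns = timepoints.
#' @return scalar in [0, 1]. A fully tied matrix (denominator <= 0) returns
#'   0 with a warning.
#' @examples
#' kendallsW(rbind(1:5, 1:5, 1:5)) # 1
#' @export
kendallsW <- function(series) {
  series <- as.matrix(series)
  m <- nrow(series)
  n <- ncol(series)
  if (m < 2L) stop("need at least 2 series (rows)")
  if (n < 2L) stop("need at least 2 timepoints (columns)")
  if (!all(is.finite(series))) stop("series must be finite")
  ranks <- t(apply(series, 1L, rank))
  tcorr <- sum(apply(series, 1L, tieTerm))
  rsum <- colSums(ranks)
  s <- sum((rsum - m * (n + 1) / 2)^2)
  denom <- m^2 * (n^3 - n) - m * tcorr
  if (denom <= 0) {
    warning("all series fully tied; Kendall's W undefined, returning 0")
    return(0)
  }
  12 * s / denom
}

#' Per-vertex surface regional homogeneity (2dReHo)
#'
#' For every vertex, Kendall's W is computed over the time series of the
#' vertex and its k-ring mesh neighborhood (ring 2 gives 19 series at
#' regular valence-6 vertices: the center, its 6 first-ring and 12
#' second-ring neighbors; the 12 valence-5 apices of an icosphere give 16).
#' The map's global mean is the unweighted arithmetic mean over vertices;
#' an area-weighted mean is available from [globalReHo()].
#'
#' The computation is vectorized: series are ranked once per vertex, and
#' neighborhood rank sums are accumulated through a sparse neighborhood
#' indicator matrix. A test asserts exact equality with per-vertex
#' [kendallsW()] calls.
#'
#' @param ts a [SubjectTimeseries-class]; vertex count must match `mesh`.
#' @param mesh a [SurfaceMesh-class].
#' @param ring neighborhood order (default 2).
#' @param neighborhoods optional precomputed result of
#'   [neighborhoodMatrix()] for `mesh` and `ring` (saves time across
#'   subjects sharing one mesh).
#' @return a [ReHoMap-class].
#' @export
rehoMap <- function(ts, mesh, ring = 2L, neighborhoods = NULL) {
  y <- tsMatrix(ts)
  if (nrow(y) != nVertices(mesh)) {
    stop(sprintf(
      "time series has %d vertices but mesh has %d",
      nrow(y), nVertices(mesh)
    ))
  }
  if (is.null(neighborhoods)) neighborhoods <- neighborhoodMatrix(mesh, ring)
  nb <- neighborhoods$indicator
  m <- neighborhoods$size
  n <- ncol(y)
  ranks <- t(apply(y, 1L, rank))
  tie <- apply(y, 1L, tieTerm)
  rsum <- as.matrix(nb %*% ranks)           # per-neighborhood column rank sums
  s <- rowSums((rsum - m * (n + 1) / 2)^2)
  tcorr <- as.numeric(nb %*% tie)
  denom <- m^2 * (n^3 - n) - m * tcorr
  w <- ifelse(denom > 0, 12 * s / pmax(denom, .Machine$double.eps), 0)
  if (any(denom <= 0)) {
    warning(sum(denom <= 0), " neighborhood(s) fully tied; set to 0")
  }
  w <- pmin(pmax(w, 0), 1)
  new("ReHoMap",
    values = w, globalMean = mean(w), ring = as.integer(ring),
    subjectId = subjectID(ts)
  )
}

#' Global mean regional homogeneity
#'
#' The average concordance across the entire surface: unweighted arithmetic
#' mean of the per-vertex values by default, or the vertex-area-weighted
#' mean when a mesh is supplied and `areaWeighted = TRUE`.
#'
#' @param map a [ReHoMap-class].
#' @param mesh optional [SurfaceMesh-class] (required for area weighting).
#' @param areaWeighted logical, default FALSE.
#' @return scalar.
#' @export
globalReHo <- function(map, mesh = NULL, areaWeighted = FALSE) {
  v <- rehoValues(map)
  if (!length(v)) stop("empty map")
  if (areaWeighted) {
    if (is.null(mesh)) stop("area weighting needs a mesh")
    a <- vertexArea(mesh)
    return(sum(v * a) / sum(a))
  }
  mean(v)
}
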