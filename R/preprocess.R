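# Temporal preprocessing of per-vertex time series: volume discard,
# global-mean intensity normalization, Friston-24 nuisance expansion and
# regression, ideal band-pass filtering, polynomial detrending, and
# framewise-displacement motion summaries.

#' Discard initial volumes
#'
#' Drops the first `nDiscard` timepoints (signal-equilibration volumes);
#' retained samples are unchanged.
#'
#' @param ts a [SubjectTimeseries-class].
#' @param nDiscard number of initial timepoints to drop (default 5, i.e.
#'   10 s at TR = 2 s).
#' @return a [SubjectTimeseries-class] with `nDiscard` fewer timepoints.
#' @export
discardInitial <- function(ts, nDiscard = 5L) {
  nt <- ncol(tsMatrix(ts))
  if (nDiscard < 0L) stop("'nDiscard' must be >= 0")
  if (nDiscard >= nt) {
    stop(sprintf("cannot discard %d of %d timepoints", nDiscard, nt))
  }
  if (nDiscard == 0L) return(ts)
  SubjectTimeseries(tsMatrix(ts)[, -seq_len(nDiscard), drop = FALSE],
    tr = repetitionTime(ts), subjectId = subjectID(ts)
  )
}

#' Global-mean intensity normalization
#'
#' Rescales the whole matrix so its grand mean equals `target` (10,000 by
#' convention), making amplitudes comparable across subjects.
#'
#' @param ts a [SubjectTimeseries-class].
#' @param target desired grand mean (default 10000).
#' @return rescaled [SubjectTimeseries-class].
#' @export
globalMeanNormalize <- function(ts, target = 10000) {
  g <- mean(tsMatrix(ts))
  if (abs(g) < .Machine$double.eps * 100) {
    stop("grand mean is zero; cannot normalize")
  }
  SubjectTimeseries(tsMatrix(ts) * (target / g),
    tr = repetitionTime(ts), subjectId = subjectID(ts)
  )
}

#' Friston-24 motion expansion
#'
#' Expands six rigid-body motion parameters into the 24-regressor set: the
#' six parameters, their one-sample-back lags (zero-padded at t = 0), and
#' the squares of both sets.
#'
#' @param motion numeric matrix with 6 columns (tx,ty,tz mm; rx,ry,rz rad).
#' @return numeric matrix, time x 24, with descriptive column labels.
#' @export
friston24 <- function(motion) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) {
    stop("'motion' must have exactly 6 columns, got ", ncol(motion))
  }
  if (nrow(motion) < 2L) stop("need at least 2 timepoints")
  if (!all(is.finite(motion))) stop("motion parameters must be finite")
  lag1 <- rbind(0, motion[-nrow(motion), , drop = FALSE])
  out <- cbind(motion, lag1, motion^2, lag1^2)
  base <- c("tx", "ty", "tz", "rx", "ry", "rz")
  colnames(out) <- c(base, paste0(base, "_lag"), paste0(base, "_sq"),
    paste0(base, "_lag_sq"))
  out
}

#' Regress nuisance covariates out of every vertex series
#'
#' Per-vertex ordinary least squares of the series on the nuisance set (plus
#' an intercept by default); returns the residuals, which are orthogonal to
#' every regressor.
#'
#' @param ts a [SubjectTimeseries-class].
#' @param nuisance numeric matrix, time x k (may have zero columns).
#' @param addIntercept include an intercept column (default TRUE).
#' @return residual [SubjectTimeseries-class].
#' @export
nuisanceRegress <- function(ts, nuisance, addIntercept = TRUE) {
  y <- tsMatrix(ts)
  nt <- ncol(y)
  if (is.null(nuisance)) nuisance <- matrix(0, nt, 0L)
  nuisance <- as.matrix(nuisance)
  if (nrow(nuisance) != nt) {
    stop("nuisance rows must match the number of timepoints")
  }
  x <- if (addIntercept) cbind(intercept = 1, nuisance) else nuisance
  if (ncol(x) == 0L) return(ts)
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    bad <- colnames(x)[setdiff(seq_len(ncol(x)), qrx$pivot[seq_len(qrx$rank)])]
    stop("nuisance design is rank deficient; collinear columns: ",
      paste(bad, collapse = ", "))
  }
  resid <- t(qr.resid(qrx, t(y)))
  SubjectTimeseries(resid, tr = repetitionTime(ts), subjectId = subjectID(ts))
}

#' Ideal band-pass filter
#'
#' Hard Fourier-domain filter: discrete-Fourier bins whose frequency lies
#' strictly outside `[fLow, fHigh]` are zeroed; band edges are inclusive
#' (a bin exactly at `fLow` or `fHigh` is kept). The zero-frequency (mean)
#' bin is outside any passband with `fLow > 0` and is removed.
#'
#' @param ts a [SubjectTimeseries-class].
#' @param fLow,fHigh passband edges in Hz (defaults 0.01 and 0.1, the
#'   conventional resting-state band).
#' @return filtered [SubjectTimeseries-class] (real-valued).
#' @export
bandpassFilter <- function(ts, fLow = 0.01, fHigh = 0.1) {
  y <- tsMatrix(ts)
  nt <- ncol(y)
  tr <- repetitionTime(ts)
  nyquist <- 1 / (2 * tr)
  if (fLow >= fHigh) stop("'fLow' must be below 'fHigh'")
  if (fHigh >= nyquist) {
    stop(sprintf("'fHigh' (%g Hz) must be below Nyquist (%g Hz)", fHigh, nyquist))
  }
  k <- seq_len(nt) - 1L
  freq <- pmin(k, nt - k) / (nt * tr)
  tol <- 1e-12
  keep <- freq >= fLow - tol & freq <= fHigh + tol
  spec <- t(stats::mvfft(t(y)))
  spec[, !keep] <- 0
  filtered <- Re(t(stats::mvfft(t(spec), inverse = TRUE))) / nt
  SubjectTimeseries(filtered, tr = tr, subjectId = subjectID(ts))
}

#' Polynomial detrending
#'
#' Removes, per vertex, the least-squares fit of polynomials in the time
#' index up to `order` (default 2: intercept, linear and quadratic trends).
#'
#' @param ts a [SubjectTimeseries-class].
#' @param order highest polynomial order (>= 0).
#' @return residual [SubjectTimeseries-class].
#' @export
detrendPoly <- function(ts, order = 2L) {
  if (order < 0L) stop("'order' must be >= 0")
  nt <- ncol(tsMatrix(ts))
  if (nt <= order + 1L) stop("time length must exceed order + 1")
  tt <- seq_len(nt)
  x <- stats::poly(tt, degree = max(order, 1L))
  if (order == 0L) x <- x[, 0, drop = FALSE]
  nuisanceRegress(ts, x, addIntercept = TRUE)
}

#' Root-mean-square framewise displacement
#'
#' Framewise displacement at frame t (t >= 2) is the sum of absolute
#' backward differences of the three translations plus `headRadius` times
#' the sum of absolute backward differences of the three rotations
#' (small-angle arc length on a sphere of `headRadius` mm). Summarized as
#' the root mean square over frames; the plain mean is available via
#' `summary = "mean"`.
#'
#' @param motion numeric matrix, time x 6 (tx,ty,tz mm; rx,ry,rz rad).
#' @param headRadius rotation-to-displacement lever arm in mm (default 50).
#' @param summary `"rms"` (default) or `"mean"`.
#' @return scalar displacement summary in mm.
#' @export
rmsFramewiseDisplacement <- function(motion, headRadius = 50,
                                     summary = c("rms", "mean")) {
  summary <- match.arg(summary)
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stop("'motion' must have 6 columns")
  if (nrow(motion) < 2L) stop("need at least 2 timepoints for displacement")
  d <- abs(diff(motion))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    headRadius * rowSums(d[, 4:6, drop = FALSE])
  if (summary == "rms") sqrt(mean(fd^2)) else mean(fd)
}

#' Run the standard temporal preprocessing chain
#'
#' Applies, in order: initial-volume discard, global-mean intensity
#' normalization, nuisance regression (Friston-24 expansion of the motion
#' parameters plus any tissue signals), ideal band-pass filtering, and
#' polynomial detrending. Any stage can be disabled through its parameter.
#'
#' @param ts a [SubjectTimeseries-class] (pre-discard length).
#' @param motion numeric matrix, time x 6, same pre-discard length as `ts`
#'   (the first `nDiscard` rows are dropped alongside the volumes). NULL
#'   skips motion regression.
#' @param tissue optional numeric matrix (time x k) of tissue-mean nuisance
#'   signals (e.g. white matter and CSF), pre-discard length.
#' @param nDiscard initial volumes to drop (default 5).
#' @param normTarget global-mean target (default 10000); NA skips.
#' @param fLow,fHigh band-pass edges in Hz (defaults 0.01, 0.1); NA skips.
#' @param detrendOrder polynomial order (default 2); negative skips.
#' @param useFriston24 expand motion to 24 regressors (default TRUE);
#'   FALSE uses the 6 raw parameters.
#' @return list with `ts` (the preprocessed [SubjectTimeseries-class]),
#'   `rmsFD` (scalar, from post-discard motion), and `nNuisance`.
#' @export
preprocessTimeseries <- function(ts, motion = NULL, tissue = NULL,
                                 nDiscard = 5L, normTarget = 10000,
                                 fLow = 0.01, fHigh = 0.1,
                                 detrendOrder = 2L, useFriston24 = TRUE) {
  out <- discardInitial(ts, nDiscard)
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) == ncol(tsMatrix(ts))) {
      motion <- motion[-seq_len(nDiscard), , drop = FALSE]
    } else if (nrow(motion) != ncol(tsMatrix(out))) {
      stop("motion length matches neither pre- nor post-discard series")
    }
  }
  if (!is.null(tissue)) {
    tissue <- as.matrix(tissue)
    if (nrow(tissue) == ncol(tsMatrix(ts))) {
      tissue <- tissue[-seq_len(nDiscard), , drop = FALSE]
    }
  }
  if (!is.na(normTarget)) out <- globalMeanNormalize(out, normTarget)
  nuis <- NULL
  if (!is.null(motion)) {
    nuis <- if (useFriston24) friston24(motion) else motion
  }
  if (!is.null(tissue)) {
    colnames(tissue) <- paste0("tissue", seq_len(ncol(tissue)))
    nuis <- if (is.null(nuis)) tissue else cbind(nuis, tissue)
  }
  if (!is.null(nuis)) out <- nuisanceRegress(out, nuis)
  if (!is.na(fLow) && !is.na(fHigh)) out <- bandpassFilter(out, fLow, fHigh)
  if (detrendOrder >= 0L) out <- detrendPoly(out, detrendOrder)
  list(
    ts = out,
    rmsFD = if (is.null(motion)) NA_real_ else rmsFramewiseDisplacement(motion),
    nNuisance = if (is.null(nuis)) 0L else ncol(nuis)
  )
}
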