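# Vertex-wise two-sample GLM on regional-homogeneity maps with scalar and
# vertex-wise covariates, cluster-forming thresholding, and Freedman-Lane
# permutation cluster-extent correction.
#
# The engine avoids per-vertex lm() loops: for each vertex's design X_v it
# precomputes the contrast weight vector w_v (so the group coefficient is
# w_v'y), the contrast variance factor c_v = [(X_v'X_v)^-1]_gg, and an
# orthonormal basis Q_v of the column space (so the residual sum of squares
# is ||y||^2 - ||Q_v'y||^2). All per-permutation work is then elementwise
# matrix algebra across vertices.

# Precompute the fit machinery. xBase: n x pBase shared columns (intercept,
# group, scalar covariates); jac: optional n x V vertex-wise column;
# groupCol: index of the group column within the full design.
glmEngine <- function(xBase, jac = NULL, groupCol = 2L, nVertex = NULL) {
  n <- nrow(xBase)
  if (is.null(jac)) {
    qrx <- qr(xBase)
    if (qrx$rank < ncol(xBase)) {
      bad <- paste(colnames(xBase)[setdiff(
        seq_len(ncol(xBase)),
        qrx$pivot[seq_len(qrx$rank)]
      )], collapse = ", ")
      stop("rank-deficient design; collinear columns: ", bad)
    }
    cmat <- chol2inv(qr.R(qrx))   # (X'X)^-1 in pivoted order
    piv <- qrx$pivot
    cmat <- cmat[order(piv), order(piv), drop = FALSE]
    w <- xBase %*% cmat[, groupCol]
    list(
      shared = TRUE, n = n, p = ncol(xBase), df = n - ncol(xBase),
      q = qr.Q(qrx), w = as.numeric(w), ckk = cmat[groupCol, groupCol]
    )
  } else {
    v <- ncol(jac)
    p <- ncol(xBase) + 1L
    qArr <- array(0, dim = c(n, p, v))
    wMat <- matrix(0, n, v)
    ckk <- numeric(v)
    for (j in seq_len(v)) {
      x <- cbind(xBase, jac[, j])
      qrx <- qr(x)
      if (qrx$rank < p) {
        stop(sprintf("rank-deficient design at vertex %d", j))
      }
      cmat <- chol2inv(qr.R(qrx))
      piv <- qrx$pivot
      cmat <- cmat[order(piv), order(piv), drop = FALSE]
      qArr[, , j] <- qr.Q(qrx)
      wMat[, j] <- x %*% cmat[, groupCol]
      ckk[j] <- cmat[groupCol, groupCol]
    }
    list(
      shared = FALSE, n = n, p = p, df = n - p,
      qArr = qArr, wMat = wMat, ckk = ckk
    )
  }
}

# t statistic of the group contrast at every vertex for response matrix
# y (n subjects x V vertices).
engineT <- function(eng, y) {
  if (eng$shared) {
    num <- as.numeric(crossprod(eng$w, y))
    ssr <- colSums(y^2) - colSums(crossprod(eng$q, y)^2)
    ckk <- eng$ckk
  } else {
    num <- colSums(eng$wMat * y)
    fit2 <- 0
    for (j in seq_len(eng$p)) {
      # slice j of the basis across vertices: n x V
      fit2 <- fit2 + colSums(eng$qArr[, j, ] * y)^2
    }
    ssr <- colSums(y^2) - fit2
    ckk <- eng$ckk
  }
  sigma2 <- pmax(ssr, 0) / eng$df
  num / sqrt(pmax(sigma2 * ckk, .Machine$double.xmin))
}

# Fitted values of the reduced (covariate-only) model for every vertex.
engineFitted <- function(eng, y) {
  if (eng$shared) {
    eng$q %*% crossprod(eng$q, y)
  } else {
    fit <- matrix(0, eng$n, ncol(y))
    for (j in seq_len(eng$p)) {
      qj <- eng$qArr[, j, ]
      fit <- fit + qj * matrix(colSums(qj * y), eng$n, ncol(y), byrow = TRUE)
    }
    fit
  }
}

assembleDesign <- function(group, covariates) {
  group <- as.numeric(group)
  n <- length(group)
  if (!all(group %in% c(0, 1))) stop("'group' must be coded 0/1")
  if (sum(group == 1) < 2L || sum(group == 0) < 2L) {
    stop("need at least 2 subjects per group")
  }
  x <- cbind(intercept = 1, group = group)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop("covariate rows must match subjects")
    if (is.null(colnames(covariates))) {
      colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
    }
    x <- cbind(x, covariates)
  }
  x
}

#' Vertex-wise covariate-adjusted two-sample GLM
#'
#' At each vertex, ordinary least squares of the regional-homogeneity values
#' on `[intercept, group, scalar covariates, vertex-wise covariate]`; the
#' returned t statistic is the group coefficient divided by its standard
#' error, with `df = n - p` and two-sided p from Student's t. With no
#' covariates this reduces exactly to the classical pooled two-sample
#' t-test at every vertex.
#'
#' @param reho numeric matrix, subjects x vertices, of per-vertex values
#'   (e.g. rows are `rehoValues()` of each subject's map).
#' @param group 0/1 vector (1 = expert group), length = subjects.
#' @param covariates optional subjects x k matrix of scalar covariates
#'   (gender, age, ICV, rmsFD, mcBBR, global ReHo, ...).
#' @param jac optional subjects x vertices matrix of a vertex-wise
#'   covariate (areal-distortion Jacobian maps).
#' @return list with `t`, `p` (two-sided), `coef` (group coefficient),
#'   and `df`.
#' @export
vertexGLM <- function(reho, group, covariates = NULL, jac = NULL) {
  reho <- as.matrix(reho)
  xBase <- assembleDesign(group, covariates)
  if (!is.null(jac)) {
    jac <- as.matrix(jac)
    stopifnot(dim(jac) == dim(reho))
  }
  eng <- glmEngine(xBase, jac)
  tstat <- engineT(eng, reho)
  # group coefficient itself (w'y)
  cf <- if (eng$shared) as.numeric(crossprod(eng$w, reho)) else
    colSums(eng$wMat * reho)
  list(
    t = tstat,
    p = 2 * stats::pt(abs(tstat), df = eng$df, lower.tail = FALSE),
    coef = cf,
    df = eng$df
  )
}

# Maximum suprathreshold cluster area over both signs.
maxSupraArea <- function(adj, area, tmap, tcrit) {
  best <- 0
  for (sgn in c(1, -1)) {
    mask <- (sgn * tmap) > tcrit
    if (!any(mask)) next
    lab <- maskComponents(adj, mask)
    sums <- tapply(area[lab > 0L], lab[lab > 0L], sum)
    best <- max(best, max(sums))
  }
  best
}

#' Cluster-extent corrected vertex-wise group comparison
#'
#' Thresholds the vertex-wise group t-map two-sided at `pVertex`
#' (separately for increases and decreases), forms edge-connected clusters,
#' and corrects their areas by a Freedman-Lane permutation scheme: the
#' maps are residualized against the reduced (covariate-only) model, the
#' residual rows are permuted `nPerm` times, the full model is refit, and
#' the null distribution of the maximum suprathreshold cluster area (over
#' both signs) is recorded. Each observed cluster gets
#' `pCorrected = (1 + #\{null max >= area\}) / (1 + nPerm)` and is flagged
#' significant when `pCorrected <= pCluster`.
#'
#' @inheritParams vertexGLM
#' @param mesh the [SurfaceMesh-class] the maps live on.
#' @param pVertex two-sided vertex-level cluster-forming threshold
#'   (default 0.01).
#' @param pCluster cluster-wise significance level (default 0.05).
#' @param nPerm number of permutations (>= 100; default 1000).
#' @param seed integer seed for the permutation stream.
#' @return list with `clusters` (data.frame: id, sign, nVertices, areaMm2,
#'   peakVertex, peakT, pCorrected, significant), `members` (list of vertex
#'   index vectors), `tMap`, `df`, `tCrit` and `nullMaxArea`.
#' @export
clusterCorrect <- function(reho, group, covariates = NULL, jac = NULL,
                           mesh, pVertex = 0.01, pCluster = 0.05,
                           nPerm = 1000L, seed = 1L) {
  if (nPerm < 100L) stop("'nPerm' must be >= 100")
  if (1 / (1 + nPerm) > pCluster) {
    warning("nPerm too small to resolve pCluster = ", pCluster)
  }
  reho <- as.matrix(reho)
  if (ncol(reho) != nVertices(mesh)) {
    stop("map width must equal the mesh vertex count")
  }
  xBase <- assembleDesign(group, covariates)
  if (!is.null(jac)) jac <- as.matrix(jac)
  full <- glmEngine(xBase, jac)
  hasCov <- ncol(xBase) > 2L
  reducedBase <- xBase[, -2L, drop = FALSE]
  reduced <- glmEngine(reducedBase, jac, groupCol = 1L)

  tObs <- engineT(full, reho)
  tcrit <- stats::qt(1 - pVertex / 2, df = full$df)
  adj <- meshAdjacency(mesh)
  area <- vertexArea(mesh)

  obs <- list()
  for (sgn in c(1, -1)) {
    mask <- (sgn * tObs) > tcrit
    for (cl in connectedClusters(mesh, mask)) {
      peak <- cl$members[which.max(abs(tObs[cl$members]))]
      obs[[length(obs) + 1L]] <- list(
        sign = sgn, members = cl$members, areaMm2 = cl$areaMm2,
        peakVertex = peak, peakT = tObs[peak]
      )
    }
  }

  fitted <- engineFitted(reduced, reho)
  resid <- reho - fitted
  n <- nrow(reho)
  nullMax <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(nPerm), function(b) {
      perm <- sample.int(n)
      tPerm <- engineT(full, fitted + resid[perm, , drop = FALSE])
      maxSupraArea(adj, area, tPerm, tcrit)
    }, numeric(1))
  })

  if (length(obs)) {
    areaObs <- vapply(obs, `[[`, numeric(1), "areaMm2")
    pCorr <- vapply(areaObs, function(a) {
      (1 + sum(nullMax >= a)) / (1 + nPerm)
    }, numeric(1))
    ord <- order(pCorr, -areaObs)
    obs <- obs[ord]
    pCorr <- pCorr[ord]
    clusters <- data.frame(
      id = seq_along(obs),
      sign = vapply(obs, `[[`, numeric(1), "sign"),
      nVertices = vapply(obs, function(o) length(o$members), integer(1)),
      areaMm2 = vapply(obs, `[[`, numeric(1), "areaMm2"),
      peakVertex = vapply(obs, `[[`, numeric(1), "peakVertex"),
      peakT = vapply(obs, `[[`, numeric(1), "peakT"),
      pCorrected = pCorr,
      significant = pCorr <= pCluster
    )
    members <- lapply(obs, `[[`, "members")
  } else {
    clusters <- data.frame(
      id = integer(), sign = numeric(), nVertices = integer(),
      areaMm2 = numeric(), peakVertex = numeric(), peakT = numeric(),
      pCorrected = numeric(), significant = logical()
    )
    members <- list()
  }
  list(
    clusters = clusters, members = members, tMap = tObs, df = full$df,
    tCrit = tcrit, nullMaxArea = nullMax, nPerm = nPerm, seed = seed,
    hasCovariates = hasCov
  )
}

#' Classical pooled two-sample t-test on per-subject scalars
#'
#' Pooled-variance two-sample t with `df = n1 + n2 - 2`; used for the
#' group comparison of global regional homogeneity and of demographic
#' scalars.
#'
#' @param values numeric vector, one scalar per subject.
#' @param group 0/1 vector; t is (mean of group 1) minus (mean of group 0)
#'   over the pooled standard error.
#' @return list with `t`, `df`, `p` (two-sided), `mean1`, `mean0`.
#' @export
scalarGroupTest <- function(values, group) {
  group <- as.numeric(group)
  x1 <- values[group == 1]
  x0 <- values[group == 0]
  n1 <- length(x1)
  n0 <- length(x0)
  if (n1 < 2L || n0 < 2L) stop("need at least 2 subjects per group")
  df <- n1 + n0 - 2L
  sp2 <- ((n1 - 1) * stats::var(x1) + (n0 - 1) * stats::var(x0)) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n0))
  tstat <- (mean(x1) - mean(x0)) / se
  list(
    t = tstat, df = df,
    p = 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE),
    mean1 = mean(x1), mean0 = mean(x0)
  )
}
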