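# Synthetic-cohort generator: mesh, per-vertex BOLD-like time series with
# plantable neighborhood-synchrony patches, motion random walks, tissue
# nuisance signals, areal-distortion (JAC) maps, group-matched covariates,
# practice history, and attention-network-test sessions whose conflict
# effect can be linked by construction to planted patch homogeneity.

subjectSeed <- function(seed, idx) {
  as.integer((as.numeric(seed) * 10007 + idx * 97) %% 2147483647)
}

#' Specify a synthetic cohort
#'
#' Collects every parameter of the generator with defaults emulating the
#' study design the pipeline targets: 22 experts and 18 controls, 243
#' volumes at TR = 2 s on a 642-vertex spherical surface, group-matched
#' demographic covariates, expert practice history (14.6 +/- 8.6 years,
#' 11.9 +/- 5.1 h/week, one injected >= 30 h/week outlier), and one planted
#' homogeneity increase plus two decreases in the expert group.
#'
#' Local synchrony is planted by signal mixing: inside a patch with weight
#' `lambda`, each vertex's series is
#' `sqrt(1 - lambda) * noise_v + sqrt(lambda) * shared_p`, so Kendall's W
#' rises monotonically with `lambda`. A patch with sign +1 is mixed in the
#' expert group only (homogeneity increase in experts), sign -1 in the
#' control group only (decrease in experts). The noise band (0.005-0.15 Hz,
#' pink-weighted) deliberately exceeds the 0.01-0.1 Hz analysis band so the
#' band-pass stage does observable work.
#'
#' @param seed master integer seed; every per-subject stream is derived
#'   from it, so a cohort is a pure function of its spec.
#' @param nExperts,nControls group sizes (defaults 22, 18).
#' @param subdivisions icosphere subdivisions (default 3: 642 vertices).
#' @param radius mesh radius, mm (default 100).
#' @param nTimepoints pre-discard series length (default 243).
#' @param tr sampling interval, s (default 2).
#' @param patches data.frame with columns `center`, `ring`, `sign`
#'   (+1 expert increase / -1 expert decrease), `lambda`; NULL for none.
#'   Default: one +1 patch and two -1 patches of ring 2, lambda 0.5.
#' @param globalSynchronyMean,globalSynchronySd each subject draws a global
#'   mixing weight (truncated to [0, 0.35]) with which one subject-specific
#'   shared signal is mixed into every vertex. This reproduces the
#'   between-subject spread of global homogeneity seen in real cohorts
#'   (without it, global means are almost deterministic and any planted
#'   patch makes the global group test spuriously significant on a
#'   desk-scale mesh). Defaults 0.12 and 0.05.
#' @param noiseBand length-2 Hz band of the subject noise (0.005-0.15).
#' @param pinkExponent spectral power falls as `1/f^pinkExponent` within
#'   the noise band (default 1, pink).
#' @param baselineOffset additive raw-intensity offset (default 10000).
#' @param tissueWeight amplitude of the two shared tissue nuisance signals
#'   leaked into every vertex, as a fraction of the noise SD (default 0.3).
#' @param motionStep,rotationStep random-walk step SDs (mm, rad).
#' @param ageMean,ageSd,maleProb,educationMean,educationSd,icvMean,icvSd
#'   length-2 vectors, expert then control group.
#' @param mcbbrMean,mcbbrSd registration-cost distribution (both groups).
#' @param practiceYearsMean,practiceYearsSd,practiceHoursMean,practiceHoursSd
#'   expert practice history distributions (truncated at 1).
#' @param injectOutlier plant one expert at `outlierHours` h/week
#'   (default TRUE, mirroring the one heavy practitioner the exclusion rule
#'   targets).
#' @param outlierHours the planted outlier load (default 32).
#' @param baselineRtMs,conflictMs shifted-lognormal RT location and the
#'   population conflict effect (defaults 300 ms shift + lognormal around
#'   300 ms; conflict 80 ms).
#' @param rtSigma lognormal sigma of per-trial RT noise (default 0.3).
#' @param conflictSdMs between-subject SD of the conflict effect around its
#'   linked mean (default 10 ms).
#' @param linkCoef ms of conflict effect per unit of (group-centered)
#'   linked-patch ReHo; negative plants "higher homogeneity, smaller
#'   conflict" (default -300).
#' @param linkPatch index into `patches` of the patch driving behavior
#'   (default: first sign +1 patch, NA if none).
#' @param errorRates named error probabilities per target condition.
#' @return a `CohortSpec` list (validated).
#' @export
cohortSpec <- function(seed = 1L,
                       nExperts = 22L, nControls = 18L,
                       subdivisions = 3L, radius = 100,
                       nTimepoints = 243L, tr = 2,
                       patches = data.frame(
                         center = c(100L, 300L, 500L),
                         ring = c(2L, 2L, 2L),
                         sign = c(1, -1, -1),
                         lambda = c(0.5, 0.5, 0.5)
                       ),
                       globalSynchronyMean = 0.12, globalSynchronySd = 0.05,
                       noiseBand = c(0.005, 0.15), pinkExponent = 1,
                       baselineOffset = 10000, tissueWeight = 0.3,
                       motionStep = 0.03, rotationStep = 5e-4,
                       ageMean = c(52.4, 54.8), ageSd = c(6.8, 6.8),
                       maleProb = c(7 / 22, 8 / 18),
                       educationMean = c(12.2, 11.8),
                       educationSd = c(2.9, 2.9),
                       icvMean = c(1.11, 1.12), icvSd = c(0.17, 0.22),
                       mcbbrMean = 0.6, mcbbrSd = 0.08,
                       practiceYearsMean = 14.6, practiceYearsSd = 8.6,
                       practiceHoursMean = 11.9, practiceHoursSd = 5.1,
                       injectOutlier = TRUE, outlierHours = 32,
                       baselineRtMs = 300, conflictMs = 80,
                       rtSigma = 0.3, conflictSdMs = 10,
                       linkCoef = -300, linkPatch = NULL,
                       errorRates = c(
                         congruent = 0.005, incongruent = 0.02,
                         neutral = 0.005
                       )) {
  spec <- as.list(environment())
  if (spec$nExperts < 3L || spec$nControls < 3L) {
    stop("need at least 3 subjects per group")
  }
  nv <- 10 * 4^spec$subdivisions + 2
  if (missing(patches) && nv < 502L) {
    # default centers assume the 642-vertex mesh; spread them over smaller ones
    spec$patches$center <- as.integer(round(nv * c(100, 300, 500) / 642))
  }
  if (!is.null(spec$patches) && nrow(spec$patches)) {
    p <- spec$patches
    if (any(p$lambda < 0 | p$lambda > 1)) stop("patch lambda must be in [0, 1]")
    if (any(p$center < 1 | p$center > nv)) stop("patch center outside mesh")
    if (!all(p$sign %in% c(-1, 1))) stop("patch sign must be +1 or -1")
    if (is.null(spec$linkPatch)) {
      inc <- which(p$sign == 1)
      spec$linkPatch <- if (length(inc)) inc[[1L]] else NA_integer_
    }
  } else {
    spec$patches <- NULL
    spec$linkPatch <- NA_integer_
  }
  if (spec$nTimepoints < 20L) stop("need at least 20 timepoints")
  class(spec) <- "CohortSpec"
  spec
}

#' @export
print.CohortSpec <- function(x, ...) {
  cat(sprintf(
    "CohortSpec: %d experts + %d controls, %d vertices, %d timepoints @ TR %g s, %d patch(es), seed %d\n",
    x$nExperts, x$nControls, 10 * 4^x$subdivisions + 2, x$nTimepoints,
    x$tr, if (is.null(x$patches)) 0L else nrow(x$patches), x$seed
  ))
  invisible(x)
}

# Band-limited pink-weighted Gaussian noise, one unit-variance series per
# row. White noise is shaped in the Fourier domain, which keeps the series
# Gaussian and exactly band-limited.
bandLimitedNoise <- function(nSeries, nt, tr, band, pinkExponent = 1) {
  white <- matrix(stats::rnorm(nSeries * nt), nSeries, nt)
  k <- seq_len(nt) - 1L
  freq <- pmin(k, nt - k) / (nt * tr)
  wgt <- ifelse(freq >= band[[1L]] & freq <= band[[2L]] & freq > 0,
    freq^(-pinkExponent / 2), 0
  )
  spec <- t(stats::mvfft(t(white))) * rep(wgt, each = nSeries)
  x <- Re(t(stats::mvfft(t(spec), inverse = TRUE))) / nt
  x / apply(x, 1L, stats::sd)
}

# Bounded random walk via a triangle-wave reflection of the free walk.
boundedWalk <- function(nt, step, bound) {
  raw <- cumsum(stats::rnorm(nt, 0, step))
  r <- (raw + bound) %% (4 * bound)
  ifelse(r < 2 * bound, r - bound, 3 * bound - r)
}

# Per-vertex mixing weights for one group. Patches apply to the expert
# group when sign = +1 and to the control group when sign = -1.
lambdaMap <- function(spec, mesh, group) {
  nv <- nVertices(mesh)
  lam <- rep(0, nv)
  patch <- rep(NA_integer_, nv)
  if (is.null(spec$patches)) return(list(lambda = lam, patch = patch))
  for (i in seq_len(nrow(spec$patches))) {
    p <- spec$patches[i, ]
    active <- (p$sign == 1 && group == 1) || (p$sign == -1 && group == 0)
    members <- kRingNeighborhood(mesh, p$center, p$ring)$members
    patch[members] <- i
    if (active) lam[members] <- p$lambda
  }
  list(lambda = lam, patch = patch)
}

#' Generate one subject's raw data
#'
#' Emits the pre-discard vertex-by-time series (noise mixed with planted
#' patch signals, plus leaked tissue signals and the baseline intensity
#' offset), the 6-parameter motion random walk, the two tissue signals, and
#' a smooth areal-distortion (JAC) map near 1.
#'
#' @param spec a [cohortSpec()].
#' @param mesh the cohort [SurfaceMesh-class].
#' @param group 0 (control) or 1 (expert).
#' @param seed integer seed for this subject.
#' @param subjectId identifier.
#' @return list with `ts` ([SubjectTimeseries-class]), `motion`
#'   (time x 6), `tissue` (time x 2), `jac` (numeric per vertex).
#' @export
generateSubjectTimeseries <- function(spec, mesh, group, seed,
                                      subjectId = "subject") {
  nv <- nVertices(mesh)
  nt <- spec$nTimepoints
  lmap <- lambdaMap(spec, mesh, group)
  withr::with_seed(as.integer(seed), {
    noise <- bandLimitedNoise(nv, nt, spec$tr, spec$noiseBand,
      spec$pinkExponent)
    nPatch <- if (is.null(spec$patches)) 0L else nrow(spec$patches)
    shared <- if (nPatch) {
      bandLimitedNoise(nPatch, nt, spec$tr, spec$noiseBand, spec$pinkExponent)
    } else NULL
    lam <- lmap$lambda
    # subject-level global synchrony: one shared signal mixed everywhere,
    # capped so total mixing never exceeds 1 inside strong patches
    lamG <- 0
    if (spec$globalSynchronyMean > 0 || spec$globalSynchronySd > 0) {
      lamG <- min(max(stats::rnorm(1, spec$globalSynchronyMean,
        spec$globalSynchronySd), 0), 0.35)
    }
    lamGv <- pmin(lamG, 1 - lam)
    gShared <- if (lamG > 0) {
      bandLimitedNoise(1L, nt, spec$tr, spec$noiseBand, spec$pinkExponent)
    } else matrix(0, 1L, nt)
    data <- sqrt(1 - lam - lamGv) * noise +
      sqrt(lamGv) * matrix(gShared, nv, nt, byrow = TRUE)
    inPatch <- which(lam > 0)
    if (length(inPatch)) {
      data[inPatch, ] <- data[inPatch, , drop = FALSE] +
        sqrt(lam[inPatch]) * shared[lmap$patch[inPatch], , drop = FALSE]
    }
    tissue <- t(bandLimitedNoise(2L, nt, spec$tr, spec$noiseBand,
      spec$pinkExponent))
    data <- data + spec$tissueWeight * matrix(rowSums(tissue), nv, nt,
      byrow = TRUE)
    data <- data + spec$baselineOffset
    motion <- cbind(
      boundedWalk(nt, spec$motionStep, 1),
      boundedWalk(nt, spec$motionStep, 1),
      boundedWalk(nt, spec$motionStep, 1),
      boundedWalk(nt, spec$rotationStep, 0.02),
      boundedWalk(nt, spec$rotationStep, 0.02),
      boundedWalk(nt, spec$rotationStep, 0.02)
    )
    colnames(motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")
    # smooth areal-distortion field near 1
    z <- stats::rnorm(nv)
    adjacency <- meshAdjacency(mesh)
    for (it in 1:3) {
      nbMean <- vapply(adjacency, function(nb) mean(z[nb]), numeric(1))
      z <- (z + nbMean) / 2
    }
    jac <- unname(1 + 0.05 * (z - mean(z)) / stats::sd(z))
    list(
      ts = SubjectTimeseries(data, tr = spec$tr, subjectId = subjectId),
      motion = motion, tissue = tissue, jac = jac
    )
  })
}

truncNorm <- function(n, mean, sd, lower = -Inf) {
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
    bad <- which(x < lower)
  }
  x
}

#' Generate one attention-network-test session
#'
#' One 24-trial training block (block 0) plus three 96-trial test blocks:
#' each block is balanced over the 12 cue-by-target cells and presented in
#' random order. RTs are shifted-lognormal with cue and target offsets;
#' the subject's conflict effect is `conflictMs` (pass the linked value for
#' behavior-homogeneity coupling). RTs are capped at the 1700 ms response
#' window; errors occur at small condition-dependent rates.
#'
#' @param spec a [cohortSpec()].
#' @param seed integer seed.
#' @param conflictMs this subject's incongruent-congruent RT offset, ms.
#' @param subjectId identifier.
#' @param noiseless logical; TRUE suppresses per-trial RT noise and errors
#'   (round-trip checks).
#' @return data.frame: subject_id, block, cue, target, rt_ms, correct.
#' @export
generateANTSession <- function(spec, seed, conflictMs = spec$conflictMs,
                               subjectId = "subject", noiseless = FALSE) {
  cueOffset <- c(none = 45, center = 40, double = 5, spatial = 0)
  targetOffset <- c(congruent = 0, incongruent = conflictMs, neutral = -10)
  cells <- expand.grid(
    cue = antCues, target = antTargets,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  oneBlock <- function(block, perCell) {
    idx <- rep(seq_len(nrow(cells)), each = perCell)
    idx <- sample(idx)
    data.frame(
      subject_id = subjectId, block = block,
      cue = cells$cue[idx], target = cells$target[idx],
      stringsAsFactors = FALSE
    )
  }
  withr::with_seed(as.integer(seed), {
    trials <- rbind(
      oneBlock(0L, 2L),
      oneBlock(1L, 8L), oneBlock(2L, 8L), oneBlock(3L, 8L)
    )
    n <- nrow(trials)
    lognorm <- if (noiseless) {
      rep(exp(log(spec$baselineRtMs)), n)
    } else {
      stats::rlnorm(n, meanlog = log(spec$baselineRtMs), sdlog = spec$rtSigma)
    }
    rt <- spec$baselineRtMs + cueOffset[trials$cue] +
      targetOffset[trials$target] + lognorm
    trials$rt_ms <- pmin(as.numeric(rt), 1700)
    errp <- spec$errorRates[trials$target]
    trials$correct <- if (noiseless) rep(TRUE, n) else
      stats::runif(n) > as.numeric(errp)
    rownames(trials) <- NULL
    trials
  })
}

#' Generate a complete synthetic cohort
#'
#' Draws group-matched covariates, per-subject imaging data (series, motion,
#' tissue signals, JAC map) and ANT sessions. The behavior link works in two
#' passes: each subject's realized mean ReHo over the linked patch is
#' computed first (ring-2 Kendall's W on the raw series), group-centered,
#' and then drives the subject's conflict effect through `linkCoef`, so a
#' negative link plants "higher patch homogeneity, faster conflict
#' resolution" within each group without shifting group means.
#'
#' @param spec a [cohortSpec()].
#' @param mesh optional prebuilt [SurfaceMesh-class] (must match the spec's
#'   subdivisions); built when NULL.
#' @param withBehavior generate ANT sessions (default TRUE).
#' @return list with `spec`, `mesh`, `manifest` (data.frame: subject_id,
#'   group, age, gender, education, icv, mcbbr, practice_years,
#'   practice_hours), `subjects` (per-subject lists: ts, motion, tissue,
#'   jac, trials, patchReho), and `patchMembers` (list of vertex sets).
#' @export
generateCohort <- function(spec, mesh = NULL, withBehavior = TRUE) {
  if (is.null(mesh)) mesh <- buildIcosphere(spec$subdivisions, spec$radius)
  nE <- spec$nExperts
  nC <- spec$nControls
  n <- nE + nC
  group <- c(rep(1L, nE), rep(0L, nC))
  gi <- ifelse(group == 1L, 1L, 2L) # index into (expert, control) vectors
  manifest <- withr::with_seed(subjectSeed(spec$seed, 0L), {
    data.frame(
      subject_id = sprintf("sub%03d", seq_len(n)),
      group = group,
      age = round(truncNorm(n, spec$ageMean[gi], spec$ageSd[gi], 18), 1),
      gender = stats::rbinom(n, 1L, spec$maleProb[gi]),
      education = round(truncNorm(n, spec$educationMean[gi],
        spec$educationSd[gi], 1), 1),
      icv = round(truncNorm(n, spec$icvMean[gi], spec$icvSd[gi], 0.5), 3),
      mcbbr = round(truncNorm(n, spec$mcbbrMean, spec$mcbbrSd, 0.1), 3),
      practice_years = ifelse(group == 1L,
        round(truncNorm(n, spec$practiceYearsMean, spec$practiceYearsSd, 1), 1),
        NA_real_),
      practice_hours = ifelse(group == 1L,
        round(truncNorm(n, spec$practiceHoursMean, spec$practiceHoursSd, 1), 1),
        NA_real_),
      stringsAsFactors = FALSE
    )
  })
  if (spec$injectOutlier && nE > 0L) {
    # deterministic choice: the expert whose drawn load was already highest
    heavy <- which.max(manifest$practice_hours[seq_len(nE)])
    manifest$practice_hours[heavy] <- spec$outlierHours
  }
  subjects <- vector("list", n)
  linkedMembers <- NULL
  if (!is.na(spec$linkPatch)) {
    p <- spec$patches[spec$linkPatch, ]
    linkedMembers <- kRingNeighborhood(mesh, p$center, p$ring)$members
  }
  nbh <- if (!is.null(linkedMembers)) {
    lapply(linkedMembers, function(v) kRingNeighborhood(mesh, v, 2L)$members)
  } else NULL
  patchReho <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    s <- generateSubjectTimeseries(spec, mesh, group[i],
      seed = subjectSeed(spec$seed, i), subjectId = manifest$subject_id[i]
    )
    if (!is.null(nbh)) {
      y <- tsMatrix(s$ts)
      patchReho[i] <- mean(vapply(nbh, function(m) {
        kendallsW(y[m, , drop = FALSE])
      }, numeric(1)))
    }
    subjects[[i]] <- s
  }
  if (withBehavior) {
    centered <- patchReho
    if (!is.na(spec$linkPatch)) {
      for (g in c(0L, 1L)) {
        sel <- group == g
        centered[sel] <- patchReho[sel] - mean(patchReho[sel])
      }
    } else {
      centered <- rep(0, n)
    }
    for (i in seq_len(n)) {
      delta <- withr::with_seed(subjectSeed(spec$seed, n + i), {
        spec$conflictMs + spec$linkCoef * centered[i] +
          stats::rnorm(1, 0, spec$conflictSdMs)
      })
      subjects[[i]]$trials <- generateANTSession(
        spec, subjectSeed(spec$seed, 2L * n + i),
        conflictMs = delta, subjectId = manifest$subject_id[i]
      )
      subjects[[i]]$plantedConflictMs <- delta
    }
  }
  for (i in seq_len(n)) subjects[[i]]$patchReho <- patchReho[i]
  patchMembers <- if (is.null(spec$patches)) list() else {
    lapply(seq_len(nrow(spec$patches)), function(i) {
      kRingNeighborhood(mesh, spec$patches$center[i], spec$patches$ring[i])$members
    })
  }
  list(
    spec = spec, mesh = mesh, manifest = manifest, subjects = subjects,
    patchMembers = patchMembers
  )
}

#' Simulate per-subject scalars with a planted partial correlation
#'
#' Draws demographic covariates (gender, age, education) and two outcome
#' variables whose residual parts, after the linear covariate effects, are
#' bivariate normal with correlation `rho` — so the population partial
#' correlation of `x` and `y` given the covariates is exactly `rho`.
#' Used to calibrate [partialCorrelation()] at realistic sample sizes.
#'
#' @param n subjects.
#' @param rho planted partial correlation in (-1, 1).
#' @param seed integer seed.
#' @return data.frame: subject_id, gender, age, education, x, y.
#' @export
generateAssociationSample <- function(n, rho, seed) {
  stopifnot(abs(rho) < 1)
  withr::with_seed(as.integer(seed), {
    gender <- stats::rbinom(n, 1L, 0.5)
    age <- stats::rnorm(n, 53, 7)
    education <- stats::rnorm(n, 12, 3)
    ex <- stats::rnorm(n)
    ey <- rho * ex + sqrt(1 - rho^2) * stats::rnorm(n)
    data.frame(
      subject_id = sprintf("sub%03d", seq_len(n)),
      gender = gender, age = age, education = education,
      x = 0.01 * age + 0.2 * gender + 0.03 * education + ex,
      y = -0.02 * age + 0.1 * gender - 0.01 * education + ey
    )
  })
}

#' Write a cohort to a self-contained directory
#'
#' Emits every file the pipeline consumes: `mesh.off`, `manifest.csv`,
#' per-subject `ts_<id>.tsv`, `motion_<id>.tsv`, `tissue_<id>.tsv`,
#' `jac_<id>.tsv`, `ant_<id>.csv`, and a `spec.yaml` echo of the scalar
#' generator settings.
#'
#' @param cohort result of [generateCohort()].
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeOFF(cohort$mesh, file.path(dir, "mesh.off"))
  write.csv(cohort$manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    id <- cohort$manifest$subject_id[i]
    writeTimeseriesTSV(s$ts, file.path(dir, sprintf("ts_%s.tsv", id)))
    writeMotionTSV(s$motion, file.path(dir, sprintf("motion_%s.tsv", id)))
    tis <- as.data.frame(s$tissue)
    names(tis) <- c("wm", "csf")
    write.table(tis, file.path(dir, sprintf("tissue_%s.tsv", id)),
      sep = "\t", quote = FALSE, row.names = FALSE)
    writeVertexScalarTSV(s$jac, file.path(dir, sprintf("jac_%s.tsv", id)),
      name = "jac")
    if (!is.null(s$trials)) {
      write.csv(s$trials, file.path(dir, sprintf("ant_%s.csv", id)),
        row.names = FALSE)
    }
  }
  scal <- cohort$spec[vapply(cohort$spec, function(v) {
    is.numeric(v) || is.character(v) || is.logical(v)
  }, logical(1))]
  yaml::write_yaml(scal, file.path(dir, "spec.yaml"))
  invisible(dir)
}
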