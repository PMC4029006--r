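# End-to-end orchestration: preprocess -> reho -> group inference ->
# behavior -> association, on an in-memory cohort or a cohort directory.

#' Pipeline configuration
#'
#' All tunable parameters of [runPipeline()] with their conventional
#' defaults: discard 5 volumes, normalize the grand mean to 10,000, regress
#' the Friston-24 motion expansion plus tissue signals, band-pass
#' 0.01-0.1 Hz, detrend up to the quadratic, ring-2 (19-series)
#' neighborhoods, vertex threshold p = 0.01 and cluster threshold p = 0.05.
#'
#' @param nDiscard,normTarget,fLow,fHigh,detrendOrder,useFriston24
#'   preprocessing parameters (see [preprocessTimeseries()]).
#' @param ring neighborhood order for [rehoMap()].
#' @param pVertex,pCluster,nPerm,seed inference parameters (see
#'   [clusterCorrect()]).
#' @param covariates scalar covariate columns entered into the vertex-wise
#'   model (besides the vertex-wise JAC map and the derived rmsFD and
#'   global-ReHo columns).
#' @param associationCovariates covariates for the partial correlations.
#' @param hoursThreshold practice-hours exclusion threshold (see
#'   [applyTransformsAndOutliers()]).
#' @param doBehavior,doAssociation stage toggles.
#' @return a named list of settings.
#' @export
pipelineConfig <- function(nDiscard = 5L, normTarget = 10000,
                           fLow = 0.01, fHigh = 0.1, detrendOrder = 2L,
                           useFriston24 = TRUE, ring = 2L,
                           pVertex = 0.01, pCluster = 0.05,
                           nPerm = 1000L, seed = 1L,
                           covariates = c("gender", "age", "icv", "mcbbr"),
                           associationCovariates = c("gender", "age", "education"),
                           hoursThreshold = 30,
                           doBehavior = TRUE, doAssociation = TRUE) {
  as.list(environment())
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the [pipelineConfig()]
#' defaults.
#'
#' @param path YAML file.
#' @return a config list.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipelineConfig))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(pipelineConfig, y)
}

#' Read a cohort directory written by [writeCohort()]
#'
#' @param dir cohort directory.
#' @param tr sampling interval for the series, seconds.
#' @return a cohort list (mesh, manifest, subjects) as from
#'   [generateCohort()] (without the generator's bookkeeping fields).
#' @export
readCohort <- function(dir, tr = 2) {
  mesh <- readOFF(file.path(dir, "mesh.off"))
  manifest <- read.csv(file.path(dir, "manifest.csv"),
    stringsAsFactors = FALSE)
  subjects <- lapply(seq_len(nrow(manifest)), function(i) {
    id <- manifest$subject_id[i]
    s <- list(
      ts = readTimeseriesTSV(file.path(dir, sprintf("ts_%s.tsv", id)),
        tr = tr, subjectId = id),
      motion = readMotionTSV(file.path(dir, sprintf("motion_%s.tsv", id))),
      jac = readVertexScalarTSV(file.path(dir, sprintf("jac_%s.tsv", id)))
    )
    tisPath <- file.path(dir, sprintf("tissue_%s.tsv", id))
    if (file.exists(tisPath)) {
      s$tissue <- as.matrix(read.table(tisPath, header = TRUE, sep = "\t",
        comment.char = "#"))
    }
    antPath <- file.path(dir, sprintf("ant_%s.csv", id))
    if (file.exists(antPath)) {
      s$trials <- read.csv(antPath, stringsAsFactors = FALSE)
    }
    s
  })
  list(mesh = mesh, manifest = manifest, subjects = subjects)
}

#' Run the full analysis pipeline
#'
#' Stages, in fixed order: temporal preprocessing of every subject (with
#' rmsFD extraction), per-subject ring-2 regional-homogeneity maps and
#' global means, the global-ReHo group test, vertex-wise covariate-adjusted
#' group inference with cluster-extent permutation correction, ANT conflict
#' scoring, and partial-correlation associations between the significant
#' clusters' mean ReHo and practice/behavior variables within the expert
#' group (with the practice-hours outlier exclusion and log-transformed
#' practice hours).
#'
#' @param cohort a cohort list from [generateCohort()]/[readCohort()], or a
#'   cohort directory path.
#' @param config a [pipelineConfig()] list.
#' @param outDir optional output directory; when given, stage outputs
#'   (reho maps, scores, clusters, associations, summary JSON) are written.
#' @return list with `rehoMatrix` (subjects x vertices), `globalReho`,
#'   `rmsFD`, `globalTest`, `inference` (see [clusterCorrect()]),
#'   `behavior` (per-subject scores), `associations`, `manifest`, `config`.
#' @export
runPipeline <- function(cohort, config = pipelineConfig(), outDir = NULL) {
  if (is.character(cohort)) cohort <- readCohort(cohort)
  mesh <- cohort$mesh
  manifest <- cohort$manifest
  n <- nrow(manifest)

  # --- preprocess + reho -------------------------------------------------
  nbh <- neighborhoodMatrix(mesh, config$ring)
  rehoMatrix <- matrix(NA_real_, n, nVertices(mesh))
  globalReho <- numeric(n)
  rmsFD <- numeric(n)
  jac <- matrix(NA_real_, n, nVertices(mesh))
  for (i in seq_len(n)) {
    s <- cohort$subjects[[i]]
    pre <- preprocessTimeseries(s$ts,
      motion = s$motion, tissue = s$tissue,
      nDiscard = config$nDiscard, normTarget = config$normTarget,
      fLow = config$fLow, fHigh = config$fHigh,
      detrendOrder = config$detrendOrder,
      useFriston24 = config$useFriston24
    )
    map <- rehoMap(pre$ts, mesh, ring = config$ring, neighborhoods = nbh)
    rehoMatrix[i, ] <- rehoValues(map)
    globalReho[i] <- map@globalMean
    rmsFD[i] <- pre$rmsFD
    jac[i, ] <- s$jac
  }

  # --- scalar + vertex-wise group inference ------------------------------
  globalTest <- scalarGroupTest(globalReho, manifest$group)
  covNames <- intersect(config$covariates, names(manifest))
  covs <- as.matrix(manifest[, covNames, drop = FALSE])
  covs <- cbind(covs, rmsfd = rmsFD, global_reho = globalReho)
  inference <- clusterCorrect(rehoMatrix, manifest$group,
    covariates = covs, jac = jac, mesh = mesh,
    pVertex = config$pVertex, pCluster = config$pCluster,
    nPerm = config$nPerm, seed = config$seed
  )

  # --- behavior ----------------------------------------------------------
  behavior <- NULL
  if (config$doBehavior &&
    any(vapply(cohort$subjects, function(s) !is.null(s$trials), logical(1)))) {
    rows <- lapply(seq_len(n), function(i) {
      tr <- cohort$subjects[[i]]$trials
      if (is.null(tr)) return(NULL)
      sc <- scoreConflict(tr)
      data.frame(
        subject_id = manifest$subject_id[i],
        rt_conflict_ms = sc$rtConflictMs,
        rt_conflict_ratio = sc$rtConflictRatio,
        acc_conflict = sc$accConflict,
        mean_rt = sc$meanRt, accuracy = sc$accuracy
      )
    })
    behavior <- do.call(rbind, rows)
  }

  # --- associations ------------------------------------------------------
  associations <- NULL
  sig <- which(inference$clusters$significant)
  if (config$doAssociation && length(sig)) {
    tab <- manifest
    if (!is.null(behavior)) tab <- merge(tab, behavior, by = "subject_id")
    experts <- tab[tab$group == 1L, , drop = FALSE]
    rowOf <- match(experts$subject_id, manifest$subject_id)
    assoc <- list()
    for (ci in sig) {
      members <- inference$members[[ci]]
      experts$cluster_reho <- rowMeans(
        rehoMatrix[rowOf, members, drop = FALSE])
      pairs <- data.frame(
        x = "cluster_reho",
        y = c("practice_years", "practice_hours",
          if (!is.null(behavior)) "rt_conflict_ratio"),
        log_x = FALSE,
        log_y = c(FALSE, TRUE, if (!is.null(behavior)) FALSE)
      )
      at <- associationTable(experts, pairs,
        covariates = config$associationCovariates,
        hoursThreshold = config$hoursThreshold
      )
      at <- cbind(cluster = ci, sign = inference$clusters$sign[ci], at)
      assoc[[length(assoc) + 1L]] <- at
    }
    associations <- do.call(rbind, assoc)
  }

  result <- list(
    rehoMatrix = rehoMatrix, globalReho = globalReho, rmsFD = rmsFD,
    globalTest = globalTest, inference = inference, behavior = behavior,
    associations = associations, manifest = manifest, config = config
  )

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(n)) {
      map <- new("ReHoMap",
        values = rehoMatrix[i, ], globalMean = mean(rehoMatrix[i, ]),
        ring = as.integer(config$ring), subjectId = manifest$subject_id[i]
      )
      writeReHoMap(map, file.path(outDir,
        sprintf("reho_%s.tsv", manifest$subject_id[i])))
    }
    write.table(inference$clusters, file.path(outDir, "clusters.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(behavior)) {
      write.table(behavior, file.path(outDir, "behavior_scores.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(associations)) {
      write.table(associations, file.path(outDir, "associations.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    summary <- list(
      settings = config[vapply(config, function(v)
        is.numeric(v) || is.character(v) || is.logical(v), logical(1))],
      n_subjects = n,
      n_experts = sum(manifest$group == 1L),
      global_reho = list(
        mean_experts = mean(globalReho[manifest$group == 1L]),
        mean_controls = mean(globalReho[manifest$group == 0L]),
        t = globalTest$t, df = globalTest$df, p = globalTest$p
      ),
      clusters = inference$clusters,
      versions = list(
        package = as.character(utils::packageVersion("ReHoSurf")),
        r = paste(R.version$major, R.version$minor, sep = ".")
      )
    )
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  result
}
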