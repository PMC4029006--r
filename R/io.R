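# Readers and writers for the plain-text interchange formats the pipeline
# consumes: OFF / FreeSurfer-ASCII meshes, TSV matrices and scalar maps,
# motion tables, cohort manifests and trial tables.

#' Read an ASCII OFF mesh
#'
#' Standard Object File Format: an `OFF` header line, a counts line
#' (`nVertices nFaces nEdges`), vertex coordinate lines, then face lines
#' beginning with the vertex count (3) followed by 0-based indices.
#'
#' @param path file path.
#' @return a [SurfaceMesh-class].
#' @export
readOFF <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!identical(toupper(lines[[1L]]), "OFF")) {
    stop("not an OFF file (missing OFF header): ", path)
  }
  counts <- as.integer(strsplit(lines[[2L]], "\\s+")[[1L]])
  nv <- counts[[1L]]
  nf <- counts[[2L]]
  vlines <- lines[3:(2L + nv)]
  flines <- lines[(3L + nv):(2L + nv + nf)]
  coords <- matrix(
    as.numeric(unlist(strsplit(vlines, "\\s+"), use.names = FALSE)),
    nrow = nv, ncol = 3L, byrow = TRUE
  )
  ftok <- matrix(
    as.integer(unlist(strsplit(flines, "\\s+"), use.names = FALSE)),
    nrow = nf, byrow = TRUE
  )
  if (any(ftok[, 1L] != 3L)) stop("only triangle faces are supported")
  SurfaceMesh(coords, ftok[, 2:4, drop = FALSE], zeroBased = TRUE)
}

#' Write a mesh as ASCII OFF
#'
#' @param mesh a [SurfaceMesh-class].
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
writeOFF <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nVertices(mesh), nFaces(mesh)), con)
  writeLines(apply(vertexCoords(mesh), 1L, function(v) {
    paste(format(v, trim = TRUE, digits = 17), collapse = " ")
  }), con)
  f0 <- meshFaces(mesh) - 1L
  writeLines(paste(3L, f0[, 1L], f0[, 2L], f0[, 3L]), con)
  invisible(path)
}

#' Read a FreeSurfer ASCII surface (.asc)
#'
#' The format produced by `mris_convert surf surf.asc`: an optional `#!ascii`
#' comment line, a `nVertices nFaces` counts line, vertex lines `x y z 0`,
#' then face lines of three 0-based indices and a trailing 0.
#'
#' @param path file path.
#' @return a [SurfaceMesh-class].
#' @export
readFreeSurferAscii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  counts <- as.integer(strsplit(lines[[1L]], "\\s+")[[1L]])
  nv <- counts[[1L]]
  nf <- counts[[2L]]
  vtok <- matrix(
    as.numeric(unlist(strsplit(lines[2:(1L + nv)], "\\s+"), use.names = FALSE)),
    nrow = nv, byrow = TRUE
  )
  ftok <- matrix(
    as.integer(unlist(strsplit(lines[(2L + nv):(1L + nv + nf)], "\\s+"),
      use.names = FALSE
    )),
    nrow = nf, byrow = TRUE
  )
  SurfaceMesh(vtok[, 1:3, drop = FALSE], ftok[, 1:3, drop = FALSE],
    zeroBased = TRUE
  )
}

#' Read / write a per-vertex time-series matrix
#'
#' TSV with a header row `t0 ... t{N-1}`; one row per vertex.
#'
#' @param path file path.
#' @param tr sampling interval in seconds.
#' @param subjectId subject identifier.
#' @return [readTimeseriesTSV()]: a [SubjectTimeseries-class];
#'   [writeTimeseriesTSV()]: `path`, invisibly.
#' @export
readTimeseriesTSV <- function(path, tr = 2, subjectId = "subject") {
  m <- as.matrix(read.table(path, header = TRUE, sep = "\t",
    comment.char = "#", check.names = FALSE))
  dimnames(m) <- NULL
  SubjectTimeseries(m, tr = tr, subjectId = subjectId)
}

#' @rdname readTimeseriesTSV
#' @param ts a [SubjectTimeseries-class].
#' @export
writeTimeseriesTSV <- function(ts, path) {
  m <- tsMatrix(ts)
  colnames(m) <- paste0("t", seq_len(ncol(m)) - 1L)
  write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a single-column per-vertex scalar map
#'
#' TSV with one named header line and one value per vertex row.
#'
#' @param path file path.
#' @return [readVertexScalarTSV()]: numeric vector.
#' @export
readVertexScalarTSV <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  as.numeric(d[[1L]])
}

#' @rdname readVertexScalarTSV
#' @param values numeric vector.
#' @param name column name for the header line.
#' @export
writeVertexScalarTSV <- function(values, path, name = "value") {
  d <- data.frame(v = as.numeric(values))
  names(d) <- name
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a six-parameter motion table
#'
#' TSV with columns `tx,ty,tz` (mm) and `rx,ry,rz` (radians), one row per
#' timepoint; a leading `#` comment line states the units.
#'
#' @param path file path.
#' @return [readMotionTSV()]: numeric matrix with the six named columns.
#' @export
readMotionTSV <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  m <- as.matrix(d[, c("tx", "ty", "tz", "rx", "ry", "rz")])
  storage.mode(m) <- "double"
  m
}

#' @rdname readMotionTSV
#' @param motion numeric matrix, 6 columns.
#' @export
writeMotionTSV <- function(motion, path) {
  colnames(motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# translations mm, rotations radians", con)
  suppressWarnings(write.table(as.data.frame(motion), con,
    sep = "\t", quote = FALSE, row.names = FALSE))
  invisible(path)
}

#' Write a regional-homogeneity map with its JSON sidecar
#'
#' The per-vertex values go to a single-column TSV; subject id, ring and
#' global mean go to `<path>.json`.
#'
#' @param map a [ReHoMap-class].
#' @param path TSV destination.
#' @return `path`, invisibly.
#' @export
writeReHoMap <- function(map, path) {
  writeVertexScalarTSV(rehoValues(map), path, name = "reho")
  side <- list(
    subject_id = subjectID(map),
    ring = map@ring,
    global_mean = map@globalMean
  )
  jsonlite::write_json(side, paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a regional-homogeneity map written by [writeReHoMap()]
#' @param path TSV path (sidecar `<path>.json` must exist).
#' @return a [ReHoMap-class].
#' @export
readReHoMap <- function(path) {
  values <- readVertexScalarTSV(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new("ReHoMap",
    values = values, globalMean = mean(values),
    ring = as.integer(side$ring), subjectId = as.character(side$subject_id)
  )
}
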