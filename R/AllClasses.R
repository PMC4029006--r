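#' @import methods
#' @importFrom Matrix sparseMatrix rowSums colSums t
#' @importFrom stats rnorm runif rbinom fft pt sd var cor coef lm qt quantile
#'   rlnorm median complete.cases setNames
#' @importFrom utils read.csv read.table write.csv write.table head
NULL

#' Triangle mesh representing a cortical surface
#'
#' A closed (or open) triangle mesh used as the spatial substrate for
#' neighborhood-based regional homogeneity and for cluster-extent inference.
#' Vertex areas follow the barycentric lumping convention: each vertex owns
#' one third of the area of every incident triangle, so vertex areas sum
#' exactly to the total surface area.
#'
#' @slot coords numeric matrix, one row per vertex, columns x/y/z in mm.
#' @slot faces integer matrix, one row per triangle, 1-based vertex indices.
#' @slot vertexArea numeric vector, mm^2 per vertex.
#' @slot adjacency list of integer vectors; `adjacency[[v]]` holds the sorted
#'   indices of vertices sharing an edge with `v`.
#'
#' @seealso [buildIcosphere()], [readOFF()], [kRingNeighborhood()]
#' @export
setClass("SurfaceMesh",
  representation(
    coords = "matrix",
    faces = "matrix",
    vertexArea = "numeric",
    adjacency = "list"
  )
)

setValidity("SurfaceMesh", function(object) {
  msg <- character()
  nv <- nrow(object@coords)
  if (ncol(object@coords) != 3L) msg <- c(msg, "coords must have 3 columns")
  if (ncol(object@faces) != 3L) msg <- c(msg, "faces must have 3 columns")
  f <- object@faces
  if (length(f) && (min(f) < 1L || max(f) > nv)) {
    msg <- c(msg, "face indices out of vertex range")
  }
  if (!all(tabulate(f, nbins = nv) >= 1L)) {
    msg <- c(msg, "every vertex must belong to at least one face")
  }
  if (length(object@vertexArea) != nv) {
    msg <- c(msg, "vertexArea length must equal vertex count")
  } else if (any(object@vertexArea <= 0)) {
    msg <- c(msg, "all vertex areas must be positive")
  }
  if (length(object@adjacency) != nv) {
    msg <- c(msg, "adjacency length must equal vertex count")
  }
  if (length(msg)) msg else TRUE
})

#' Per-vertex BOLD-like time series for one subject
#'
#' Holds a vertex-by-time real matrix together with the sampling interval
#' (repetition time, seconds) and a subject identifier. This is the input to
#' the temporal preprocessing stages and to [rehoMap()].
#'
#' @slot data numeric matrix, rows = vertices, columns = timepoints.
#' @slot tr numeric scalar, sampling interval in seconds.
#' @slot subjectId character scalar.
#'
#' @export
setClass("SubjectTimeseries",
  representation(data = "matrix", tr = "numeric", subjectId = "character")
)

setValidity("SubjectTimeseries", function(object) {
  msg <- character()
  if (!is.numeric(object@data)) msg <- c(msg, "data must be numeric")
  if (!all(is.finite(object@data))) msg <- c(msg, "data must be finite")
  if (nrow(object@data) < 2L) msg <- c(msg, "need at least 2 vertices")
  if (length(object@tr) != 1L || object@tr <= 0) {
    msg <- c(msg, "tr must be a positive scalar")
  }
  if (length(msg)) msg else TRUE
})

#' Per-vertex regional homogeneity map
#'
#' Kendall's W computed over each vertex's neighborhood time series, together
#' with the global (unweighted) mean over the surface.
#'
#' @slot values numeric vector of per-vertex concordance values in [0, 1].
#' @slot globalMean numeric scalar, arithmetic mean of `values`.
#' @slot ring integer, the neighborhood ring order used.
#' @slot subjectId character scalar.
#'
#' @export
setClass("ReHoMap",
  representation(
    values = "numeric",
    globalMean = "numeric",
    ring = "integer",
    subjectId = "character"
  )
)

setValidity("ReHoMap", function(object) {
  msg <- character()
  v <- object@values
  if (!length(v)) msg <- c(msg, "values must be non-empty")
  if (any(v < -1e-12 | v > 1 + 1e-12)) {
    msg <- c(msg, "all values must lie in [0, 1]")
  }
  if (abs(object@globalMean - mean(v)) > 1e-12) {
    msg <- c(msg, "globalMean must equal mean(values)")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn SurfaceMesh-class number of vertices
#' @param object,x a `SurfaceMesh`
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))

#' @rdname SurfaceMesh-class
#' @export
setMethod("nVertices", "SurfaceMesh", function(x) nrow(x@coords))

#' @rdname SurfaceMesh-class
#' @export
setGeneric("nFaces", function(x) standardGeneric("nFaces"))

#' @rdname SurfaceMesh-class
#' @export
setMethod("nFaces", "SurfaceMesh", function(x) nrow(x@faces))

#' @rdname SurfaceMesh-class
#' @export
setGeneric("vertexCoords", function(x) standardGeneric("vertexCoords"))

#' @rdname SurfaceMesh-class
#' @export
setMethod("vertexCoords", "SurfaceMesh", function(x) x@coords)

#' @rdname SurfaceMesh-class
#' @export
setGeneric("meshFaces", function(x) standardGeneric("meshFaces"))

#' @rdname SurfaceMesh-class
#' @export
setMethod("meshFaces", "SurfaceMesh", function(x) x@faces)

#' @rdname SurfaceMesh-class
#' @export
setGeneric("vertexArea", function(x) standardGeneric("vertexArea"))

#' @rdname SurfaceMesh-class
#' @export
setMethod("vertexArea", "SurfaceMesh", function(x) x@vertexArea)

#' @rdname SurfaceMesh-class
#' @export
setGeneric("meshAdjacency", function(x) standardGeneric("meshAdjacency"))

#' @rdname SurfaceMesh-class
#' @export
setMethod("meshAdjacency", "SurfaceMesh", function(x) x@adjacency)

setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf(
    "SurfaceMesh: %d vertices, %d faces, total area %.2f mm^2\n",
    nVertices(object), nFaces(object), sum(object@vertexArea)
  ))
})

#' @rdname SubjectTimeseries-class
#' @param x a `SubjectTimeseries`
#' @export
setGeneric("tsMatrix", function(x) standardGeneric("tsMatrix"))

#' @rdname SubjectTimeseries-class
#' @export
setMethod("tsMatrix", "SubjectTimeseries", function(x) x@data)

#' @rdname SubjectTimeseries-class
#' @export
setGeneric("repetitionTime", function(x) standardGeneric("repetitionTime"))

#' @rdname SubjectTimeseries-class
#' @export
setMethod("repetitionTime", "SubjectTimeseries", function(x) x@tr)

#' @rdname SubjectTimeseries-class
#' @export
setGeneric("subjectID", function(x) standardGeneric("subjectID"))

#' @rdname SubjectTimeseries-class
#' @export
setMethod("subjectID", "SubjectTimeseries", function(x) x@subjectId)

#' @rdname ReHoMap-class
#' @export
setMethod("subjectID", "ReHoMap", function(x) x@subjectId)

setMethod("show", "SubjectTimeseries", function(object) {
  cat(sprintf(
    "SubjectTimeseries '%s': %d vertices x %d timepoints, TR = %g s\n",
    object@subjectId, nrow(object@data), ncol(object@data), object@tr
  ))
})

#' @rdname ReHoMap-class
#' @param x,object a `ReHoMap`
#' @export
setGeneric("rehoValues", function(x) standardGeneric("rehoValues"))

#' @rdname ReHoMap-class
#' @export
setMethod("rehoValues", "ReHoMap", function(x) x@values)

setMethod("show", "ReHoMap", function(object) {
  cat(sprintf(
    "ReHoMap '%s': %d vertices, ring %d, global mean %.4f\n",
    object@subjectId, length(object@values), object@ring, object@globalMean
  ))
})

#' Construct a SubjectTimeseries
#'
#' @param data numeric matrix, rows = vertices, columns = timepoints.
#' @param tr sampling interval in seconds (default 2, the usual EPI TR).
#' @param subjectId identifier string.
#' @return a [SubjectTimeseries-class] object.
#' @export
SubjectTimeseries <- function(data, tr = 2, subjectId = "subject") {
  new("SubjectTimeseries",
    data = as.matrix(data), tr = as.numeric(tr),
    subjectId = as.character(subjectId)
  )
}
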