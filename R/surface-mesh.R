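# Mesh geometry: construction, neighborhoods, clustering.

triangleAreas <- function(coords, faces) {
  a <- coords[faces[, 1L], , drop = FALSE]
  b <- coords[faces[, 2L], , drop = FALSE]
  c_ <- coords[faces[, 3L], , drop = FALSE]
  u <- b - a
  v <- c_ - a
  cx <- u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L]
  cy <- u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L]
  cz <- u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

buildAdjacency <- function(nv, faces) {
  # undirected edge list from the three sides of every triangle
  e <- rbind(faces[, c(1L, 2L)], faces[, c(2L, 3L)], faces[, c(3L, 1L)])
  lo <- pmin(e[, 1L], e[, 2L])
  hi <- pmax(e[, 1L], e[, 2L])
  keep <- !duplicated(lo * (nv + 1) + hi)
  lo <- lo[keep]
  hi <- hi[keep]
  adj <- split(c(hi, lo), factor(c(lo, hi), levels = seq_len(nv)))
  adj <- lapply(adj, function(x) sort.int(unique(x)))
  names(adj) <- NULL
  adj
}

#' Create a SurfaceMesh from vertices and faces
#'
#' Computes vertex areas (one third of the summed incident triangle areas)
#' and the edge-adjacency structure used by neighborhood extraction and
#' clustering.
#'
#' @param coords numeric matrix of vertex coordinates (n x 3, mm).
#' @param faces matrix of triangles; 1-based vertex index triples by default.
#' @param zeroBased logical; set `TRUE` when `faces` uses 0-based indices
#'   (as in OFF files).
#' @return a [SurfaceMesh-class] object.
#' @export
SurfaceMesh <- function(coords, faces, zeroBased = FALSE) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (zeroBased) faces <- faces + 1L
  nv <- nrow(coords)
  if (length(faces) && (min(faces) < 1L || max(faces) > nv)) {
    stop("face indices out of vertex range")
  }
  if (!all(tabulate(faces, nbins = nv) >= 1L)) {
    stop("every vertex must belong to at least one face")
  }
  triArea <- triangleAreas(coords, faces)
  va <- rep(0, nv)
  for (j in 1:3) {
    inc <- tapply(triArea, factor(faces[, j], levels = seq_len(nv)), sum)
    inc[is.na(inc)] <- 0
    va <- va + as.numeric(inc)
  }
  va <- va / 3
  new("SurfaceMesh",
    coords = coords, faces = faces, vertexArea = va,
    adjacency = buildAdjacency(nv, faces)
  )
}

#' Build a subdivided icosahedral sphere mesh
#'
#' Starts from the regular icosahedron and applies `subdivisions` rounds of
#' 1-to-4 triangle subdivision, projecting every vertex onto the sphere of
#' the requested radius. The result is a closed 2-manifold with
#' `10 * 4^subdivisions + 2` vertices, of which exactly 12 have valence 5 and
#' the rest valence 6 — the same local structure as the standard spherical
#' cortical-surface templates it stands in for.
#'
#' @param subdivisions integer >= 0 (and <= 6 to stay desk-scale).
#' @param radius sphere radius in mm (default 100, roughly cortical scale).
#' @return a [SurfaceMesh-class] object.
#' @examples
#' mesh <- buildIcosphere(2)
#' nVertices(mesh) # 162
#' @export
buildIcosphere <- function(subdivisions, radius = 100) {
  if (length(subdivisions) != 1L || is.na(subdivisions) || subdivisions < 0 ||
    subdivisions != round(subdivisions)) {
    stop("'subdivisions' must be a non-negative integer")
  }
  if (subdivisions > 6) {
    stop("'subdivisions' must be <= 6")
  }
  phi <- (1 + sqrt(5)) / 2
  verts <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  faces <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(subdivisions)) {
    nv <- nrow(verts)
    nf <- nrow(faces)
    # midpoint of each unique edge becomes one new vertex
    midIndex <- new.env(hash = TRUE, size = 4L * nf)
    midOf <- function(i, j) {
      key <- if (i < j) paste0(i, "_", j) else paste0(j, "_", i)
      idx <- midIndex[[key]]
      if (is.null(idx)) {
        verts <<- rbind(verts, (verts[i, ] + verts[j, ]) / 2)
        idx <- nrow(verts)
        midIndex[[key]] <- idx
      }
      idx
    }
    newFaces <- matrix(0L, nrow = 4L * nf, ncol = 3L)
    for (f in seq_len(nf)) {
      v1 <- faces[f, 1L]; v2 <- faces[f, 2L]; v3 <- faces[f, 3L]
      a <- midOf(v1, v2); b <- midOf(v2, v3); c_ <- midOf(v3, v1)
      newFaces[4L * f - 3L, ] <- c(v1, a, c_)
      newFaces[4L * f - 2L, ] <- c(v2, b, a)
      newFaces[4L * f - 1L, ] <- c(v3, c_, b)
      newFaces[4L * f, ] <- c(a, b, c_)
    }
    faces <- newFaces
    verts <- verts / sqrt(rowSums(verts^2))
  }
  verts <- verts / sqrt(rowSums(verts^2)) * radius
  SurfaceMesh(verts, faces)
}

#' Extract the k-ring graph neighborhood of a vertex
#'
#' Breadth-first search over the mesh edge graph: the neighborhood contains
#' the center and every vertex reachable within `ring` edges. On a regular
#' (valence-6) region of a subdivided icosphere the 2-ring holds
#' 1 + 6 + 12 = 19 vertices — the neighborhood size used for surface
#' regional homogeneity; at the 12 valence-5 apices it holds 16.
#'
#' Members are returned ring by ring, in ascending vertex index within each
#' ring, so the ordering is deterministic.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param center 1-based vertex index.
#' @param ring neighborhood order, integer >= 1.
#' @return list with elements `center`, `members` (integer vector including
#'   the center first) and `ring`.
#' @export
kRingNeighborhood <- function(mesh, center, ring = 2L) {
  nv <- nVertices(mesh)
  if (length(center) != 1L || center < 1L || center > nv) {
    stop("'center' must be a valid vertex index")
  }
  if (ring < 1L) stop("'ring' must be >= 1")
  adj <- mesh@adjacency
  if (!length(adj[[center]])) {
    stop(sprintf("vertex %d is isolated (no incident edges)", center))
  }
  seen <- logical(nv)
  seen[center] <- TRUE
  members <- as.integer(center)
  frontier <- as.integer(center)
  for (r in seq_len(ring)) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[!seen[nxt]]
    if (!length(nxt)) break
    nxt <- sort.int(nxt)
    seen[nxt] <- TRUE
    members <- c(members, nxt)
    frontier <- nxt
  }
  list(center = as.integer(center), members = members, ring = as.integer(ring))
}

#' Neighborhood membership for every vertex as a sparse indicator
#'
#' Internal workhorse behind [rehoMap()]: a sparse nv x nv 0/1 matrix whose
#' row v marks the members of the k-ring neighborhood of v.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param ring neighborhood order.
#' @return list with `indicator` (sparse dgCMatrix) and `size` (integer
#'   members per vertex).
#' @export
neighborhoodMatrix <- function(mesh, ring = 2L) {
  nv <- nVertices(mesh)
  memb <- lapply(seq_len(nv), function(v) kRingNeighborhood(mesh, v, ring)$members)
  sizes <- lengths(memb)
  ind <- Matrix::sparseMatrix(
    i = rep.int(seq_len(nv), sizes),
    j = unlist(memb, use.names = FALSE),
    x = 1,
    dims = c(nv, nv)
  )
  list(indicator = ind, size = as.integer(sizes))
}

# Connected components of a masked vertex set over a precomputed adjacency
# list; returns an integer label per masked vertex position (0 = unmasked).
maskComponents <- function(adj, mask) {
  nv <- length(mask)
  label <- integer(nv)
  nextLab <- 0L
  for (v in which(mask)) {
    if (label[v]) next
    nextLab <- nextLab + 1L
    queue <- v
    label[v] <- nextLab
    while (length(queue)) {
      u <- queue[[1L]]
      queue <- queue[-1L]
      nb <- adj[[u]]
      nb <- nb[mask[nb] & label[nb] == 0L]
      if (length(nb)) {
        label[nb] <- nextLab
        queue <- c(queue, nb)
      }
    }
  }
  label
}

#' Connected clusters of a vertex mask
#'
#' Maximal edge-connected components of the masked vertices, each reported
#' with its member set and summed vertex area. This is the cluster-defining
#' step for cluster-extent correction.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param mask logical vector, one entry per vertex.
#' @return list of clusters, each a list with `members` (integer vector) and
#'   `areaMm2`. Empty mask gives an empty list.
#' @export
connectedClusters <- function(mesh, mask) {
  if (length(mask) != nVertices(mesh)) {
    stop("'mask' length must equal the vertex count")
  }
  mask <- as.logical(mask)
  lab <- maskComponents(mesh@adjacency, mask)
  ids <- setdiff(unique(lab), 0L)
  lapply(ids, function(k) {
    members <- which(lab == k)
    list(members = members, areaMm2 = sum(mesh@vertexArea[members]))
  })
}
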