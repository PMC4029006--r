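test_that("icosphere construction yields the expected counts and valences", {
  m0 <- fixtureMesh(0)
  expect_equal(nVertices(m0), 12L)
  expect_equal(nFaces(m0), 20L)
  for (s in c(2L, 3L)) {
    m <- fixtureMesh(s)
    expect_equal(nVertices(m), 10L * 4L^s + 2L)
    expect_equal(nFaces(m), 20L * 4L^s)
    valence <- lengths(meshAdjacency(m))
    expect_equal(sum(valence == 5L), 12L)
    expect_true(all(valence %in% c(5L, 6L)))
    # barycentric vertex areas partition the surface area exactly
    expect_equal(sum(vertexArea(m)),
      sum(ReHoSurf:::triangleAreas(vertexCoords(m), meshFaces(m))),
      tolerance = 1e-9
    )
  }
  expect_error(buildIcosphere(-1), "non-negative")
  expect_error(buildIcosphere(7), "<= 6")
})

test_that("k-ring neighborhoods have the expected sizes and structure", {
  m <- fixtureMesh(3)
  valence <- lengths(meshAdjacency(m))
  regular <- which(valence == 6L)[[1L]]
  apex <- which(valence == 5L)[[1L]]
  expect_length(kRingNeighborhood(m, regular, 1L)$members, 7L)
  expect_length(kRingNeighborhood(m, regular, 2L)$members, 19L)
  expect_length(kRingNeighborhood(m, apex, 2L)$members, 16L)
  nb <- kRingNeighborhood(m, regular, 2L)
  expect_identical(nb$members[[1L]], regular)
  expect_false(any(duplicated(nb$members)))
  # ring monotonicity: the 1-ring is a strict subset of the 2-ring
  r1 <- kRingNeighborhood(m, regular, 1L)$members
  expect_true(all(r1 %in% nb$members) && length(r1) < length(nb$members))
  expect_error(kRingNeighborhood(m, 0L, 2L), "valid vertex")
  expect_error(kRingNeighborhood(m, 1L, 0L), "ring")
})

test_that("neighborhood membership is symmetric across all vertex pairs", {
  for (s in c(1L, 2L)) {
    for (ring in c(1L, 2L)) {
      ind <- neighborhoodMatrix(fixtureMesh(s), ring)$indicator
      expect_true(all(ind == Matrix::t(ind)))
    }
  }
})

test_that("connected clusters partition the masked vertices", {
  m <- fixtureMesh(2)
  nv <- nVertices(m)
  expect_identical(connectedClusters(m, rep(FALSE, nv)), list())
  one <- rep(FALSE, nv)
  one[[5L]] <- TRUE
  cl <- connectedClusters(m, one)
  expect_length(cl, 1L)
  expect_equal(cl[[1L]]$areaMm2, vertexArea(m)[[5L]])
  # two masked vertices not sharing an edge form two clusters
  far <- rep(FALSE, nv)
  far[c(1L, 80L)] <- TRUE
  expect_false(80L %in% meshAdjacency(m)[[1L]])
  expect_length(connectedClusters(m, far), 2L)
  # random masks: every masked vertex in exactly one cluster, areas add up
  set.seed(11)
  for (i in 1:5) {
    mask <- runif(nv) < 0.2
    cl <- connectedClusters(m, mask)
    members <- unlist(lapply(cl, `[[`, "members"))
    expect_setequal(members, which(mask))
    expect_false(any(duplicated(members)))
    expect_equal(sum(vapply(cl, `[[`, numeric(1), "areaMm2")),
      sum(vertexArea(m)[mask]))
  }
  expect_error(connectedClusters(m, TRUE), "length")
})

test_that("OFF and FreeSurfer-ASCII round trips preserve the mesh", {
  m <- fixtureMesh(1)
  off <- withr::local_tempfile(fileext = ".off")
  writeOFF(m, off)
  m2 <- readOFF(off)
  expect_equal(vertexCoords(m2), vertexCoords(m))
  expect_equal(meshFaces(m2), meshFaces(m))
  expect_equal(vertexArea(m2), vertexArea(m))
  # FreeSurfer ASCII: counts line, "x y z 0" vertex rows, "i j k 0" faces
  asc <- withr::local_tempfile(fileext = ".asc")
  writeLines(c(
    "#!ascii version of a tiny surface",
    paste(nVertices(m), nFaces(m)),
    apply(vertexCoords(m), 1, function(v) paste(c(v, 0), collapse = " ")),
    apply(meshFaces(m) - 1L, 1, function(f) paste(c(f, 0), collapse = " "))
  ), asc)
  m3 <- readFreeSurferAscii(asc)
  expect_equal(vertexCoords(m3), vertexCoords(m))
  expect_equal(meshFaces(m3), meshFaces(m))
})

test_that("SurfaceMesh validity catches malformed inputs", {
  expect_error(
    SurfaceMesh(matrix(rnorm(9), 3), rbind(c(1, 2, 4))),
    "out of vertex range"
  )
  expect_error(
    SurfaceMesh(matrix(rnorm(12), 4), rbind(c(1, 2, 3))),
    "at least one face"
  )
})
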