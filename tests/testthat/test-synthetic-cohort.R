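smallSpec <- function(patches = NULL, nTimepoints = 60, ...) {
  cohortSpec(nExperts = 3, nControls = 3, subdivisions = 2,
    nTimepoints = nTimepoints, patches = patches, ...)
}

test_that("subject generation is a pure function of its seed", {
  mesh <- fixtureMesh(2)
  spec <- smallSpec(patches = data.frame(center = 10L, ring = 2L,
    sign = 1, lambda = 0.5))
  a <- generateSubjectTimeseries(spec, mesh, group = 1, seed = 99L)
  b <- generateSubjectTimeseries(spec, mesh, group = 1, seed = 99L)
  expect_identical(tsMatrix(a$ts), tsMatrix(b$ts))
  expect_identical(a$motion, b$motion)
  expect_identical(a$jac, b$jac)
  c_ <- generateSubjectTimeseries(spec, mesh, group = 1, seed = 100L)
  expect_false(identical(tsMatrix(a$ts), tsMatrix(c_$ts)))
})

test_that("planted mixing drives neighborhood concordance monotonically", {
  mesh <- fixtureMesh(2)
  center <- which(lengths(meshAdjacency(mesh)) == 6L)[[1L]]
  nbh <- kRingNeighborhood(mesh, center, 2L)$members
  meanW <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(lam) {
    spec <- smallSpec(
      nTimepoints = 120, tissueWeight = 0,
      globalSynchronyMean = 0, globalSynchronySd = 0,
      patches = if (lam > 0) {
        data.frame(center = center, ring = 2L, sign = 1, lambda = lam)
      } else NULL
    )
    mean(vapply(1:4, function(i) {
      s <- generateSubjectTimeseries(spec, mesh, group = 1, seed = 200L + i)
      kendallsW(tsMatrix(s$ts)[nbh, ])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(meanW) > 0))
  expect_lt(abs(meanW[[1L]] - 1 / 19), 0.04) # independence null
  expect_gt(meanW[[5L]], 0.95)               # shared-signal limit
})

test_that("cohorts carry the demographic structure and injected outlier", {
  spec <- cohortSpec(nExperts = 22, nControls = 18, subdivisions = 2,
    nTimepoints = 24, patches = NULL)
  # spec rejects bad patch/lambda settings
  expect_error(cohortSpec(patches = data.frame(center = 1L, ring = 2L,
    sign = 1, lambda = 1.5)), "lambda")
  expect_error(cohortSpec(nExperts = 0), "at least 3")
  coh <- generateCohort(spec, mesh = fixtureMesh(2), withBehavior = FALSE)
  man <- coh$manifest
  expect_equal(nrow(man), 40L)
  expect_equal(sum(man$group == 1), 22L)
  expect_true(all(is.na(man$practice_hours[man$group == 0])))
  expect_equal(sum(man$practice_hours >= 30, na.rm = TRUE), 1L)
  expect_true(all(man$age > 18))
  expect_true(all(man$gender %in% 0:1))
  # same spec twice: identical cohort
  coh2 <- generateCohort(spec, mesh = fixtureMesh(2), withBehavior = FALSE)
  expect_identical(man, coh2$manifest)
  expect_identical(
    tsMatrix(coh$subjects[[5]]$ts),
    tsMatrix(coh2$subjects[[5]]$ts)
  )
})

test_that("behavior link couples conflict effects to patch homogeneity", {
  mesh <- fixtureMesh(2)
  spec <- cohortSpec(nExperts = 12, nControls = 3, subdivisions = 2,
    nTimepoints = 100, seed = 3,
    patches = data.frame(center = 10L, ring = 2L, sign = 1, lambda = 0.5),
    linkCoef = -500, conflictSdMs = 1)
  coh <- generateCohort(spec, mesh = mesh)
  experts <- which(coh$manifest$group == 1)
  reho <- vapply(coh$subjects[experts], `[[`, numeric(1), "patchReho")
  planted <- vapply(coh$subjects[experts], `[[`, numeric(1),
    "plantedConflictMs")
  expect_lt(cor(reho, planted), -0.9) # strong negative link, tiny noise
})

test_that("cohort directories round-trip through write and read", {
  spec <- smallSpec(patches = NULL, nTimepoints = 30)
  coh <- generateCohort(spec, mesh = fixtureMesh(2))
  dir <- withr::local_tempdir()
  writeCohort(coh, dir)
  expect_true(file.exists(file.path(dir, "mesh.off")))
  expect_true(file.exists(file.path(dir, "spec.yaml")))
  back <- readCohort(dir)
  expect_equal(back$manifest$subject_id, coh$manifest$subject_id)
  expect_equal(back$manifest$practice_hours, coh$manifest$practice_hours)
  expect_equal(nVertices(back$mesh), nVertices(coh$mesh))
  expect_equal(
    tsMatrix(back$subjects[[2]]$ts), tsMatrix(coh$subjects[[2]]$ts),
    tolerance = 1e-6
  )
  expect_equal(back$subjects[[3]]$jac, coh$subjects[[3]]$jac,
    tolerance = 1e-6)
  expect_equal(nrow(back$subjects[[1]]$trials),
    nrow(coh$subjects[[1]]$trials))
})

test_that("reho and motion summaries land in realistic ranges", {
  mesh <- fixtureMesh(2)
  spec <- smallSpec(nTimepoints = 243)
  s <- generateSubjectTimeseries(spec, mesh, group = 0, seed = 77L)
  fd <- rmsFramewiseDisplacement(s$motion)
  expect_gt(fd, 0.02)
  expect_lt(fd, 0.5)
  expect_true(all(s$jac > 0.7 & s$jac < 1.3))
  expect_gt(mean(tsMatrix(s$ts)), 9000) # positive raw intensity offset
})
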