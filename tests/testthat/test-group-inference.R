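test_that("vertex GLM without covariates equals the pooled two-sample t", {
  set.seed(21)
  n <- 20
  y <- matrix(rnorm(n * 162), n, 162)
  g <- rep(c(1, 0), each = 10)
  fit <- vertexGLM(y, g)
  oracle <- apply(y, 2, function(col) {
    t.test(col[g == 1], col[g == 0], var.equal = TRUE)$statistic
  })
  expect_equal(fit$t, unname(oracle), tolerance = 1e-10)
  expect_equal(fit$df, n - 2L)
})

test_that("vertex GLM with a vertex-wise covariate matches lm at every vertex", {
  set.seed(22)
  n <- 14
  V <- 50
  y <- matrix(rnorm(n * V), n, V)
  g <- rep(c(1, 0), each = 7)
  covs <- cbind(age = rnorm(n, 50, 5), gender = rbinom(n, 1, 0.5))
  jac <- matrix(1 + 0.05 * rnorm(n * V), n, V)
  fit <- vertexGLM(y, g, covs, jac)
  oracle <- vapply(seq_len(V), function(j) {
    summary(lm(y[, j] ~ g + covs + jac[, j]))$coefficients["g", "t value"]
  }, numeric(1))
  expect_equal(fit$t, oracle, tolerance = 1e-8)
  expect_equal(fit$df, n - 5L)
})

test_that("degenerate designs are rejected with informative errors", {
  set.seed(23)
  y <- matrix(rnorm(10 * 5), 10, 5)
  g <- rep(c(1, 0), each = 5)
  expect_error(vertexGLM(y, g, covariates = cbind(dup = g)), "collinear")
  expect_error(vertexGLM(y, rep(1, 10)), "per group")
  expect_error(vertexGLM(y, c(2, g[-1])), "0/1")
})

test_that("a noiseless planted effect is recovered exactly", {
  set.seed(24)
  n <- 12
  V <- 30
  g <- rep(c(1, 0), each = 6)
  base <- matrix(rep(rnorm(V), each = n), n, V)
  delta <- 0.3
  y <- base + outer(g, rep(delta, V))
  fit <- vertexGLM(y, g)
  expect_equal(fit$coef, rep(delta, V), tolerance = 1e-12)
  expect_true(all(fit$t > 1e6))
})

test_that("cluster correction applies the add-one permutation formula", {
  mesh <- fixtureMesh(2)
  set.seed(25)
  n <- 16
  g <- rep(c(1, 0), each = 8)
  # strong planted patch so the observed cluster beats every permutation
  patch <- kRingNeighborhood(mesh, 40L, 2L)$members
  y <- matrix(rnorm(n * nVertices(mesh), sd = 0.1), n, nVertices(mesh))
  y[g == 1, patch] <- y[g == 1, patch] + 5
  cc <- clusterCorrect(y, g, mesh = mesh, nPerm = 100L, seed = 3L)
  top <- cc$clusters[1, ]
  expect_true(top$significant)
  expect_equal(top$pCorrected, 1 / 101, tolerance = 1e-12)
  expect_equal(top$sign, 1)
  expect_true(all(patch %in% cc$members[[1]]))
  expect_error(clusterCorrect(y, g, mesh = mesh, nPerm = 50L), ">= 100")
})

test_that("cluster correction is reproducible for a fixed seed", {
  mesh <- fixtureMesh(2)
  set.seed(26)
  n <- 12
  g <- rep(c(1, 0), each = 6)
  y <- matrix(rnorm(n * nVertices(mesh)), n, nVertices(mesh))
  covs <- cbind(age = rnorm(n))
  a <- clusterCorrect(y, g, covariates = covs, mesh = mesh,
    nPerm = 150L, seed = 7L)
  b <- clusterCorrect(y, g, covariates = covs, mesh = mesh,
    nPerm = 150L, seed = 7L)
  expect_identical(a$nullMaxArea, b$nullMaxArea)
  expect_identical(a$clusters, b$clusters)
  d <- clusterCorrect(y, g, covariates = covs, mesh = mesh,
    nPerm = 150L, seed = 8L)
  expect_false(identical(a$nullMaxArea, d$nullMaxArea))
})

test_that("scalar group test matches the classical pooled t", {
  st <- scalarGroupTest(c(1, 2, 3, 4, 5, 6), c(1, 1, 1, 0, 0, 0))
  expect_equal(st$t, -3.674235, tolerance = 1e-6)
  expect_equal(st$df, 4L)
  oracle <- t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(st$p, oracle$p.value, tolerance = 1e-12)
  # identical groups: t = 0, p = 1
  same <- scalarGroupTest(c(1, 2, 3, 1, 2, 3), c(1, 1, 1, 0, 0, 0))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # translation invariance
  shifted <- scalarGroupTest(c(1, 2, 3, 4, 5, 6) + 100, c(1, 1, 1, 0, 0, 0))
  expect_equal(shifted$t, st$t, tolerance = 1e-12)
  expect_error(scalarGroupTest(c(1, 2), c(1, 0)), "per group")
})
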