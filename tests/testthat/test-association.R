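test_that("partial correlation reduces to Pearson and handles exact fits", {
  set.seed(51)
  x <- rnorm(20)
  y <- rnorm(20)
  pc <- partialCorrelation(x, y)
  expect_equal(pc$r, cor(x, y), tolerance = 1e-12)
  expect_equal(pc$df, 18L)
  expect_equal(pc$p, cor.test(x, y)$p.value, tolerance = 1e-10)
  z <- cbind(rnorm(20))
  expect_warning(p1 <- partialCorrelation(x, x, z), "r\\| = 1")
  expect_equal(p1$p, 0)
  expect_error(partialCorrelation(x, y, cbind(z, 2 * z)), "rank")
  expect_error(partialCorrelation(rnorm(4), rnorm(4), matrix(rnorm(8), 4)),
    "n >= k")
})

test_that("partial correlation matches the residualization oracle", {
  set.seed(52)
  for (i in 1:100) {
    n <- sample(10:30, 1)
    k <- sample(1:3, 1)
    z <- matrix(rnorm(n * k), n, k)
    x <- z %*% rnorm(k) + rnorm(n)
    y <- z %*% rnorm(k) + rnorm(n)
    pc <- partialCorrelation(x, y, z)
    oracle <- cor(resid(lm(x ~ z)), resid(lm(y ~ z)))
    expect_equal(pc$r, oracle, tolerance = 1e-12)
    expect_equal(pc$df, n - 2L - k)
  }
})

test_that("partial r is invariant to affine rescaling of covariates", {
  set.seed(53)
  n <- 25
  z <- cbind(age = rnorm(n, 50, 5), gender = rbinom(n, 1, 0.5))
  x <- rnorm(n)
  y <- rnorm(n)
  a <- partialCorrelation(x, y, z)
  z2 <- cbind(age = 10 * z[, 1] - 300, gender = 2 * z[, 2] + 1)
  b <- partialCorrelation(x, y, z2)
  expect_equal(a$r, b$r, tolerance = 1e-12)
})

test_that("planted partial correlations are recovered without bias", {
  rho <- 0.5
  est <- vapply(1:200, function(i) {
    d <- generateAssociationSample(21, rho, seed = 5000 + i)
    partialCorrelation(d$x, d$y, d[, c("gender", "age", "education")])$r
  }, numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - rho), 2 * se + 0.02)
})

test_that("the practice-hours outlier rule excludes the heavy practitioner", {
  set.seed(54)
  tab <- data.frame(
    subject_id = sprintf("s%02d", 1:22),
    practice_hours = c(runif(21, 5, 20), 30),
    practice_years = runif(22, 2, 30)
  )
  out <- applyTransformsAndOutliers(tab, hoursThreshold = 30)
  expect_equal(nrow(out$table), 21L)
  expect_equal(out$excluded$subject_id, "s22")
  # disabled rule keeps everyone
  keep <- applyTransformsAndOutliers(tab, hoursThreshold = NA)
  expect_equal(nrow(keep$table), 22L)
  # IQR rule flags a gross outlier too
  tab$practice_hours[22] <- 200
  iqr <- applyTransformsAndOutliers(tab, rule = "iqr")
  expect_equal(iqr$excluded$subject_id, "s22")
})

test_that("log transforms require positive values and apply natural log", {
  tab <- data.frame(subject_id = c("a", "b"), practice_hours = c(10, 20))
  out <- applyTransformsAndOutliers(tab, logVars = "practice_hours",
    hoursThreshold = NA)
  expect_equal(out$table$practice_hours, log(c(10, 20)))
  bad <- data.frame(subject_id = c("a", "b"), practice_hours = c(0, 20))
  expect_error(
    applyTransformsAndOutliers(bad, logVars = "practice_hours",
      hoursThreshold = NA),
    "subject a"
  )
})

test_that("association tables join transforms, exclusions and correlations", {
  set.seed(55)
  n <- 22
  tab <- data.frame(
    subject_id = sprintf("s%02d", 1:n),
    gender = rbinom(n, 1, 0.4), age = rnorm(n, 53, 6),
    education = rnorm(n, 12, 3),
    practice_hours = c(runif(n - 1, 5, 20), 32),
    cluster_reho = runif(n, 0.2, 0.6)
  )
  pairs <- data.frame(x = "cluster_reho", y = "practice_hours",
    log_x = FALSE, log_y = TRUE)
  at <- associationTable(tab, pairs)
  expect_equal(at$n, 21L)
  expect_equal(at$df, 21L - 2L - 3L)
  expect_equal(at$excluded_subjects, sprintf("s%02d", n))
  # matches a direct computation on the filtered, transformed table
  kept <- tab[-n, ]
  pc <- partialCorrelation(kept$cluster_reho, log(kept$practice_hours),
    kept[, c("gender", "age", "education")])
  expect_equal(at$r, pc$r, tolerance = 1e-12)
})
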