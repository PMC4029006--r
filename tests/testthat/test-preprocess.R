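makeTs <- function(data, tr = 2) SubjectTimeseries(data, tr = tr)

test_that("initial-volume discard drops exactly the leading samples", {
  ts <- makeTs(matrix(seq_len(2 * 243), 2, 243))
  out <- discardInitial(ts, 5L)
  expect_equal(ncol(tsMatrix(out)), 238L)
  expect_equal(tsMatrix(out), tsMatrix(ts)[, -(1:5)])
  expect_identical(tsMatrix(discardInitial(ts, 0L)), tsMatrix(ts))
  short <- makeTs(matrix(rnorm(20), 2, 10))
  expect_error(discardInitial(short, 10L), "cannot discard")
})

test_that("global-mean normalization hits the target exactly", {
  set.seed(1)
  ts <- makeTs(matrix(rexp(200) + 1, 4, 50))
  out <- globalMeanNormalize(ts)
  expect_equal(mean(tsMatrix(out)), 10000, tolerance = 1e-9)
  expect_equal(tsMatrix(globalMeanNormalize(out)), tsMatrix(out),
    tolerance = 1e-12)
  con <- makeTs(matrix(5, 3, 30))
  expect_true(all(tsMatrix(globalMeanNormalize(con)) == 10000))
  zero <- makeTs(matrix(c(-1, 1), 2, 30))
  expect_error(globalMeanNormalize(zero), "zero")
})

test_that("Friston-24 expansion places lags and squares correctly", {
  zero <- matrix(0, 10, 6)
  expect_equal(dim(friston24(zero)), c(10L, 24L))
  expect_true(all(friston24(zero) == 0))
  m <- matrix(0, 10, 6)
  m[3, 1] <- 2
  f <- unname(friston24(m))
  expect_equal(f[3, 1], 2)        # raw parameter
  expect_equal(f[4, 7], 2)        # one-sample-back lag
  expect_equal(f[3, 13], 4)       # square
  expect_equal(f[4, 19], 4)       # lagged square
  expect_true(all(f[1, 7:12] == 0))  # zero padding at t = 0
  expect_error(friston24(matrix(0, 10, 5)), "6 columns")
})

test_that("nuisance regression leaves residuals orthogonal to regressors", {
  set.seed(2)
  nt <- 60
  tt <- seq_len(nt)
  sine <- sin(2 * pi * tt / 20)
  y <- rbind(3 * sine + rnorm(nt), rnorm(nt))
  ts <- makeTs(y)
  out <- nuisanceRegress(ts, cbind(sine = sine))
  proj <- abs(tsMatrix(out) %*% sine) / (sqrt(rowSums(tsMatrix(out)^2)) *
    sqrt(sum(sine^2)))
  expect_true(all(proj < 1e-8))
  # empty regressor set with intercept demeans
  dm <- nuisanceRegress(ts, NULL)
  expect_equal(tsMatrix(dm), y - rowMeans(y))
  # regressing a series on itself gives (near) zero residuals
  self <- nuisanceRegress(makeTs(rbind(sine, sine)), cbind(sine))
  expect_lt(max(abs(tsMatrix(self))), 1e-10)
  expect_error(
    nuisanceRegress(ts, cbind(a = sine, b = 2 * sine)),
    "rank deficient"
  )
})

test_that("ideal band-pass keeps in-band and kills out-of-band components", {
  tt <- (0:249) * 2
  inBand <- rbind(sin(2 * pi * 0.05 * tt + 1), cos(2 * pi * 0.05 * tt))
  out <- bandpassFilter(makeTs(inBand))
  expect_equal(sd(tsMatrix(out)[1, ]) / sd(inBand[1, ]), 1, tolerance = 0.01)
  outBand <- rbind(sin(2 * pi * 0.2 * tt + 0.3), cos(2 * pi * 0.2 * tt))
  filtered <- bandpassFilter(makeTs(outBand))
  expect_lt(max(abs(tsMatrix(filtered))), 1e-8)
  # a constant series sits at 0 Hz, outside the band
  con <- bandpassFilter(makeTs(matrix(7, 2, 100)))
  expect_lt(max(abs(tsMatrix(con))), 1e-10)
  # applying the filter twice changes nothing
  set.seed(3)
  noisy <- makeTs(matrix(rnorm(500), 2, 250))
  once <- bandpassFilter(noisy)
  expect_equal(tsMatrix(bandpassFilter(once)), tsMatrix(once),
    tolerance = 1e-10)
  expect_error(bandpassFilter(noisy, 0.01, 0.3), "Nyquist")
  expect_error(bandpassFilter(noisy, 0.1, 0.01), "below")
})

test_that("polynomial detrending annihilates trends of its order", {
  nt <- 50
  tt <- seq_len(nt)
  lin <- makeTs(rbind(3 + 2 * tt, 1 - tt))
  expect_lt(max(abs(tsMatrix(detrendPoly(lin, 1L)))), 1e-9)
  quad <- makeTs(rbind(tt^2, tt^2 / 10))
  expect_lt(max(abs(tsMatrix(detrendPoly(quad, 2L)))), 1e-8)
  expect_gt(max(abs(tsMatrix(detrendPoly(quad, 1L)))), 1)
  set.seed(4)
  wn <- makeTs(matrix(rnorm(200), 4, 50))
  out <- detrendPoly(wn)
  expect_lt(max(abs(rowMeans(tsMatrix(out)))), 1e-10)
  expect_equal(tsMatrix(detrendPoly(out)), tsMatrix(out), tolerance = 1e-10)
  expect_error(detrendPoly(wn, -1L), "order")
})

test_that("framewise displacement follows the backward-difference form", {
  expect_equal(rmsFramewiseDisplacement(matrix(0, 20, 6)), 0)
  drift <- cbind(seq(0, by = 0.1, length.out = 100), 0, 0, 0, 0, 0)
  expect_equal(rmsFramewiseDisplacement(drift), 0.1, tolerance = 1e-12)
  # one 0.002 rad step on a 50 mm sphere is 0.1 mm at a single frame
  nT <- 50
  rot <- matrix(0, nT, 6)
  rot[20:nT, 4] <- 0.002
  expect_equal(rmsFramewiseDisplacement(rot), 0.1 / sqrt(nT - 1),
    tolerance = 1e-12)
  expect_equal(rmsFramewiseDisplacement(rot, summary = "mean"),
    0.1 / (nT - 1), tolerance = 1e-12)
  expect_error(rmsFramewiseDisplacement(matrix(0, 1, 6)), "2 timepoints")
})

test_that("the preprocessing chain composes the stages in the stated order", {
  set.seed(5)
  nt <- 243
  tissue <- cbind(wm = rnorm(nt), csf = rnorm(nt))
  motion <- matrix(rnorm(nt * 6, sd = 0.01), nt, 6)
  leak <- matrix(rowSums(tissue), 6, nt, byrow = TRUE)
  y <- matrix(rnorm(6 * nt), 6, nt) + 0.5 * leak + 100
  ts <- SubjectTimeseries(y, tr = 2)
  pre <- preprocessTimeseries(ts, motion = motion, tissue = tissue)
  expect_equal(ncol(tsMatrix(pre$ts)), 238L)
  expect_equal(pre$nNuisance, 26L)  # 24 motion regressors + 2 tissue means
  expect_equal(pre$rmsFD, rmsFramewiseDisplacement(motion[-(1:5), ]))
  # manual composition: discard -> normalize -> nuisance -> bandpass -> detrend
  manual <- discardInitial(ts, 5L)
  manual <- globalMeanNormalize(manual, 10000)
  tis <- tissue[-(1:5), , drop = FALSE]
  colnames(tis) <- c("tissue1", "tissue2")
  manual <- nuisanceRegress(manual, cbind(friston24(motion[-(1:5), ]), tis))
  manual <- bandpassFilter(manual, 0.01, 0.1)
  manual <- detrendPoly(manual, 2L)
  expect_equal(tsMatrix(pre$ts), tsMatrix(manual), tolerance = 1e-12)
})
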