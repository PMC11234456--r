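# Sensor-response estimation from sweep fixtures, and the noise / lamp
# variation model fits.

gaussResponse <- function(peaks, sigma = 8) {
  r <- t(vapply(peaks, function(p) exp(-(400:700 - p)^2 / (2 * sigma^2)),
                numeric(301)))
  pad <- matrix(0, 16 - length(peaks), 301)
  new("SensorResponse", r = rbind(r, pad) + 1e-12 * 0, meta = list())
}

maxNormMae <- function(a, b) mean(abs(a / max(a) - b / max(b)))

test_that("the penalty vector vanishes where it should", {
  resp <- defaultSensorResponse()
  ds <- generateLctfFixture(resp, seed = 1)
  gm <- mean(ds@I)
  # constant response: all smoothness terms are zero
  pv <- penaltyVector(rep(0.5, 301), ds, 3, gm)
  expect_equal(pv[302:601], rep(0, 300))
  # zero response: the guarded smoothness terms are zero, not NaN
  pv0 <- penaltyVector(rep(0, 301), ds, 3, gm)
  expect_true(all(is.finite(pv0)))
  expect_equal(pv0[302:601], rep(0, 300))
  # forward-generated data: intensity residuals vanish at the scaled truth
  rTrue <- resp@r[3, ] / gm
  pvT <- penaltyVector(rTrue, ds, 3, gm)
  expect_lt(max(abs(pvT[1:301])), 1e-10)
})

test_that("the analytic penalty Jacobian matches finite differences", {
  resp <- defaultSensorResponse()
  ds <- generateLctfFixture(resp, seed = 2)
  gm <- mean(ds@I)
  set.seed(3)
  r <- pmax(resp@r[5, ] / gm + rnorm(301, 0, 1e-4), 0)
  J <- msiSO2:::.penaltyJacobian(r, ds, 5, gm)
  cols <- c(1, 50, 150, 301)
  h <- 1e-7
  for (j in cols) {
    rp <- r; rp[j] <- rp[j] + h
    rm <- r; rm[j] <- rm[j] - h
    fd <- (penaltyVector(rp, ds, 5, gm) - penaltyVector(rm, ds, 5, gm)) / (2 * h)
    expect_lt(max(abs(J[, j] - fd)), 1e-4)
  }
})

test_that("a known response is recovered from a clean sweep", {
  truth <- gaussResponse(c(500, 560, 610, 650))
  ds <- generateLctfFixture(truth, seed = 4)
  res <- estimateResponse(ds, bands = 1:4)
  for (n in 1:4)
    expect_lt(maxNormMae(res@rStar@r[n, ], truth@r[n, ]), 0.01)
})

test_that("recovery degrades gracefully under 1% intensity noise", {
  truth <- gaussResponse(c(500, 560, 610, 650))
  ds <- generateLctfFixture(truth, noiseLevel = 0.01, seed = 5)
  res <- estimateResponse(ds, bands = 1:4)
  for (n in 1:4)
    expect_lt(maxNormMae(res@rStar@r[n, ], truth@r[n, ]), 0.03)
})

test_that("estimation is invariant to overall lamp intensity", {
  truth <- gaussResponse(c(520, 600))
  ds <- generateLctfFixture(truth, seed = 6)
  ds2 <- calibrationDataset(2.5 * ds@I, ds@R, ds@settings)
  r1 <- estimateResponse(ds, bands = 1:2)@rStar@r
  r2 <- estimateResponse(ds2, bands = 1:2)@rStar@r
  for (n in 1:2)
    expect_lt(maxNormMae(r1[n, ], r2[n, ]), 1e-3)
})

test_that("the smoothness penalty damps high-frequency energy", {
  truth <- gaussResponse(c(550))
  ds <- generateLctfFixture(truth, noiseLevel = 0.02, seed = 7)
  gm <- mean(ds@I)
  penalized <- estimateResponse(ds, bands = 1)@rStar@r[1, ]
  # unpenalized reference: plain ridge inversion of the linear model
  RRt <- tcrossprod(ds@R)
  raw <- pmax(as.numeric(solve(RRt + diag(1e-8 * mean(diag(RRt)), 301),
                               ds@R %*% (ds@I[1, ] / gm))), 0)
  hf <- function(r) sum(diff(r / max(r))^2)
  expect_lt(hf(penalized), hf(raw))
})

test_that("dual-peak responses keep their peak positions within 2 nm", {
  # two bands with in-house-style dual-peak characteristics at high SNR
  r <- matrix(0, 16, 301)
  mk <- function(p1, p2, a2) exp(-(400:700 - p1)^2 / (2 * 7^2)) +
    a2 * exp(-(400:700 - p2)^2 / (2 * 9^2))
  r[1, ] <- mk(520, 610, 0.6)
  r[2, ] <- mk(480, 575, 0.8)
  truth <- new("SensorResponse", r = r, meta = list())
  ds <- generateLctfFixture(truth, noiseLevel = 0.01, seed = 8)  # SNR 100
  est <- estimateResponse(ds, bands = 1:2)@rStar@r
  grid <- 400:700
  truePeaks <- list(c(520, 610), c(480, 575))
  for (n in 1:2) {
    for (tp in truePeaks[[n]]) {
      win <- which(abs(grid - tp) <= 20)
      ep <- grid[win][which.max(est[n, win])]
      expect_lte(abs(tp - ep), 2)
    }
  }
})

test_that("noise model coefficients are recovered from a white stack", {
  truth <- defaultNoiseModel()
  stack <- generateWhiteStack(truth, nRepeats = 200, seed = 9)
  fit <- fitNoiseModel(stack, iMax = truth@iMax)
  expect_lt(max(abs(fit@a - truth@a) / truth@a), 0.5)
  expect_lt(max(abs(1 / fit@b - 1 / truth@b) / (1 / truth@b)), 0.5)
  # band-averaged coefficients are much tighter (the per-band values share
  # the truth, so averaging beats the chi-square spread of single fits)
  expect_lt(abs(mean(fit@a) - truth@a[1]) / truth@a[1], 0.1)
  expect_lt(abs(mean(1 / fit@b) - 1 / truth@b[1]) / (1 / truth@b[1]), 0.1)
  # zero-noise stack gives a ~ 0, 1/b ~ 0
  quiet <- lapply(c(500, 1500, 3000), function(I0) matrix(I0, 50, 16))
  f0 <- fitNoiseModel(quiet)
  expect_equal(f0@a, rep(0, 16))
  expect_equal(1 / f0@b, rep(0, 16))
  expect_error(fitNoiseModel(stack[1]), "two intensity levels")
})

test_that("lamp variation extraction matches its defining ratios", {
  opt <- defaultOptics()
  L60 <- opt@L
  L0 <- Spectrum(specValues(L60) * (1 + specValues(opt@deltaTMax)))
  fitted <- fitLampVariation(
    list(list(t = 0, L = L0), list(t = 60, L = L60)),
    list(deg0 = L60, deg22 = Spectrum(1.02 * specValues(L60))))
  expect_equal(specValues(fitted$L), specValues(L60))
  expect_equal(specValues(fitted$deltaTMax), specValues(opt@deltaTMax),
               tolerance = 1e-12)
  expect_equal(specValues(fitted$deltaThetaMax), rep(0.02, 301),
               tolerance = 1e-12)
  # identical endpoint spectra give zero deviation
  same <- fitLampVariation(list(list(t = 0, L = L60), list(t = 60, L = L60)),
                           list(deg0 = L60, deg22 = L60))
  expect_equal(specValues(same$deltaTMax), rep(0, 301))
  # an intermediate-time spectrum recovers its scale factor
  Lmid <- Spectrum(specValues(L60) * (1 + 0.4 * specValues(opt@deltaTMax)))
  expect_equal(lampScaleFactor(Lmid, L60, opt@deltaTMax), 0.4,
               tolerance = 1e-10)
})
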