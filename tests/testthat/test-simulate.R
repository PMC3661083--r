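# Benchmark model, simulator, and the analytic (Lyapunov) oracle.

test_that("benchmark VAR(5) has the published coefficients and is stable", {
  m <- benchModel()
  A <- lagMatrices(m)
  expect_equal(dim(A), c(4, 4, 5))
  expect_identical(A[1, 1, 1], 0.8)
  expect_identical(A[2, 2, 1], 0.6)
  expect_identical(A[3, 1, 1], -0.6)
  expect_identical(A[4, 4, 1], 1.2)
  expect_identical(A[4, 4, 2], -0.7)
  expect_identical(A[3, 3, 3], 0.5)
  expect_identical(A[1, 2, 4], 0.65)
  expect_identical(A[3, 2, 4], 0.4)
  expect_identical(A[2, 4, 5], 0.6)
  # every unlisted coefficient is zero
  listed <- rbind(c(1,1,1), c(2,2,1), c(3,1,1), c(4,4,1), c(4,4,2),
                  c(3,3,3), c(1,2,4), c(3,2,4), c(2,4,5))
  Az <- A; Az[listed] <- 0
  expect_true(all(Az == 0))
  expect_identical(noiseCov(m), diag(4))
  expect_lt(spectralRadius(m), 1)
  expect_equal(spectralRadius(m), 0.83666, tolerance = 1e-4)
})

test_that("simulateVar is deterministic, shaped, and rejects unstable models", {
  m <- benchModel()
  r1 <- simulateVar(m, 12800, samplingRate = 128, seed = 42)
  expect_s4_class(r1, "Recording")
  expect_equal(nChannels(r1), 4)
  expect_equal(nSamples(r1), 12800)
  expect_equal(samplingRate(r1), 128)
  r2 <- simulateVar(m, 12800, samplingRate = 128, seed = 42)
  expect_identical(signalMatrix(r1), signalMatrix(r2))
  bad <- varModel(matrix(1.2))
  expect_error(simulateVar(bad, 100), "1\\.2")
})

test_that("zero-coefficient model simulates white noise", {
  m <- varModel(array(0, dim = c(3, 3, 2)), diag(3))
  rec <- simulateVar(m, 10000, seed = 3)
  W <- signalMatrix(rec)
  for (k in 1:3) {
    r1 <- cor(W[k, -1], W[k, -ncol(W)])
    expect_lt(abs(r1), 0.03)
  }
})

test_that("AR(1) simulation matches the closed-form stationary variance", {
  m <- varModel(matrix(0.8))
  rec <- simulateVar(m, 200000, seed = 11)
  v <- var(as.numeric(signalMatrix(rec)))
  expect_equal(v, 1 / (1 - 0.64), tolerance = 0.02)
})

test_that("stationary autocovariance solves the AR(1) case exactly", {
  g <- stationaryAutocov(varModel(matrix(0.8)), maxLag = 2)
  expect_equal(g$gamma[[1]][1, 1], 1 / 0.36, tolerance = 1e-12)
  expect_equal(g$gamma[[2]][1, 1], 0.8 / 0.36, tolerance = 1e-12)
  expect_equal(g$gamma[[3]][1, 1], 0.64 / 0.36, tolerance = 1e-12)
  # zero-dynamics model: Gamma(0) = noise covariance, higher lags vanish
  S <- matrix(c(2, 0.5, 0.5, 1), 2)
  g0 <- stationaryAutocov(varModel(array(0, dim = c(2, 2, 1)), S),
                          maxLag = 2)
  expect_equal(g0$gamma[[1]], S, tolerance = 1e-12)
  expect_true(all(abs(g0$gamma[[2]]) < 1e-12))
})

test_that("Lyapunov autocovariances match a long simulation", {
  m <- benchModel()
  ac <- stationaryAutocov(m, maxLag = 4)
  rec <- simulateVar(m, 3e5, seed = 5)
  W <- signalMatrix(rec); W <- W - rowMeans(W)
  samp0 <- tcrossprod(W) / ncol(W)
  expect_equal(unname(diag(samp0)), diag(ac$gamma[[1]]),
               tolerance = 0.05)
  samp1 <- W[, -1] %*% t(W[, -ncol(W)]) / ncol(W)
  expect_lt(max(abs(samp1 - ac$gamma[[2]])) / max(abs(ac$gamma[[2]])),
            0.05)
})

test_that("population EIPR matches the independent oracle and its structure", {
  eta <- trueEipr(benchModel())
  expect_equal(eta, benchTrueEipr(), tolerance = 1e-5)
  expect_identical(diag(eta), rep(1, 4))
  nc <- benchNoncausalPairs()
  expect_true(all(eta[nc] == 0))
  expect_true(all(eta[benchCausalPairs()] > 0))
})

test_that("population EIPR vanishes iff the source coefficients vanish", {
  for (s in 1:5) {
    m <- randomStableVar(3, 2, seed = s)
    eta <- trueEipr(m)
    A <- lagMatrices(m)
    for (k in 1:3) for (l in 1:3) {
      if (k == l) next
      zero <- all(A[k, l, ] == 0)
      expect_identical(eta[k, l] == 0, zero)
    }
  }
})

test_that("population EIPR is invariant under per-channel rescaling", {
  m <- randomStableVar(3, 2, seed = 9)
  A <- lagMatrices(m); S <- noiseCov(m)
  c2 <- 7.3  # rescale channel 2: x2 -> c*x2
  A2 <- A
  A2[2, , ] <- A[2, , ] * c2     # equations feeding the scaled channel
  A2[, 2, ] <- A2[, 2, ] / c2    # uses of the scaled channel
  S2 <- S; S2[2, ] <- S2[2, ] * c2; S2[, 2] <- S2[, 2] * c2
  expect_equal(trueEipr(varModel(A2, S2)), trueEipr(m),
               tolerance = 1e-10)
})

test_that("EIPR is linked to PDC: zero entry iff PDC vanishes on the grid", {
  for (s in c(2, 4)) {
    m <- randomStableVar(3, 2, seed = s)
    eta <- trueEipr(m)
    pv <- pdcGrid(m, 64)@values
    for (k in 1:3) for (l in 1:3) {
      if (k == l) next
      expect_identical(eta[k, l] == 0, all(pv[k, l, ] < 1e-24))
    }
  }
})

test_that("synthetic focus fixture is deterministic and raises post-onset coupling", {
  r1 <- synthEcog(4, focusChannel = 1, onsetSample = 513, nSamples = 1024,
                  seed = 21)
  r2 <- synthEcog(4, focusChannel = 1, onsetSample = 513, nSamples = 1024,
                  seed = 21)
  expect_identical(signalMatrix(r1), signalMatrix(r2))
  expect_identical(attr(r1, "driven"), c(2L, 3L))
  W <- signalMatrix(r1); dimnames(W) <- NULL
  pre <- W[, 1:512]; post <- W[, 513:1024]
  ePre <- couplingValues(eiprMatrix(pre, 3, useSelection = FALSE))
  ePost <- couplingValues(eiprMatrix(post, 3, useSelection = FALSE))
  expect_gt(ePost[2, 1], ePre[2, 1])
  expect_gt(ePost[3, 1], ePre[3, 1])
  expect_error(synthEcog(4, 1, 513, 1024, oscRadius = 1.01),
               "unstable")
})

test_that("zero-gain fixture shows no systematic post-onset coupling", {
  hits <- 0
  for (s in 1:10) {
    rec <- synthEcog(4, 1, onsetSample = 513, nSamples = 1024, seed = s,
                     gain = 0)
    W <- signalMatrix(rec)[, 513:1024]; dimnames(W) <- NULL
    cm <- eiprSignificance(W, 3,
            config = significanceConfig(nSurrogates = 50, seed = 900 + s),
            useSelection = TRUE)
    sig <- significanceMask(cm)
    hits <- hits + sum(sig[1, -1] | sig[-1, 1], na.rm = TRUE)
  }
  expect_lte(hits, 2)  # near-zero focus couplings across 10 seeds
})
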