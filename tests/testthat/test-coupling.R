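# EIPR estimation, PDC, and the spectral cross-checks.

test_that("estimated EIPR on the benchmark approaches the population values", {
  etaHat <- matrix(0, 4, 4)
  nSeeds <- 3
  for (s in 1:nSeeds) {
    rec <- simulateVar(benchModel(), 12800, seed = 40 + s)
    etaHat <- etaHat +
      couplingValues(eiprMatrix(rec, 5, useSelection = FALSE)) / nSeeds
  }
  eta <- benchTrueEipr()
  cp <- benchCausalPairs()
  expect_equal(etaHat[cp], eta[cp], tolerance = 0.10)
  expect_identical(unname(diag(etaHat)), rep(1, 4))
  expect_true(all(etaHat[benchNoncausalPairs()] < 0.01))
})

test_that("selection mode zeroes unselected pairs", {
  rec <- simulateVar(benchModel(), 12800, seed = 44)
  cm <- eiprMatrix(rec, 5, useSelection = TRUE)
  v <- couplingValues(cm)
  expect_true(all(v[benchNoncausalPairs()] == 0))
  expect_true(all(v[benchCausalPairs()] > 0))
  expect_identical(extrinsicSets(cm),
                   list(2L, 4L, c(1L, 2L), integer(0)))
})

test_that("empirical and plug-in partial-power estimators agree", {
  rec <- simulateVar(benchModel(), 12800, seed = 45)
  W <- signalMatrix(rec); dimnames(W) <- NULL
  f <- fitEquation(W, 3, c(1L, 2L, 4L), 5)
  for (l in c(1, 2, 3)) {
    ve <- partialPower(f, W, l, "empirical")
    vp <- partialPower(f, W, l, "plugin")
    expect_equal(ve, vp, tolerance = 0.02)
  }
})

test_that("estimated partial power matches the population value", {
  V <- truePartialPower(benchModel())
  vals <- sapply(1:5, function(s) {
    rec <- simulateVar(benchModel(), 12800, seed = 50 + s)
    W <- signalMatrix(rec); dimnames(W) <- NULL
    f <- fitEquation(W, 3, c(1L, 2L, 4L), 5)
    partialPower(f, W, 1)
  })
  expect_lt(abs(mean(vals) - V[3, 1]),
            3 * sd(vals) / sqrt(length(vals)) + 0.02 * V[3, 1])
})

test_that("estimated EIPR is invariant under channel rescaling", {
  rec <- simulateVar(benchModel(), 3200, seed = 46)
  W <- signalMatrix(rec); dimnames(W) <- NULL
  e1 <- couplingValues(eiprMatrix(W, 5, useSelection = FALSE))
  W2 <- W; W2[2, ] <- W2[2, ] * 137.5
  e2 <- couplingValues(eiprMatrix(W2, 5, useSelection = FALSE))
  expect_lt(max(abs(e1 - e2)), 1e-8)
})

test_that("PDC columns are normalized and the identity model is diagonal", {
  g <- pdcGrid(benchModel(), nFreqs = 128)
  sums <- apply(g@values, c(2, 3), sum)
  expect_lt(max(abs(sums - 1)), 1e-10)
  gi <- pdcGrid(varModel(array(0, dim = c(3, 3, 1)), diag(3)), 16)
  for (i in 1:16) expect_equal(gi@values[, , i], diag(3))
})

test_that("benchmark PDC is dominated by the strong couplings", {
  g <- pdcGrid(benchModel(), nFreqs = 256)
  avg <- apply(g@values, c(1, 2), mean)
  diag(avg) <- 0
  ord <- order(avg, decreasing = TRUE)
  top2 <- arrayInd(ord[1:2], dim(avg))
  expect_setequal(paste(top2[, 1], top2[, 2]), c("3 1", "2 4"))
})

test_that("EIPR normalization is local; PDC's is not", {
  # x2 drives x1 and x3; perturbing the 3<-2 coefficient must move
  # pi^2_{1,2} but leave eta^2_{1,2} untouched (fixed coefficients)
  A <- array(0, dim = c(3, 3, 1))
  diag(A[, , 1]) <- 0.5
  A[1, 2, 1] <- 0.4
  A[3, 2, 1] <- 0.3
  m1 <- varModel(A, diag(3))
  A2 <- A; A2[3, 2, 1] <- 0.9
  m2 <- varModel(A2, diag(3))
  p1 <- pdcGrid(m1, 64)@values[1, 2, ]
  p2 <- pdcGrid(m2, 64)@values[1, 2, ]
  expect_gt(max(abs(p1 - p2)), 0.01)
  expect_equal(trueEipr(m1)[1, 2], trueEipr(m2)[1, 2],
               tolerance = 1e-12)
})

test_that("spectral representations agree with time-domain oracles", {
  cc <- spectralCrossCheck(benchModel(), nFreqs = 1024)
  expect_lt(cc$maxRelDevPower, 1e-3)
  expect_lt(cc$maxRelDevEipr, 1e-3)
  expect_lt(cc$maxAbsDevPdc, 1e-10)
  # uncoupled model: every off-diagonal spectral integral is zero
  A <- array(0, dim = c(2, 2, 1)); diag(A[, , 1]) <- c(0.5, -0.3)
  cc0 <- spectralCrossCheck(varModel(A), nFreqs = 256)
  off <- !diag(2)
  expect_true(all(cc0$specPower[off] == 0))
})

test_that("zeroed source coefficients give zero partial power", {
  set.seed(61)
  W <- matrix(rnorm(2 * 200), 2, 200)
  f <- fitEquation(W, 1, 2L, 2)
  f@coeffs[, 2] <- 0  # wipe the extrinsic coefficients by hand
  expect_identical(partialPower(f, W, 2), 0)
  expect_identical(partialPower(f, W, 2, "plugin"), 0)
})
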