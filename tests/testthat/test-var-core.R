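# Single-equation OLS, partial contributions, stability checks.

test_that("fitEquation matches a brute-force normal-equations solve", {
  set.seed(31)
  W <- matrix(rnorm(3 * 30), 3, 30)
  for (set in list(integer(), 1L, c(1L, 3L))) {
    f <- fitEquation(W, target = 2, extrinsicSet = set, order = 1)
    o <- bruteOls(W, 2, set, 1)
    expect_equal(as.numeric(f@coeffs), as.numeric(o$beta),
                 tolerance = 1e-10)
    expect_equal(f@rss, o$rss, tolerance = 1e-10)
    expect_equal(f@nRows, 29L)
  }
})

test_that("residuals are orthogonal to every regressor column", {
  set.seed(7)
  W <- matrix(rnorm(4 * 300), 4, 300)
  f <- fitEquation(W, 1, c(2L, 4L), order = 3)
  o <- bruteOls(W, 1, c(2L, 4L), 3)
  scale <- max(abs(o$X))
  expect_lt(max(abs(t(o$X) %*% f@residuals)), 1e-8 * 300 * scale)
})

test_that("white-noise fits give near-zero coefficients and unit noise variance", {
  set.seed(12)
  W <- matrix(rnorm(3 * 8000), 3, 8000)
  f <- fitEquation(W, 2, integer(), order = 4)
  expect_true(all(abs(f@coeffs) < 0.05))
  expect_equal(f@rss / f@nRows, 1, tolerance = 0.05)
})

test_that("benchmark intrinsic coefficients of channel 4 are recovered", {
  rec <- simulateVar(benchModel(), 12800, seed = 8)
  f <- fitEquation(signalMatrix(rec), 4, integer(), order = 5)
  expect_equal(unname(f@coeffs[1, "4"]), 1.2, tolerance = 0.05)
  expect_equal(unname(f@coeffs[2, "4"]), -0.7, tolerance = 0.08)
})

test_that("partial contributions reconstruct the target exactly", {
  set.seed(4)
  m <- randomStableVar(3, 2, seed = 4)
  rec <- simulateVar(m, 500, seed = 4)
  W <- signalMatrix(rec); dimnames(W) <- NULL
  f <- fitEquation(W, 1, c(2L, 3L), order = 2)
  mu <- sapply(c(1, 2, 3), function(l) partialContribution(f, W, l))
  Wd <- W - rowMeans(W)
  target <- Wd[1, 3:500]
  expect_equal(rowSums(mu) + f@residuals, target, tolerance = 1e-10)
  expect_error(partialContribution(f, W, 4), "zero by construction")
})

test_that("zero-coefficient source yields a zero partial contribution", {
  f <- new("EquationFit", target = 1L, extrinsicSet = 2L, order = 2L,
           coeffs = matrix(c(0.5, 0.1, 0, 0), 2, 2,
                           dimnames = list(NULL, c("1", "2"))),
           residuals = 0, rss = 0, nRows = 1L)
  W <- matrix(rnorm(2 * 50), 2, 50)
  expect_true(all(partialContribution(f, W, 2) == 0))
})

test_that("adding a channel never increases the residual sum of squares", {
  for (s in 1:5) {
    set.seed(s)
    W <- matrix(rnorm(4 * 200), 4, 200)
    r0 <- fitEquation(W, 1, integer(), 2)@rss
    r1 <- fitEquation(W, 1, 2L, 2)@rss
    r2 <- fitEquation(W, 1, c(2L, 3L), 2)@rss
    r3 <- fitEquation(W, 1, c(2L, 3L, 4L), 2)@rss
    expect_true(all(diff(c(r0, r1, r2, r3)) <= 1e-10))
  }
})

test_that("coefficient error shrinks like N^(-1/2)", {
  m <- benchModel()
  A <- lagMatrices(m)
  sizes <- c(800, 3200, 12800, 51200)
  rmse <- sapply(seq_along(sizes), function(i) {
    errs <- sapply(1:3, function(r) {
      rec <- simulateVar(m, sizes[i], seed = 100 * i + r)
      fit <- fullVarFit(signalMatrix(rec), 5)
      sqrt(mean((lagMatrices(fit) - A)^2))
    })
    mean(errs)
  })
  slope <- coef(lm(log(rmse) ~ log(sizes)))[2]
  expect_equal(unname(slope), -0.5, tolerance = 0.1)
})

test_that("stability check reports the spectral radius", {
  expect_true(checkStability(benchModel()))
  s1 <- checkStability(varModel(matrix(1.0)))
  expect_false(s1)
  expect_equal(attr(s1, "spectralRadius"), 1.0, tolerance = 1e-12)
  s2 <- checkStability(varModel(matrix(1.2)))
  expect_false(s2)
  expect_equal(attr(s2, "spectralRadius"), 1.2, tolerance = 1e-12)
})

test_that("degenerate designs are rejected with diagnostics", {
  W <- matrix(rnorm(2 * 20), 2, 20)
  W[2, ] <- W[1, ]  # duplicated channel -> singular design
  expect_error(fitEquation(W, 1, 2L, 3), "ill-conditioned")
  expect_error(fitEquation(matrix(rnorm(2 * 8), 2, 8), 1, 2L, 3),
               "too short")
})
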