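# Surrogate resampling and the one-sided t-quantile threshold rule.

test_that("threshold matches the closed-form rule with the Student quantile", {
  set.seed(71)
  W <- matrix(rnorm(3 * 600), 3, 600)
  cfg <- significanceConfig(nSurrogates = 40, alpha = 0.01, seed = 5)
  thr <- significanceThresholds(W, 2, cfg)
  m <- attr(thr, "surrogateMean"); s <- attr(thr, "surrogateSd")
  q <- -qt(0.01, df = 39)
  off <- !diag(3)
  expect_equal(unclass(thr)[off], (m + q * s / sqrt(40))[off],
               tolerance = 1e-12)
  expect_true(all(is.na(diag(thr))))
  # the N = 100 / alpha = 0.01 factor used throughout is +2.3646
  expect_equal(-qt(0.01, 99), 2.3646, tolerance = 1e-4)
  # worked example: mean 0.01, sd 0.02, N = 100 -> 0.014729
  expect_equal(0.01 + (-qt(0.01, 99)) * 0.02 / sqrt(100), 0.014729,
               tolerance = 1e-4)
})

test_that("surrogates are deterministic and preserve marginal samples", {
  set.seed(72)
  W <- matrix(rnorm(3 * 512), 3, 512)
  for (mth in c("loom", "circular_shift", "block_permute")) {
    cfg <- significanceConfig(nSurrogates = 5, method = mth, seed = 9)
    s1 <- makeSurrogates(W, cfg)
    s2 <- makeSurrogates(W, cfg)
    expect_identical(s1, s2)
    expect_length(s1, 5)
    for (k in 1:3)
      expect_true(all(s1[[1]][k, ] %in% W[k, ]))
  }
  # circular shift keeps every sample; loom drops one segment
  cs <- makeSurrogates(W, significanceConfig(3, method = "circular_shift",
                                             seed = 1))
  expect_identical(sort(cs[[1]][1, ]), sort(W[1, ]))
  lo <- makeSurrogates(W, significanceConfig(4, method = "loom",
                                             seed = 1))
  expect_lt(ncol(lo[[1]]), ncol(W))
})

test_that("circular shifts preserve each channel's autocorrelation", {
  set.seed(73)
  rec <- simulateVar(benchModel(), 2048, seed = 73)
  W <- signalMatrix(rec); dimnames(W) <- NULL
  s <- makeSurrogates(W, significanceConfig(3, method = "circular_shift",
                                            seed = 2))[[1]]
  for (k in 1:4) {
    a0 <- acf(W[k, ], lag.max = 5, plot = FALSE)$acf
    a1 <- acf(s[k, ], lag.max = 5, plot = FALSE)$acf
    expect_equal(a1, a0, tolerance = 0.05)
  }
})

test_that("surrogates destroy the imposed cross-channel alignment", {
  rec <- simulateVar(benchModel(), 12800, seed = 74)
  W <- signalMatrix(rec); dimnames(W) <- NULL
  # x1 drives x3 at lag 1: strong lagged cross-correlation in the data
  ccOrig <- cor(W[3, -1], W[1, -ncol(W)])
  expect_gt(abs(ccOrig), 0.3)
  ss <- makeSurrogates(W, significanceConfig(20, method = "circular_shift",
                                             seed = 3))
  ccSurr <- sapply(ss, function(s) cor(s[3, -1], s[1, -ncol(s)]))
  # signed correlations center on zero once alignment is destroyed
  expect_lt(abs(mean(ccSurr)), 0.05)
  expect_lt(mean(abs(ccSurr)), 0.25 * abs(ccOrig))
})

test_that("thresholds rise with the surrogate mean and spread", {
  thr <- function(m, s, N = 100) m - qt(0.01, N - 1) * s / sqrt(N)
  expect_gt(thr(0.02, 0.02), thr(0.01, 0.02))
  expect_gt(thr(0.01, 0.04), thr(0.01, 0.02))
})

test_that("true couplings are significant on the benchmark", {
  hits <- 0
  for (s in 1:5) {
    rec <- simulateVar(benchModel(), 12800, seed = 80 + s)
    cm <- eiprSignificance(rec, 5,
            config = significanceConfig(nSurrogates = 50, seed = 300 + s),
            useSelection = TRUE)
    sig <- significanceMask(cm)
    hits <- hits + all(sig[benchCausalPairs()])
  }
  expect_gte(hits, 5 - 1)
})

test_that("the full method flags almost nothing under the independent null", {
  flagged <- 0; total <- 0
  for (s in 1:10) {
    set.seed(s)
    W <- matrix(rnorm(4 * 512), 4, 512)
    cm <- eiprSignificance(W, 3,
            config = significanceConfig(nSurrogates = 50, seed = 400 + s),
            useSelection = TRUE)
    flagged <- flagged + sum(significanceMask(cm), na.rm = TRUE)
    total <- total + 12
  }
  expect_lte(flagged / total, 0.05)
})

test_that("reselection on surrogates is available and deterministic", {
  rec <- simulateVar(benchModel(), 1600, seed = 85)
  cfg <- significanceConfig(nSurrogates = 5, seed = 7,
                            reselectOnSurrogates = TRUE)
  t1 <- significanceThresholds(rec, 5, cfg, useSelection = TRUE)
  t2 <- significanceThresholds(rec, 5, cfg, useSelection = TRUE)
  expect_identical(t1, t2)
})
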