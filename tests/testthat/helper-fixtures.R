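# Shared fixtures, all generated in code.

benchModel <- function() winterhalderModel()

# Population EIPR of the benchmark, frozen from an independent
# implementation (companion-form discrete Lyapunov solve + Eq.-5
# quadratic form, coded separately in numpy/scipy).
benchTrueEipr <- function() {
  eta <- matrix(0, 4, 4)
  diag(eta) <- 1
  eta[1, 2] <- 0.190345
  eta[2, 4] <- 0.754693
  eta[3, 1] <- 1.963365
  eta[3, 2] <- 0.251602
  eta
}

benchCausalPairs <- function()
  rbind(c(1, 2), c(2, 4), c(3, 1), c(3, 2))

benchNoncausalPairs <- function() {
  all <- which(!diag(4), arr.ind = TRUE)
  cp <- benchCausalPairs()
  keep <- !(paste(all[, 1], all[, 2]) %in% paste(cp[, 1], cp[, 2]))
  all[keep, , drop = FALSE]
}

# small random stable VAR for property tests
randomStableVar <- function(K, p, sparsity = 0.4, seed = 1) {
  set.seed(seed)
  A <- array(0, dim = c(K, K, p))
  mask <- array(runif(K * K * p) < sparsity, dim = dim(A))
  A[mask] <- runif(sum(mask), -0.8, 0.8)
  for (k in seq_len(K)) A[k, k, 1] <- runif(1, 0.2, 0.6)  # intrinsic part
  rho <- spectralRadius(A)
  if (rho >= 0.95) A <- A * (0.9 / rho)^(1 / 1)  # crude damping
  while (spectralRadius(A) >= 0.95) A <- A * 0.9
  varModel(A, diag(K))
}

# brute-force textbook OLS (explicit normal equations) as an
# independent oracle for fitEquation
bruteOls <- function(window, target, extrinsicSet, p) {
  W <- window - rowMeans(window)
  N <- ncol(W)
  rows <- (p + 1):N
  sources <- c(target, sort(extrinsicSet))
  X <- NULL
  for (src in sources)
    for (j in 1:p)
      X <- cbind(X, W[src, rows - j])
  y <- W[target, rows]
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - drop(X %*% beta)
  list(beta = drop(beta), rss = sum(res^2), X = X, res = res)
}
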