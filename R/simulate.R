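# Benchmark and fixture signal generators plus the analytic
# (Lyapunov-equation) oracle for stationary second-order statistics.

#' Four-channel VAR(5) benchmark system
#'
#' Returns the classic 4-channel order-5 benchmark used to validate
#' directed coupling measures:
#' \deqn{x_1[n] = 0.8 x_1[n-1] + 0.65 x_2[n-4] + \epsilon_1[n]}
#' \deqn{x_2[n] = 0.6 x_2[n-1] + 0.6 x_4[n-5] + \epsilon_2[n]}
#' \deqn{x_3[n] = 0.5 x_3[n-3] - 0.6 x_1[n-1] + 0.4 x_2[n-4] + \epsilon_3[n]}
#' \deqn{x_4[n] = 1.2 x_4[n-1] - 0.7 x_4[n-2] + \epsilon_4[n]}
#' with identity innovation covariance. The imposed directed dependencies
#' are 2\eqn{\to}1, 4\eqn{\to}2, 1\eqn{\to}3 and 2\eqn{\to}3.
#'
#' @return A stable \linkS4class{VarModel} (companion spectral
#'   radius \eqn{\approx 0.837}).
#' @examples
#' m <- winterhalderModel()
#' spectralRadius(m)
#' @export
winterhalderModel <- function() {
  A <- array(0, dim = c(4, 4, 5))
  A[1, 1, 1] <- 0.8
  A[2, 2, 1] <- 0.6
  A[3, 1, 1] <- -0.6
  A[4, 4, 1] <- 1.2
  A[4, 4, 2] <- -0.7
  A[3, 3, 3] <- 0.5
  A[1, 2, 4] <- 0.65
  A[3, 2, 4] <- 0.4
  A[2, 4, 5] <- 0.6
  varModel(A, diag(4))
}

# companion matrix (Kp x Kp) of a K x K x p coefficient array
.companion <- function(A) {
  K <- dim(A)[1L]; p <- dim(A)[3L]
  F <- matrix(0, K * p, K * p)
  for (j in seq_len(p))
    F[seq_len(K), (j - 1L) * K + seq_len(K)] <- A[, , j]
  if (p > 1L)
    F[K + seq_len(K * (p - 1L)), seq_len(K * (p - 1L))] <-
      diag(K * (p - 1L))
  F
}

.spectralRadius <- function(A) {
  max(Mod(eigen(.companion(A), only.values = TRUE)$values))
}

#' @describeIn spectralRadius of a VAR model
#' @export
setMethod("spectralRadius", "VarModel",
          function(x) .spectralRadius(x@coeffs))

#' @describeIn spectralRadius of a raw K x K x p coefficient array
#' @export
setMethod("spectralRadius", "array", function(x) .spectralRadius(x))

.stopIfUnstable <- function(model, what = "operation") {
  rho <- spectralRadius(model)
  if (rho >= 1)
    stop(sprintf(
      "%s requires a stable model: companion spectral radius = %.4f >= 1",
      what, rho))
  invisible(rho)
}

#' Simulate a stationary VAR realization
#'
#' Draws Gaussian innovations with the model's covariance, iterates the
#' autoregression from zero initial conditions, discards a burn-in
#' transient and returns the remaining samples as a
#' \linkS4class{Recording}. Identical seeds give identical output.
#'
#' @param model a stable \linkS4class{VarModel}.
#' @param nSamples samples per channel to return.
#' @param samplingRate nominal sampling rate attached to the output (Hz).
#' @param seed integer RNG seed, or NULL to use the current RNG state.
#' @param burnIn transient samples discarded before recording starts.
#'   The default 1000 is ample for companion spectral radii up to ~0.95.
#' @param noiseFun optional innovation sampler \code{function(n, K)}
#'   returning an \eqn{n \times K} matrix of unit-variance white noise;
#'   defaults to Gaussian. The model covariance is applied on top via its
#'   Cholesky factor.
#' @return A \linkS4class{Recording} with \eqn{K} channels and
#'   \code{nSamples} samples.
#' @examples
#' rec <- simulateVar(winterhalderModel(), 12800, samplingRate = 128,
#'                    seed = 1)
#' rec
#' @export
simulateVar <- function(model, nSamples, samplingRate = 128, seed = NULL,
                        burnIn = 1000, noiseFun = NULL) {
  stopifnot(is(model, "VarModel"), nSamples >= 1)
  .stopIfUnstable(model, "simulateVar")
  K <- nChannels(model); p <- modelOrder(model)
  if (!is.null(seed)) set.seed(as.integer(seed))
  ntot <- nSamples + burnIn
  E <- if (is.null(noiseFun)) matrix(stats::rnorm(ntot * K), ntot, K)
       else noiseFun(ntot, K)
  E <- E %*% chol(noiseCov(model))
  # stacked-state iteration: state = (x[n-1], ..., x[n-p])
  Astack <- matrix(lagMatrices(model), K, K * p)
  X <- matrix(0, K, ntot)
  state <- numeric(K * p)
  keep <- seq_len(K * (p - 1L))
  for (n in seq_len(ntot)) {
    xn <- E[n, ] + drop(Astack %*% state)
    X[, n] <- xn
    state <- if (p > 1L) c(xn, state[keep]) else xn
  }
  recording(X[, burnIn + seq_len(nSamples), drop = FALSE],
            samplingRate = samplingRate)
}

#' Exact stationary autocovariances of a VAR model
#'
#' Population autocovariance matrices
#' \eqn{\Gamma(s) = E\{x[n+s] x[n]^T\}} of the stationary solution,
#' computed from the companion-form discrete Lyapunov equation (exact to
#' machine precision, no spectral quadrature) and extended to higher lags
#' through the Yule-Walker recursion
#' \eqn{\Gamma(s) = \sum_j A[j] \Gamma(s-j)}.
#'
#' @param model a stable \linkS4class{VarModel}.
#' @param maxLag largest lag \eqn{s} to return (>= p - 1).
#' @return List with \code{lags} (0..maxLag) and \code{gamma}, a list of
#'   \eqn{K \times K} matrices; \eqn{\Gamma(-s) = \Gamma(s)^T} is implied.
#' @examples
#' g <- stationaryAutocov(varModel(matrix(0.8)), maxLag = 1)
#' g$gamma[[1]]  # 1/(1 - 0.64) = 2.7778
#' @export
stationaryAutocov <- function(model, maxLag = modelOrder(model)) {
  stopifnot(is(model, "VarModel"))
  .stopIfUnstable(model, "stationaryAutocov")
  K <- nChannels(model); p <- modelOrder(model)
  stopifnot(maxLag >= p - 1L)
  F <- .companion(lagMatrices(model))
  Sc <- matrix(0, K * p, K * p)
  Sc[seq_len(K), seq_len(K)] <- noiseCov(model)
  # vec(G) = (I - F (x) F)^{-1} vec(Sc): G = F G F' + Sc
  n2 <- (K * p)^2
  vecG <- solve(diag(n2) - kronecker(F, F), as.vector(Sc))
  G <- matrix(vecG, K * p, K * p)
  gam <- vector("list", maxLag + 1L)
  for (s in 0:min(maxLag, p - 1L))
    gam[[s + 1L]] <- G[seq_len(K), s * K + seq_len(K), drop = FALSE]
  A <- lagMatrices(model)
  gfull <- function(s) if (s >= 0) gam[[s + 1L]] else t(gam[[-s + 1L]])
  if (maxLag >= p)
    for (s in p:maxLag) {
      acc <- matrix(0, K, K)
      for (j in seq_len(p)) acc <- acc + A[, , j] %*% gfull(s - j)
      gam[[s + 1L]] <- acc
    }
  list(lags = 0:maxLag, gamma = gam)
}

#' Population partial-contribution variances
#'
#' The variance of the partial contribution of source channel \eqn{l} to
#' target channel \eqn{k},
#' \deqn{V\{\mu_{k,l}\} = \sum_{j=1}^p \sum_{j'=1}^p A_{k,l}[j]\,
#'       r_{x_l}[j - j']\, A_{k,l}[j'],}
#' evaluated with the true model coefficients and the exact stationary
#' autocovariance function \eqn{r_{x_l}} from the Lyapunov solution.
#'
#' @param model a stable \linkS4class{VarModel}.
#' @return \eqn{K \times K} matrix of variances; entry \eqn{(k, l)} is
#'   exactly 0 when all \eqn{A_{k,l}[j] = 0}.
#' @seealso \code{\link{trueEipr}}
#' @export
truePartialPower <- function(model) {
  K <- nChannels(model); p <- modelOrder(model)
  ac <- stationaryAutocov(model, maxLag = p - 1L)
  A <- lagMatrices(model)
  V <- matrix(0, K, K)
  # r_l[s] for s = 0..p-1 (symmetric in s)
  r <- vapply(0:(p - 1L), function(s) diag(ac$gamma[[s + 1L]]),
              numeric(K))
  r <- matrix(r, nrow = K)  # K x p
  for (k in seq_len(K)) for (l in seq_len(K)) {
    a <- A[k, l, ]
    if (all(a == 0)) next
    q <- 0
    for (j in seq_len(p)) for (jp in seq_len(p))
      q <- q + a[j] * r[l, abs(j - jp) + 1L] * a[jp]
    V[k, l] <- q
  }
  V
}

#' Population EIPR matrix of a VAR model
#'
#' The extrinsic-to-intrinsic power ratio evaluated with the true model
#' parameters: \eqn{\eta^2_{k,l} = V\{\mu_{k,l}\} / V\{\mu_{k,k}\}}. The
#' diagonal is exactly 1 and an off-diagonal entry is exactly 0 iff all
#' coefficients \eqn{A_{k,l}[j]} vanish (i.e. iff \eqn{l} is
#' Granger-non-causal for \eqn{k} in the model). Serves as the analytic
#' oracle for estimated EIPR.
#'
#' @param model a stable \linkS4class{VarModel}.
#' @return \eqn{K \times K} numeric matrix.
#' @examples
#' round(trueEipr(winterhalderModel()), 4)
#' @export
trueEipr <- function(model) {
  V <- truePartialPower(model)
  intr <- diag(V)
  if (any(intr <= 0))
    stop("intrinsic power is not bounded below by a positive constant: ",
         "channel(s) ", paste(which(intr <= 0), collapse = ", "),
         " have zero intrinsic partial-contribution variance")
  eta <- V / intr
  diag(eta) <- 1
  eta
}

#' Synthetic ECoG-like fixture with a driving focus channel
#'
#' Generates a multichannel recording emulating a focal seizure onset:
#' before \code{onsetSample} every channel is an independent stable AR(2)
#' process; from onset on, the focus channel switches to a strongly
#' resonant AR(2) oscillation (frequency \code{oscHz}) and drives each
#' channel in \code{driven} with a lagged gain, so that the focus's
#' outgoing EIPR rises after onset. Deterministic given the seed.
#'
#' @param nChannels number of channels (>= 2).
#' @param focusChannel index of the driving channel.
#' @param onsetSample first sample of the post-onset regime.
#' @param nSamples total samples per channel.
#' @param samplingRate sampling rate in Hz.
#' @param seed integer RNG seed.
#' @param driven indices of channels driven by the focus after onset;
#'   default: the two channels following the focus (wrapping around).
#' @param gain post-onset coupling gain from focus to driven channels.
#' @param couplingLag lag (samples) of the focus drive.
#' @param oscHz post-onset oscillation frequency of the focus (Hz).
#' @param oscRadius pole radius of the post-onset focus AR(2); < 1.
#' @return A \linkS4class{Recording} with attribute \code{"onsetSample"}.
#' @examples
#' rec <- synthEcog(4, focusChannel = 1, onsetSample = 1024,
#'                  nSamples = 2048, seed = 7)
#' @export
synthEcog <- function(nChannels = 4, focusChannel = 1, onsetSample,
                      nSamples, samplingRate = 128, seed = NULL,
                      driven = NULL, gain = 0.5, couplingLag = 2,
                      oscHz = 8, oscRadius = 0.95) {
  stopifnot(nChannels >= 2, focusChannel >= 1, focusChannel <= nChannels,
            onsetSample >= 1, onsetSample < nSamples)
  if (oscRadius >= 1)
    stop(sprintf("unstable focus oscillation: pole radius %.3f >= 1",
                 oscRadius))
  if (abs(gain) >= 1.5)
    stop(sprintf("coupling gain %.3f risks instability; use |gain| < 1.5",
                 gain))
  if (is.null(driven))
    driven <- setdiff(1L + (focusChannel - 1L + 1:2) %% nChannels,
                      focusChannel)
  driven <- setdiff(as.integer(driven), focusChannel)
  if (!is.null(seed)) set.seed(as.integer(seed))
  K <- nChannels
  # baseline AR(2): mild damped oscillation, distinct per channel
  th <- 2 * pi * stats::runif(K, 0.05, 0.35)
  rho <- stats::runif(K, 0.5, 0.7)
  a1 <- 2 * rho * cos(th); a2 <- -rho^2
  # post-onset focus: resonant AR(2) at oscHz
  thF <- 2 * pi * oscHz / samplingRate
  f1 <- 2 * oscRadius * cos(thF); f2 <- -oscRadius^2
  burn <- 500L
  ntot <- nSamples + burn
  E <- matrix(stats::rnorm(ntot * K), ntot, K)
  X <- matrix(0, ntot, K)
  onset <- onsetSample + burn
  for (n in seq_len(ntot)) {
    for (kk in seq_len(K)) {
      v <- E[n, kk]
      post <- n >= onset
      if (post && kk == focusChannel) {
        if (n > 1) v <- v + f1 * X[n - 1, kk]
        if (n > 2) v <- v + f2 * X[n - 2, kk]
      } else {
        if (n > 1) v <- v + a1[kk] * X[n - 1, kk]
        if (n > 2) v <- v + a2[kk] * X[n - 2, kk]
      }
      if (post && kk %in% driven && n > couplingLag)
        v <- v + gain * X[n - couplingLag, focusChannel]
      X[n, kk] <- v
    }
  }
  rec <- recording(t(X[burn + seq_len(nSamples), , drop = FALSE]),
                   samplingRate = samplingRate)
  attr(rec, "onsetSample") <- as.integer(onsetSample)
  attr(rec, "focusChannel") <- as.integer(focusChannel)
  attr(rec, "driven") <- driven
  rec
}
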