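# Single-equation OLS estimation of the (reduced) autoregression and the
# partial-contribution decomposition.

# Demean each channel over the window; the model assumes zero-mean
# channels but real recordings are not.
.demean <- function(window) window - rowMeans(window)

# Design matrix for target ~ lags 1..p of sources, rows n = p+1..N.
# Columns ordered source-major, lag-minor; colnames "<src>.l<j>".
.lagDesign <- function(window, sources, p) {
  N <- ncol(window)
  rows <- (p + 1L):N
  X <- matrix(0, length(rows), length(sources) * p)
  cn <- character(ncol(X))
  c0 <- 0L
  for (src in sources) {
    xs <- window[src, ]
    for (j in seq_len(p)) {
      X[, c0 + j] <- xs[rows - j]
      cn[c0 + j] <- sprintf("%d.l%d", src, j)
    }
    c0 <- c0 + p
  }
  colnames(X) <- cn
  X
}

#' Fit one target channel's reduced autoregression by OLS
#'
#' Regresses target channel \eqn{k} on lags \eqn{1..p} of itself and of
#' every channel in the extrinsic set \eqn{L_k}, over rows
#' \eqn{n = p+1, \dots, N_{win}} (conditional least squares; no pre-sample
#' padding). Channels are demeaned over the window first. The normal
#' equations are solved through a QR factorization; the contract is the
#' OLS minimizer.
#'
#' @param window \eqn{K \times N_{win}} numeric matrix (channels in rows)
#'   or a \linkS4class{Recording}.
#' @param target target channel index \eqn{k}.
#' @param extrinsicSet integer vector of source channels \eqn{L_k}
#'   (must not contain the target); empty for the intrinsic-only model.
#' @param order lag order \eqn{p}.
#' @return An \linkS4class{EquationFit}.
#' @examples
#' rec <- simulateVar(winterhalderModel(), 2000, seed = 1)
#' fitEquation(signalMatrix(rec), target = 4, extrinsicSet = integer(),
#'             order = 5)
#' @export
fitEquation <- function(window, target, extrinsicSet = integer(),
                        order = 1L) {
  if (is(window, "Recording")) window <- window@data
  K <- nrow(window); N <- ncol(window)
  p <- as.integer(order)
  target <- as.integer(target)
  extrinsicSet <- sort(unique(as.integer(extrinsicSet)))
  stopifnot(p >= 1L, target >= 1L, target <= K)
  if (target %in% extrinsicSet)
    stop("the target channel cannot be in its own extrinsic set")
  if (any(extrinsicSet < 1L) || any(extrinsicSet > K))
    stop("extrinsic set indices out of range")
  sources <- c(target, extrinsicSet)
  nPar <- length(sources) * p
  if (N - p <= nPar)
    stop(sprintf(
      "window too short: %d regression rows for %d parameters", N - p,
      nPar))
  W <- .demean(window)
  X <- .lagDesign(W, sources, p)
  y <- W[target, (p + 1L):N]
  qrx <- qr(X, LAPACK = TRUE)
  R <- qr.R(qrx)
  kap <- kappa(R, exact = FALSE)
  if (kap^2 > 1e12)
    stop(sprintf(paste0(
      "ill-conditioned normal equations (condition number ~%.3g > 1e12);",
      " reduce the extrinsic channel set"), kap^2))
  beta <- qr.coef(qrx, y)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  cf <- matrix(beta, nrow = p, ncol = length(sources))
  colnames(cf) <- as.character(sources)
  new("EquationFit", target = target, extrinsicSet = extrinsicSet,
      order = p, coeffs = cf, residuals = as.numeric(res),
      rss = sum(res^2), nRows = length(y))
}

#' Partial contribution of a source channel
#'
#' The lag-filtered portion of the target explained by one source,
#' \deqn{\mu_{k,l}[n] = \sum_{j=1}^{p} \hat A_{k,l}[j]\, x_l[n-j],}
#' evaluated on the same rows as the regression. Summing the intrinsic
#' contribution, all extrinsic contributions and the residual reproduces
#' the (demeaned) target exactly.
#'
#' @param fit an \linkS4class{EquationFit}.
#' @param window the window the fit was computed on.
#' @param source a channel in \code{c(target, extrinsicSet)} of the fit.
#' @return Numeric series of length \code{fit@nRows}.
#' @export
partialContribution <- function(fit, window, source) {
  if (is(window, "Recording")) window <- window@data
  source <- as.integer(source)
  sources <- c(fit@target, fit@extrinsicSet)
  if (!source %in% sources)
    stop("source ", source, " was not in the fitted channel set; ",
         "its contribution is identically zero by construction")
  p <- fit@order
  W <- .demean(window)
  rows <- (p + 1L):ncol(W)
  a <- fit@coeffs[, match(source, sources)]
  mu <- numeric(length(rows))
  xs <- W[source, ]
  for (j in seq_len(p))
    mu <- mu + a[j] * xs[rows - j]
  mu
}

#' Stability check of a coefficient stack
#'
#' @param x a \linkS4class{VarModel} or a \eqn{K \times K \times p}
#'   coefficient array.
#' @return Logical scalar, TRUE iff the companion spectral radius is < 1;
#'   the radius is attached as attribute \code{"spectralRadius"}.
#' @examples
#' checkStability(varModel(matrix(1.2)))  # FALSE, radius 1.2
#' @export
checkStability <- function(x) {
  rho <- spectralRadius(x)
  structure(rho < 1, spectralRadius = rho)
}

#' Fit the full VAR by per-target OLS
#'
#' Fits all K single-channel equations with every other channel as
#' extrinsic input (channel selection disabled). Equivalent to joint
#' multivariate OLS done row-wise. Returns the assembled
#' \linkS4class{VarModel} (innovation covariance estimated from the
#' residuals, 1/n convention) with the per-target fits attached.
#'
#' @param window \eqn{K \times N} matrix or \linkS4class{Recording}.
#' @param order lag order p.
#' @return A \linkS4class{VarModel} with attribute \code{"fits"}
#'   (list of \linkS4class{EquationFit}).
#' @export
fullVarFit <- function(window, order) {
  if (is(window, "Recording")) window <- window@data
  K <- nrow(window); p <- as.integer(order)
  fits <- lapply(seq_len(K), function(k)
    fitEquation(window, k, setdiff(seq_len(K), k), p))
  A <- array(0, dim = c(K, K, p))
  for (k in seq_len(K)) {
    f <- fits[[k]]
    srcs <- as.integer(colnames(f@coeffs))
    for (i in seq_along(srcs)) A[k, srcs[i], ] <- f@coeffs[, i]
  }
  E <- t(vapply(fits, function(f) f@residuals,
                numeric(fits[[1L]]@nRows)))
  Sig <- tcrossprod(E) / ncol(E)
  # guard: residual covariance can be numerically semi-definite
  Sig <- (Sig + t(Sig)) / 2
  m <- varModel(A, Sig + diag(1e-12 * mean(diag(Sig)), K))
  attr(m, "fits") <- fits
  m
}
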