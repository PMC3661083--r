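# Partial extrinsic power, EIPR, PDC and the spectral-domain cross-checks.

#' PdcGrid: partial directed coherence on a frequency grid
#'
#' @slot frequencies normalized frequencies in [0, 0.5], strictly
#'   increasing.
#' @slot values \eqn{K \times K \times n_f} array of squared PDC
#'   \eqn{\pi^2_{k,l}(f)}; columns over targets sum to 1 at every f.
#' @seealso \code{\link{pdcGrid}}
#' @export
setClass("PdcGrid",
  representation(frequencies = "numeric", values = "array"))

setValidity("PdcGrid", function(object) {
  if (any(diff(object@frequencies) <= 0))
    return("frequency grid must be strictly increasing")
  if (dim(object@values)[3L] != length(object@frequencies))
    return("third dimension of 'values' must match the grid")
  if (any(object@values < -1e-12) || any(object@values > 1 + 1e-12))
    return("squared PDC must lie in [0, 1]")
  TRUE
})

setMethod("show", "PdcGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf("PdcGrid: %d x %d channels, %d frequencies in [%g, %g]\n",
              d[1L], d[2L], d[3L], min(object@frequencies),
              max(object@frequencies)))
  cat("  frequency-averaged pi^2:\n")
  print(signif(apply(object@values, c(1, 2), mean), 4))
})

#' Estimate the partial power of one source channel
#'
#' Estimates \eqn{V\{\mu_{k,l}\}}, the variance of the partial
#' contribution of source \eqn{l} to target \eqn{k}. The default
#' estimator is the empirical variance (1/n convention) of the realized
#' \eqn{\mu_{k,l}[n]} series; the alternative plugs the fitted
#' coefficients and the sample autocovariance of the source into the
#' quadratic form
#' \eqn{\sum_{j,j'} \hat A_{k,l}[j]\, \hat r_{x_l}[j-j']\, \hat A_{k,l}[j']}.
#' Both converge to the same population quantity.
#'
#' @param fit an \linkS4class{EquationFit}.
#' @param window the window the fit was computed on.
#' @param source channel in \code{c(target, extrinsicSet)}.
#' @param estimator \code{"empirical"} or \code{"plugin"}.
#' @return Nonnegative scalar.
#' @export
partialPower <- function(fit, window, source,
                         estimator = c("empirical", "plugin")) {
  estimator <- match.arg(estimator)
  if (is(window, "Recording")) window <- window@data
  source <- as.integer(source)
  sources <- c(fit@target, fit@extrinsicSet)
  if (!source %in% sources)
    stop("source ", source, " was not in the fitted channel set")
  if (estimator == "empirical") {
    mu <- partialContribution(fit, window, source)
    v <- mean((mu - mean(mu))^2)
    if (!is.finite(v)) v <- 0
    return(v)
  }
  p <- fit@order
  a <- fit@coeffs[, match(source, sources)]
  xs <- .demean(window)[source, ]
  r <- drop(stats::acf(xs, lag.max = p - 1L, type = "covariance",
                       plot = FALSE, demean = TRUE)$acf)
  q <- 0
  for (j in seq_len(p)) for (jp in seq_len(p))
    q <- q + a[j] * r[abs(j - jp) + 1L] * a[jp]
  max(q, 0)
}

# Core: EIPR from fixed extrinsic sets. Returns values + fits.
.eiprCore <- function(window, order, sets,
                      estimator = "empirical", intrinsicFloor = 1e-12) {
  K <- nrow(window)
  fits <- lapply(seq_len(K), function(k)
    fitEquation(window, k, sets[[k]], order))
  V <- matrix(0, K, K)
  for (k in seq_len(K)) {
    f <- fits[[k]]
    for (l in c(k, f@extrinsicSet))
      V[k, l] <- partialPower(f, window, l, estimator)
    chanVar <- mean((window[k, ] - mean(window[k, ]))^2)
    if (V[k, k] < intrinsicFloor * chanVar)
      stop(sprintf(paste0(
        "intrinsic power of channel %d (%.3g) is below the positive ",
        "floor; the EIPR denominator must be bounded below"), k, V[k, k]))
  }
  eta <- V / diag(V)
  diag(eta) <- 1
  list(values = eta, partialPowers = V, fits = fits)
}

#' EIPR matrix of a data window
#'
#' Computes the extrinsic-to-intrinsic power ratio
#' \eqn{\eta^2_{k,l} = \hat V\{\mu_{k,l}\} / \hat V\{\mu_{k,k}\}} for all
#' channel pairs of a window. With \code{useSelection = TRUE} each
#' target's regression uses its greedily selected extrinsic set and
#' unselected pairs are exactly 0; otherwise every equation uses all
#' other channels (selection disabled). The diagonal is exactly 1.
#'
#' @param window \eqn{K \times N_{win}} matrix or
#'   \linkS4class{Recording}.
#' @param order lag order p.
#' @param useSelection logical; run greedy channel selection per target.
#' @param estimator partial-power estimator, see
#'   \code{\link{partialPower}}.
#' @param sets optional list of extrinsic sets per target, overriding
#'   both modes (used e.g. to re-apply original sets to surrogates).
#' @param windowIndex index recorded in the result.
#' @return A \linkS4class{CouplingMatrix} of kind \code{"eipr"} with the
#'   estimated partial powers in attribute \code{"partialPowers"} and the
#'   per-target fits in attribute \code{"fits"}.
#' @examples
#' rec <- simulateVar(winterhalderModel(), 12800, seed = 1)
#' em <- eiprMatrix(rec, order = 5, useSelection = FALSE)
#' round(couplingValues(em), 5)
#' @export
eiprMatrix <- function(window, order, useSelection = FALSE,
                       estimator = c("empirical", "plugin"), sets = NULL,
                       windowIndex = 0L) {
  estimator <- match.arg(estimator)
  labels <- if (is(window, "Recording")) channelLabels(window) else
    rownames(window)
  if (is(window, "Recording")) window <- window@data
  K <- nrow(window)
  if (is.null(labels)) labels <- paste0("ch", seq_len(K))
  if (is.null(sets)) {
    sets <- if (useSelection)
      lapply(seq_len(K), function(k)
        selectChannels(window, k, order)@finalSet)
    else
      lapply(seq_len(K), function(k) setdiff(seq_len(K), k))
  }
  core <- .eiprCore(window, order, sets, estimator)
  vals <- core$values
  dimnames(vals) <- list(target = labels, source = labels)
  out <- new("CouplingMatrix", values = vals, kind = "eipr",
             windowIndex = as.integer(windowIndex), thresholds = NULL,
             significant = NULL, sets = sets)
  attr(out, "partialPowers") <- core$partialPowers
  attr(out, "fits") <- core$fits
  out
}

# A(f) = sum_j A[j] e^{-2 pi i f j} and Atilde(f) = I - A(f)
.freqResponse <- function(A, f) {
  K <- dim(A)[1L]; p <- dim(A)[3L]
  Af <- matrix(0 + 0i, K, K)
  for (j in seq_len(p))
    Af <- Af + A[, , j] * exp(-2i * pi * f * j)
  Af
}

#' Partial directed coherence of a VAR model
#'
#' Squared PDC on a uniform grid of normalized frequencies in [0, 0.5]:
#' \deqn{\pi^2_{k,l}(f) = \frac{|\tilde A_{k,l}(f)|^2}
#'       {\sum_{n=1}^K |\tilde A_{n,l}(f)|^2}, \quad
#'       \tilde A(f) = I - \sum_{j=1}^p A[j]\, e^{-2\pi i f j}.}
#' Columns (fixed source l) sum to 1 over targets at every frequency.
#'
#' @param model a \linkS4class{VarModel} (e.g. from
#'   \code{\link{fullVarFit}}).
#' @param nFreqs number of grid points.
#' @return A \linkS4class{PdcGrid}.
#' @examples
#' g <- pdcGrid(winterhalderModel(), nFreqs = 64)
#' apply(g@values[, , 1], 2, sum)  # all 1
#' @export
pdcGrid <- function(model, nFreqs = 512L) {
  stopifnot(is(model, "VarModel"), nFreqs >= 2)
  A <- lagMatrices(model)
  K <- dim(A)[1L]
  freqs <- seq(0, 0.5, length.out = nFreqs)
  vals <- array(0, dim = c(K, K, nFreqs))
  for (i in seq_along(freqs)) {
    At <- diag(K) - .freqResponse(A, freqs[i])
    m2 <- Mod(At)^2
    den <- colSums(m2)
    if (any(den == 0))
      stop(sprintf(
        "PDC undefined: all-zero column of Atilde at f = %.4f",
        freqs[i]))
    vals[, , i] <- sweep(m2, 2L, den, "/")
  }
  new("PdcGrid", frequencies = freqs, values = vals)
}

# trapezoid rule on a uniform grid
.trapz <- function(f, y) {
  n <- length(f)
  sum((y[-1L] + y[-n]) * diff(f)) / 2
}

#' Spectral-domain cross-check of EIPR and PDC
#'
#' Verifies the frequency-domain representations of the time-domain
#' quantities on a known model: (a) the partial-contribution variance as
#' a spectral integral \eqn{\int |\tilde A_{k,l}(f)|^2 S_{x_l}(f) df}
#' against the exact Lyapunov-equation value, (b) the spectral form of
#' EIPR against its time-domain definition, and (c) PDC rewritten through
#' partial-contribution spectral densities against its coefficient form.
#' Off-diagonal filters are taken from \eqn{\tilde A} and the intrinsic
#' (diagonal) filter from \eqn{A_{k,k}(f)}, whose moduli coincide
#' off-diagonally. Integration is by the trapezoid rule over [0, 0.5]
#' (doubled for the negative half-axis).
#'
#' @param model a stable \linkS4class{VarModel}.
#' @param nFreqs grid points for the quadrature.
#' @return List with matrices \code{specPower}, \code{timePower},
#'   \code{specEipr}, \code{timeEipr}, and scalars
#'   \code{maxRelDevPower}, \code{maxRelDevEipr}, \code{maxAbsDevPdc}.
#' @examples
#' cc <- spectralCrossCheck(winterhalderModel(), nFreqs = 1024)
#' cc$maxRelDevPower
#' @export
spectralCrossCheck <- function(model, nFreqs = 512L) {
  stopifnot(is(model, "VarModel"))
  .stopIfUnstable(model, "spectralCrossCheck")
  A <- lagMatrices(model)
  K <- dim(A)[1L]
  Sig <- noiseCov(model)
  freqs <- seq(0, 0.5, length.out = nFreqs)
  Smu <- array(0, dim = c(K, K, nFreqs))       # Eq.-consistent filters
  SmuTilde <- array(0, dim = c(K, K, nFreqs))  # Atilde everywhere (PDC)
  for (i in seq_along(freqs)) {
    Af <- .freqResponse(A, freqs[i])
    At <- diag(K) - Af
    H <- solve(At)
    Sx <- Re(diag(H %*% Sig %*% Conj(t(H))))   # channel spectra
    m2 <- Mod(At)^2
    diag(m2) <- Mod(diag(Af))^2                # intrinsic filter is A_kk
    Smu[, , i] <- sweep(m2, 2L, Sx, "*")
    mt <- Mod(At)^2
    SmuTilde[, , i] <- sweep(mt, 2L, Sx, "*")
  }
  specPower <- matrix(0, K, K)
  for (k in seq_len(K)) for (l in seq_len(K))
    specPower[k, l] <- 2 * .trapz(freqs, Smu[k, l, ])
  timePower <- truePartialPower(model)
  specEipr <- specPower / diag(specPower)
  diag(specEipr) <- 1
  timeEipr <- trueEipr(model)
  nz <- timePower > 0
  maxRelDevPower <- if (any(nz))
    max(abs(specPower[nz] - timePower[nz]) / timePower[nz]) else 0
  nzE <- timeEipr > 0
  maxRelDevEipr <- max(abs(specEipr[nzE] - timeEipr[nzE]) / timeEipr[nzE])
  # PDC via spectral densities of partial contributions vs coefficients
  pdcRef <- pdcGrid(model, nFreqs = nFreqs)@values
  pdcSpec <- array(0, dim = dim(SmuTilde))
  for (i in seq_along(freqs)) {
    den <- colSums(SmuTilde[, , i])
    pdcSpec[, , i] <- sweep(SmuTilde[, , i], 2L, den, "/")
  }
  list(specPower = specPower, timePower = timePower,
       specEipr = specEipr, timeEipr = timeEipr,
       maxRelDevPower = maxRelDevPower,
       maxRelDevEipr = maxRelDevEipr,
       maxAbsDevPdc = max(abs(pdcSpec - pdcRef)))
}
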