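#' VarModel: a vector autoregressive model specification
#'
#' Container for a (ground-truth or fitted) VAR model
#' \deqn{x[n] = \sum_{j=1}^{p} A[j] x[n-j] + \epsilon[n],}
#' with per-lag coefficient matrices \eqn{A[j]} and innovation covariance
#' \eqn{\Sigma_\epsilon}. The model is stable (admits a stationary solution)
#' iff the spectral radius of its companion matrix is below 1; stability is
#' not enforced at construction so that unstable candidates can be examined
#' with \code{\link{spectralRadius}}, but all simulation and analytic
#' routines reject unstable models.
#'
#' @slot coeffs \eqn{K \times K \times p} numeric array of lag matrices.
#' @slot noiseCov \eqn{K \times K} symmetric positive-definite matrix.
#'
#' @seealso \code{\link{varModel}}, \code{\link{winterhalderModel}},
#'   \code{\link{simulateVar}}, \code{\link{trueEipr}}
#' @export
setClass("VarModel",
  representation(coeffs = "array", noiseCov = "matrix"))

setValidity("VarModel", function(object) {
  d <- dim(object@coeffs)
  if (length(d) != 3L || d[1L] != d[2L])
    return("'coeffs' must be a K x K x p array")
  if (d[3L] < 1L)
    return("model order p must be >= 1")
  if (!all(is.finite(object@coeffs)))
    return("'coeffs' contains non-finite values")
  S <- object@noiseCov
  if (!is.numeric(S) || nrow(S) != d[1L] || ncol(S) != d[1L])
    return("'noiseCov' must be a K x K numeric matrix")
  if (!all(is.finite(S)) || max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S))))
    return("'noiseCov' must be symmetric")
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    return("'noiseCov' must be positive definite")
  TRUE
})

#' Construct a VarModel
#'
#' @param coeffs \eqn{K \times K \times p} array of lag coefficient
#'   matrices, or a list of \eqn{p} \eqn{K \times K} matrices (lag 1 first).
#' @param noiseCov innovation covariance matrix; defaults to the identity.
#' @return A \linkS4class{VarModel}.
#' @examples
#' m <- varModel(list(matrix(c(0.5, 0, 0.3, 0.4), 2, 2, byrow = TRUE)))
#' spectralRadius(m)
#' @export
varModel <- function(coeffs, noiseCov = NULL) {
  if (is.list(coeffs)) {
    K <- nrow(coeffs[[1L]])
    coeffs <- array(unlist(coeffs), dim = c(K, K, length(coeffs)))
  }
  if (is.matrix(coeffs))
    coeffs <- array(coeffs, dim = c(dim(coeffs), 1L))
  if (is.null(noiseCov))
    noiseCov <- diag(dim(coeffs)[1L])
  new("VarModel", coeffs = coeffs, noiseCov = as.matrix(noiseCov))
}

#' @describeIn nChannels channels of a VAR model
#' @export
setMethod("nChannels", "VarModel", function(x) dim(x@coeffs)[1L])

#' @describeIn modelOrder lag order of a VAR model
#' @export
setMethod("modelOrder", "VarModel", function(x) dim(x@coeffs)[3L])

#' @describeIn lagMatrices coefficient array of a VAR model
#' @export
setMethod("lagMatrices", "VarModel", function(x) x@coeffs)

#' @describeIn noiseCov innovation covariance of a VAR model
#' @export
setMethod("noiseCov", "VarModel", function(x) x@noiseCov)

setMethod("show", "VarModel", function(object) {
  K <- nChannels(object); p <- modelOrder(object)
  nz <- sum(object@coeffs != 0)
  cat(sprintf("VarModel: K = %d channels, order p = %d, %d nonzero coefficients\n",
              K, p, nz))
  cat(sprintf("  companion spectral radius: %.4f (%s)\n",
              spectralRadius(object),
              if (spectralRadius(object) < 1) "stable" else "UNSTABLE"))
})

#' Recording: a multichannel signal
#'
#' A \eqn{K \times N} matrix of uniformly sampled signals (channels in
#' rows) with a sampling rate and unique channel labels. This is the raw
#' substrate for windowed autoregressive coupling analysis.
#'
#' @slot data \eqn{K \times N} numeric matrix, channels in rows.
#' @slot samplingRate sampling rate in Hz.
#' @slot channelLabels character vector of K unique labels.
#' @slot startTime optional POSIXct start time (or NULL).
#'
#' @seealso \code{\link{recording}}, \code{\link{readRecording}},
#'   \code{\link{analyzeCoupling}}
#' @export
setClass("Recording",
  representation(data = "matrix", samplingRate = "numeric",
                 channelLabels = "character", startTime = "ANY"))

setValidity("Recording", function(object) {
  d <- object@data
  if (!is.numeric(d) || nrow(d) < 1L || ncol(d) < 1L)
    return("'data' must be a K x N numeric matrix with K, N >= 1")
  if (!all(is.finite(d)))
    return("'data' contains non-finite samples")
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    return("'samplingRate' must be a positive scalar (Hz)")
  if (length(object@channelLabels) != nrow(d))
    return("need one channel label per row of 'data'")
  if (anyDuplicated(object@channelLabels))
    return("channel labels must be unique")
  TRUE
})

#' Construct a Recording
#'
#' @param data \eqn{K \times N} numeric matrix, channels in rows.
#' @param samplingRate sampling rate in Hz.
#' @param channelLabels optional labels; default \code{ch1, ch2, ...}.
#' @param startTime optional POSIXct.
#' @return A \linkS4class{Recording}.
#' @examples
#' rec <- recording(matrix(rnorm(200), 2), samplingRate = 100)
#' nSamples(rec)
#' @export
recording <- function(data, samplingRate, channelLabels = NULL,
                      startTime = NULL) {
  data <- as.matrix(data)
  if (is.null(channelLabels))
    channelLabels <- paste0("ch", seq_len(nrow(data)))
  new("Recording", data = data, samplingRate = as.numeric(samplingRate),
      channelLabels = as.character(channelLabels), startTime = startTime)
}

#' @describeIn nChannels channels of a recording
#' @export
setMethod("nChannels", "Recording", function(x) nrow(x@data))

#' @describeIn nSamples samples per channel of a recording
#' @export
setMethod("nSamples", "Recording", function(x) ncol(x@data))

#' @describeIn samplingRate sampling rate of a recording
#' @export
setMethod("samplingRate", "Recording", function(x) x@samplingRate)

#' @describeIn channelLabels labels of a recording
#' @export
setMethod("channelLabels", "Recording", function(x) x@channelLabels)

#' @describeIn signalMatrix sample matrix of a recording
#' @export
setMethod("signalMatrix", "Recording", function(x) {
  m <- x@data
  rownames(m) <- x@channelLabels
  m
})

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording: %d channels x %d samples at %g Hz (%.3g s)\n",
              nChannels(object), nSamples(object), samplingRate(object),
              nSamples(object) / samplingRate(object)))
  cat("  channels:", paste(utils::head(object@channelLabels, 8L),
                           collapse = ", "),
      if (nChannels(object) > 8L) "..." else "", "\n")
})

#' EquationFit: one target channel's reduced regression
#'
#' Result of regressing target channel \eqn{k} on lags \eqn{1..p} of itself
#' and of every channel in its extrinsic set \eqn{L_k} by ordinary least
#' squares over rows \eqn{n = p+1, \dots, N_{win}}. Coefficients of
#' channels outside \eqn{\{k\} \cup L_k} are implicitly zero.
#'
#' @slot target integer target channel index \eqn{k}.
#' @slot extrinsicSet integer vector \eqn{L_k} (never contains the target).
#' @slot order lag order \eqn{p}.
#' @slot coeffs \eqn{p \times m} matrix of coefficients; columns in the
#'   order \code{c(target, extrinsicSet)}, named by channel index.
#' @slot residuals residual series over the regression rows.
#' @slot rss residual sum of squares.
#' @slot nRows number of regression rows, \eqn{N_{win} - p}.
#'
#' @seealso \code{\link{fitEquation}}, \code{\link{partialContribution}}
#' @export
setClass("EquationFit",
  representation(target = "integer", extrinsicSet = "integer",
                 order = "integer", coeffs = "matrix",
                 residuals = "numeric", rss = "numeric", nRows = "integer"))

setValidity("EquationFit", function(object) {
  if (object@target %in% object@extrinsicSet)
    return("target channel cannot belong to its own extrinsic set")
  if (ncol(object@coeffs) != 1L + length(object@extrinsicSet))
    return("coefficient columns must match {target} U extrinsic set")
  if (nrow(object@coeffs) != object@order)
    return("coefficient rows must equal the lag order")
  if (abs(object@rss - sum(object@residuals^2)) >
      1e-8 * max(1, object@rss))
    return("'rss' inconsistent with residuals")
  TRUE
})

#' @describeIn modelOrder lag order of a single-equation fit
#' @export
setMethod("modelOrder", "EquationFit", function(x) x@order)

setMethod("show", "EquationFit", function(object) {
  cat(sprintf("EquationFit: target %d, extrinsic set {%s}, p = %d\n",
              object@target,
              paste(object@extrinsicSet, collapse = ","), object@order))
  cat(sprintf("  rows = %d, RSS = %.6g, sigma^2 = %.6g\n",
              object@nRows, object@rss, object@rss / object@nRows))
})

#' SelectionTrace: record of greedy BIC channel selection
#'
#' Stepwise history of the bottom-up construction of an extrinsic channel
#' set: each step holds the candidate BIC evaluations, the chosen channel
#' (NA when the step stopped the search) and the criterion value after the
#' step.
#'
#' @slot target target channel index.
#' @slot steps list of steps; each a list with \code{candidates} (named
#'   numeric of candidate BIC values), \code{chosen} (integer or NA) and
#'   \code{bicAfter}.
#' @slot finalSet integer vector, the selected extrinsic channel set.
#' @slot finalBic BIC value of the selected model.
#'
#' @seealso \code{\link{selectChannels}}, \code{\link{bicValue}}
#' @export
setClass("SelectionTrace",
  representation(target = "integer", steps = "list",
                 finalSet = "integer", finalBic = "numeric"))

setMethod("show", "SelectionTrace", function(object) {
  cat(sprintf("SelectionTrace: target %d, final set {%s}, BIC = %.4f\n",
              object@target, paste(object@finalSet, collapse = ","),
              object@finalBic))
  for (i in seq_along(object@steps)) {
    st <- object@steps[[i]]
    cat(sprintf("  step %d: %s -> %s\n", i,
                paste(sprintf("%s:%.4f", names(st$candidates),
                              st$candidates), collapse = " "),
                if (is.na(st$chosen)) "STOP"
                else sprintf("choose %d (BIC %.4f)", st$chosen, st$bicAfter)))
  }
})

#' CouplingMatrix: directed coupling values between channel pairs
#'
#' A \eqn{K \times K} matrix of directed coupling values: entry
#' \eqn{(k, l)} quantifies the influence of source channel \eqn{l} on
#' target channel \eqn{k}. For kind \code{"eipr"} the diagonal is exactly
#' 1 and entries for sources outside the target's extrinsic set are 0.
#' Optional surrogate significance thresholds and the resulting mask are
#' carried alongside.
#'
#' @slot values \eqn{K \times K} numeric matrix (row = target,
#'   column = source).
#' @slot kind \code{"eipr"} or \code{"partial_power"}.
#' @slot windowIndex analysis window index (0 for a single-window run).
#' @slot thresholds \eqn{K \times K} numeric matrix or NULL.
#' @slot significant \eqn{K \times K} logical matrix (diagonal NA) or NULL.
#' @slot sets list of extrinsic sets used per target.
#'
#' @seealso \code{\link{eiprMatrix}}, \code{\link{significanceThresholds}},
#'   \code{\link{buildGraph}}
#' @export
setClass("CouplingMatrix",
  representation(values = "matrix", kind = "character",
                 windowIndex = "integer", thresholds = "ANY",
                 significant = "ANY", sets = "list"))

setValidity("CouplingMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v))
    return("'values' must be square")
  if (!object@kind %in% c("eipr", "partial_power"))
    return("kind must be 'eipr' or 'partial_power'")
  if (object@kind == "eipr") {
    if (any(v < 0))
      return("EIPR values must be nonnegative")
    if (any(diag(v) != 1))
      return("EIPR diagonal must be exactly 1")
  }
  if (!is.null(object@thresholds) &&
      !identical(dim(object@thresholds), dim(v)))
    return("'thresholds' must match 'values' in shape")
  TRUE
})

#' @describeIn nChannels channels of a coupling matrix
#' @export
setMethod("nChannels", "CouplingMatrix", function(x) nrow(x@values))

#' @describeIn couplingValues value matrix
#' @export
setMethod("couplingValues", "CouplingMatrix", function(x) x@values)

#' @describeIn thresholdMatrix surrogate thresholds (or NULL)
#' @export
setMethod("thresholdMatrix", "CouplingMatrix", function(x) x@thresholds)

#' @describeIn significanceMask significance mask (or NULL)
#' @export
setMethod("significanceMask", "CouplingMatrix", function(x) x@significant)

#' @describeIn extrinsicSets extrinsic sets used per target
#' @export
setMethod("extrinsicSets", "CouplingMatrix", function(x) x@sets)

#' @describeIn channelLabels labels of a coupling matrix
#' @export
setMethod("channelLabels", "CouplingMatrix",
          function(x) rownames(x@values))

setMethod("show", "CouplingMatrix", function(object) {
  cat(sprintf("CouplingMatrix (%s), %d channels, window %d\n",
              object@kind, nChannels(object), object@windowIndex))
  print(signif(object@values, 5))
  if (!is.null(object@significant)) {
    ns <- sum(object@significant, na.rm = TRUE)
    cat(sprintf("  %d significant directed pair(s)\n", ns))
  }
})

#' CouplingGraph: directed graph of significant couplings
#'
#' Directed graph over electrode/channel nodes for one analysis window:
#' an edge \eqn{l \to k} states that source channel \eqn{l} couples into
#' target channel \eqn{k} with weight equal to the coupling value. The
#' diagonal (self-coupling) is never rendered.
#'
#' @slot nodes data.frame with columns \code{label} and optionally
#'   \code{x}, \code{y} layout coordinates.
#' @slot edges data.frame with columns \code{source}, \code{target}
#'   (labels), \code{weight}, \code{significant}.
#' @slot windowIndex analysis window index.
#' @slot timeSpan numeric length-2, window start/end in seconds.
#'
#' @seealso \code{\link{buildGraph}}, \code{\link{asIgraph}},
#'   \code{\link{writeGraphML}}
#' @export
setClass("CouplingGraph",
  representation(nodes = "data.frame", edges = "data.frame",
                 windowIndex = "integer", timeSpan = "numeric"))

setValidity("CouplingGraph", function(object) {
  if (!all(c("source", "target", "weight") %in% colnames(object@edges)) &&
      nrow(object@edges) > 0)
    return("edges need 'source', 'target' and 'weight' columns")
  if (nrow(object@edges) > 0) {
    if (!all(object@edges$source %in% object@nodes$label) ||
        !all(object@edges$target %in% object@nodes$label))
      return("edges may only connect existing nodes")
    if (any(object@edges$source == object@edges$target))
      return("self-loops are not rendered")
  }
  TRUE
})

#' @describeIn nChannels nodes of a coupling graph
#' @export
setMethod("nChannels", "CouplingGraph", function(x) nrow(x@nodes))

#' @describeIn channelLabels node labels of a coupling graph
#' @export
setMethod("channelLabels", "CouplingGraph", function(x) x@nodes$label)

#' @describeIn asIgraph build the igraph representation
#' @export
setMethod("asIgraph", "CouplingGraph", function(x) {
  g <- igraph::graph_from_data_frame(
    if (nrow(x@edges)) x@edges else
      data.frame(source = character(), target = character()),
    directed = TRUE, vertices = x@nodes)
  g
})

setMethod("show", "CouplingGraph", function(object) {
  cat(sprintf("CouplingGraph: window %d (%.2f-%.2f s), %d nodes, %d edges\n",
              object@windowIndex, object@timeSpan[1L], object@timeSpan[2L],
              nrow(object@nodes), nrow(object@edges)))
  if (nrow(object@edges))
    for (i in seq_len(min(nrow(object@edges), 12L)))
      cat(sprintf("  %s -> %s  (%.4g%s)\n", object@edges$source[i],
                  object@edges$target[i], object@edges$weight[i],
                  if (isTRUE(object@edges$significant[i])) ", sig" else ""))
})
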