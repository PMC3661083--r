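#' Number of channels
#'
#' @param x a \linkS4class{VarModel}, \linkS4class{Recording},
#'   \linkS4class{CouplingMatrix} or \linkS4class{CouplingGraph}.
#' @return Integer scalar, the number of channels \eqn{K}.
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' Autoregressive model order
#'
#' @param x a \linkS4class{VarModel} or \linkS4class{EquationFit}.
#' @return Integer scalar, the lag order \eqn{p}.
#' @export
setGeneric("modelOrder", function(x) standardGeneric("modelOrder"))

#' Lag coefficient matrices
#'
#' @param x a \linkS4class{VarModel}.
#' @return A \eqn{K \times K \times p} array; \code{lagMatrices(x)[ , , j]}
#'   is the coefficient matrix at lag \eqn{j}.
#' @export
setGeneric("lagMatrices", function(x) standardGeneric("lagMatrices"))

#' Innovation noise covariance
#'
#' @param x a \linkS4class{VarModel}.
#' @return The \eqn{K \times K} innovation covariance matrix.
#' @export
setGeneric("noiseCov", function(x) standardGeneric("noiseCov"))

#' Companion-matrix spectral radius
#'
#' Largest eigenvalue modulus of the companion form of an autoregressive
#' coefficient stack; the process is stable (stationary) iff this is < 1.
#'
#' @param x a \linkS4class{VarModel}, \linkS4class{EquationFit} of a full
#'   system, or a \eqn{K \times K \times p} coefficient array.
#' @return Nonnegative numeric scalar.
#' @export
setGeneric("spectralRadius", function(x) standardGeneric("spectralRadius"))

#' Sampling rate accessor
#'
#' @param x a \linkS4class{Recording}.
#' @return Sampling rate in Hz.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Channel labels accessor
#'
#' @param x a \linkS4class{Recording}, \linkS4class{CouplingMatrix} or
#'   \linkS4class{CouplingGraph}.
#' @return Character vector of channel labels.
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' Signal matrix accessor
#'
#' @param x a \linkS4class{Recording}.
#' @return The \eqn{K \times N} numeric matrix of samples (channels in rows).
#' @export
setGeneric("signalMatrix", function(x) standardGeneric("signalMatrix"))

#' Number of samples
#'
#' @param x a \linkS4class{Recording}.
#' @return Integer scalar, samples per channel.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' Coupling value matrix accessor
#'
#' @param x a \linkS4class{CouplingMatrix}.
#' @return \eqn{K \times K} numeric matrix; entry \eqn{(k, l)} measures the
#'   directed influence of source channel \eqn{l} on target channel \eqn{k}.
#' @export
setGeneric("couplingValues", function(x) standardGeneric("couplingValues"))

#' Significance threshold matrix accessor
#'
#' @param x a \linkS4class{CouplingMatrix}.
#' @return \eqn{K \times K} numeric matrix of surrogate thresholds, or NULL.
#' @export
setGeneric("thresholdMatrix", function(x) standardGeneric("thresholdMatrix"))

#' Significance mask accessor
#'
#' @param x a \linkS4class{CouplingMatrix}.
#' @return \eqn{K \times K} logical matrix (diagonal NA), or NULL.
#' @export
setGeneric("significanceMask", function(x) standardGeneric("significanceMask"))

#' Extrinsic channel sets accessor
#'
#' @param x a \linkS4class{CouplingMatrix}.
#' @return List of length \eqn{K}; element \eqn{k} holds the source indices
#'   retained in target \eqn{k}'s regression.
#' @export
setGeneric("extrinsicSets", function(x) standardGeneric("extrinsicSets"))

#' Convert to an igraph object
#'
#' @param x a \linkS4class{CouplingGraph}.
#' @return A directed \pkg{igraph} graph with edge attribute \code{weight}.
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))
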