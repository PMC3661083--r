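# Greedy bottom-up extrinsic channel selection under BIC.

#' Bayesian information criterion of a reduced regression
#'
#' For target \eqn{k} with extrinsic set \eqn{L_k}, fits the reduced
#' autoregression and evaluates
#' \deqn{BIC(L_k) = \ln\big(S_{err} / n_{rows}\big) +
#'       \frac{M \ln N_{win}}{N_{win}}, \quad M = (|L_k| + 1)\, p.}
#' The residual sum of squares is normalized by the number of regression
#' rows inside the logarithm (mean squared residual); the argmin over
#' candidate sets is unchanged by this constant shift and the resulting
#' magnitudes line up with a residual-variance reading of the criterion.
#'
#' @param window \eqn{K \times N_{win}} matrix or
#'   \linkS4class{Recording}.
#' @param target target channel index.
#' @param extrinsicSet candidate extrinsic set.
#' @param order lag order p.
#' @param fit optionally, a precomputed \linkS4class{EquationFit} for this
#'   target/set (skips refitting).
#' @return List with \code{value}, \code{nParams}, \code{rss}, \code{n}
#'   (window length) and \code{nRows}.
#' @seealso \code{\link{selectChannels}}
#' @export
bicValue <- function(window, target, extrinsicSet = integer(), order = 1L,
                     fit = NULL) {
  if (is(window, "Recording")) window <- window@data
  N <- ncol(window)
  if (is.null(fit))
    fit <- fitEquation(window, target, extrinsicSet, order)
  M <- (length(fit@extrinsicSet) + 1L) * fit@order
  list(value = log(fit@rss / fit@nRows) + M * log(N) / N,
       nParams = M, rss = fit@rss, n = N, nRows = fit@nRows)
}

#' Greedy bottom-up extrinsic channel selection
#'
#' Builds the extrinsic channel set \eqn{L_k} for one target channel by
#' forward selection: starting from the empty set, each step evaluates
#' the BIC of \eqn{L_k \cup \{l\}} for every remaining channel
#' \eqn{l \neq k} and adds the minimizer if it strictly decreases the
#' current criterion value, otherwise stops. Exact ties are broken
#' towards the lowest channel index for determinism. Coefficients of
#' unselected channels are zero by construction.
#'
#' @param window \eqn{K \times N_{win}} matrix or
#'   \linkS4class{Recording}.
#' @param target target channel index.
#' @param order lag order p.
#' @param maxSetSize optional cap on \eqn{|L_k|}; default K - 1 (no cap).
#' @return A \linkS4class{SelectionTrace}; the accepted-step BIC sequence
#'   is strictly decreasing.
#' @examples
#' rec <- simulateVar(winterhalderModel(), 12800, seed = 1)
#' selectChannels(rec, target = 1, order = 5)  # selects {2}
#' @export
selectChannels <- function(window, target, order, maxSetSize = NULL) {
  if (is(window, "Recording")) window <- window@data
  K <- nrow(window)
  stopifnot(K >= 2)
  target <- as.integer(target)
  if (is.null(maxSetSize)) maxSetSize <- K - 1L
  current <- integer()
  curBic <- bicValue(window, target, current, order)$value
  steps <- list()
  repeat {
    remaining <- setdiff(seq_len(K), c(target, current))
    if (!length(remaining) || length(current) >= maxSetSize) break
    cand <- vapply(remaining, function(l)
      bicValue(window, target, c(current, l), order)$value, numeric(1))
    names(cand) <- remaining
    best <- which.min(cand)  # first minimum = lowest channel index
    if (cand[best] < curBic) {
      chosen <- remaining[best]
      current <- sort(c(current, chosen))
      curBic <- unname(cand[best])
      steps[[length(steps) + 1L]] <-
        list(candidates = cand, chosen = chosen, bicAfter = curBic)
    } else {
      steps[[length(steps) + 1L]] <-
        list(candidates = cand, chosen = NA_integer_, bicAfter = curBic)
      break
    }
  }
  new("SelectionTrace", target = target, steps = steps,
      finalSet = current, finalBic = curBic)
}

#' Tabulate a selection trace
#'
#' Flattens a \linkS4class{SelectionTrace} into a data.frame mirroring the
#' stepwise report layout (step, candidate channel, candidate BIC, chosen).
#'
#' @param trace a \linkS4class{SelectionTrace}.
#' @return data.frame with columns \code{step}, \code{candidate},
#'   \code{bic}, \code{chosen}.
#' @export
selectionTable <- function(trace) {
  rows <- lapply(seq_along(trace@steps), function(i) {
    st <- trace@steps[[i]]
    data.frame(step = i,
               candidate = as.integer(names(st$candidates)),
               bic = unname(st$candidates),
               chosen = ifelse(is.na(st$chosen), "STOP",
                               as.character(st$chosen)))
  })
  do.call(rbind, rows)
}
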