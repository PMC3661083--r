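# End-to-end windowed analysis: preprocessing, sliding windows,
# per-window EIPR + significance, directed coupling graphs.

#' Pipeline configuration
#'
#' @param notchHz line-interference notch frequency in Hz (default 50).
#' @param lowpassHz anti-aliasing low-pass cut-off in Hz (default 64).
#' @param targetRate rate after downsampling in Hz (default 128).
#' @param windowSeconds analysis window length in seconds (default 4).
#' @param order autoregressive lag order p (default 7, enough for a
#'   spectrum with three peaks plus slow components at 128 Hz).
#' @param stepSeconds window step; defaults to the window length
#'   (non-overlapping windows).
#' @param edgeRule list with \code{mode} (\code{"significant"}: every
#'   threshold-exceeding pair becomes an edge; \code{"top_fraction"}:
#'   only the top \code{fraction} of significant pairs by EIPR) and
#'   \code{fraction}.
#' @param notchQ quality factor of the 2nd-order notch (default 35).
#' @param lowpassOrder order of the Butterworth low-pass (default 8).
#' @return List of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(notchHz = 50, lowpassHz = 64, targetRate = 128,
                           windowSeconds = 4, order = 7L,
                           stepSeconds = windowSeconds,
                           edgeRule = list(mode = "significant",
                                           fraction = 0.1),
                           notchQ = 35, lowpassOrder = 8L) {
  if (!is.null(lowpassHz) && lowpassHz > targetRate / 2)
    stop("low-pass cut-off must not exceed the target Nyquist rate")
  stopifnot(windowSeconds > 0, order >= 1)
  structure(list(notchHz = notchHz, lowpassHz = lowpassHz,
                 targetRate = targetRate, windowSeconds = windowSeconds,
                 order = as.integer(order), stepSeconds = stepSeconds,
                 edgeRule = edgeRule, notchQ = notchQ,
                 lowpassOrder = as.integer(lowpassOrder)),
            class = "PipelineConfig")
}

# RBJ-cookbook 2nd-order notch biquad at f0 with quality factor Q
.notchCoefs <- function(f0, fs, Q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1L], a = a / a[1L])
}

#' Preprocess a recording
#'
#' Standard conditioning chain for clinical biosignals: zero-phase
#' (forward-backward) notch filtering of line interference, zero-phase
#' Butterworth low-pass to avoid aliasing, then integer-factor
#' decimation to the target rate. Skipped automatically when the
#' recording is already at the target rate and the notch frequency is
#' above the new Nyquist rate.
#'
#' @param rec a \linkS4class{Recording}.
#' @param config a \code{\link{pipelineConfig}}.
#' @return A \linkS4class{Recording} at \code{config$targetRate} Hz.
#' @examples
#' rec <- recording(matrix(rnorm(2 * 2560), 2), samplingRate = 256)
#' preprocessRecording(rec)  # 128 Hz, half the samples
#' @export
preprocessRecording <- function(rec, config = pipelineConfig()) {
  stopifnot(is(rec, "Recording"))
  fs <- samplingRate(rec)
  if (fs < config$targetRate)
    stop(sprintf("sampling rate %g Hz below target %g Hz", fs,
                 config$targetRate))
  factor <- fs / config$targetRate
  if (abs(factor - round(factor)) > 1e-9)
    stop(sprintf(paste0(
      "non-integer decimation factor %.4f from %g to %g Hz; resample ",
      "to an integer multiple of the target rate first"), factor, fs,
      config$targetRate))
  factor <- as.integer(round(factor))
  X <- rec@data
  if (!is.null(config$notchHz) && config$notchHz < fs / 2) {
    nf <- .notchCoefs(config$notchHz, fs, config$notchQ)
    for (k in seq_len(nrow(X)))
      X[k, ] <- signal::filtfilt(nf$b, nf$a, X[k, ])
  }
  if (!is.null(config$lowpassHz) && config$lowpassHz < fs / 2) {
    bw <- signal::butter(config$lowpassOrder,
                         config$lowpassHz / (fs / 2), type = "low")
    for (k in seq_len(nrow(X)))
      X[k, ] <- signal::filtfilt(bw, X[k, ])
  }
  if (factor > 1L)
    X <- X[, seq(1L, ncol(X), by = factor), drop = FALSE]
  recording(X, samplingRate = config$targetRate,
            channelLabels = channelLabels(rec),
            startTime = rec@startTime)
}

#' Windowed EIPR analysis of a recording
#'
#' Slides non-overlapping (by default) analysis windows over a
#' preprocessed recording and, per window, selects each target's
#' extrinsic channel set, computes the EIPR matrix, derives surrogate
#' significance thresholds and builds the directed coupling graph.
#' Windows whose regressions are singular are skipped with a warning
#' rather than aborting the run.
#'
#' @param rec a preprocessed \linkS4class{Recording} (see
#'   \code{\link{preprocessRecording}}); it is analyzed as-is.
#' @param config a \code{\link{pipelineConfig}}.
#' @param sig a \code{\link{significanceConfig}}.
#' @param useSelection logical; greedy channel selection per target
#'   (default TRUE, the intended operating mode).
#' @param layout optional data.frame with columns \code{label},
#'   \code{x}, \code{y} for graph rendering.
#' @param windows optional integer vector restricting which window
#'   indices to analyze (1-based; default all complete windows).
#' @return List of class \code{"CouplingAnalysis"}: per analyzed window a
#'   list with \code{matrix} (a \linkS4class{CouplingMatrix} with
#'   thresholds and mask), \code{graph} (a \linkS4class{CouplingGraph})
#'   and \code{timeSpan} in seconds.
#' @export
analyzeCoupling <- function(rec, config = pipelineConfig(),
                            sig = significanceConfig(),
                            useSelection = TRUE, layout = NULL,
                            windows = NULL) {
  stopifnot(is(rec, "Recording"))
  fs <- samplingRate(rec)
  Nwin <- as.integer(round(config$windowSeconds * fs))
  step <- as.integer(round(config$stepSeconds * fs))
  N <- nSamples(rec)
  K <- nChannels(rec)
  if (Nwin > N) stop("recording shorter than one analysis window")
  if (Nwin - config$order <= (config$order + 1) * (K + 1))
    warning("window barely identifies the full model; consider a longer",
            " window or smaller order")
  starts <- seq(1L, N - Nwin + 1L, by = step)
  idx <- seq_along(starts)
  if (!is.null(windows)) idx <- intersect(idx, as.integer(windows))
  out <- list()
  for (w in idx) {
    s0 <- starts[w]
    win <- rec@data[, s0:(s0 + Nwin - 1L), drop = FALSE]
    res <- tryCatch({
      sets <- if (useSelection)
        lapply(seq_len(K), function(k)
          selectChannels(win, k, config$order)@finalSet)
      else
        lapply(seq_len(K), function(k) setdiff(seq_len(K), k))
      sigW <- sig
      sigW$seed <- .streamSeed(sig$seed, 1000L * w)
      cm <- eiprSignificance(win, config$order, config = sigW,
                             sets = sets, windowIndex = w)
      rownames(cm@values) <- colnames(cm@values) <- channelLabels(rec)
      span <- c(s0 - 1L, s0 - 1L + Nwin) / fs
      g <- buildGraph(cm, labels = channelLabels(rec), layout = layout,
                      edgeRule = config$edgeRule, timeSpan = span)
      list(matrix = cm, graph = g, timeSpan = span, window = w)
    }, error = function(e) {
      warning(sprintf("window %d skipped: %s", w, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (!is.null(res)) out[[length(out) + 1L]] <- res
  }
  structure(out, class = "CouplingAnalysis",
            samplingRate = fs, windowSamples = Nwin)
}
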