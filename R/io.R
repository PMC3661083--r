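# File formats: delimited recordings with a sampling-rate header, minimal
# EDF (European Data Format) reading/writing, VAR model configs (YAML),
# coupling tables and run manifests.
#
# No installed R package reads EDF, so a minimal reader/writer for the
# standard 16-bit variant is implemented here with readBin/writeBin.

#' Write a recording to file
#'
#' Delimited format: a one-line header \code{# fs=<Hz> channels=<labels>}
#' followed by the K x N sample matrix (channels in rows). EDF format:
#' standard 16-bit EDF with 1-second data records; samples beyond a whole
#' number of records are dropped with a warning.
#'
#' @param rec a \linkS4class{Recording}.
#' @param file output path.
#' @param format \code{"auto"} (by extension: .edf is EDF, anything else
#'   delimited), \code{"delim"} or \code{"edf"}.
#' @return Invisibly, the file path.
#' @export
writeRecording <- function(rec, file, format = c("auto", "delim", "edf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", file, ignore.case = TRUE)) "edf"
              else "delim"
  if (format == "edf") return(.writeEdf(rec, file))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%g channels=%s", samplingRate(rec),
                     paste(channelLabels(rec), collapse = ",")), con)
  utils::write.table(rec@data, con, row.names = FALSE,
                     col.names = FALSE, sep = " ")
  invisible(file)
}

#' Read a recording from file
#'
#' Accepts the delimited format written by \code{\link{writeRecording}}
#' (header line \code{# fs=<Hz> channels=<comma-separated labels>}, then
#' channels x samples) or a standard 16-bit EDF file.
#'
#' @param file input path.
#' @param format \code{"auto"}, \code{"delim"} or \code{"edf"}.
#' @return A \linkS4class{Recording}.
#' @export
readRecording <- function(file, format = c("auto", "delim", "edf")) {
  format <- match.arg(format)
  if (format == "auto") {
    if (grepl("\\.edf$", file, ignore.case = TRUE)) format <- "edf"
    else {
      magic <- readBin(file, "raw", n = 1L)
      format <- if (length(magic) && magic == charToRaw("#")) "delim"
                else "edf"
    }
  }
  if (format == "edf") return(.readEdf(file))
  lines <- readLines(file, n = 1L)
  if (!grepl("^#\\s*fs=", lines))
    stop("missing '# fs=<Hz> channels=...' header in ", file)
  fs <- as.numeric(sub("^#\\s*fs=([0-9.eE+-]+).*$", "\\1", lines))
  labels <- NULL
  if (grepl("channels=", lines))
    labels <- strsplit(sub("^.*channels=([^ ]+).*$", "\\1", lines),
                       ",")[[1L]]
  M <- as.matrix(utils::read.table(file, skip = 1L))
  dimnames(M) <- NULL
  if (nrow(M) < 1L || !nrow(M)) stop("empty recording file: ", file)
  recording(M, samplingRate = fs, channelLabels = labels)
}

.padAscii <- function(x, width) {
  x <- substr(x, 1L, width)
  sprintf("%-*s", width, x)
}

.writeEdf <- function(rec, file) {
  fs <- samplingRate(rec)
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF writer requires an integer sampling rate")
  spr <- as.integer(round(fs))           # 1-second records
  K <- nChannels(rec); N <- nSamples(rec)
  nrec <- N %/% spr
  if (nrec < 1L) stop("recording shorter than one EDF data record (1 s)")
  if (nrec * spr < N)
    warning(sprintf("dropping %d trailing sample(s) beyond %d full 1-s records",
                    N - nrec * spr, nrec))
  X <- rec@data[, seq_len(nrec * spr), drop = FALSE]
  physMin <- apply(X, 1L, min); physMax <- apply(X, 1L, max)
  same <- physMax - physMin < 1e-12
  physMax[same] <- physMin[same] + 1
  digMin <- -32768; digMax <- 32767
  con <- file(file, "wb")
  on.exit(close(con))
  hdr <- paste0(.padAscii("0", 8L),
                .padAscii("synthetic recording", 80L),
                .padAscii("eipr package export", 80L),
                .padAscii("01.01.00", 8L), .padAscii("00.00.00", 8L),
                .padAscii(as.character(256L + 256L * K), 8L),
                .padAscii("", 44L),
                .padAscii(as.character(nrec), 8L),
                .padAscii("1", 8L),
                .padAscii(as.character(K), 4L))
  writeChar(hdr, con, eos = NULL)
  fld <- function(vals, width)
    writeChar(paste(vapply(vals, .padAscii, "", width = width),
                    collapse = ""), con, eos = NULL)
  fld(channelLabels(rec), 16L)
  fld(rep("", K), 80L)                    # transducer
  fld(rep("uV", K), 8L)                   # physical dimension
  fld(sprintf("%.8g", physMin), 8L)
  fld(sprintf("%.8g", physMax), 8L)
  fld(rep(as.character(digMin), K), 8L)
  fld(rep(as.character(digMax), K), 8L)
  fld(rep("", K), 80L)                    # prefiltering
  fld(rep(as.character(spr), K), 8L)
  fld(rep("", K), 32L)
  scale <- (physMax - physMin) / (digMax - digMin)
  for (r in seq_len(nrec)) {
    cols <- (r - 1L) * spr + seq_len(spr)
    for (k in seq_len(K)) {
      dig <- round((X[k, cols] - physMin[k]) / scale[k] + digMin)
      writeBin(as.integer(pmin(pmax(dig, digMin), digMax)), con,
               size = 2L, endian = "little")
    }
  }
  invisible(file)
}

.readEdf <- function(file) {
  con <- file(file, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8L)                                  # version
  rd(80L); rd(80L); rd(8L)
  startTime <- rd(8L)
  rd(8L); rd(44L)
  nrec <- as.integer(rd(8L))
  dur <- as.numeric(rd(8L))
  K <- as.integer(rd(4L))
  if (is.na(K) || K < 1L) stop("not a valid EDF file: ", file)
  rdv <- function(w) vapply(seq_len(K), function(i) rd(w), "")
  labels <- rdv(16L)
  rdv(80L); rdv(8L)
  physMin <- as.numeric(rdv(8L)); physMax <- as.numeric(rdv(8L))
  digMin <- as.numeric(rdv(8L)); digMax <- as.numeric(rdv(8L))
  rdv(80L)
  spr <- as.integer(rdv(8L))
  rdv(32L)
  if (length(unique(spr)) != 1L)
    stop("EDF reader requires a common sampling rate across signals")
  scale <- (physMax - physMin) / (digMax - digMin)
  X <- matrix(0, K, nrec * spr[1L])
  for (r in seq_len(nrec)) {
    for (k in seq_len(K)) {
      dig <- readBin(con, "integer", n = spr[1L], size = 2L,
                     signed = TRUE, endian = "little")
      X[k, (r - 1L) * spr[1L] + seq_len(spr[1L])] <-
        (dig - digMin[k]) * scale[k] + physMin[k]
    }
  }
  if (anyDuplicated(labels))
    labels <- make.unique(labels)
  recording(X, samplingRate = spr[1L] / dur, channelLabels = labels)
}

#' Write a VAR model specification
#'
#' Serializes a \linkS4class{VarModel} as a YAML config with lag-indexed
#' coefficient matrices and the noise covariance.
#'
#' @param model a \linkS4class{VarModel}.
#' @param file output path.
#' @return Invisibly, the file path.
#' @export
writeVarModel <- function(model, file) {
  A <- lagMatrices(model)
  p <- dim(A)[3L]
  obj <- list(n_channels = nChannels(model), order = p)
  # store row-wise lists for readability
  obj$coeffs <- lapply(seq_len(p), function(j)
    lapply(seq_len(nChannels(model)), function(k) unname(A[k, , j])))
  obj$noise_cov <- lapply(seq_len(nChannels(model)), function(k)
    unname(noiseCov(model)[k, ]))
  yaml::write_yaml(obj, file)
  invisible(file)
}

#' Read a VAR model specification
#'
#' @param file YAML path written by \code{\link{writeVarModel}} (fields
#'   \code{order}, \code{coeffs}: list of row-wise lag matrices,
#'   \code{noise_cov}).
#' @return A \linkS4class{VarModel}.
#' @export
readVarModel <- function(file) {
  obj <- yaml::read_yaml(file)
  if (is.null(obj$coeffs)) stop("no 'coeffs' field in ", file)
  mats <- lapply(obj$coeffs, function(m)
    do.call(rbind, lapply(m, as.numeric)))
  S <- if (is.null(obj$noise_cov)) NULL
       else do.call(rbind, lapply(obj$noise_cov, as.numeric))
  varModel(mats, S)
}

#' Write a coupling matrix as a labeled table
#'
#' Tab-separated table with targets in rows and sources in columns; when
#' thresholds are present they are written to a parallel table
#' \code{<file>.thresholds} in the same layout.
#'
#' @param cm a \linkS4class{CouplingMatrix}.
#' @param file output path.
#' @return Invisibly, the file path.
#' @export
writeCouplingTable <- function(cm, file) {
  v <- couplingValues(cm)
  df <- data.frame(target = rownames(v), v, check.names = FALSE)
  utils::write.table(df, file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  thr <- thresholdMatrix(cm)
  if (!is.null(thr)) {
    dimnames(thr) <- dimnames(v)
    dft <- data.frame(target = rownames(v), thr, check.names = FALSE)
    utils::write.table(dft, paste0(file, ".thresholds"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(file)
}

#' Read a coupling table written by \code{\link{writeCouplingTable}}
#'
#' @param file input path.
#' @return Numeric matrix with target rows and source columns.
#' @export
readCouplingTable <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = TRUE,
                          check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Write a run manifest
#'
#' JSON record of a pipeline invocation sufficient to re-run it:
#' command, configuration snapshot, master seed, MD5 digest of the input
#' file, package version and timestamp.
#'
#' @param command character, the command executed.
#' @param config list of configuration values.
#' @param seed master seed.
#' @param inputFile path of the main input (digested), or NULL.
#' @param file output path.
#' @return Invisibly, the file path.
#' @export
writeManifest <- function(command, config, seed, inputFile = NULL,
                          file) {
  man <- list(command = command,
              config = config,
              master_seed = seed,
              input = if (is.null(inputFile)) NULL else list(
                path = inputFile,
                md5 = unname(tools::md5sum(inputFile))),
              tool = "eipr",
              version = as.character(utils::packageVersion("eipr")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(man, file, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(file)
}
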