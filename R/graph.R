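# Directed coupling-graph construction and export.

#' Build a directed coupling graph from a coupling matrix
#'
#' Emits a directed edge source \eqn{l \to} target \eqn{k} for every
#' qualifying off-diagonal entry of the coupling matrix. With edge rule
#' \code{"significant"} an entry qualifies when it exceeds its surrogate
#' threshold; with \code{"top_fraction"} only the top fraction (by
#' coupling value) of the significant entries are kept, mirroring a
#' rendering restricted to the highest coupling values. Ties are broken
#' by (source, target) index for determinism.
#'
#' @param cm a \linkS4class{CouplingMatrix}; must carry a significance
#'   mask for mode \code{"significant"} (see
#'   \code{\link{eiprSignificance}}).
#' @param labels node labels; default the matrix labels.
#' @param layout optional data.frame with \code{label}, \code{x},
#'   \code{y}; when missing the graph is emitted without coordinates.
#' @param edgeRule list with \code{mode} and \code{fraction}; see
#'   \code{\link{pipelineConfig}}.
#' @param timeSpan numeric length-2 window span in seconds.
#' @return A \linkS4class{CouplingGraph}.
#' @examples
#' v <- matrix(c(1, 0.5, 0, 1), 2, 2, byrow = TRUE)
#' cm <- new("CouplingMatrix", values = v, kind = "eipr",
#'           windowIndex = 0L, thresholds = matrix(0.1, 2, 2),
#'           significant = v > 0.1, sets = list(2L, 1L))
#' buildGraph(cm)
#' @export
buildGraph <- function(cm, labels = NULL, layout = NULL,
                       edgeRule = list(mode = "significant",
                                       fraction = 0.1),
                       timeSpan = c(0, 0)) {
  stopifnot(is(cm, "CouplingMatrix"))
  K <- nChannels(cm)
  if (is.null(labels)) labels <- channelLabels(cm)
  if (is.null(labels)) labels <- paste0("ch", seq_len(K))
  mode <- if (is.null(edgeRule$mode)) "significant" else edgeRule$mode
  sig <- significanceMask(cm)
  if (is.null(sig))
    stop("coupling matrix carries no significance mask; compute ",
         "thresholds first (eiprSignificance)")
  vals <- couplingValues(cm)
  qual <- which(sig & !diag(K), arr.ind = TRUE)  # row = target, col = src
  if (nrow(qual)) {
    w <- vals[qual]
    ord <- order(-w, qual[, 2L], qual[, 1L])  # weight desc, then indices
    qual <- qual[ord, , drop = FALSE]
    w <- w[ord]
    if (mode == "top_fraction") {
      keep <- max(0L, ceiling(edgeRule$fraction * nrow(qual)))
      qual <- qual[seq_len(min(keep, nrow(qual))), , drop = FALSE]
      w <- w[seq_len(nrow(qual))]
    }
    edges <- data.frame(source = labels[qual[, 2L]],
                        target = labels[qual[, 1L]],
                        weight = w,
                        significant = TRUE,
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(source = character(), target = character(),
                        weight = numeric(), significant = logical(),
                        stringsAsFactors = FALSE)
  }
  nodes <- data.frame(label = labels, stringsAsFactors = FALSE)
  if (!is.null(layout)) {
    m <- match(nodes$label, layout$label)
    nodes$x <- layout$x[m]
    nodes$y <- layout$y[m]
  }
  new("CouplingGraph", nodes = nodes, edges = edges,
      windowIndex = cm@windowIndex, timeSpan = as.numeric(timeSpan))
}

#' Write a coupling graph as GraphML
#'
#' @param graph a \linkS4class{CouplingGraph}.
#' @param file output path.
#' @return Invisibly, the file path.
#' @export
writeGraphML <- function(graph, file) {
  igraph::write_graph(asIgraph(graph), file, format = "graphml")
  invisible(file)
}

#' Write a coupling graph in DOT format
#'
#' @param graph a \linkS4class{CouplingGraph}.
#' @param file output path.
#' @return Invisibly, the file path.
#' @export
writeDot <- function(graph, file) {
  g <- asIgraph(graph)
  # DOT has no boolean attribute type
  if ("significant" %in% igraph::edge_attr_names(g))
    igraph::E(g)$significant <- as.integer(igraph::E(g)$significant)
  igraph::write_graph(g, file, format = "dot")
  invisible(file)
}

#' Out-degrees of a coupling graph
#'
#' Number of outgoing edges per node; the natural summary for locating a
#' driving (focus) channel.
#'
#' @param graph a \linkS4class{CouplingGraph}.
#' @return Named integer vector over node labels.
#' @export
outDegrees <- function(graph) {
  tab <- table(factor(graph@edges$source, levels = graph@nodes$label))
  structure(as.integer(tab), names = names(tab))
}
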