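# Layered TF -> TG regulation networks built by iterated extraction.

#' Build a layered gene regulation network
#'
#' Layer 1 holds the target genes extracted for the query TF. Every
#' extracted TG that is itself in the TF dictionary becomes a query for the
#' next round, up to `n_layers` rounds (the classic construction repeats
#' four times). A symbol is used as a query at most once, so cyclic corpora
#' terminate; nodes keep the layer of their first discovery. Edge frequency
#' counts supporting extracted sentences (accumulated over deduplicated
#' edges) and confidence is the frequency normalized by the maximal edge
#' frequency in the network.
#'
#' @param query_tf Query TF symbol or synonym (must resolve in the TF
#'   dictionary).
#' @param corpus List of `abstract` objects.
#' @param patterns A `pattern_set` (typically thresholded).
#' @param lexicon A `gene_lexicon`.
#' @param n_layers Number of expansion rounds (default 4).
#' @param weight_floor Minimal combined weight for a record to support an
#'   edge (default 0; raise to trade recall for precision).
#' @param weights A [weight_config()].
#' @return Object of class `regulation_network`: `query_tf`, `n_layers`, a
#'   `nodes` data frame (`symbol`, `layer`) and an `edges` data frame
#'   (`source`, `target`, `frequency`, `confidence`, `layer`).
#' @export
expand_layers <- function(query_tf, corpus, patterns, lexicon,
                          n_layers = 4L, weight_floor = 0,
                          weights = weight_config()) {
  stopifnot(n_layers >= 1L)
  root <- .resolve_query_tf(query_tf, lexicon)  # errors when absent
  node_layer <- stats::setNames(0L, root)
  visited <- root
  frontier <- root
  edges <- list()  # key -> list(source, target, frequency, layer)
  for (k in seq_len(n_layers)) {
    next_frontier <- character(0)
    for (q in frontier) {
      rec <- extract_records(corpus, q, patterns, lexicon, weights)
      rec <- rec[rec$combined_weight >= weight_floor, , drop = FALSE]
      if (nrow(rec) == 0L) next
      for (tg in unique(rec$tg)) {
        support <- sum(rec$tg == tg)
        key <- paste(q, tg, sep = "\r")
        if (is.null(edges[[key]])) {
          edges[[key]] <- list(source = q, target = tg,
                               frequency = support, layer = k)
        } else {
          edges[[key]]$frequency <- edges[[key]]$frequency + support
        }
        if (!(tg %in% names(node_layer))) {
          node_layer[[tg]] <- k
        }
        if (tg %in% names(lexicon$tf) && !(tg %in% visited)) {
          visited <- c(visited, tg)
          next_frontier <- c(next_frontier, tg)
        }
      }
    }
    frontier <- next_frontier
    if (length(frontier) == 0L) break
  }
  edf <- if (length(edges)) {
    do.call(rbind, lapply(edges, function(e) {
      data.frame(source = e$source, target = e$target,
                 frequency = e$frequency, layer = e$layer,
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(source = character(), target = character(),
               frequency = numeric(), layer = integer(),
               stringsAsFactors = FALSE)
  }
  rownames(edf) <- NULL
  edf$confidence <- if (nrow(edf)) edf$frequency / max(edf$frequency)
                    else numeric(0)
  edf <- edf[, c("source", "target", "frequency", "confidence", "layer")]
  nodes <- data.frame(symbol = names(node_layer),
                      layer = as.integer(unname(node_layer)),
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$layer, nodes$symbol), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(query_tf = root, n_layers = as.integer(n_layers),
                 nodes = nodes, edges = edf),
            class = "regulation_network")
}

#' @export
print.regulation_network <- function(x, ...) {
  cat("<regulation_network> root ", x$query_tf, ": ",
      nrow(x$nodes), " nodes, ", nrow(x$edges), " edges, ",
      max(c(0L, x$nodes$layer)), " layer(s)\n", sep = "")
  invisible(x)
}

.network_graph <- function(net) {
  igraph::graph_from_data_frame(
    net$edges[, c("source", "target", "frequency", "confidence", "layer")],
    directed = TRUE,
    vertices = net$nodes[, c("symbol", "layer")])
}

#' Classify a TF -> TG relation as direct or indirect
#'
#' A relation is direct when an edge `tf -> tg` exists, and indirect when
#' `tg` is reachable from `tf` through at least one intermediate node. Both
#' can hold (a gene regulated directly and through an intermediate
#' regulator); the classification then reports `"direct"` and the
#' multi-step paths separately.
#'
#' @param net A `regulation_network`.
#' @param tf Source symbol (defaults to the network root).
#' @param tg Target symbol.
#' @return List with `relation` (`"direct"`, `"indirect"` or `"absent"`),
#'   `direct` (logical) and `paths` (list of symbol vectors, each a path
#'   with at least one intermediate node).
#' @export
classify_relation <- function(net, tf = net$query_tf, tg) {
  stopifnot(inherits(net, "regulation_network"))
  if (!(tf %in% net$nodes$symbol) || !(tg %in% net$nodes$symbol)) {
    return(list(relation = "absent", direct = FALSE, paths = list()))
  }
  g <- .network_graph(net)
  direct <- any(net$edges$source == tf & net$edges$target == tg)
  paths <- list()
  if (tf != tg) {
    sp <- igraph::all_simple_paths(g, from = tf, to = tg, mode = "out")
    for (p in sp) {
      v <- names(p)
      if (length(v) >= 3L) paths[[length(paths) + 1L]] <- v
    }
  }
  relation <- if (direct) "direct" else if (length(paths)) "indirect"
              else "absent"
  list(relation = relation, direct = direct, paths = paths)
}

#' Export a regulation network
#'
#' Nodes carry their layer; edges carry frequency, confidence and a
#' high-confidence flag (`confidence >= high_conf_cut`, the bold-line edges
#' of a rendered network). Formats: SIF (`source<TAB>regulates<TAB>target`),
#' GraphML and DOT (via igraph).
#'
#' @param net A `regulation_network`.
#' @param format `"sif"`, `"graphml"` or `"dot"`.
#' @param path Output file path.
#' @param high_conf_cut Confidence cut for the flag (default 0.5).
#' @return The path, invisibly.
#' @export
export_network <- function(net, format = c("sif", "graphml", "dot"), path,
                           high_conf_cut = 0.5) {
  stopifnot(inherits(net, "regulation_network"))
  format <- match.arg(format)
  if (format == "sif") {
    writeLines(paste(net$edges$source, "regulates", net$edges$target,
                     sep = "\t"),
               path, useBytes = TRUE)
    return(invisible(path))
  }
  edges <- net$edges
  edges$high_confidence <- as.numeric(edges$confidence >= high_conf_cut)
  g <- igraph::graph_from_data_frame(
    edges[, c("source", "target", "frequency", "confidence", "layer",
              "high_confidence")],
    directed = TRUE,
    vertices = net$nodes[, c("symbol", "layer")])
  igraph::write_graph(g, path, format = format)
  invisible(path)
}
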