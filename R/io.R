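#' Convert a network to an igraph object
#'
#' @param net A `ggm_network` (undirected, edge attribute `partial_r`) or
#'   `relimp_network` (directed, edge attributes `lmg` and `lmg_percent`).
#' @return An igraph graph including isolated nodes.
#' @export
as_igraph <- function(net) {
  if (inherits(net, "ggm_network")) {
    el <- network_edge_list(net)
    g <- igraph::graph_from_data_frame(el, directed = FALSE,
                                       vertices = data.frame(name = net$labels))
    igraph::E(g)$weight <- el$partial_r
    g
  } else if (inherits(net, "relimp_network")) {
    el <- relimp_edge_list(net)
    g <- igraph::graph_from_data_frame(el, directed = TRUE,
                                       vertices = data.frame(name = net$labels))
    igraph::E(g)$weight <- el$lmg
    g
  } else {
    stop("unsupported network class", call. = FALSE)
  }
}

#' Directed edge list of a relative-importance network
#'
#' @param rin A `relimp_network`.
#' @return Data frame with `from`, `to`, `lmg` (proportion of variance) and
#'   `lmg_percent`.
#' @export
relimp_edge_list <- function(rin) {
  stopifnot(inherits(rin, "relimp_network"))
  idx <- which(rin$weights != 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(
    from = rin$labels[idx[, 1]],
    to = rin$labels[idx[, 2]],
    lmg = rin$weights[idx],
    lmg_percent = 100 * rin$weights[idx],
    stringsAsFactors = FALSE
  )
}

#' Write a network edge list to CSV
#'
#' Undirected networks get columns `node_i, node_j, partial_r`; directed
#' ones `from, to, lmg, lmg_percent`.
#'
#' @param net A `ggm_network` or `relimp_network`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  el <- if (inherits(net, "ggm_network")) network_edge_list(net)
        else relimp_edge_list(net)
  utils::write.csv(el, path, row.names = FALSE)
  invisible(path)
}

#' Read an undirected partial-correlation edge list
#'
#' Reconstructs a `ggm_network` from a CSV written by [write_edge_list()].
#' Node labels not present in any edge can be supplied to preserve isolated
#' nodes.
#'
#' @param path CSV with columns `node_i`, `node_j`, `partial_r`.
#' @param labels Optional full node set (superset of the edge endpoints).
#' @param n Sample size to record; default `NA`.
#' @return A `ggm_network` (with `loglik`/`ebic` set to `NA`).
#' @export
read_edge_list <- function(path, labels = NULL, n = NA_integer_) {
  el <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("node_i", "node_j", "partial_r") %in% names(el)))
  if (is.null(labels)) labels <- sort(unique(c(el$node_i, el$node_j)))
  p <- length(labels)
  W <- matrix(0, p, p, dimnames = list(labels, labels))
  for (r in seq_len(nrow(el))) {
    W[el$node_i[r], el$node_j[r]] <- el$partial_r[r]
    W[el$node_j[r], el$node_i[r]] <- el$partial_r[r]
  }
  structure(list(labels = labels, weights = W, mask = W != 0, n = n,
                 gamma = NA_real_, loglik = NA_real_, ebic = NA_real_,
                 n_edges = sum(W[upper.tri(W)] != 0), steps = character(0)),
            class = "ggm_network")
}

#' Write a network to GraphML
#'
#' @param net A `ggm_network` or `relimp_network`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' Read a GraphML network
#'
#' @param path GraphML file written by [write_graphml()].
#' @return An igraph graph.
#' @export
read_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}

#' Deterministic force-directed layout coordinates
#'
#' Seeded Fruchterman-Reingold layout (absolute edge weights as attraction),
#' for export alongside GraphML; no figure rendering is implied.
#'
#' @param net A `ggm_network` or `relimp_network`.
#' @param seed Integer seed.
#' @return Data frame with `node`, `x`, `y`.
#' @export
network_layout <- function(net, seed = 1) {
  g <- as_igraph(net)
  w <- abs(igraph::E(g)$weight)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g, weights = if (length(w)) w else NULL)
  data.frame(node = igraph::V(g)$name, x = xy[, 1], y = xy[, 2],
             stringsAsFactors = FALSE)
}
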