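#' Undirected microbial association networks
#'
#' `mb_network()` builds an undirected, unsigned network over a fixed node set
#' (typically taxa). Edges are stored canonically as lexicographically sorted
#' id pairs, so two networks over the same nodes are equal iff their edge
#' tibbles are equal. Self-loops are rejected and duplicate edges collapsed.
#'
#' @param nodes Character vector of unique node ids.
#' @param edges A two-column data frame (`from`, `to`) of node-id pairs, a
#'   character matrix with two columns, or `NULL` for an edgeless network.
#' @return An object of class `mb_network`: a list with elements `nodes`
#'   (character) and `edges` (tibble with columns `from`, `to`, canonical
#'   order, sorted).
#' @examples
#' net <- mb_network(c("a", "b", "c"), data.frame(from = "b", to = "a"))
#' n_edges(net)
#' @export
mb_network <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (length(nodes) == 0) abort("a network needs at least one node")
  if (anyDuplicated(nodes)) {
    abort(paste0("duplicate node ids: ",
                 paste(unique(nodes[duplicated(nodes)]), collapse = ", ")))
  }
  if (is.null(edges) || NROW(edges) == 0) {
    edges <- tibble::tibble(from = character(), to = character())
  } else {
    if (is.matrix(edges)) edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    from <- as.character(edges[[1]])
    to <- as.character(edges[[2]])
    bad <- !(from %in% nodes) | !(to %in% nodes)
    if (any(bad)) {
      abort(paste0("edge endpoints not in node set: ",
                   paste(unique(c(from[bad], to[bad])), collapse = ", ")))
    }
    if (any(from == to)) abort("self-loops are not allowed")
    swap <- from > to
    tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
    key <- paste(from, to, sep = "\r")
    keep <- !duplicated(key)
    ord <- order(from[keep], to[keep])
    edges <- tibble::tibble(from = from[keep][ord], to = to[keep][ord])
  }
  structure(list(nodes = nodes, edges = edges), class = "mb_network")
}

#' @export
print.mb_network <- function(x, ...) {
  cat("<mb_network> ", length(x$nodes), " nodes, ", nrow(x$edges), " edges\n",
      sep = "")
  invisible(x)
}

#' Number of edges in a network
#' @param net An `mb_network`.
#' @return Integer edge count.
#' @export
n_edges <- function(net) nrow(net$edges)

#' Canonical edge keys
#'
#' One string per edge, `"<from>|<to>"` with `from < to`; shared by every
#' module that compares edge sets.
#' @param net An `mb_network`.
#' @return Character vector of edge keys.
#' @export
edge_keys <- function(net) {
  if (nrow(net$edges) == 0) return(character())
  paste(net$edges$from, net$edges$to, sep = "|")
}

#' @method tidy mb_network
#' @export
tidy.mb_network <- function(x, ...) x$edges

#' Adjacency matrix of a network
#' @param net An `mb_network`.
#' @return Symmetric 0/1 integer matrix with node ids as dimnames.
#' @export
network_adjacency <- function(net) {
  p <- length(net$nodes)
  adj <- matrix(0L, p, p, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges) > 0) {
    i <- match(net$edges$from, net$nodes)
    j <- match(net$edges$to, net$nodes)
    adj[cbind(i, j)] <- 1L
    adj[cbind(j, i)] <- 1L
  }
  adj
}

#' Build a network from a 0/1 adjacency matrix
#' @param adj Square symmetric matrix with node ids as dimnames (row names
#'   used; column names must agree if present). Nonzero off-diagonal entries
#'   become edges; the diagonal is ignored.
#' @return An `mb_network`.
#' @export
network_from_adjacency <- function(adj) {
  if (!is.matrix(adj) || nrow(adj) != ncol(adj)) abort("adjacency must be square")
  nodes <- rownames(adj)
  if (is.null(nodes)) nodes <- paste0("v", seq_len(nrow(adj)))
  idx <- which(adj != 0 & upper.tri(adj), arr.ind = TRUE)
  mb_network(nodes, tibble::tibble(from = nodes[idx[, 1]], to = nodes[idx[, 2]]))
}

#' Convert to an igraph graph
#' @param net An `mb_network`.
#' @return An undirected `igraph` graph with the same vertices and edges.
#' @export
as_igraph <- function(net) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(net$nodes), name = net$nodes)
  if (nrow(net$edges) > 0) {
    g <- igraph::add_edges(g, rbind(match(net$edges$from, net$nodes),
                                    match(net$edges$to, net$nodes)))
  }
  g
}

#' @method autoplot mb_network
#' @export
autoplot.mb_network <- function(object, ...) {
  g <- as_igraph(object)
  set.seed(1L)
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble::tibble(node = object$nodes, x = xy[, 1], y = xy[, 2])
  seg <- dplyr::left_join(object$edges,
                          dplyr::rename(nodes, from = "node", x0 = "x", y0 = "y"),
                          by = "from")
  seg <- dplyr::left_join(seg,
                          dplyr::rename(nodes, to = "node", x1 = "x", y1 = "y"),
                          by = "to")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x1, yend = .data$y1),
                          colour = "grey60") +
    ggplot2::geom_point(data = nodes, ggplot2::aes(x = .data$x, y = .data$y),
                        size = 2) +
    ggplot2::theme_void()
}
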