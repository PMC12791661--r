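#' Build a weighted consensus network by simple voting
#'
#' Combines binarized networks inferred by different methods over the same
#' taxa into one integer-weighted network: each unordered pair's weight is
#' the number of input networks containing that edge, from 0 (no method) to
#' M (all M methods). Edges are treated as unsigned dependencies; signed or
#' weighted inputs must be binarized upstream. Thresholding the weight
#' ([threshold_consensus()]) controls sparsity: weight >= 1 keeps any
#' support, weight = M keeps only edges every method agrees on.
#'
#' @param networks List of at least two [mb_network()] objects with identical
#'   node sets.
#' @param method_names Character vector naming the methods; defaults to
#'   `names(networks)`. Must be unique.
#' @return An object of class `consensus_network`: list with `nodes`,
#'   `weights` (symmetric integer matrix), and `methods`. [tidy()] returns a
#'   tibble of pairs with positive weight.
#' @export
build_consensus <- function(networks, method_names = names(networks)) {
  if (length(networks) < 2) abort("at least 2 networks required")
  if (is.null(method_names)) method_names <- paste0("method", seq_along(networks))
  if (length(method_names) != length(networks)) abort("one name per network required")
  if (anyDuplicated(method_names)) abort("duplicate method names")
  check_same_nodes(networks)
  nodes <- networks[[1]]$nodes
  weights <- Reduce(`+`, lapply(networks, network_adjacency))
  storage.mode(weights) <- "integer"
  structure(list(nodes = nodes, weights = weights, methods = method_names),
            class = "consensus_network")
}

check_same_nodes <- function(networks) {
  ref <- sort(networks[[1]]$nodes)
  for (i in seq_along(networks)[-1]) {
    cur <- sort(networks[[i]]$nodes)
    if (!identical(cur, ref)) {
      diff <- c(setdiff(ref, cur), setdiff(cur, ref))
      abort(paste0("node sets differ; symmetric difference: ",
                   paste(diff, collapse = ", ")))
    }
  }
  invisible(networks)
}

#' @export
print.consensus_network <- function(x, ...) {
  cat("<consensus_network> ", length(x$nodes), " nodes, ",
      length(x$methods), " methods (", paste(x$methods, collapse = ", "), ")\n",
      sep = "")
  tab <- table(factor(x$weights[upper.tri(x$weights)], levels = 0:length(x$methods)))
  cat("  edges by weight:",
      paste(sprintf("%s:%d", names(tab), as.integer(tab)), collapse = " "), "\n")
  invisible(x)
}

#' @method tidy consensus_network
#' @export
tidy.consensus_network <- function(x, ...) {
  idx <- which(x$weights > 0 & upper.tri(x$weights), arr.ind = TRUE)
  out <- tibble::tibble(from = x$nodes[idx[, 1]], to = x$nodes[idx[, 2]],
                        weight = x$weights[idx])
  dplyr::arrange(out, .data$from, .data$to)
}

#' @method autoplot consensus_network
#' @export
autoplot.consensus_network <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$weight))) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "number of supporting methods", y = "edges") +
    ggplot2::theme_minimal()
}

#' Threshold a consensus network
#'
#' @param cn A `consensus_network`.
#' @param min_weight Minimum number of supporting methods, between 1 and M.
#' @return An [mb_network()] with exactly the pairs of weight >= `min_weight`.
#' @export
threshold_consensus <- function(cn, min_weight) {
  m <- length(cn$methods)
  if (min_weight < 1 || min_weight > m) {
    abort(paste0("min_weight must be between 1 and ", m))
  }
  network_from_adjacency((cn$weights >= min_weight) * 1L)
}

#' Edge counts of every method-subset overlap cell
#'
#' For every nonempty subset of methods, counts the edges present in exactly
#' that subset of the input networks (the cells of a Venn diagram over edge
#' sets); the cell counts sum to the size of the union of all edge sets.
#'
#' @param networks Named list of >= 2 [mb_network()] objects on a shared node
#'   set.
#' @return A tibble with columns `methods` (subset label, names joined by
#'   `"+"`), `n_methods`, and `n_edges`, one row per nonempty subset.
#' @export
edge_overlap_partition <- function(networks) {
  if (length(networks) < 2) abort("at least 2 networks required")
  check_same_nodes(networks)
  nms <- names(networks)
  if (is.null(nms)) nms <- paste0("method", seq_along(networks))
  keys <- lapply(networks, edge_keys)
  all_edges <- unique(unlist(keys))
  membership <- vapply(keys, function(k) all_edges %in% k,
                       logical(length(all_edges)))
  if (length(all_edges) == 1) membership <- matrix(membership, nrow = 1)
  cell <- apply(membership, 1, function(row) paste(nms[row], collapse = "+"))
  subsets <- unlist(lapply(seq_along(nms), function(k)
    combn(nms, k, paste, collapse = "+")))
  counts <- table(factor(cell, levels = subsets))
  tibble::tibble(methods = subsets,
                 n_methods = lengths(strsplit(subsets, "+", fixed = TRUE)),
                 n_edges = as.integer(counts))
}
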