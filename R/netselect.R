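#' Default centrality weights for the composite keystone score
#'
#' Path-based metrics get the larger share (betweenness 0.5, closeness 0.2)
#' because bridging and global-reach taxa are the usual keystone candidates;
#' the neighbor-based metrics (degree, eigenvector, PageRank) get 0.1 each.
#' @export
composite_weights_default <- c(degree = 0.1, eigenvector = 0.1, pagerank = 0.1,
                               closeness = 0.2, betweenness = 0.5)

centrality_metrics <- names(composite_weights_default)

#' Five node centralities of a network
#'
#' Per node: degree (edge count); eigenvector centrality (principal
#' eigenvector of the adjacency, computed per connected component and scaled
#' to max 1 within each component, 0 for isolated nodes); PageRank with
#' damping 0.85 (sums to 1 over nodes); harmonic closeness normalized by
#' n - 1 (finite on disconnected graphs); and shortest-path betweenness
#' normalized by (n-1)(n-2)/2.
#'
#' @param net An [mb_network()]; may be disconnected or edgeless.
#' @return A tibble with columns `node`, `degree`, `eigenvector`, `pagerank`,
#'   `closeness`, `betweenness`.
#' @export
network_centralities <- function(net) {
  g <- as_igraph(net)
  n <- length(net$nodes)
  ev <- numeric(n)
  comp <- igraph::components(g)
  for (cid in seq_len(comp$no)) {
    members <- which(comp$membership == cid)
    if (length(members) >= 2) {
      sub <- igraph::induced_subgraph(g, members)
      ev[members] <- igraph::eigen_centrality(sub, options = list(tol = 1e-10))$vector
    }
  }
  btw <- igraph::betweenness(g, directed = FALSE,
                             normalized = n > 2)
  tibble::tibble(
    node = net$nodes,
    degree = as.numeric(igraph::degree(g)),
    eigenvector = ev,
    pagerank = as.numeric(igraph::page_rank(g, damping = 0.85)$vector),
    closeness = as.numeric(igraph::harmonic_centrality(g, normalized = TRUE)),
    betweenness = as.numeric(btw)
  )
}

# top-ceiling(frac * p) items by value, ties at the boundary all included
top_fraction <- function(values, top_frac, what = "items") {
  k <- ceiling(top_frac * length(values))
  thr <- sort(values, decreasing = TRUE)[k]
  sel <- names(values)[values >= thr]
  if (length(sel) > k) {
    warn(paste0("ties at the top-", top_frac, " boundary expanded the ",
                what, " set from ", k, " to ", length(sel)))
  }
  sel
}

#' Differential-centrality taxon selection (Strategy 1)
#'
#' Compares condition-specific networks (healthy vs diseased) inferred by
#' each method. Per method and per centrality metric, taxa are ranked by the
#' absolute difference of their centrality between the two conditions; a
#' taxon is flagged for a method if it falls in the top `ceiling(top_frac*p)`
#' for at least one metric. The final selection is the intersection across
#' all methods — taxa whose network role shifts with disease no matter which
#' inference method built the networks. Identical networks in both conditions
#' make every difference 0; everything then ties at the boundary and the
#' selection degenerates to all taxa, with a warning.
#'
#' @param clean_nets,scab_nets Named lists of [mb_network()] objects (same
#'   method names in both, same taxa everywhere), for the healthy ("clean")
#'   and diseased ("scab") condition.
#' @param top_frac Fraction of taxa to flag per metric. Default 0.20.
#' @return A list with `selected` (character; intersection across methods),
#'   `per_method` (named list of per-method flagged sets), `features` (tibble
#'   mapping each selected taxon to the metrics responsible per method), and
#'   `differences` (tibble of all absolute centrality differences).
#' @export
strategy1_differential <- function(clean_nets, scab_nets, top_frac = 0.20) {
  check_condition_nets(clean_nets, scab_nets)
  methods <- names(clean_nets)
  taxa <- clean_nets[[1]]$nodes
  diffs <- purrr::map_dfr(methods, function(m) {
    cc <- network_centralities(clean_nets[[m]])
    cs <- network_centralities(scab_nets[[m]])
    cs <- cs[match(cc$node, cs$node), ]
    purrr::map_dfr(centrality_metrics, function(met) {
      tibble::tibble(method = m, metric = met, taxon = cc$node,
                     abs_diff = abs(cc[[met]] - cs[[met]]))
    })
  })
  flagged <- diffs |>
    dplyr::group_by(.data$method, .data$metric) |>
    dplyr::group_modify(function(d, key) {
      vals <- setNames(d$abs_diff, d$taxon)
      if (all(vals == 0)) {
        warn(paste0("all centrality differences are zero for ", key$method,
                    "/", key$metric, "; selection is degenerate"))
      }
      d$flagged <- d$taxon %in% top_fraction(vals, top_frac, "taxon")
      d
    }) |>
    dplyr::ungroup()
  per_method <- lapply(setNames(methods, methods), function(m) {
    sort(unique(flagged$taxon[flagged$method == m & flagged$flagged]))
  })
  selected <- sort(Reduce(intersect, per_method))
  features <- flagged |>
    dplyr::filter(.data$flagged, .data$taxon %in% selected) |>
    dplyr::group_by(.data$taxon, .data$method) |>
    dplyr::summarise(features = paste(.data$metric, collapse = ","),
                     .groups = "drop")
  list(selected = selected, per_method = per_method, features = features,
       differences = flagged)
}

check_condition_nets <- function(clean_nets, scab_nets) {
  if (is.null(names(clean_nets)) || is.null(names(scab_nets)) ||
      !setequal(names(clean_nets), names(scab_nets))) {
    abort("clean and scab networks must share the same method names")
  }
  check_same_nodes(c(unname(clean_nets), unname(scab_nets)))
  invisible(NULL)
}

#' Composite centrality score of every taxon (Strategy 2)
#'
#' Scores each node as a weighted sum of the five centralities,
#' `score = w_DE*DE + w_EV*EV + w_PR*PR + w_CL*CL + w_BE*BE`, after min-max
#' scaling each metric to \[0, 1\] across the nodes of the network so the
#' metrics are commensurate (raw betweenness would otherwise dominate
#' regardless of the weights). A metric constant across nodes carries no
#' ranking information and contributes 0, with a warning.
#'
#' @param net An [mb_network()].
#' @param weights Named nonnegative weights for `degree`, `eigenvector`,
#'   `pagerank`, `closeness`, `betweenness`. Default
#'   [composite_weights_default] (0.1, 0.1, 0.1, 0.2, 0.5).
#' @param top_frac Fraction of taxa in the top set. Default 0.20.
#' @return A tibble with `node`, the five scaled metrics, `score`, and
#'   `selected` (membership of the top `ceiling(top_frac*p)` set, ties at the
#'   boundary included).
#' @export
strategy2_composite <- function(net, weights = composite_weights_default,
                                top_frac = 0.20) {
  if (!all(centrality_metrics %in% names(weights))) {
    abort(paste0("weights must be named: ",
                 paste(centrality_metrics, collapse = ", ")))
  }
  cent <- network_centralities(net)
  for (met in centrality_metrics) {
    v <- cent[[met]]
    # a range below 1e-9 is solver noise, not signal; min-max scaling would
    # inflate it to order 1, so such metrics are treated as constant
    if (max(v) - min(v) < 1e-9) {
      warn(paste0("metric '", met, "' is constant across nodes; it contributes 0"))
      cent[[met]] <- rep(0, length(v))
    } else {
      cent[[met]] <- (v - min(v)) / (max(v) - min(v))
    }
  }
  cent$score <- as.numeric(as.matrix(cent[, centrality_metrics]) %*%
                             weights[centrality_metrics])
  sel <- top_fraction(setNames(cent$score, cent$node), top_frac, "taxon")
  cent$selected <- cent$node %in% sel
  dplyr::arrange(cent, dplyr::desc(.data$score))
}

#' Cross-method consensus of composite-score selections (Strategy 2)
#'
#' Applies [strategy2_composite()] to each method's network in each
#' condition, then keeps per condition only the taxa in the top set for
#' *all* methods.
#'
#' @inheritParams strategy1_differential
#' @param weights As in [strategy2_composite()].
#' @return A list with `clean` and `scab` (per-condition consensus sets),
#'   their `union` and `intersection`, and `per_method` (tibble of per
#'   method/condition top sets).
#' @export
strategy2_consensus <- function(clean_nets, scab_nets,
                                weights = composite_weights_default,
                                top_frac = 0.20) {
  check_condition_nets(clean_nets, scab_nets)
  methods <- names(clean_nets)
  tops <- purrr::map_dfr(c(clean = "clean", scab = "scab"), function(cond) {
    nets <- if (cond == "clean") clean_nets else scab_nets
    purrr::map_dfr(methods, function(m) {
      sc <- strategy2_composite(nets[[m]], weights, top_frac)
      tibble::tibble(condition = cond, method = m,
                     taxon = sc$node[sc$selected])
    })
  })
  consensus_of <- function(cond) {
    sets <- lapply(methods, function(m)
      tops$taxon[tops$condition == cond & tops$method == m])
    sort(Reduce(intersect, sets))
  }
  clean <- consensus_of("clean")
  scab <- consensus_of("scab")
  list(clean = clean, scab = scab, union = sort(union(clean, scab)),
       intersection = sort(intersect(clean, scab)), per_method = tops)
}

#' Combine ML-based and network-based selections into a final report
#'
#' Crosses the three selection routes — the machine-learning TOTAL-score set,
#' the differential-centrality set (Strategy 1), and the composite-score
#' consensus set (Strategy 2) — and assigns each taxon its evidence tier:
#' `"a"` selected by all three, `"b"` by ML and Strategy 1, `"c"` by ML and
#' Strategy 2, `"d"` by both network strategies only.
#'
#' @param ml_selected,s1_selected,s2_selected Character vectors of selected
#'   taxa from the three routes; all must be subsets of `taxa`.
#' @param taxa The shared taxon universe.
#' @param rule Final-selection rule: `"intersection_all"` (all three routes)
#'   or `"ml_and_any_network"` (ML plus at least one network strategy).
#' @return A tibble with one row per taxon: `taxon`, `in_ml`, `in_s1`,
#'   `in_s2`, `tier`, `final_selected`.
#' @export
finalize_selection <- function(ml_selected, s1_selected, s2_selected, taxa,
                               rule = c("intersection_all", "ml_and_any_network")) {
  rule <- match.arg(rule)
  sets <- list(ml_selected, s1_selected, s2_selected)
  extra <- setdiff(unlist(sets), taxa)
  if (length(extra) > 0) {
    abort(paste0("selected taxa outside the taxon universe: ",
                 paste(extra, collapse = ", ")))
  }
  out <- tibble::tibble(
    taxon = taxa,
    in_ml = taxa %in% ml_selected,
    in_s1 = taxa %in% s1_selected,
    in_s2 = taxa %in% s2_selected
  )
  out$tier <- dplyr::case_when(
    out$in_ml & out$in_s1 & out$in_s2 ~ "a",
    out$in_ml & out$in_s1 ~ "b",
    out$in_ml & out$in_s2 ~ "c",
    out$in_s1 & out$in_s2 ~ "d",
    TRUE ~ NA_character_
  )
  out$final_selected <- if (rule == "intersection_all") {
    out$in_ml & out$in_s1 & out$in_s2
  } else {
    out$in_ml & (out$in_s1 | out$in_s2)
  }
  out
}

#' @rdname network_centralities
#' @param data A tibble as returned by `network_centralities()`.
#' @export
plot_centralities <- function(data) {
  df <- tidyr::pivot_longer(data, dplyr::all_of(centrality_metrics),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 20) +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::theme_minimal()
}
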