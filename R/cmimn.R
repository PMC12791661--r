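#' Empirical quantile threshold
#'
#' The q-th empirical quantile with linear interpolation between order
#' statistics ([stats::quantile()] type 7). Downstream edge filters remove
#' items *strictly below* the returned threshold, so ties at the threshold
#' are kept.
#'
#' @param values Nonempty numeric vector.
#' @param q Quantile in (0, 1).
#' @return A single number.
#' @export
quantile_threshold <- function(values, q) {
  if (length(values) == 0) abort("empty value vector")
  if (q <= 0 || q >= 1) abort("q must be in (0, 1)")
  unname(quantile(values, q, type = 7, names = FALSE))
}

#' Infer a microbial association network by conditional mutual information
#'
#' Learns an undirected skeleton over the taxa of a count table in two
#' quantile-thresholded stages:
#'
#' 1. **Initialization** — start from the complete graph on the taxa.
#' 2. **MI stage** — compute the Gaussian MI ([mi_gaussian()]) for every pair
#'    on the normalized data ([default_pipeline()]); drop edges whose MI is
#'    strictly below the empirical `q1` quantile of all pairwise MI values.
#'    The surviving graph is `S0`.
#' 3. **CMI stage** — with candidate separators *frozen* from `S0` (for each
#'    edge, the common neighbors of its endpoints in `S0`), compute
#'    [cmi_gaussian()] for each single separator and keep the maximum: the
#'    strongest conditional dependency left after accounting for any single
#'    mediator.
#' 4. **Thresholding** — drop edges whose maximum CMI is strictly below the
#'    `q2` quantile of the max-CMI values of edges that have at least one
#'    separator. Edges with no common neighbor bypass the CMI filter (no
#'    conditioning evidence can explain them away). The result `S1` is the
#'    final undirected skeleton.
#'
#' Freezing the separator sets before any removal makes the result
#' independent of the order in which taxa or edges are processed (see
#' [permutation_invariance_check()]). `q1` and `q2` control sparsity
#' directly: lower quantiles yield denser graphs. Taxon columns that are
#' constant after normalization carry no information and are dropped with a
#' warning before inference. The procedure uses no random numbers.
#'
#' @param data An abundance tibble (see [read_abundance()]); at least 3
#'   samples and 2 usable taxa.
#' @param q1 Quantile for the MI filter, in (0, 1). Default 0.70.
#' @param q2 Quantile for the max-CMI filter, in (0, 1). Default 0.95.
#' @param quantitative Logical; log-transform the input before estimation
#'   (default `TRUE`). Set `FALSE` when supplying externally normalized data
#'   (e.g. CLR).
#' @param pseudocount Pseudocount for the log transform. Default 1.
#' @param cap Cap for divergent MI/CMI estimates, in nats. Default 10.
#' @return An object of class `cmi_network_fit` with elements `network` (the
#'   skeleton, an [mb_network()]), `s0` (the MI-stage network), `mi`
#'   (tibble of all pairwise MI values), `cmi` (tibble of per-`S0`-edge max
#'   CMI, argmax separator, and retention), `thresholds`, and `params`.
#'   [tidy()] gives a per-pair tibble, [glance()] a one-row summary.
#' @examples
#' set.seed(1)
#' z <- rnorm(120)
#' tbl <- tibble::tibble(
#'   sample_id = paste0("s", 1:120),
#'   t1 = rpois(120, exp(1 + z)), t2 = rpois(120, exp(1 + z)),
#'   t3 = rpois(120, 5)
#' )
#' fit <- infer_cmi_network(tbl, q1 = 0.3, q2 = 0.5)
#' glance(fit)
#' @export
infer_cmi_network <- function(data, q1 = 0.70, q2 = 0.95, quantitative = TRUE,
                              pseudocount = 1, cap = 10) {
  if (q1 <= 0 || q1 >= 1 || q2 <= 0 || q2 >= 1) abort("q1 and q2 must be in (0, 1)")
  norm <- default_pipeline(data, quantitative = quantitative, pseudocount = pseudocount)
  mat <- abundance_matrix(norm)
  if (nrow(mat) < 3) abort("at least 3 samples required")
  const <- apply(mat, 2, var) == 0
  if (any(const)) {
    warn(paste0("dropping constant taxon column(s): ",
                paste(colnames(mat)[const], collapse = ", ")))
    mat <- mat[, !const, drop = FALSE]
  }
  taxa <- colnames(mat)
  p <- length(taxa)
  if (p < 2) abort("fewer than 2 usable taxa after dropping constant columns")

  pairs <- combn(taxa, 2)
  mi <- tibble::tibble(
    from = pairs[1, ], to = pairs[2, ],
    mi = purrr::map2_dbl(pairs[1, ], pairs[2, ],
                         ~ mi_gaussian(mat[, .x], mat[, .y], cap = cap))
  )
  mi_threshold <- quantile_threshold(mi$mi, q1)
  s0_edges <- mi[mi$mi >= mi_threshold, c("from", "to")]
  s0 <- mb_network(taxa, s0_edges)

  # neighborhoods in S0, frozen before any CMI-stage removal
  nbrs <- lapply(setNames(taxa, taxa), function(v) {
    c(s0$edges$to[s0$edges$from == v], s0$edges$from[s0$edges$to == v])
  })
  empty_cmi <- tibble::tibble(from = character(), to = character(),
                              max_cmi = numeric(), separator = character(),
                              has_separator = logical())
  cmi_tbl <- if (nrow(s0$edges) == 0) empty_cmi else
    purrr::pmap_dfr(s0$edges, function(from, to) {
    seps <- sort(intersect(nbrs[[from]], nbrs[[to]]))
    if (length(seps) == 0) {
      return(tibble::tibble(from = from, to = to, max_cmi = NA_real_,
                            separator = NA_character_, has_separator = FALSE))
    }
    vals <- vapply(seps, function(zz)
      cmi_gaussian(mat[, from], mat[, to], mat[, zz], cap = cap), numeric(1))
    best <- max(vals)
    tibble::tibble(from = from, to = to, max_cmi = best,
                   separator = seps[which(vals == best)[1]],
                   has_separator = TRUE)
    })

  if (nrow(cmi_tbl) > 0 && any(cmi_tbl$has_separator)) {
    cmi_threshold <- quantile_threshold(cmi_tbl$max_cmi[cmi_tbl$has_separator], q2)
    kept <- !cmi_tbl$has_separator | cmi_tbl$max_cmi >= cmi_threshold
  } else {
    cmi_threshold <- NA_real_
    kept <- rep(TRUE, nrow(cmi_tbl))
  }
  cmi_tbl$kept <- kept
  s1 <- mb_network(taxa, cmi_tbl[kept, c("from", "to")])

  structure(list(
    network = s1, s0 = s0, mi = mi, cmi = cmi_tbl,
    thresholds = list(q1 = q1, q2 = q2, mi_threshold = mi_threshold,
                      cmi_threshold = cmi_threshold),
    params = list(quantitative = quantitative, pseudocount = pseudocount, cap = cap),
    taxa = taxa, dropped = names(const)[const], n_samples = nrow(mat)
  ), class = "cmi_network_fit")
}

#' @export
print.cmi_network_fit <- function(x, ...) {
  cat("<cmi_network_fit> ", length(x$taxa), " taxa, ", x$n_samples, " samples\n",
      "  S0 (MI stage, q1 = ", x$thresholds$q1, "): ", n_edges(x$s0), " edges\n",
      "  S1 (CMI stage, q2 = ", x$thresholds$q2, "): ", n_edges(x$network),
      " edges\n", sep = "")
  invisible(x)
}

#' @method tidy cmi_network_fit
#' @export
tidy.cmi_network_fit <- function(x, ...) {
  out <- dplyr::left_join(x$mi, x$cmi, by = c("from", "to"))
  out$in_s0 <- !is.na(match(paste(out$from, out$to, sep = "|"), edge_keys(x$s0)))
  out$in_s1 <- !is.na(match(paste(out$from, out$to, sep = "|"), edge_keys(x$network)))
  out$kept <- NULL
  out
}

#' @method glance cmi_network_fit
#' @export
glance.cmi_network_fit <- function(x, ...) {
  tibble::tibble(
    n_taxa = length(x$taxa), n_samples = x$n_samples, n_pairs = nrow(x$mi),
    n_edges_s0 = n_edges(x$s0), n_edges_s1 = n_edges(x$network),
    q1 = x$thresholds$q1, q2 = x$thresholds$q2,
    mi_threshold = x$thresholds$mi_threshold,
    cmi_threshold = x$thresholds$cmi_threshold
  )
}

#' @method autoplot cmi_network_fit
#' @export
autoplot.cmi_network_fit <- function(object, ...) autoplot(object$network, ...)

#' Check order independence of the skeleton inference
#'
#' Runs [infer_cmi_network()] on `n_perms` random column permutations of the
#' input and reports whether every run returns the identical edge set (under
#' canonical ids). Separator sets are frozen from `S0` before any removal,
#' so this holds by construction; the check exists to guard regressions.
#'
#' @param data An abundance tibble.
#' @param q1,q2,quantitative,pseudocount As in [infer_cmi_network()].
#' @param n_perms Number of random permutations. Default 5.
#' @param seed RNG seed for the permutations.
#' @return `TRUE` if all permutations agree, else `FALSE`.
#' @export
permutation_invariance_check <- function(data, q1 = 0.70, q2 = 0.95,
                                         quantitative = TRUE, pseudocount = 1,
                                         n_perms = 5, seed = 1) {
  ref <- sort(edge_keys(infer_cmi_network(data, q1, q2, quantitative,
                                          pseudocount)$network))
  taxa <- taxon_names(data)
  meta <- intersect(names(data), c("sample_id", "label"))
  set.seed(seed)
  for (i in seq_len(n_perms)) {
    perm <- data[, c(meta, sample(taxa))]
    keys <- sort(edge_keys(infer_cmi_network(perm, q1, q2, quantitative,
                                             pseudocount)$network))
    if (!identical(keys, ref)) return(FALSE)
  }
  TRUE
}

#' Choose q2 to match a target edge count
#'
#' The max-CMI values do not depend on `q2`, so the fit is computed once and
#' the CMI-stage threshold is then searched over a fine grid of `q2` values
#' for the edge count closest to `target_edges`. Useful when comparing
#' methods at matched density, e.g. against a ground-truth network of known
#' size (separator-less edges bypass the filter, so the reachable count has a
#' floor).
#'
#' @param data An abundance tibble.
#' @param target_edges Desired number of edges in the final skeleton.
#' @param q1,quantitative,pseudocount As in [infer_cmi_network()].
#' @return A list with `q2` (the selected quantile), `fit` (the
#'   `cmi_network_fit` at that `q2`), and `n_edges`.
#' @export
tune_q2_to_edges <- function(data, target_edges, q1 = 0.70, quantitative = TRUE,
                             pseudocount = 1) {
  fit <- infer_cmi_network(data, q1 = q1, q2 = 0.5, quantitative = quantitative,
                           pseudocount = pseudocount)
  withsep <- fit$cmi$max_cmi[fit$cmi$has_separator]
  n_nosep <- sum(!fit$cmi$has_separator)
  grid <- seq(0.001, 0.999, by = 0.001)
  counts <- vapply(grid, function(q) {
    n_nosep + sum(withsep >= quantile_threshold(withsep, q))
  }, numeric(1))
  q2 <- grid[which.min(abs(counts - target_edges))]
  fit2 <- refit_q2(fit, q2)
  list(q2 = q2, fit = fit2, n_edges = n_edges(fit2$network))
}

# re-threshold an existing fit at a new q2 without recomputing MI/CMI
refit_q2 <- function(fit, q2) {
  cmi_tbl <- fit$cmi
  if (nrow(cmi_tbl) > 0 && any(cmi_tbl$has_separator)) {
    thr <- quantile_threshold(cmi_tbl$max_cmi[cmi_tbl$has_separator], q2)
    kept <- !cmi_tbl$has_separator | cmi_tbl$max_cmi >= thr
  } else {
    thr <- NA_real_
    kept <- rep(TRUE, nrow(cmi_tbl))
  }
  cmi_tbl$kept <- kept
  fit$cmi <- cmi_tbl
  fit$network <- mb_network(fit$taxa, cmi_tbl[kept, c("from", "to")])
  fit$thresholds$q2 <- q2
  fit$thresholds$cmi_threshold <- thr
  fit
}
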