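#' Band-graph adjacency
#'
#' The ground-truth graph family for benchmarking: nodes are ordered and an
#' edge joins i and j iff `0 < |i - j| <= band_width`. `band_width = 1` is a
#' chain; `band_width = p - 1` the complete graph.
#'
#' @param p Number of nodes (>= 2).
#' @param band_width Band width, between 1 and p - 1.
#' @return Symmetric 0/1 integer matrix with taxon names `t01, t02, ...`.
#' @export
band_graph <- function(p, band_width) {
  if (p < 2) abort("p must be at least 2")
  if (band_width < 1 || band_width >= p) abort("band_width must be in [1, p - 1]")
  nodes <- sprintf("t%0*d", nchar(p), seq_len(p))
  d <- abs(outer(seq_len(p), seq_len(p), `-`))
  adj <- (d > 0 & d <= band_width) * 1L
  dimnames(adj) <- list(nodes, nodes)
  adj
}

#' Precision matrix with a prescribed support
#'
#' Builds a symmetric positive-definite precision (inverse covariance)
#' matrix whose off-diagonal support matches the given adjacency: entries
#' are `+-strength` on edges (random signs, seeded), 0 elsewhere, and the
#' diagonal is set uniformly to the maximum absolute off-diagonal row sum
#' plus 0.1, which guarantees positive definiteness by diagonal dominance.
#' Inverting it yields a covariance whose nonzero partial correlations sit
#' exactly on the edges — the Gaussian graphical model the counts are
#' sampled from.
#'
#' @param adjacency Symmetric 0/1 matrix (see [band_graph()]).
#' @param strength Absolute value of the off-diagonal entries. Default 0.3.
#' @param seed Integer seed for the signs. Default 1.
#' @return The precision matrix (same dimnames), with attribute
#'   `min_eigenvalue`.
#' @export
make_precision <- function(adjacency, strength = 0.3, seed = 1) {
  p <- nrow(adjacency)
  set.seed(seed)
  signs <- matrix(0, p, p)
  up <- which(adjacency != 0 & upper.tri(adjacency))
  signs[up] <- sample(c(-1, 1), length(up), replace = TRUE)
  signs <- signs + t(signs)
  omega <- signs * strength
  diag(omega) <- max(rowSums(abs(omega))) + 0.1
  dimnames(omega) <- dimnames(adjacency)
  attr(omega, "min_eigenvalue") <- min(eigen(omega, symmetric = TRUE,
                                             only.values = TRUE)$values)
  omega
}

#' Ground truth for a synthetic benchmark
#'
#' @param p Number of taxa.
#' @param band_width Band width of the true graph. Default 2.
#' @param strength Precision off-diagonal magnitude. Default 0.3.
#' @param seed Integer seed.
#' @return A list of class `ground_truth`: `adjacency`, `precision`,
#'   `network` (the adjacency as an [mb_network()]), `params`.
#' @export
make_ground_truth <- function(p, band_width = 2, strength = 0.3, seed = 1) {
  adj <- band_graph(p, band_width)
  omega <- make_precision(adj, strength = strength, seed = seed)
  structure(list(adjacency = adj, precision = omega,
                 network = network_from_adjacency(adj),
                 params = list(p = p, band_width = band_width,
                               strength = strength, seed = seed)),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> p = ", nrow(x$adjacency), ", band width = ",
      x$params$band_width, ", ", n_edges(x$network), " edges\n", sep = "")
  invisible(x)
}

# quantile function of the chosen count marginal
marginal_quantile <- function(u, marginal) {
  family <- marginal$family %||% "zero_inflated_nb"
  if (family == "negative_binomial") {
    qnbinom(u, mu = marginal$mean, size = marginal$dispersion)
  } else if (family == "zero_inflated_nb") {
    pz <- marginal$zero_prob %||% 0
    out <- numeric(length(u))
    pos <- u > pz
    out[pos] <- qnbinom((u[pos] - pz) / (1 - pz), mu = marginal$mean,
                        size = marginal$dispersion)
    out
  } else if (family == "poisson") {
    qpois(u, lambda = marginal$mean)
  } else {
    abort(paste0("unknown marginal family: ", family))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample zero-rich overdispersed counts from a Gaussian copula
#'
#' Draws latent multivariate-normal data with covariance equal to the
#' inverse of the ground-truth precision matrix, then maps each column
#' through its normal CDF and the inverse CDF of the target count marginal
#' (the "normal to anything" construction). The counts inherit the latent
#' rank-dependence structure — so the true conditional-independence graph is
#' known — while the marginals emulate microbiome data: negative-binomial
#' overdispersion and, with `zero_inflated_nb`, an excess-zero mass.
#'
#' @param truth A `ground_truth` from [make_ground_truth()].
#' @param n Number of samples (>= 3).
#' @param marginal List describing the count marginal:
#'   `family` (`"zero_inflated_nb"`, `"negative_binomial"`, or `"poisson"`),
#'   `mean` (NB mean, default 20), `dispersion` (NB size parameter; smaller
#'   is more overdispersed, and the Poisson limit is approached as it grows;
#'   default 0.5), `zero_prob` (extra zero mass, default 0.3).
#' @param seed Integer seed.
#' @return An abundance tibble (`sample_id` + one count column per taxon).
#' @export
sample_counts <- function(truth, n,
                          marginal = list(family = "zero_inflated_nb",
                                          mean = 20, dispersion = 0.5,
                                          zero_prob = 0.3),
                          seed = 1) {
  if (n < 3) abort("n must be at least 3")
  if (is.null(marginal$mean) || marginal$mean <= 0) abort("marginal mean must be positive")
  if (!is.null(marginal$dispersion) && marginal$dispersion <= 0) {
    abort("marginal dispersion must be positive")
  }
  sigma <- solve(truth$precision)
  p <- nrow(sigma)
  set.seed(seed)
  z <- matrix(rnorm(n * p), n, p) %*% chol(sigma)
  u <- pnorm(sweep(z, 2, sqrt(diag(sigma)), "/"))
  counts <- apply(u, 2, marginal_quantile, marginal = marginal)
  colnames(counts) <- colnames(truth$adjacency)
  out <- tibble::tibble(sample_id = sprintf("s%0*d", nchar(n), seq_len(n)))
  dplyr::bind_cols(out, tibble::as_tibble(counts))
}

#' Two-class synthetic dataset with partially shared network structure
#'
#' Emulates a healthy/diseased study design: both classes share a core of
#' `shared_frac` of the band-graph edges; the remaining edges are rewired
#' differently (and disjointly) in each class, so class-specific structure
#' exists by construction. Counts are drawn per class with [sample_counts()]
#' and concatenated with labels 0 (clean) / 1 (scab).
#'
#' @param p Number of taxa.
#' @param n_per_class Samples per class.
#' @param shared_frac Fraction of edges shared between the class graphs, in
#'   \[0, 1\].
#' @param seed Integer seed.
#' @param band_width,strength,marginal As in [make_ground_truth()] and
#'   [sample_counts()].
#' @return A list with `data` (labelled abundance tibble), `truth_clean`,
#'   `truth_scab`.
#' @export
two_class_dataset <- function(p, n_per_class, shared_frac = 0.6, seed = 1,
                              band_width = 2, strength = 0.3,
                              marginal = list(family = "zero_inflated_nb",
                                              mean = 20, dispersion = 0.5,
                                              zero_prob = 0.3)) {
  if (shared_frac < 0 || shared_frac > 1) abort("shared_frac must be in [0, 1]")
  adj <- band_graph(p, band_width)
  nodes <- rownames(adj)
  band_idx <- which(adj != 0 & upper.tri(adj))
  n_edge <- length(band_idx)
  n_shared <- round(shared_frac * n_edge)
  n_specific <- n_edge - n_shared
  nonband_idx <- which(adj == 0 & upper.tri(adj))
  if (2 * n_specific > length(nonband_idx)) {
    abort("shared_frac too small for the requested density: not enough non-band pairs to rewire into")
  }
  set.seed(seed)
  shared <- sample(band_idx, n_shared)
  rewire <- sample(nonband_idx, 2 * n_specific)
  adj_class <- function(extra) {
    a <- matrix(0L, p, p, dimnames = dimnames(adj))
    a[c(shared, extra)] <- 1L
    a + t(a)
  }
  adj_clean <- adj_class(rewire[seq_len(n_specific)])
  adj_scab <- adj_class(rewire[n_specific + seq_len(n_specific)])
  truth_clean <- structure(list(
    adjacency = adj_clean,
    precision = make_precision(adj_clean, strength, seed = seed + 1),
    network = network_from_adjacency(adj_clean),
    params = list(p = p, band_width = band_width, strength = strength,
                  seed = seed, condition = "clean")), class = "ground_truth")
  truth_scab <- structure(list(
    adjacency = adj_scab,
    precision = make_precision(adj_scab, strength, seed = seed + 2),
    network = network_from_adjacency(adj_scab),
    params = list(p = p, band_width = band_width, strength = strength,
                  seed = seed, condition = "scab")), class = "ground_truth")
  clean <- sample_counts(truth_clean, n_per_class, marginal, seed = seed + 3)
  scab <- sample_counts(truth_scab, n_per_class, marginal, seed = seed + 4)
  clean$label <- 0
  scab$label <- 1
  scab$sample_id <- paste0("d_", scab$sample_id)
  clean$sample_id <- paste0("h_", clean$sample_id)
  list(data = dplyr::bind_rows(clean, scab),
       truth_clean = truth_clean, truth_scab = truth_scab)
}

#' Expected F1 of a density-matched random guess
#'
#' Closed form for the F1 a uniformly random test network of `n_test` edges
#' attains against a reference of `n_ref` edges over the same
#' `choose(n_nodes, 2)` pairs, at the expected number of true positives
#' `n_ref * n_test / n_pairs`: the baseline any informative inference method
#' should beat.
#'
#' @param n_nodes Number of nodes.
#' @param n_ref,n_test Edge counts of the reference and the random test
#'   network.
#' @return Expected F1 (a single number).
#' @export
random_baseline_f1 <- function(n_nodes, n_ref, n_test) {
  n_pairs <- choose(n_nodes, 2)
  tp <- n_ref * n_test / n_pairs
  if (n_ref + n_test == 0) return(1)
  2 * tp / (n_ref + n_test)
}
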