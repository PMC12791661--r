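test_that("band graphs have exactly the within-band edges", {
  chain <- band_graph(5, 1)
  expect_equal(sum(chain) / 2, 4)
  b2 <- band_graph(5, 2)
  expect_equal(sum(b2) / 2, 7)  # 4 + 3 pairs with |i - j| <= 2
  full <- band_graph(5, 4)
  expect_equal(sum(full) / 2, choose(5, 2))
  expect_identical(b2, t(b2))
  expect_true(all(diag(b2) == 0))
  expect_error(band_graph(5, 5), "band_width")
  expect_error(band_graph(1, 1), "at least 2")
})

test_that("precision matrices are positive definite with the prescribed support", {
  for (seed in 1:5) {
    adj <- band_graph(12, 2)
    omega <- make_precision(adj, strength = 0.3, seed = seed)
    expect_gt(attr(omega, "min_eigenvalue"), 0)
    off <- omega; diag(off) <- 0
    expect_identical(unname(off != 0), unname(adj == 1))
    expect_true(all(abs(off[off != 0]) == 0.3))
    # the implied partial correlations are nonzero exactly on edges
    sigma <- solve(omega)
    pinv <- solve(sigma)  # round trip through the covariance
    pc <- -pinv / sqrt(outer(diag(pinv), diag(pinv)))
    diag(pc) <- 0
    expect_true(all(abs(pc[adj == 1]) > 1e-8))
    expect_true(all(abs(pc[adj == 0 & upper.tri(adj)]) < 1e-8))
  }
  # edgeless adjacency: diagonal precision
  empty <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  omd <- make_precision(empty, seed = 1)
  expect_true(all(omd[upper.tri(omd)] == 0))
})

test_that("count sampling is seeded, nonnegative, and respects its marginal family", {
  truth <- make_ground_truth(8, band_width = 1, seed = 2)
  a <- sample_counts(truth, 25, seed = 5)
  b <- sample_counts(truth, 25, seed = 5)
  expect_identical(a, b)
  m <- abundance_matrix(a)
  expect_true(all(m >= 0 & m == round(m)))

  # the zero-inflated marginal produces materially more zeros than plain NB
  zinb <- abundance_matrix(sample_counts(truth, 400,
    marginal = list(family = "zero_inflated_nb", mean = 20, dispersion = 0.5,
                    zero_prob = 0.3), seed = 6))
  nb <- abundance_matrix(sample_counts(truth, 400,
    marginal = list(family = "negative_binomial", mean = 20, dispersion = 0.5),
    seed = 6))
  expect_gt(mean(zinb == 0), mean(nb == 0) + 0.15)

  # large dispersion approaches the Poisson marginal through the same copula
  nb_lim <- abundance_matrix(sample_counts(truth, 200,
    marginal = list(family = "negative_binomial", mean = 10, dispersion = 1e9),
    seed = 7))
  pois <- abundance_matrix(sample_counts(truth, 200,
    marginal = list(family = "poisson", mean = 10), seed = 7))
  expect_equal(nb_lim, pois)
})

test_that("copula counts carry the latent correlation structure", {
  # with no zero inflation and a high-mean marginal, rank correlation of the
  # counts tracks the latent normal correlation
  truth <- make_ground_truth(6, band_width = 1, strength = 0.4, seed = 3)
  sigma <- solve(truth$precision)
  latent_cor <- stats::cov2cor(sigma)
  counts <- abundance_matrix(sample_counts(truth, 1e4,
    marginal = list(family = "negative_binomial", mean = 500, dispersion = 50),
    seed = 9))
  sp <- cor(counts, method = "spearman")
  pearson_equiv <- 2 * sin(pi * sp / 6)  # rank-to-linear for Gaussian copulas
  expect_lt(max(abs(pearson_equiv - latent_cor)), 0.05)
  expect_true(all(sign(sp[truth$adjacency == 1]) ==
                    sign(latent_cor[truth$adjacency == 1])))
})

test_that("two-class datasets share the requested fraction of edges", {
  full <- two_class_dataset(12, n_per_class = 10, shared_frac = 1, seed = 4)
  expect_identical(full$truth_clean$adjacency, full$truth_scab$adjacency)
  none <- two_class_dataset(12, n_per_class = 10, shared_frac = 0, seed = 4)
  expect_length(intersect(edge_keys(none$truth_clean$network),
                          edge_keys(none$truth_scab$network)), 0)
  half <- two_class_dataset(20, n_per_class = 10, shared_frac = 0.5, seed = 4)
  ec <- edge_keys(half$truth_clean$network)
  es <- edge_keys(half$truth_scab$network)
  expect_equal(length(ec), length(es))
  # equal-size edge sets sharing s edges: jaccard = s / (2|E| - s)
  s <- length(intersect(ec, es))
  expect_equal(length(intersect(ec, es)) / length(union(ec, es)),
               s / (2 * length(ec) - s))
  expect_equal(s / length(ec), 0.5, tolerance = 0.06)  # round(0.5 * 37) / 37

  d <- half$data
  expect_equal(sum(d$label == 0), 10)
  expect_equal(sum(d$label == 1), 10)
  expect_error(two_class_dataset(5, 10, shared_frac = 0, band_width = 3),
               "shared_frac too small")
})

test_that("taxa with class-specific edges are enriched in the differential selection", {
  ds <- two_class_dataset(16, n_per_class = 150, shared_frac = 0.5, seed = 8,
                          marginal = list(family = "negative_binomial",
                                          mean = 20, dispersion = 0.5))
  d <- ds$data
  infn <- function(x) infer_cmi_network(x, q1 = 0.5, q2 = 0.8)$network
  clean_net <- infn(d[d$label == 0, setdiff(names(d), "label")])
  scab_net <- infn(d[d$label == 1, setdiff(names(d), "label")])
  res <- suppressWarnings(strategy1_differential(list(m = clean_net),
                                                 list(m = scab_net),
                                                 top_frac = 0.25))
  # taxa touched by class-specific true edges vs the shared-core-only taxa
  diff_keys <- c(setdiff(edge_keys(ds$truth_clean$network),
                         edge_keys(ds$truth_scab$network)),
                 setdiff(edge_keys(ds$truth_scab$network),
                         edge_keys(ds$truth_clean$network)))
  diff_taxa <- unique(unlist(strsplit(diff_keys, "|", fixed = TRUE)))
  sel_rate_diff <- mean(diff_taxa %in% res$selected)
  others <- setdiff(clean_net$nodes, diff_taxa)
  sel_rate_other <- if (length(others) > 0) mean(others %in% res$selected) else 0
  expect_gte(sel_rate_diff, sel_rate_other)
  expect_gt(sel_rate_diff, 0)
})
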