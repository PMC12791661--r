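#' Edge-set agreement between two networks
#'
#' Precision, recall, F1 and the Jaccard index on the edge sets of two
#' networks over the same nodes. With `TP` the number of shared edges,
#' precision = TP/|test|, recall = TP/|reference|,
#' F1 = 2PR/(P+R), Jaccard = |intersection|/|union|. Two empty networks agree
#' perfectly (all metrics 1); one empty, one not gives 0. F1 and Jaccard are
#' symmetric in the two networks; precision and recall swap when reference
#' and test are exchanged.
#'
#' @param reference,test [mb_network()] objects with identical node sets.
#' @return A one-row tibble with `precision`, `recall`, `f1`, `jaccard`,
#'   `reference_size`, `test_size`.
#' @export
score_agreement <- function(reference, test) {
  check_same_nodes(list(reference, test))
  a <- edge_keys(reference)
  b <- edge_keys(test)
  tp <- length(intersect(a, b))
  un <- length(union(a, b))
  if (length(a) == 0 && length(b) == 0) {
    precision <- recall <- f1 <- jaccard <- 1
  } else {
    precision <- if (length(b) > 0) tp / length(b) else 0
    recall <- if (length(a) > 0) tp / length(a) else 0
    f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
    jaccard <- tp / un
  }
  tibble::tibble(precision = precision, recall = recall, f1 = f1,
                 jaccard = jaccard, reference_size = length(a),
                 test_size = length(b))
}

# seeded bootstrap resample indices, one vector per replicate; replicate r
# draws from its own stream (seed + r) so different analyses can share
# identical resamples
bootstrap_indices <- function(n, n_boot, seed) {
  lapply(seq_len(n_boot), function(r) {
    set.seed(seed + r)
    sample.int(n, n, replace = TRUE)
  })
}

#' Bootstrap reproducibility of a network inference procedure
#'
#' Infers a reference network from the full table, then re-infers on
#' `n_boot` bootstrap replicates (rows resampled with replacement, original
#' size preserved; replicate r uses the seeded stream `seed + r`) and scores
#' each replicate network against the reference with [score_agreement()].
#' High, tight F1 distributions indicate that the procedure recovers stable
#' edge sets under resampling — reproducibility, not biological accuracy.
#'
#' @param data An abundance tibble.
#' @param inferrer Function mapping an abundance tibble to an [mb_network()]
#'   (deterministic given its own configuration), e.g.
#'   `function(d) infer_cmi_network(d)$network`.
#' @param n_boot Number of bootstrap replicates. Default 50.
#' @param seed Integer seed for the resampling.
#' @return An object of class `bootstrap_stability`: list with
#'   `replicate_scores` (tibble, one row per replicate), `median_f1`, `sd_f1`,
#'   and `ci_f1` (2.5% and 97.5% percentiles of the replicate F1s).
#'   [tidy()] returns the per-replicate scores, [glance()] the summaries.
#' @export
bootstrap_stability <- function(data, inferrer, n_boot = 50, seed = 1) {
  if (n_boot < 2) abort("n_boot must be at least 2")
  data <- validate_abundance(data, nonnegative = FALSE)
  reference <- inferrer(data)
  idx <- bootstrap_indices(nrow(data), n_boot, seed)
  scores <- purrr::map_dfr(seq_len(n_boot), function(r) {
    boot <- data[idx[[r]], ]
    boot$sample_id <- paste0("b", seq_len(nrow(boot)))
    dplyr::bind_cols(tibble::tibble(replicate = r),
                     score_agreement(reference, inferrer(boot)))
  })
  ci <- unname(quantile(scores$f1, c(0.025, 0.975), type = 7))
  structure(list(replicate_scores = scores, reference = reference,
                 median_f1 = median(scores$f1), sd_f1 = sd(scores$f1),
                 ci_f1 = ci, n_boot = n_boot, seed = seed),
            class = "bootstrap_stability")
}

#' @export
print.bootstrap_stability <- function(x, ...) {
  cat("<bootstrap_stability> ", x$n_boot, " replicates\n",
      "  median F1 = ", format(x$median_f1, digits = 3),
      ", sd = ", format(x$sd_f1, digits = 3),
      ", 95% percentile CI = (", format(x$ci_f1[1], digits = 3), ", ",
      format(x$ci_f1[2], digits = 3), ")\n", sep = "")
  invisible(x)
}

#' @method tidy bootstrap_stability
#' @export
tidy.bootstrap_stability <- function(x, ...) x$replicate_scores

#' @method glance bootstrap_stability
#' @export
glance.bootstrap_stability <- function(x, ...) {
  tibble::tibble(n_boot = x$n_boot, median_f1 = x$median_f1, sd_f1 = x$sd_f1,
                 ci_low = x$ci_f1[1], ci_high = x$ci_f1[2],
                 median_jaccard = median(x$replicate_scores$jaccard))
}

#' @method autoplot bootstrap_stability
#' @export
autoplot.bootstrap_stability <- function(object, ...) {
  df <- tidyr::pivot_longer(object$replicate_scores, c("f1", "jaccard"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "agreement with reference network") +
    ggplot2::theme_minimal()
}

#' Pairwise similarity of networks under different normalizations
#'
#' For each bootstrap replicate (the *same* seeded resamples for every
#' normalization, so the comparison isolates the normalization), infers one
#' network per normalization method and scores every pair of methods with
#' [score_agreement()] on that replicate; reports the median and sd of the 50
#' (or `n_boot`) F1 values per method pair.
#'
#' @param data An abundance tibble of raw counts.
#' @param methods Character vector of >= 2 normalization methods (see
#'   [normalize_abundance()]).
#' @param n_boot Number of bootstrap replicates. Default 50.
#' @param seed Integer seed.
#' @param q1,q2 Quantile thresholds passed to [infer_cmi_network()], which is
#'   run with `quantitative = FALSE` on each normalized replicate.
#' @param pseudocount Pseudocount for log/clr.
#' @return A tibble with `method_a`, `method_b`, `median_f1`, `sd_f1`.
#' @export
pairwise_normalization_similarity <- function(data, methods, n_boot = 50, seed = 1,
                                              q1 = 0.70, q2 = 0.95, pseudocount = 1) {
  if (length(methods) < 2) abort("at least 2 normalization methods required")
  data <- validate_abundance(data)
  idx <- bootstrap_indices(nrow(data), n_boot, seed)
  nets <- lapply(seq_len(n_boot), function(r) {
    boot <- data[idx[[r]], ]
    boot$sample_id <- paste0("b", seq_len(nrow(boot)))
    lapply(setNames(methods, methods), function(m) {
      infer_cmi_network(normalize_abundance(boot, m, pseudocount = pseudocount),
                        q1 = q1, q2 = q2, quantitative = FALSE)$network
    })
  })
  pairs <- combn(methods, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    f1 <- vapply(nets, function(nn) score_agreement(nn[[a]], nn[[b]])$f1, numeric(1))
    tibble::tibble(method_a = a, method_b = b,
                   median_f1 = median(f1), sd_f1 = sd(f1))
  })
}

#' Paired comparison of bootstrap F1 distributions across methods
#'
#' Wilcoxon signed-rank tests on paired per-replicate F1 scores for every
#' pair of methods, with Holm adjustment for the multiple pairs. All-zero
#' paired differences (identical distributions) are reported with p = 1.
#'
#' @param distributions Named list of equal-length numeric vectors of F1
#'   scores, paired by replicate.
#' @param adjust Multiple-testing adjustment method for [stats::p.adjust()].
#'   Default `"holm"`.
#' @return A tibble with `method_a`, `method_b`, `median_diff`
#'   (median(A) - median(B)), `p_value`, `p_adjusted`.
#' @export
compare_method_f1 <- function(distributions, adjust = "holm") {
  nms <- names(distributions)
  if (length(distributions) < 2 || is.null(nms)) {
    abort("a named list of at least 2 score vectors is required")
  }
  len <- lengths(distributions)
  if (length(unique(len)) != 1) abort("score vectors must have equal length (paired)")
  pairs <- combn(nms, 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    a <- distributions[[pairs[1, k]]]
    b <- distributions[[pairs[2, k]]]
    p <- if (all(a == b)) 1 else
      suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value)
    tibble::tibble(method_a = pairs[1, k], method_b = pairs[2, k],
                   median_diff = median(a) - median(b), p_value = p)
  })
  out$p_adjusted <- p.adjust(out$p_value, method = adjust)
  out
}
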