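# fixtures built in code: random count tables, random networks, and a naive
# reference implementation of the skeleton algorithm used as an oracle

random_count_table <- function(n, p, seed, mu = 10, size = 1) {
  set.seed(seed)
  counts <- matrix(stats::rnbinom(n * p, mu = mu, size = size), n, p)
  colnames(counts) <- sprintf("t%02d", seq_len(p))
  dplyr::bind_cols(tibble::tibble(sample_id = sprintf("s%03d", seq_len(n))),
                   tibble::as_tibble(counts))
}

random_network <- function(nodes, prob, seed) {
  set.seed(seed)
  pairs <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(pairs)) < prob
  mb_network(nodes, tibble::tibble(from = pairs[1, keep], to = pairs[2, keep]))
}

canon_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

# naive loop implementation of the two-stage skeleton: explicit matrices and
# for-loops, no shared code with infer_cmi_network beyond the two estimator
# primitives it is specified in terms of
naive_skeleton <- function(data, q1 = 0.70, q2 = 0.95, quantitative = TRUE,
                           pseudocount = 1) {
  mat <- as.matrix(data[, setdiff(names(data), c("sample_id", "label"))])
  if (quantitative) mat <- log(mat + pseudocount)
  mat <- mat[, apply(mat, 2, stats::var) > 0, drop = FALSE]
  taxa <- colnames(mat)
  p <- ncol(mat)
  mi <- matrix(NA_real_, p, p)
  for (i in seq_len(p - 1)) {
    for (j in seq(i + 1, p)) {
      mi[i, j] <- mi[j, i] <- mi_gaussian(mat[, i], mat[, j])
    }
  }
  t1 <- as.numeric(stats::quantile(mi[upper.tri(mi)], q1))
  adj0 <- mi >= t1
  adj0[is.na(adj0)] <- FALSE
  s0_keys <- character()
  max_cmi <- numeric()
  has_sep <- logical()
  for (i in seq_len(p - 1)) {
    for (j in seq(i + 1, p)) {
      if (!adj0[i, j]) next
      key <- canon_key(taxa[i], taxa[j])
      s0_keys <- c(s0_keys, key)
      seps <- setdiff(which(adj0[i, ] & adj0[j, ]), c(i, j))
      if (length(seps) == 0) {
        max_cmi[key] <- NA_real_
        has_sep[key] <- FALSE
      } else {
        best <- -Inf
        for (s in seps) best <- max(best, cmi_gaussian(mat[, i], mat[, j], mat[, s]))
        max_cmi[key] <- best
        has_sep[key] <- TRUE
      }
    }
  }
  if (any(has_sep)) {
    t2 <- as.numeric(stats::quantile(max_cmi[has_sep], q2))
    s1_keys <- names(has_sep)[!has_sep | max_cmi >= t2]
  } else {
    s1_keys <- s0_keys
  }
  list(s0 = sort(s0_keys), max_cmi = max_cmi[has_sep], s1 = sort(s1_keys))
}
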