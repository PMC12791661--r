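#' Normalize a count table
#'
#' The four sample-wise transforms commonly compared for co-occurrence network
#' inference, applied to a samples-by-taxa count tibble:
#'
#' * `log` — elementwise `log(count + pseudocount)` (natural log). A simple
#'   variance stabilizer for sequencing counts; the default upstream of MI/CMI
#'   estimation.
#' * `clr` — centered log-ratio: per sample, `log(count + pseudocount)` minus
#'   the mean of those logs, so each row sums to 0. Addresses compositionality.
#' * `tss` — total-sum scaling: each row divided by its row sum (relative
#'   abundances; rows sum to 1).
#' * `gmpr` — each row divided by its geometric-mean-of-pairwise-ratios size
#'   factor (see [gmpr_size_factors()]); values stay on a scaled-count scale.
#' * `none` — values passed through unchanged.
#'
#' @param data An abundance tibble (see [read_abundance()]).
#' @param method One of `"log"`, `"clr"`, `"tss"`, `"gmpr"`, `"none"`.
#' @param pseudocount Positive constant added before logs (`log`, `clr`);
#'   default 1.
#' @return A tibble of the same shape and ids, with attributes `norm_method`
#'   and `pseudocount`.
#' @export
normalize_abundance <- function(data, method = c("log", "clr", "tss", "gmpr", "none"),
                                pseudocount = 1) {
  method <- match.arg(method)
  data <- validate_abundance(data, nonnegative = method != "none")
  mat <- abundance_matrix(data)
  if (method %in% c("log", "clr")) {
    if (pseudocount <= 0 && any(mat == 0)) {
      abort("a positive pseudocount is required for log/clr when zeros are present")
    }
  }
  vals <- switch(method,
    none = mat,
    log = log(mat + pseudocount),
    clr = {
      lg <- log(mat + pseudocount)
      lg - rowMeans(lg)
    },
    tss = {
      rs <- rowSums(mat)
      if (any(rs == 0)) {
        abort(paste0("tss undefined for all-zero sample(s): ",
                     paste(rownames(mat)[rs == 0], collapse = ", ")))
      }
      mat / rs
    },
    gmpr = mat / gmpr_size_factors(data)
  )
  out <- data
  out[, colnames(mat)] <- tibble::as_tibble(vals)
  attr(out, "norm_method") <- method
  attr(out, "pseudocount") <- pseudocount
  out
}

#' GMPR size factors
#'
#' Geometric mean of pairwise ratios: for sample *i*, the median of the count
#' ratios `c[i, k] / c[j, k]` is taken over the taxa `k` nonzero in both *i*
#' and *j*, and the size factor is the geometric mean of those medians over
#' all partner samples *j* for which at least one shared nonzero taxon exists.
#' Robust to the zero inflation that breaks median-of-ratios factors computed
#' against a reference sample.
#'
#' @param data An abundance tibble.
#' @return Named numeric vector of size factors, one per sample. A sample that
#'   shares no nonzero taxon with any other sample is an error (its factor
#'   would be undefined).
#' @export
gmpr_size_factors <- function(data) {
  mat <- abundance_matrix(data)
  n <- nrow(mat)
  if (n < 2) abort("gmpr needs at least 2 samples")
  sf <- numeric(n)
  for (i in seq_len(n)) {
    logmed <- c()
    for (j in seq_len(n)[-i]) {
      shared <- mat[i, ] > 0 & mat[j, ] > 0
      if (any(shared)) {
        logmed <- c(logmed, log(median(mat[i, shared] / mat[j, shared])))
      }
    }
    if (length(logmed) == 0) {
      abort(paste0("gmpr undefined: sample '", rownames(mat)[i],
                   "' shares no nonzero taxon with any other sample"))
    }
    sf[i] <- exp(mean(logmed))
  }
  setNames(sf, rownames(mat))
}

#' Default preprocessing ahead of MI/CMI estimation
#'
#' With `quantitative = TRUE` the counts are log-transformed
#' (`log(count + pseudocount)`); with `quantitative = FALSE` the values are
#' passed through unchanged, for callers supplying data already normalized
#' (e.g. CLR-transformed) externally.
#'
#' @param data An abundance tibble.
#' @param quantitative Logical; apply the log transform? Default `TRUE`.
#' @param pseudocount Pseudocount for the log transform; default 1.
#' @return A normalized tibble (see [normalize_abundance()]).
#' @export
default_pipeline <- function(data, quantitative = TRUE, pseudocount = 1) {
  normalize_abundance(data, if (isTRUE(quantitative)) "log" else "none",
                      pseudocount = pseudocount)
}
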