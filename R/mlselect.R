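#' The seven machine-learning feature rankers
#' @export
ml_methods_all <- c("f_test_kbest", "mutual_info_kbest", "rfe_logistic",
                    "rfe_tree", "rfe_boosting", "rfe_forest", "abundance_top")

# per-feature one-way F statistic between the two classes
f_statistic <- function(x, labels) {
  groups <- split(x, labels)
  n <- length(x)
  grand <- mean(x)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2, numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- length(groups) - 1
  dfw <- n - length(groups)
  if (ssw == 0) return(Inf)
  (ssb / dfb) / (ssw / dfw)
}

# discrete MI between an equal-frequency binning of x and the binary label
binned_mi <- function(x, labels, n_bins = NULL) {
  n <- length(x)
  if (is.null(n_bins)) n_bins <- max(2L, min(10L, floor(sqrt(n / 2))))
  brk <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1), type = 7))
  if (length(brk) < 2) return(0)
  bins <- cut(x, breaks = brk, include.lowest = TRUE)
  joint <- table(bins, labels) / n
  px <- rowSums(joint); py <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / outer(px, py)[nz]))
}

# recursive feature elimination: repeatedly drop the least important feature
# according to `importance(mat, labels)` until k remain
rfe <- function(mat, labels, k, importance) {
  feats <- colnames(mat)
  while (length(feats) > k) {
    imp <- importance(mat[, feats, drop = FALSE], labels)
    drop <- feats[which.min(imp)]
    feats <- setdiff(feats, drop)
  }
  feats
}

rfe_importance <- function(method, seed) {
  switch(method,
    rfe_logistic = function(mat, labels) {
      # ridge-penalized logistic regression (L2, fixed penalty), |coef| as
      # importance on standardized features
      fit <- glmnet::glmnet(mat, factor(labels), family = "binomial",
                            alpha = 0, lambda = 1 / nrow(mat),
                            standardize = TRUE)
      co <- abs(as.numeric(fit$beta))
      setNames(co, rownames(fit$beta))[colnames(mat)]
    },
    rfe_tree = function(mat, labels) {
      df <- data.frame(mat, check.names = FALSE)
      df$.y <- factor(labels)
      fit <- rpart::rpart(.y ~ ., data = df, method = "class")
      imp <- setNames(rep(0, ncol(mat)), colnames(mat))
      vi <- fit$variable.importance
      imp[names(vi)] <- vi
      imp
    },
    rfe_boosting = function(mat, labels) {
      set.seed(seed)
      dtrain <- xgboost::xgb.DMatrix(mat, label = labels, nthread = 1)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = 3,
                      eta = 0.3, nthread = 1),
        data = dtrain, nrounds = 100, verbose = 0)
      imp <- setNames(rep(0, ncol(mat)), colnames(mat))
      gi <- xgboost::xgb.importance(model = fit)
      imp[gi$Feature] <- gi$Gain
      imp
    },
    rfe_forest = function(mat, labels) {
      set.seed(seed)
      fit <- randomForest::randomForest(mat, factor(labels), ntree = 100)
      imp <- fit$importance[, "MeanDecreaseGini"]
      imp[colnames(mat)]
    }
  )
}

#' Select the top taxa for disease status with one ranking method
#'
#' All methods return `k = ceiling(top_frac * p)` taxa (the abundance filter
#' may return more on ties):
#'
#' * `f_test_kbest` — top k by the one-way ANOVA F statistic between classes.
#' * `mutual_info_kbest` — top k by a nonparametric mutual-information score
#'   with the label (equal-frequency binning).
#' * `rfe_logistic` / `rfe_tree` / `rfe_boosting` / `rfe_forest` — recursive
#'   feature elimination down to k features, dropping at each step the
#'   feature least important to a ridge logistic regression, a decision tree
#'   (rpart), gradient-boosted trees (xgboost, 100 rounds), or a random
#'   forest (100 trees); seeded for the stochastic learners.
#' * `abundance_top` — taxa whose maximum abundance reaches the
#'   `1 - top_frac` quantile of the per-taxon maxima: a model-free filter
#'   keeping highly abundant taxa that model-driven selection may miss.
#'
#' @param data A (possibly normalized) abundance tibble; any `label` column
#'   is ignored in favour of `labels`.
#' @param labels Binary vector (0/1), one per sample; both classes present.
#' @param method One of [ml_methods_all].
#' @param top_frac Fraction of taxa to keep. Default 0.20.
#' @param seed Integer seed for the stochastic learners. Default 1.
#' @return Character vector of selected taxon ids.
#' @export
rank_features <- function(data, labels, method, top_frac = 0.20, seed = 1) {
  method <- match.arg(method, ml_methods_all)
  mat <- abundance_matrix_any(data)
  if (ncol(mat) < 2) abort("at least 2 taxa required")
  if (nrow(mat) != length(labels)) abort("one label per sample required")
  if (length(unique(labels)) < 2) abort("labels must contain both classes")
  k <- ceiling(top_frac * ncol(mat))
  switch(method,
    f_test_kbest = {
      sc <- apply(mat, 2, f_statistic, labels = labels)
      names(sort(sc, decreasing = TRUE))[seq_len(k)]
    },
    mutual_info_kbest = {
      sc <- apply(mat, 2, binned_mi, labels = labels)
      names(sort(sc, decreasing = TRUE))[seq_len(k)]
    },
    abundance_top = {
      mx <- apply(mat, 2, max)
      thr <- quantile(mx, 1 - top_frac, type = 7)
      colnames(mat)[mx >= thr]
    },
    rfe(mat, labels, k, rfe_importance(method, seed))
  )
}

# accept either an abundance tibble or a plain numeric matrix
abundance_matrix_any <- function(data) {
  if (is.matrix(data)) return(data)
  abundance_matrix(validate_labels_free(data))
}

# normalized tables may hold negative values (clr, log of fractions), so
# skip the nonnegativity check that raw counts get
validate_labels_free <- function(data) {
  data <- tibble::as_tibble(data)
  if (!"sample_id" %in% names(data)) abort("abundance table needs a 'sample_id' column")
  data
}

#' TOTAL consensus score over all ML rankers and normalizations
#'
#' Runs every ranking method on every requested normalization of the counts.
#' Within one normalization, a taxon's TOTAL score is the number of methods
#' (0-7) that selected it; taxa are then called selected when TOTAL exceeds
#' the majority-rule cutoff (see [ml_selected()]). Per-normalization
#' selections and their intersection across normalizations are both
#' reported, since normalization alone can change which taxa rank highly.
#'
#' @param data A raw-count abundance tibble.
#' @param labels Binary disease labels (0/1), one per sample; defaults to the
#'   table's `label` column.
#' @param methods Ranking methods to run. Default all seven.
#' @param normalizations Normalizations to run them under. Default
#'   `c("clr", "none", "log", "tss")`.
#' @param top_frac Fraction each method keeps. Default 0.20.
#' @param cutoff Majority-rule cutoff; a taxon is selected when
#'   TOTAL > cutoff. Default 3.
#' @param pseudocount Pseudocount for log/clr. Default 1.
#' @param seed Integer seed. Default 1.
#' @return An object of class `ml_total_report`: list with `flags` (tibble:
#'   taxon x normalization x method selection flags), `totals` (tibble with
#'   per-normalization TOTAL and selection), `intersection` (taxa selected
#'   under every normalization), and the configuration. [tidy()] returns
#'   `totals`.
#' @export
total_score <- function(data, labels = data$label, methods = ml_methods_all,
                        normalizations = c("clr", "none", "log", "tss"),
                        top_frac = 0.20, cutoff = 3, pseudocount = 1, seed = 1) {
  data <- validate_abundance(data)
  if (is.null(labels)) abort("labels are required (0 healthy / 1 diseased)")
  methods <- match.arg(methods, ml_methods_all, several.ok = TRUE)
  taxa <- taxon_names(data)
  flags <- purrr::map_dfr(normalizations, function(nrm) {
    norm <- normalize_abundance(data, nrm, pseudocount = pseudocount)
    purrr::map_dfr(methods, function(m) {
      sel <- rank_features(norm, labels, m, top_frac = top_frac, seed = seed)
      tibble::tibble(normalization = nrm, method = m, taxon = taxa,
                     selected = taxa %in% sel)
    })
  })
  totals <- flags |>
    dplyr::group_by(.data$normalization, .data$taxon) |>
    dplyr::summarise(total = sum(.data$selected), .groups = "drop") |>
    dplyr::mutate(selected = .data$total > cutoff)
  per_norm <- split(totals$taxon[totals$selected], totals$normalization[totals$selected])
  per_norm <- per_norm[normalizations[normalizations %in% names(per_norm)]]
  inter <- if (length(per_norm) == length(normalizations)) {
    sort(Reduce(intersect, per_norm))
  } else character()
  structure(list(flags = flags, totals = totals, intersection = inter,
                 methods = methods, normalizations = normalizations,
                 top_frac = top_frac, cutoff = cutoff, seed = seed),
            class = "ml_total_report")
}

#' @export
print.ml_total_report <- function(x, ...) {
  cat("<ml_total_report> ", length(x$methods), " methods x ",
      length(x$normalizations), " normalizations (cutoff TOTAL > ", x$cutoff,
      ")\n", sep = "")
  for (nrm in x$normalizations) {
    sel <- x$totals$taxon[x$totals$normalization == nrm & x$totals$selected]
    cat("  ", nrm, ": ", length(sel), " taxa selected\n", sep = "")
  }
  cat("  intersection: ", length(x$intersection), " taxa\n", sep = "")
  invisible(x)
}

#' @method tidy ml_total_report
#' @export
tidy.ml_total_report <- function(x, ...) x$totals

#' Taxa passing the majority-rule TOTAL cutoff
#'
#' @param total_report An `ml_total_report` from [total_score()].
#' @param cutoff Select taxa with TOTAL strictly greater than this. Default 3
#'   (supported by more than half of the seven methods).
#' @param normalization Which normalization's TOTAL to use. Default `"log"`.
#' @return Character vector of selected taxa.
#' @export
ml_selected <- function(total_report, cutoff = 3, normalization = "log") {
  tot <- total_report$totals
  if (!normalization %in% tot$normalization) {
    abort(paste0("normalization '", normalization, "' not in the report"))
  }
  keep <- tot$normalization == normalization & tot$total > cutoff
  sort(tot$taxon[keep])
}
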