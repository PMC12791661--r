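#' Read a taxon abundance table
#'
#' Reads a delimited count table (TSV or CSV, auto-detected from the file
#' extension) with a header row and identifiers in the first column, and
#' returns it as a validated samples-by-taxa tibble: one `sample_id` column
#' followed by one numeric column per taxon. Files stored taxa-as-rows are
#' transposed on read so downstream code always sees samples as rows.
#'
#' @param path Path to a `.tsv` or `.csv` file.
#' @param orientation Either `"samples_as_rows"` (default; first column holds
#'   sample ids, remaining columns are taxa) or `"taxa_as_rows"` (first column
#'   holds taxon ids, remaining columns are samples).
#' @return A tibble with a `sample_id` character column and one nonnegative
#'   numeric column per taxon.
#' @seealso [filter_prevalence()], [normalize_abundance()]
#' @export
read_abundance <- function(path, orientation = c("samples_as_rows", "taxa_as_rows")) {
  orientation <- match.arg(orientation)
  raw <- read_delimited(path)
  ids <- as.character(raw[[1]])
  mat <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!vapply(raw[-1], is.numeric, logical(1)))
    abort(paste0("non-numeric values in column(s): ",
                 paste(names(raw)[-1][bad], collapse = ", ")))
  }
  rownames(mat) <- ids
  if (orientation == "taxa_as_rows") mat <- t(mat)
  if (anyDuplicated(colnames(mat))) {
    dup <- unique(colnames(mat)[duplicated(colnames(mat))])
    abort(paste0("duplicate taxon ids: ", paste(dup, collapse = ", ")))
  }
  if (anyDuplicated(rownames(mat))) {
    dup <- unique(rownames(mat)[duplicated(rownames(mat))])
    abort(paste0("duplicate sample ids: ", paste(dup, collapse = ", ")))
  }
  out <- tibble::tibble(sample_id = rownames(mat))
  out <- dplyr::bind_cols(out, tibble::as_tibble(mat))
  validate_abundance(out)
}

read_delimited <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    readr::read_csv(path, show_col_types = FALSE, name_repair = "minimal")
  } else {
    readr::read_tsv(path, show_col_types = FALSE, name_repair = "minimal")
  }
}

#' Validate a samples-by-taxa abundance tibble
#'
#' Checks the invariants every downstream function relies on: a `sample_id`
#' column of unique ids, unique taxon column names, numeric nonnegative
#' counts, and (if present) a binary `label` column.
#'
#' @param data A data frame with `sample_id`, optional `label`, and taxon
#'   columns.
#' @param nonnegative Require all values to be nonnegative (appropriate for
#'   raw counts; set `FALSE` for normalized tables, e.g. CLR values).
#' @return The validated data, as a tibble.
#' @export
validate_abundance <- function(data, nonnegative = TRUE) {
  data <- tibble::as_tibble(data)
  if (!"sample_id" %in% names(data)) abort("abundance table needs a 'sample_id' column")
  sid <- as.character(data$sample_id)
  if (anyDuplicated(sid)) {
    abort(paste0("duplicate sample ids: ",
                 paste(unique(sid[duplicated(sid)]), collapse = ", ")))
  }
  taxa <- taxon_names(data)
  if (length(taxa) == 0) abort("abundance table has no taxon columns")
  if (anyDuplicated(taxa)) {
    abort(paste0("duplicate taxon ids: ",
                 paste(unique(taxa[duplicated(taxa)]), collapse = ", ")))
  }
  for (tx in taxa) {
    col <- data[[tx]]
    if (!is.numeric(col)) abort(paste0("non-numeric values in taxon column '", tx, "'"))
    if (anyNA(col)) abort(paste0("missing values in taxon column '", tx, "'"))
    if (nonnegative && any(col < 0)) {
      row <- sid[which(col < 0)[1]]
      abort(paste0("negative count at sample '", row, "', taxon '", tx, "'"))
    }
  }
  if ("label" %in% names(data)) {
    if (!all(data$label %in% c(0, 1))) abort("labels must be 0 (healthy) or 1 (diseased)")
  }
  data
}

taxon_names <- function(data) setdiff(names(data), c("sample_id", "label"))

#' Extract the numeric count/value matrix from an abundance tibble
#' @param data An abundance tibble (see [read_abundance()]).
#' @return A numeric matrix, samples as rows (named), taxa as columns.
#' @export
abundance_matrix <- function(data) {
  taxa <- taxon_names(data)
  mat <- as.matrix(data[, taxa, drop = FALSE])
  rownames(mat) <- as.character(data$sample_id)
  mat
}

#' Attach binary disease labels to an abundance table
#' @param data An abundance tibble.
#' @param labels Numeric vector in {0, 1}, one per sample (0 healthy,
#'   1 diseased), in row order.
#' @return The tibble with a `label` column.
#' @export
add_labels <- function(data, labels) {
  if (length(labels) != nrow(data)) abort("one label per sample required")
  data$label <- labels
  validate_abundance(data)
}

#' Filter taxa by prevalence
#'
#' Keeps exactly the taxa observed (count > 0) in at least `min_samples`
#' samples; the sample set is unchanged. The default of 15 targets taxa
#' prevalent enough to contribute to network and selection analyses.
#'
#' @param data An abundance tibble.
#' @param min_samples Minimum number of samples a taxon must appear in
#'   (count > 0) to be kept. Default 15.
#' @return The filtered tibble.
#' @export
filter_prevalence <- function(data, min_samples = 15) {
  data <- validate_abundance(data)
  if (min_samples < 1) abort("min_samples must be >= 1")
  mat <- abundance_matrix(data)
  prev <- colSums(mat > 0)
  keep <- names(prev)[prev >= min_samples]
  if (length(keep) == 0) {
    abort(paste0("no taxon appears in at least ", min_samples,
                 " samples; lower min_samples"))
  }
  data[, c(intersect(names(data), c("sample_id", "label")), keep)]
}

#' Write a network to disk
#'
#' @param net An `mb_network`.
#' @param path Output file path (TSV).
#' @param format `"edge_list"` (two-column TSV `node_a`, `node_b` of canonical
#'   pairs) or `"adjacency_matrix"` (square symmetric 0/1 TSV with node ids as
#'   header and first column).
#' @return Invisibly, `net`.
#' @export
write_network <- function(net, path, format = c("edge_list", "adjacency_matrix")) {
  format <- match.arg(format)
  if (format == "edge_list") {
    readr::write_tsv(tibble::tibble(node_a = net$edges$from, node_b = net$edges$to), path)
  } else {
    adj <- network_adjacency(net)
    out <- dplyr::bind_cols(tibble::tibble(node_id = rownames(adj)),
                            tibble::as_tibble(adj))
    readr::write_tsv(out, path)
  }
  invisible(net)
}

#' Read a network from a labeled adjacency matrix file
#'
#' Nonzero off-diagonal entries become edges; the diagonal is ignored. This is
#' the entry point for adjacency exports of external inference methods
#' (e.g. SPIEC-EASI, SPRING, SPARCC runs done elsewhere). An asymmetric matrix
#' is symmetrized by logical OR with a warning, since all edges here are
#' undirected and unsigned.
#'
#' @param path Path to a square labeled TSV/CSV adjacency matrix (first column
#'   = row labels, header = column labels).
#' @return An `mb_network`.
#' @export
read_adjacency <- function(path) {
  raw <- read_delimited(path)
  nodes <- as.character(raw[[1]])
  mat <- as.matrix(raw[, -1, drop = FALSE])
  if (nrow(mat) != ncol(mat)) abort("adjacency matrix must be square")
  if (!identical(colnames(mat), nodes)) {
    abort("adjacency header and row labels disagree")
  }
  rownames(mat) <- nodes
  if (!isTRUE(all.equal(mat, t(mat), check.attributes = FALSE))) {
    warn("asymmetric adjacency input; symmetrizing by logical OR")
  }
  sym <- (mat != 0) | (t(mat) != 0)
  diag(sym) <- FALSE
  network_from_adjacency(sym * 1L)
}

#' Read a network from an edge-list file
#'
#' @param path Path to a TSV/CSV with columns `node_a`, `node_b` (a third
#'   weight column, if present, is ignored).
#' @param node_ids Optional full node universe; defaults to the ids appearing
#'   in the edges (isolated nodes are then lost, so pass `node_ids` when the
#'   universe matters).
#' @return An `mb_network`.
#' @export
read_edge_list <- function(path, node_ids = NULL) {
  raw <- read_delimited(path)
  if (ncol(raw) < 2) abort("edge list needs columns node_a and node_b")
  from <- as.character(raw[[1]])
  to <- as.character(raw[[2]])
  if (is.null(node_ids)) node_ids <- sort(unique(c(from, to)))
  if (length(node_ids) == 0) abort("empty edge list and no node_ids given")
  mb_network(node_ids, tibble::tibble(from = from, to = to))
}
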