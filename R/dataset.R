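#' Expression dataset container
#'
#' Bundles a samples-by-genes expression matrix with sample identifiers,
#' gene identifiers and a binary clinical-response label per sample.
#' Responders are encoded 100 and non-responders 0, so that averaged
#' classifier predictions live on the same 0-100 scale; labels supplied
#' as 0/1 are rescaled on construction.
#'
#' @param values numeric matrix (samples in rows, genes in columns) or a
#'   data frame whose first column holds sample identifiers.
#' @param labels numeric vector of per-sample responses in `{0, 100}`
#'   (or `{0, 1}`, rescaled), in the same order as the rows of `values`.
#' @param sample_ids,gene_ids optional character identifiers; default to
#'   the dimnames of `values` (or `s1..sN` / `g1..gs`).
#'
#' @return An object of class `flowps_dataset`: a list with elements
#'   `values`, `sample_ids`, `gene_ids` and `labels`.
#' @examples
#' x <- matrix(rnorm(12), 3, 4)
#' ds <- flowps_dataset(x, labels = c(0, 100, 0))
#' ds
#' @export
flowps_dataset <- function(values, labels, sample_ids = NULL, gene_ids = NULL) {
  if (is.data.frame(values)) {
    if (is.null(sample_ids) && (is.character(values[[1]]) || is.factor(values[[1]]))) {
      sample_ids <- as.character(values[[1]])
      values <- values[, -1, drop = FALSE]
    }
    gene_ids <- gene_ids %||% colnames(values)
    values <- as.matrix(values)
  }
  if (!is.matrix(values) || !is.numeric(values))
    abort("`values` must be a numeric matrix (samples x genes).")
  n <- nrow(values); s <- ncol(values)
  sample_ids <- sample_ids %||% rownames(values) %||% paste0("s", seq_len(n))
  gene_ids <- gene_ids %||% colnames(values) %||% paste0("g", seq_len(s))
  sample_ids <- as.character(sample_ids)
  gene_ids <- as.character(gene_ids)
  if (length(sample_ids) != n)
    abort("length(sample_ids) must equal nrow(values).")
  if (length(gene_ids) != s)
    abort("length(gene_ids) must equal ncol(values).")
  if (anyDuplicated(sample_ids))
    abort(paste0("duplicated sample id: ",
                 sample_ids[duplicated(sample_ids)][1]))
  if (anyDuplicated(gene_ids))
    abort(paste0("duplicated gene id: ", gene_ids[duplicated(gene_ids)][1]))
  if (anyNA(values)) {
    bad <- which(rowSums(is.na(values)) > 0)[1]
    abort(paste0("missing values are not allowed (first offending sample: ",
                 sample_ids[bad], ")"))
  }
  labels <- canonical_labels(labels, n)
  dimnames(values) <- list(sample_ids, gene_ids)
  structure(
    list(values = values, sample_ids = sample_ids, gene_ids = gene_ids,
         labels = labels),
    class = "flowps_dataset"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Coerce labels to the canonical {0, 100} coding; error on anything else.
canonical_labels <- function(labels, n) {
  if (length(labels) != n)
    abort("length(labels) must equal the number of samples.")
  labels <- as.numeric(labels)
  if (anyNA(labels)) abort("labels must not contain missing values.")
  u <- sort(unique(labels))
  if (all(u %in% c(0, 1))) labels <- labels * 100
  else if (!all(u %in% c(0, 100)))
    abort("labels must take values in {0, 100} (or {0, 1}).")
  as.integer(labels)
}

#' @export
print.flowps_dataset <- function(x, ...) {
  cat("<flowps_dataset> ", nrow(x$values), " samples x ", ncol(x$values),
      " genes (", sum(x$labels == 100), " responders, ",
      sum(x$labels == 0), " non-responders)\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.flowps_dataset <- function(x, ...) {
  dplyr::bind_cols(
    tibble(sample_id = x$sample_ids, label = x$labels),
    as_tibble(x$values, .name_repair = "minimal")
  )
}

#' @export
dim.flowps_dataset <- function(x) dim(x$values)

# Subset samples (used internally for leave-one-out folds).
subset_samples <- function(ds, idx) {
  flowps_dataset(ds$values[idx, , drop = FALSE], ds$labels[idx],
                 sample_ids = ds$sample_ids[idx], gene_ids = ds$gene_ids)
}

detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (lengths(regmatches(first, gregexpr("\t", first))) >=
      lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
}

#' Read an expression matrix and response labels from delimited text
#'
#' The matrix file is TSV or CSV (auto-detected) with one header row of
#' identifiers and identifiers in the first column; the labels file has two
#' columns, `sample_id` and `label` (0/100, or 0/1 which is rescaled).
#' Files with genes in rows are transposed via
#' `orientation = "genes_by_samples"`.
#'
#' @param matrix_path,labels_path paths to the delimited text files.
#' @param orientation `"samples_by_genes"` (default) or `"genes_by_samples"`.
#' @return A [flowps_dataset].
#' @export
read_expression_dataset <- function(matrix_path, labels_path,
                                    orientation = c("samples_by_genes",
                                                    "genes_by_samples")) {
  orientation <- match.arg(orientation)
  delim <- detect_delim(matrix_path)
  raw <- utils::read.delim(matrix_path, sep = delim, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids))
    abort(paste0("duplicated row id in ", matrix_path, ": ",
                 ids[duplicated(ids)][1]))
  body <- raw[, -1, drop = FALSE]
  if (anyDuplicated(colnames(body)))
    abort(paste0("duplicated column id in ", matrix_path, ": ",
                 colnames(body)[duplicated(colnames(body))][1]))
  nonnum <- !vapply(body, is.numeric, logical(1))
  if (any(nonnum))
    abort(paste0("non-numeric cells in column '",
                 colnames(body)[nonnum][1], "' of ", matrix_path))
  values <- as.matrix(body)
  rownames(values) <- ids
  if (orientation == "genes_by_samples") values <- t(values)
  if (anyNA(values)) {
    bad <- rownames(values)[which(rowSums(is.na(values)) > 0)[1]]
    abort(paste0("missing values in ", matrix_path, " (sample ", bad, ")"))
  }

  ldelim <- detect_delim(labels_path)
  lab <- utils::read.delim(labels_path, sep = ldelim, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(lab) < 2) abort("labels file must have two columns: sample_id, label.")
  lab_ids <- as.character(lab[[1]])
  if (anyDuplicated(lab_ids))
    abort(paste0("duplicated sample id in ", labels_path, ": ",
                 lab_ids[duplicated(lab_ids)][1]))
  missing_lab <- setdiff(rownames(values), lab_ids)
  if (length(missing_lab) > 0)
    abort(paste0("no label for sample: ", missing_lab[1]))
  extra_lab <- setdiff(lab_ids, rownames(values))
  if (length(extra_lab) > 0)
    abort(paste0("label for unknown sample: ", extra_lab[1]))
  labels <- lab[[2]][match(rownames(values), lab_ids)]
  flowps_dataset(values, labels)
}

#' Quantile-normalize expression values across samples
#'
#' Replaces each sample's values by the rank-wise means across samples
#' (every sample ends up with the same sorted value multiset); ties within
#' a sample receive the mean of the reference values at their tied ranks.
#'
#' @param x a [flowps_dataset] or a numeric samples-by-genes matrix.
#' @param axis normalization axis; only `"per_sample"` (rows) is defined.
#' @return The same type as `x`, normalized. A matrix with fewer than two
#'   samples is returned unchanged with a warning.
#' @examples
#' quantile_normalize(rbind(a = c(1, 2, 3), b = c(4, 5, 6)))
#' @export
quantile_normalize <- function(x, axis = "per_sample") {
  axis <- match.arg(axis, "per_sample")
  if (inherits(x, "flowps_dataset")) {
    out <- x
    out$values <- quantile_normalize(x$values)
    return(out)
  }
  if (!is.matrix(x) || !is.numeric(x)) abort("`x` must be a numeric matrix.")
  if (anyNA(x)) abort("missing values are not allowed.")
  if (nrow(x) < 2) {
    warn("fewer than 2 samples; returning the matrix unchanged.")
    return(x)
  }
  ref <- rowMeans(apply(x, 1, sort))
  out <- x
  for (i in seq_len(nrow(x))) {
    v <- x[i, ]
    row <- numeric(length(v))
    row[order(v)] <- ref
    # tied values share the mean of the reference entries at their ranks
    out[i, ] <- stats::ave(row, v, FUN = mean)
  }
  out
}

#' Equalize responder and non-responder counts by downsampling
#'
#' Keeps the full smaller class and a seeded uniform random subsample of
#' the larger class, preserving original sample order.
#'
#' @param ds a [flowps_dataset] with both classes present.
#' @param seed integer seed making the subsample reproducible.
#' @return A balanced [flowps_dataset] whose samples are a subset of `ds`.
#' @export
equalize_classes <- function(ds, seed = 1L) {
  stopifnot(inherits(ds, "flowps_dataset"))
  pos <- which(ds$labels == 100)
  neg <- which(ds$labels == 0)
  if (length(pos) == 0 || length(neg) == 0)
    abort("both classes must be present to equalize.")
  if (length(pos) == length(neg)) return(ds)
  small <- if (length(pos) < length(neg)) pos else neg
  big <- if (length(pos) < length(neg)) neg else pos
  keep_big <- local_seed(seed, sample(big, length(small)))
  subset_samples(ds, sort(c(small, keep_big)))
}

#' Write and read per-sample prediction tables
#'
#' Tab-separated with a stable column order
#' (`sample_id`, `true_label`, `p_f`, `n_cells`, `classifier`, `config`);
#' round-trips losslessly.
#'
#' @param records a data frame of per-sample predictions.
#' @param path output file path.
#' @export
write_predictions <- function(records, path) {
  records <- as_tibble(records)
  lead <- intersect(c("sample_id", "true_label", "p_f", "n_cells",
                      "classifier", "config"), names(records))
  records <- records[, c(lead, setdiff(names(records), lead)), drop = FALSE]
  readr::write_tsv(records, path)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write an AUC topogram as a dense TSV matrix
#'
#' Rows are labelled by m, columns by k; invalid cells are written as NA.
#'
#' @param topogram a `flowps_topogram` (see [auc_topogram()]).
#' @param path output file path.
#' @export
write_topogram <- function(topogram, path) {
  stopifnot(inherits(topogram, "flowps_topogram"))
  df <- as.data.frame(topogram$auc)
  colnames(df) <- paste0("k", topogram$grid$k_values)
  df <- cbind(m = topogram$grid$m_values, df)
  readr::write_tsv(as_tibble(df), path)
  invisible(path)
}

#' Write a dataset to the delimited formats the readers accept
#'
#' @param ds a [flowps_dataset].
#' @param matrix_path,labels_path output paths (TSV).
#' @export
write_expression_dataset <- function(ds, matrix_path, labels_path) {
  stopifnot(inherits(ds, "flowps_dataset"))
  mat <- cbind(tibble(sample_id = ds$sample_ids),
               as_tibble(ds$values, .name_repair = "minimal"))
  readr::write_tsv(mat, matrix_path)
  readr::write_tsv(tibble(sample_id = ds$sample_ids, label = ds$labels),
                   labels_path)
  invisible(matrix_path)
}
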