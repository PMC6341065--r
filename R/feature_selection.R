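#' Single-gene ROC AUC
#'
#' AUC of one gene's expression as a score for responder status; identical
#' contract to [roc_auc()] (shared implementation).
#'
#' @param values numeric expression values for one gene across samples.
#' @param labels binary labels in `{0, 100}` (or `{0, 1}`).
#' @export
gene_auc <- function(values, labels) roc_auc(values, labels)

# AUC of every gene at once (average-rank formula, vectorized by column).
all_gene_auc <- function(ds) {
  pos <- ds$labels == 100
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    abort("both classes must be present to rank genes.")
  R <- apply(ds$values, 2, rank)
  (colSums(R[pos, , drop = FALSE]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Rank genes by single-gene ROC AUC
#'
#' By default genes are ranked by the oriented AUC `max(AUC, 1 - AUC)` so
#' that strongly down-regulated markers rank as high as up-regulated ones;
#' `rank_by = "raw"` restores ranking on the raw AUC. Ties are broken by
#' gene identifier (ascending) for reproducibility.
#'
#' @param ds a [flowps_dataset] with both classes present.
#' @param rank_by `"oriented"` (default) or `"raw"`.
#' @return A tibble with columns `gene_id`, `auc`, `oriented_auc`, sorted
#'   by the ranking criterion (descending).
#' @export
rank_genes <- function(ds, rank_by = c("oriented", "raw")) {
  rank_by <- match.arg(rank_by)
  auc <- all_gene_auc(ds)
  out <- tibble(gene_id = ds$gene_ids, auc = unname(auc),
                oriented_auc = pmax(auc, 1 - auc))
  key <- if (rank_by == "oriented") out$oriented_auc else out$auc
  out[order(-key, out$gene_id), ]
}

#' Top marker genes by single-gene ROC AUC
#'
#' @inheritParams rank_genes
#' @param n number of genes to keep (default 30, the usual marker-panel
#'   size for cohorts of 50+ samples).
#' @return The first `n` rows of [rank_genes()].
#' @export
top_n_genes <- function(ds, n = 30, rank_by = c("oriented", "raw")) {
  if (n > length(ds$gene_ids))
    abort("n exceeds the number of genes.")
  if (n < 1) abort("n must be a positive integer.")
  slice_head(rank_genes(ds, rank_by), n = n)
}

#' Core marker genes via leave-one-out intersection
#'
#' Removes each sample in turn, ranks genes on the remaining N - 1
#' samples, takes the per-subdataset top `n`, and returns the intersection
#' of all N top-n sets — markers whose selection does not hinge on any
#' single patient.
#'
#' @inheritParams top_n_genes
#' @return Character vector of core gene identifiers, ordered by the
#'   full-dataset ranking.
#' @export
core_genes <- function(ds, n = 30, rank_by = c("oriented", "raw")) {
  rank_by <- match.arg(rank_by)
  N <- nrow(ds$values)
  if (N < 3) abort("core_genes needs at least 3 samples.")
  tops <- lapply(seq_len(N), function(i) {
    sub <- subset_samples(ds, setdiff(seq_len(N), i))
    if (length(unique(sub$labels)) < 2)
      abort(paste0("removing sample ", ds$sample_ids[i],
                   " leaves a single class."))
    top_n_genes(sub, n, rank_by)$gene_id
  })
  core <- Reduce(intersect, tops)
  full <- rank_genes(ds, rank_by)$gene_id
  full[full %in% core]
}

#' Restrict a dataset to a set of genes
#'
#' @param ds a [flowps_dataset].
#' @param gene_ids genes to keep (e.g. from [top_n_genes()] or
#'   [core_genes()]).
#' @export
select_genes <- function(ds, gene_ids) {
  gene_ids <- if (is.data.frame(gene_ids)) gene_ids$gene_id else gene_ids
  missing <- setdiff(gene_ids, ds$gene_ids)
  if (length(missing) > 0)
    abort(paste0("unknown gene id: ", missing[1]))
  keep <- match(gene_ids, ds$gene_ids)
  flowps_dataset(ds$values[, keep, drop = FALSE], ds$labels,
                 sample_ids = ds$sample_ids, gene_ids = ds$gene_ids[keep])
}
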