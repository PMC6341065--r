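#' Inner leave-one-out AUC topogram
#'
#' For every cell (m, k) of the trimming lattice, each training sample is
#' held out in turn, trimmed against the remaining ones and predicted by
#' the cell's SVM; the cell's score is the ROC AUC of those inner
#' predictions against the true labels. A cell is invalid (AUC undefined)
#' as soon as any inner point loses every feature to the m-condition.
#'
#' @param training_ds a [flowps_dataset] with both classes present.
#' @param grid a [trim_grid()].
#' @param config a [flowps_config()].
#' @return An object of class `flowps_topogram`: the grid, an
#'   `|m| x |k|` AUC matrix (NA where invalid), the matching validity
#'   matrix, and the inner prediction matrix.
#' @export
auc_topogram <- function(training_ds, grid, config) {
  stopifnot(inherits(training_ds, "flowps_dataset"),
            inherits(grid, "trim_grid"))
  y01 <- training_ds$labels
  if (length(unique(y01)) < 2)
    abort("the training set must contain both classes.")
  y <- ifelse(y01 == 100, 1, -1)
  res <- cpp_inner_loo_cells(
    training_ds$values, as.numeric(y), grid$m_values, grid$k_values,
    config$C, kernel_code(config), -1, config$coef0, config$degree,
    if (config$prediction_mode == "label") 0L else 1L,
    if (isTRUE(config$scale_features)) 1L else 0L
  )
  nm <- length(grid$m_values); nk <- length(grid$k_values)
  valid <- matrix(res$valid, nm, nk)
  if (!any(valid)) abort("every cell of the grid is invalid.")
  auc <- matrix(NA_real_, nm, nk,
                dimnames = list(paste0("m", grid$m_values),
                                paste0("k", grid$k_values)))
  for (cell in which(res$valid))
    auc[cell] <- roc_auc(res$pred[cell, ], y01)
  structure(list(grid = grid, auc = auc, valid = valid,
                 inner_pred = res$pred, n_inner = length(y01)),
            class = "flowps_topogram")
}

#' @export
print.flowps_topogram <- function(x, ...) {
  cat("<flowps_topogram> ", length(x$grid$m_values), " m x ",
      length(x$grid$k_values), " k cells; max AUC = ",
      format(max(x$auc, na.rm = TRUE), digits = 3), "\n", sep = "")
  invisible(x)
}

#' @describeIn auc_topogram topogram as a tidy tibble of (m, k, auc, valid).
#' @param x a `flowps_topogram`.
#' @param ... unused.
#' @export
tidy.flowps_topogram <- function(x, ...) {
  g <- expand.grid(m = x$grid$m_values, k = x$grid$k_values,
                   KEEP.OUT.ATTRS = FALSE)
  tibble(m = g$m, k = g$k, auc = as.vector(x$auc),
         valid = as.vector(x$valid))
}

#' Prediction-accountable set of trimming cells
#'
#' All valid cells whose topogram AUC reaches the threshold
#' `theta = p * max(AUC)`. Non-empty by construction (the argmax cell
#' always qualifies); lowering p can only add cells.
#'
#' @param topogram a `flowps_topogram` from [auc_topogram()].
#' @param p confidence threshold in (0, 1].
#' @return A tibble of class `accountable_set` with columns `m`, `k`,
#'   `auc`, and attributes `theta` and `p`.
#' @export
accountable_set <- function(topogram, p) {
  stopifnot(inherits(topogram, "flowps_topogram"))
  if (p <= 0 || p > 1) abort("p must lie in (0, 1].")
  max_auc <- max(topogram$auc, na.rm = TRUE)
  theta <- p * max_auc
  # epsilon guards the boundary: p * max(AUC) must not exclude a cell whose
  # AUC equals the threshold up to floating-point rounding
  keep <- which(topogram$valid & !is.na(topogram$auc) &
                  topogram$auc >= theta - 1e-9)
  cells <- tidy(topogram)[keep, c("m", "k", "auc")]
  out <- arrange(cells, .data$m, .data$k)
  attr(out, "theta") <- theta
  attr(out, "p") <- p
  class(out) <- c("accountable_set", class(out))
  out
}

#' Floating-window prediction for one held-out sample
#'
#' Builds the AUC topogram on the remaining N - 1 samples, forms the
#' prediction-accountable set at confidence `config$p`, trims the data for
#' the held-out sample at each accountable (m, k) and averages the per-cell
#' SVM predictions: `P_F = mean(P(m, k))` over the set. Cells whose trim is
#' invalid for the held-out sample are skipped and `n_cells` counts the
#' cells actually used.
#'
#' @param ds a [flowps_dataset].
#' @param validation_index sample to hold out and predict.
#' @param config a [flowps_config()].
#' @param grid optional [trim_grid()]; defaults to the per-sample lattice
#'   (k from `k_min` to N - 1, m from 0 to the auto cap).
#' @return One-row tibble: `sample_id`, `true_label`, `p_f`, `n_cells`,
#'   `theta`, `config`.
#' @export
flowps_predict_one <- function(ds, validation_index, config = flowps_config(),
                               grid = NULL) {
  stopifnot(inherits(ds, "flowps_dataset"))
  N <- nrow(ds$values)
  tr_idx <- setdiff(seq_len(N), validation_index)
  training_ds <- subset_samples(ds, tr_idx)
  if (length(unique(training_ds$labels)) < 2)
    abort("removing this sample leaves a single-class training set.")
  grid <- grid %||% default_trim_grid(ds, validation_index, config)
  topo <- auc_topogram(training_ds, grid, config)
  cells <- accountable_set(topo, config$p)
  preds <- numeric(0)
  for (r in seq_len(nrow(cells))) {
    tset <- trim(ds, validation_index, cells$m[r], cells$k[r],
                 scale_features = config$scale_features)
    if (!tset$valid) next
    preds <- c(preds, svm_cell_predict(tset, ds, validation_index, config))
  }
  if (length(preds) == 0)
    abort("no accountable cell yields a valid trim for this sample.")
  tibble(sample_id = ds$sample_ids[validation_index],
         true_label = ds$labels[validation_index],
         p_f = mean(preds), n_cells = length(preds),
         theta = attr(cells, "theta"), config = config_digest(config))
}

#' Leave-one-out evaluation of the floating-window classifier
#'
#' Runs [flowps_predict_one()] for every sample (each fold is independent,
#' so sample order cannot change the result) and summarizes the P_F vector
#' against the true labels with the full metrics panel.
#'
#' @inheritParams flowps_predict_one
#' @return An object of class `flowps_loo`: `predictions` (per-sample
#'   tibble), `metrics` (a [metrics_report()] row) and `config`. `tidy()`
#'   returns the predictions, `glance()` the metrics.
#' @examples
#' \donttest{
#' ds <- make_global_linear(n_samples = 24, n_features = 4, effect_size = 4)
#' fit <- flowps_loo(ds, flowps_config(p = 0.9))
#' glance(fit)
#' }
#' @export
flowps_loo <- function(ds, config = flowps_config(), grid = NULL) {
  stopifnot(inherits(ds, "flowps_dataset"))
  N <- nrow(ds$values)
  if (N < 4 || sum(ds$labels == 100) < 2 || sum(ds$labels == 0) < 2)
    abort("need N >= 4 with at least two samples per class.")
  preds <- purrr::map(seq_len(N),
                      function(i) flowps_predict_one(ds, i, config, grid))
  predictions <- bind_rows(preds)
  structure(
    list(predictions = predictions,
         metrics = metrics_report(predictions$p_f, predictions$true_label),
         config = config, classifier = "flowps"),
    class = "flowps_loo"
  )
}

#' @export
print.flowps_loo <- function(x, ...) {
  m <- x$metrics
  cat("<", x$classifier, " LOO> N=", m$n, "  AUC=", format(m$auc, digits = 3),
      "  FDR=", format(m$fdr, digits = 3), "  ACC=", format(m$acc, digits = 3),
      "  (", config_digest(x$config), ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.flowps_loo <- function(x, ...) x$predictions

#' @export
glance.flowps_loo <- function(x, ...) {
  mutate(as_tibble(x$metrics), classifier = x$classifier,
         config = config_digest(x$config))
}
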