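#' Classical SVM leave-one-out baseline
#'
#' Plain soft-margin SVM without data trimming: each sample is predicted
#' from a model trained on the other N - 1 samples with all features —
#' exactly the (m = 0, k = N - 1) corner of the trimming lattice.
#'
#' @inheritParams flowps_loo
#' @return A `flowps_loo`-style object (`classifier = "classical_svm"`).
#' @export
classical_svm_loo <- function(ds, config = flowps_config()) {
  stopifnot(inherits(ds, "flowps_dataset"))
  N <- nrow(ds$values)
  if (N < 4 || sum(ds$labels == 100) < 2 || sum(ds$labels == 0) < 2)
    abort("need N >= 4 with at least two samples per class.")
  p_f <- vapply(seq_len(N), function(i) {
    tset <- trim(ds, i, m = 0, k = N - 1,
                 scale_features = config$scale_features)
    svm_cell_predict(tset, ds, i, config)
  }, numeric(1))
  predictions <- tibble(sample_id = ds$sample_ids, true_label = ds$labels,
                        p_f = p_f, n_cells = 1L, theta = NA_real_,
                        config = config_digest(config))
  structure(
    list(predictions = predictions,
         metrics = metrics_report(p_f, ds$labels),
         config = config, classifier = "classical_svm"),
    class = "flowps_loo"
  )
}

#' PCA-assisted SVM leave-one-out baseline
#'
#' For every outer held-out sample, principal components are fitted on the
#' N - 1 training samples (centered on training means, covariance-based,
#' no variance scaling). For each candidate number of components, an inner
#' leave-one-out AUC over the training samples is computed from SVMs on
#' the truncated scores; the candidate maximizing the inner AUC (smallest
#' on ties) is then used to predict the held-out sample projected with the
#' training loadings. All loadings come from training folds only — there
#' is no leakage from the held-out sample.
#'
#' @inheritParams flowps_loo
#' @param n_pc_candidates integer vector of PC counts to try; defaults to
#'   `1..min(10, N - 2, s)`. Candidates exceeding the training-fold rank
#'   are skipped with a warning.
#' @return A `flowps_loo`-style object (`classifier = "pca_svm"`) whose
#'   predictions carry the chosen PC count per sample.
#' @export
pca_svm_loo <- function(ds, config = flowps_config(), n_pc_candidates = NULL) {
  stopifnot(inherits(ds, "flowps_dataset"))
  N <- nrow(ds$values); s <- ncol(ds$values)
  if (N < 4 || sum(ds$labels == 100) < 2 || sum(ds$labels == 0) < 2)
    abort("need N >= 4 with at least two samples per class.")
  n_pc_candidates <- n_pc_candidates %||% seq_len(min(10, N - 2, s))

  one <- function(i) {
    tr_idx <- setdiff(seq_len(N), i)
    Xtr <- ds$values[tr_idx, , drop = FALSE]
    ytr <- ds$labels[tr_idx]
    ctr <- colMeans(Xtr)
    pc <- prcomp(Xtr, center = ctr, scale. = FALSE)
    rank_tr <- sum(pc$sdev > pc$sdev[1] * 1e-8)
    cand <- n_pc_candidates[n_pc_candidates <= rank_tr]
    if (length(cand) < length(n_pc_candidates))
      warn("PC candidates exceeding the training-fold rank were skipped.")
    if (length(cand) == 0) abort("no PC candidate is within the data rank.")
    scores_tr <- pc$x  # training scores = centered Xtr %*% rotation
    inner_auc <- vapply(cand, function(q) {
      Tq <- scores_tr[, seq_len(q), drop = FALSE]
      inner <- vapply(seq_len(nrow(Tq)), function(r) {
        lab <- ytr[-r]
        if (length(unique(lab)) == 1)
          return(if (config$prediction_mode == "label") lab[1]
                 else if (lab[1] == 100) 1 else -1)
        dec <- svm_decision(Tq[-r, , drop = FALSE], lab,
                            Tq[r, , drop = FALSE], config)
        if (config$prediction_mode == "label") (if (dec > 0) 100 else 0)
        else dec
      }, numeric(1))
      roc_auc(inner, ytr)
    }, numeric(1))
    q_best <- cand[which.max(inner_auc)]  # smallest index wins ties
    Tq <- scores_tr[, seq_len(q_best), drop = FALSE]
    x_proj <- (ds$values[i, ] - ctr) %*% pc$rotation[, seq_len(q_best), drop = FALSE]
    dec <- svm_decision(Tq, ytr, x_proj, config)
    p_f <- if (config$prediction_mode == "label") (if (dec > 0) 100 else 0) else dec
    tibble(sample_id = ds$sample_ids[i], true_label = ds$labels[i],
           p_f = p_f, n_cells = 1L, n_pc = q_best,
           config = config_digest(config))
  }

  predictions <- bind_rows(lapply(seq_len(N), one))
  structure(
    list(predictions = predictions,
         metrics = metrics_report(predictions$p_f, predictions$true_label),
         config = config, classifier = "pca_svm"),
    class = "flowps_loo"
  )
}
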