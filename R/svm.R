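# R surface over the compiled SMO solver.

# Decision values of a soft-margin SVM fit on (Xtr, labels01) for rows of
# Xte.  labels01 on the 0/100 (or 0/1) scale; decision > 0 means responder.
svm_decision <- function(Xtr, labels01, Xte, config) {
  y <- ifelse(canonical_labels(labels01, nrow(Xtr)) == 100, 1, -1)
  cpp_svm_fit_predict(Xtr, as.numeric(y), Xte, config$C, kernel_code(config),
                      -1, config$coef0, config$degree)
}

#' SVM prediction for one trimmed cell
#'
#' Fits a soft-margin SVM (linear or polynomial kernel, cost C, otherwise
#' library-default settings) on the masked features of the selected
#' neighbors and predicts the validation sample. When every neighbor
#' carries the same label, that class is returned without fitting. With
#' `prediction_mode = "label"` the result is the predicted class on the
#' 0/100 scale; with `"decision"` it is the signed decision value (the
#' single-class shortcut then returns -1 or +1).
#'
#' @param trimmed a valid `trimmed_set` from [trim()].
#' @param ds the [flowps_dataset] the trim was taken from.
#' @param validation_index index of the sample to predict.
#' @param config a [flowps_config()].
#' @return A single numeric prediction.
#' @export
svm_cell_predict <- function(trimmed, ds, validation_index, config) {
  stopifnot(inherits(trimmed, "trimmed_set"))
  if (!trimmed$valid) abort("cannot predict from an invalid trimmed set.")
  labels <- ds$labels[trimmed$neighbor_indices]
  label_mode <- config$prediction_mode == "label"
  if (length(unique(labels)) == 1) {
    return(if (label_mode) labels[1] else if (labels[1] == 100) 1 else -1)
  }
  Xtr <- ds$values[trimmed$neighbor_indices, trimmed$feature_mask, drop = FALSE]
  Xte <- ds$values[validation_index, trimmed$feature_mask, drop = FALSE]
  dec <- svm_decision(Xtr, labels, matrix(Xte, nrow = 1), config)
  if (label_mode) (if (dec > 0) 100 else 0) else dec
}
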