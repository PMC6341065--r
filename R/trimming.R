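#' Per-feature m-condition mask
#'
#' A feature is kept for a validation point when, along that feature's
#' axis, at least `m` training projections lie strictly below the
#' validation value and at least `m` strictly above it. Training values
#' exactly equal to the validation value count as neither. `m = 0` keeps
#' every feature.
#'
#' @param validation_point numeric vector of length s (the held-out
#'   sample's expression profile).
#' @param training numeric training matrix, samples in rows.
#' @param m non-negative integer flanking requirement.
#' @return Logical vector of length s.
#' @examples
#' feature_mask(5, matrix(c(1, 2, 3, 6, 7)), m = 2)  # TRUE
#' feature_mask(5, matrix(c(1, 2, 3, 6, 7)), m = 3)  # FALSE: only 2 above
#' @export
feature_mask <- function(validation_point, training, m) {
  stopifnot(m >= 0)
  max_valid_m(validation_point, training) >= m
}

#' Per-feature flanking cap
#'
#' For each feature, the largest m at which the m-condition still holds:
#' `min(#training values strictly below, #strictly above)` the validation
#' value. `feature_mask(v, X, m)` equals `max_valid_m(v, X) >= m` for
#' every m.
#'
#' @inheritParams feature_mask
#' @return Integer vector of length s.
#' @export
max_valid_m <- function(validation_point, training) {
  training <- as.matrix(training)
  if (length(validation_point) != ncol(training))
    abort("validation point length must match the training feature count.")
  tt <- t(training)
  below <- rowSums(tt < validation_point)
  above <- rowSums(tt > validation_point)
  as.integer(pmin(below, above))
}

#' k nearest training samples in a masked feature space
#'
#' Euclidean distances are computed over the masked features only, on the
#' data's given scale. Distance ties are broken by ascending training
#' index; `k` larger than the available training set returns everything.
#'
#' @inheritParams feature_mask
#' @param mask logical feature mask with at least one TRUE entry.
#' @param k number of neighbors (>= 1).
#' @param scale if TRUE, z-score each masked feature by its training-set
#'   standard deviation before computing distances (zero-variance features
#'   then contribute nothing).
#' @return Integer vector of training-row indices, closest first.
#' @export
knn_select <- function(validation_point, training, mask, k, scale = FALSE) {
  training <- as.matrix(training)
  if (!any(mask)) abort("all features are masked out; no distance is defined.")
  if (k < 1) abort("k must be >= 1.")
  diffs <- t(training[, mask, drop = FALSE]) - validation_point[mask]
  if (isTRUE(scale)) {
    sds <- apply(training[, mask, drop = FALSE], 2, stats::sd)
    w <- ifelse(sds > 0, 1 / sds, 0)
    diffs <- diffs * w
  }
  d2 <- colSums(diffs^2)
  ord <- order(d2, seq_along(d2))
  ord[seq_len(min(k, length(ord)))]
}

#' Trim the training data for one validation sample
#'
#' Composes the m-condition feature mask (computed against all N - 1
#' training samples) with k-nearest-neighbor selection in the masked
#' space: the "floating window" that individualizes the training set for
#' each held-out sample. `m = 0, k = N - 1` reproduces the classical-SVM
#' setting (all features, all training samples).
#'
#' @param ds a [flowps_dataset].
#' @param validation_index sample index in `1..N` to hold out.
#' @param m,k trimming parameters.
#' @param scale_features z-score distances by training-fold sd (see
#'   [knn_select()]).
#' @return An object of class `trimmed_set`: `m`, `k`, `feature_mask`,
#'   `neighbor_indices` (dataset row indices, closest first) and `valid`
#'   (FALSE when no feature survives the m-condition).
#' @export
trim <- function(ds, validation_index, m, k, scale_features = FALSE) {
  stopifnot(inherits(ds, "flowps_dataset"))
  N <- nrow(ds$values)
  if (validation_index < 1 || validation_index > N)
    abort("validation_index out of range.")
  tr_idx <- setdiff(seq_len(N), validation_index)
  v <- ds$values[validation_index, ]
  training <- ds$values[tr_idx, , drop = FALSE]
  mask <- feature_mask(v, training, m)
  if (!any(mask)) {
    return(structure(list(m = m, k = k, feature_mask = mask,
                          neighbor_indices = integer(0), valid = FALSE),
                     class = "trimmed_set"))
  }
  nn <- knn_select(v, training, mask, k, scale = scale_features)
  structure(list(m = m, k = k, feature_mask = mask,
                 neighbor_indices = tr_idx[nn], valid = TRUE),
            class = "trimmed_set")
}

#' @export
print.trimmed_set <- function(x, ...) {
  cat("<trimmed_set> m=", x$m, " k=", x$k, " | ", sum(x$feature_mask),
      " features, ", length(x$neighbor_indices), " neighbors",
      if (!x$valid) " [invalid]", "\n", sep = "")
  invisible(x)
}

#' Construct a (m, k) trimming lattice
#'
#' @param m_values ascending non-negative integers.
#' @param k_values ascending integers, each >= 1.
#' @return An object of class `trim_grid`.
#' @export
trim_grid <- function(m_values, k_values) {
  m_values <- as.integer(m_values); k_values <- as.integer(k_values)
  if (length(m_values) == 0 || length(k_values) == 0)
    abort("the grid must be non-empty.")
  if (any(m_values < 0) || is.unsorted(m_values, strictly = TRUE))
    abort("m_values must be strictly ascending non-negative integers.")
  if (any(k_values < 1) || is.unsorted(k_values, strictly = TRUE))
    abort("k_values must be strictly ascending integers >= 1.")
  structure(list(m_values = m_values, k_values = k_values),
            class = "trim_grid")
}

# Default lattice for one validation point of an N-sample dataset:
# k from k_min (or the small-N fallback) to N - 1; m from 0 to the largest
# m at which the validation point keeps a feature, capped at (N-1)/2.
default_trim_grid <- function(ds, validation_index, config) {
  N <- nrow(ds$values)
  k_hi <- N - 1
  k_lo <- if (k_hi < config$k_min) max(3, k_hi - 10) else config$k_min
  if (k_lo > k_hi) k_lo <- k_hi
  if (identical(config$m_max, "auto")) {
    tr_idx <- setdiff(seq_len(N), validation_index)
    caps <- max_valid_m(ds$values[validation_index, ],
                        ds$values[tr_idx, , drop = FALSE])
    m_hi <- min(max(caps), floor((N - 1) / 2))
  } else {
    m_hi <- config$m_max
  }
  trim_grid(0:m_hi, k_lo:k_hi)
}
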