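#' Classifier configuration
#'
#' Collects the tunable settings of the floating-window SVM classifier and
#' its baselines.
#'
#' @param kernel SVM kernel: `"linear"` or `"polynomial"` (degree 3,
#'   `coef0 = 0`, `gamma = 1/n_features` over the surviving features,
#'   mirroring the defaults of the usual libsvm wrappers).
#' @param C positive soft-margin cost.
#' @param p confidence threshold in (0, 1]: the prediction-accountable set
#'   keeps every (m, k) cell whose internally cross-validated AUC reaches
#'   `p * max(AUC)`.
#' @param k_min smallest window size in the k grid (default 20; datasets
#'   with fewer than 21 samples fall back to `max(3, N - 11) .. N - 1`).
#' @param m_max upper bound of the m grid, or `"auto"`: the largest m at
#'   which at least one feature survives for the validation point, capped
#'   at `floor((N - 1) / 2)`.
#' @param seed integer seed for any randomized step (class equalization,
#'   synthetic data).
#' @param prediction_mode `"label"`: each per-cell SVM votes 0 or 100 and
#'   the final prediction is the mean vote (the bounded 0-100 scale);
#'   `"decision"`: signed SVM decision values are averaged instead.
#' @param scale_features if TRUE, the k-window distance z-scores each
#'   surviving feature by its training-fold standard deviation (training
#'   statistics only; the SVM still sees the raw values). Default FALSE:
#'   distances on the data's given scale, as quantile-normalized expression
#'   is fed to the SVM unscaled.
#'
#' @return An object of class `flowps_config`.
#' @examples
#' flowps_config(kernel = "linear", C = 1, p = 0.9)
#' @export
flowps_config <- function(kernel = c("linear", "polynomial"), C = 1,
                          p = 0.95, k_min = 20L, m_max = "auto",
                          seed = 1L,
                          prediction_mode = c("label", "decision"),
                          scale_features = FALSE) {
  kernel <- match.arg(kernel)
  prediction_mode <- match.arg(prediction_mode)
  if (!is.numeric(C) || length(C) != 1 || C <= 0) abort("C must be > 0.")
  if (!is.numeric(p) || length(p) != 1 || p <= 0 || p > 1)
    abort("p must lie in (0, 1].")
  if (!is.numeric(k_min) || k_min < 1) abort("k_min must be >= 1.")
  if (!identical(m_max, "auto") && (!is.numeric(m_max) || m_max < 0))
    abort("m_max must be a non-negative integer or \"auto\".")
  structure(
    list(kernel = kernel, C = C, p = p, k_min = as.integer(k_min),
         m_max = m_max, seed = as.integer(seed),
         prediction_mode = prediction_mode,
         scale_features = isTRUE(scale_features),
         degree = 3L, coef0 = 0),
    class = "flowps_config"
  )
}

#' @export
print.flowps_config <- function(x, ...) {
  cat("<flowps_config> ", config_digest(x), "\n", sep = "")
  invisible(x)
}

# Short human-readable digest carried along with every prediction record.
config_digest <- function(config) {
  paste0(config$kernel, "-C", format(config$C), "-p", format(config$p),
         "-kmin", config$k_min, "-m",
         if (identical(config$m_max, "auto")) "auto" else config$m_max,
         "-", config$prediction_mode,
         if (isTRUE(config$scale_features)) "-zdist" else "")
}

kernel_code <- function(config) if (config$kernel == "linear") 0L else 1L
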