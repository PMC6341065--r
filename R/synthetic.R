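# Seeded generators for the three data regimes the method's behaviour is
# argued on: globally separable data, locally-ordered / globally-disordered
# data, and expression-like matrices with a small informative panel.
# All are pure functions of their arguments (seed included) and produce
# exactly class-balanced datasets (the equalized regime).

new_synth_dataset <- function(values, labels, informative) {
  n <- nrow(values); s <- ncol(values)
  ds <- flowps_dataset(values, labels,
                       sample_ids = sprintf("s%03d", seq_len(n)),
                       gene_ids = sprintf("g%04d", seq_len(s)))
  attr(ds, "informative_genes") <- ds$gene_ids[informative]
  ds
}

check_spec <- function(n_samples, n_features, n_informative) {
  if (n_samples < 4 || n_samples %% 2 != 0)
    abort("n_samples must be an even integer >= 4.")
  if (n_features < 1) abort("n_features must be positive.")
  if (n_informative < 1 || n_informative > n_features)
    abort("n_informative must lie in 1..n_features.")
}

#' Globally separable Gaussian classes (positive control)
#'
#' Two isotropic Gaussian classes separated by `effect_size` along each of
#' `n_informative` randomly placed coordinates; the remaining features are
#' pure noise with the same spread. Labels alternate so the class sequence
#' carries no information.
#'
#' @param n_samples even number of samples (balanced classes).
#' @param n_features total feature count.
#' @param n_informative number of separating coordinates.
#' @param effect_size class-mean separation, in units of `noise_sd`.
#' @param noise_sd isotropic standard deviation.
#' @param seed integer seed; identical seeds give identical datasets.
#' @return A [flowps_dataset] with attribute `informative_genes`.
#' @export
make_global_linear <- function(n_samples = 40, n_features = 10,
                               n_informative = 3, effect_size = 2,
                               noise_sd = 1, seed = 1L) {
  check_spec(n_samples, n_features, n_informative)
  if (noise_sd <= 0) abort("noise_sd must be positive.")
  local_seed(seed, {
    labels <- rep(c(100L, 0L), length.out = n_samples)
    values <- matrix(rnorm(n_samples * n_features, sd = noise_sd),
                     n_samples, n_features)
    inf <- sample(n_features, n_informative)
    shift <- ifelse(labels == 100, effect_size / 2, -effect_size / 2)
    values[, inf] <- values[, inf] + shift
    new_synth_dataset(values, labels, inf)
  })
}

#' Checkerboard clusters: local order without global order
#'
#' Tight Gaussian clusters centered on a 2-D grid whose class alternates
#' between adjacent cells, so nearby samples share a class while no global
#' linear separator exists. Any features beyond the first two are pure
#' noise. Each class's samples are spread round-robin over its cells.
#'
#' @inheritParams make_global_linear
#' @param n_informative must be 2 (the locally ordered plane).
#' @param grid_dim cells per side; a length-2 vector gives a rectangular
#'   grid (e.g. `c(1, 2)` degenerates to two separable clusters).
#' @param cluster_sd cluster standard deviation as a fraction of the unit
#'   cell width.
#' @param noise_sd standard deviation of the extra noise features.
#' @export
make_checkerboard <- function(n_samples = 64, n_features = 2,
                              n_informative = 2, grid_dim = 4,
                              cluster_sd = 0.1, noise_sd = 1, seed = 1L) {
  if (n_informative != 2) abort("the checkerboard plane needs n_informative = 2.")
  if (n_features < 2) abort("n_features must be >= 2.")
  check_spec(n_samples, n_features, n_informative)
  if (length(grid_dim) == 1) grid_dim <- c(grid_dim, grid_dim)
  cells <- expand.grid(a = seq_len(grid_dim[1]) - 1,
                       b = seq_len(grid_dim[2]) - 1)
  cells$class <- ifelse((cells$a + cells$b) %% 2 == 0, 100L, 0L)
  if (length(unique(cells$class)) < 2)
    abort("the grid must contain cells of both parities.")
  local_seed(seed, {
    labels <- rep(c(100L, 0L), length.out = n_samples)
    values <- matrix(0, n_samples, n_features)
    for (cl in c(100L, 0L)) {
      idx <- which(labels == cl)
      own <- cells[cells$class == cl, , drop = FALSE]
      pick <- own[rep(seq_len(nrow(own)), length.out = length(idx)), ]
      values[idx, 1] <- pick$a + 0.5 + rnorm(length(idx), sd = cluster_sd)
      values[idx, 2] <- pick$b + 0.5 + rnorm(length(idx), sd = cluster_sd)
    }
    if (n_features > 2)
      values[, 3:n_features] <- rnorm(n_samples * (n_features - 2),
                                      sd = noise_sd)
    new_synth_dataset(values, labels, 1:2)
  })
}

#' Expression-like matrix with a small informative gene panel
#'
#' Log-scale values with gene-specific baselines and sample-specific
#' offsets (so quantile normalization has work to do); `n_informative`
#' randomly placed genes are shifted by `effect_size` in responders.
#'
#' @inheritParams make_global_linear
#' @param effect_size responder shift of the informative genes, in log
#'   units.
#' @param noise_sd residual per-measurement noise (log units).
#' @param sample_offset_sd spread of the sample-specific baselines.
#' @export
make_expression_like <- function(n_samples = 60, n_features = 2000,
                                 n_informative = 20, effect_size = 1.5,
                                 noise_sd = 1, sample_offset_sd = 0.3,
                                 seed = 1L) {
  check_spec(n_samples, n_features, n_informative)
  local_seed(seed, {
    labels <- rep(c(100L, 0L), length.out = n_samples)
    mu <- runif(n_features, 2, 12)
    offset <- rnorm(n_samples, sd = sample_offset_sd)
    values <- outer(offset, mu, "+") +
      matrix(rnorm(n_samples * n_features, sd = noise_sd),
             n_samples, n_features)
    inf <- sample(n_features, n_informative)
    values[labels == 100, inf] <- values[labels == 100, inf] + effect_size
    new_synth_dataset(values, labels, inf)
  })
}
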