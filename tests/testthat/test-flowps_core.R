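cfg_lin <- flowps_config(kernel = "linear", C = 1, p = 0.9)

test_that("the topogram fast path equals the R composition of trim + SVM", {
  ds <- make_global_linear(n_samples = 10, n_features = 3, effect_size = 2,
                           seed = 6)
  grid <- trim_grid(0:2, c(3, 5, 7, 9))
  topo <- auc_topogram(ds, grid, cfg_lin)
  nm <- length(grid$m_values)
  for (i in seq_len(nrow(ds$values))) {
    tr_idx <- setdiff(seq_len(nrow(ds$values)), i)
    for (mi in seq_along(grid$m_values)) {
      for (ki in seq_along(grid$k_values)) {
        tset <- trim(ds, i, grid$m_values[mi], grid$k_values[ki])
        # trim() here is against the full dataset minus i, which is exactly
        # the inner fold the topogram used
        if (!tset$valid) {
          expect_true(is.na(topo$inner_pred[mi + nm * (ki - 1), i]))
        } else {
          ref <- svm_cell_predict(tset, ds, i, cfg_lin)
          expect_equal(topo$inner_pred[mi + nm * (ki - 1), i], ref,
                       tolerance = 1e-9)
        }
      }
    }
  }
})

test_that("the fast path matches the R composition under scaled distances too", {
  ds <- make_global_linear(n_samples = 10, n_features = 3, effect_size = 2,
                           seed = 6)
  # stretch one feature so scaling actually changes neighbor order
  ds$values[, 2] <- ds$values[, 2] * 50
  cfg <- flowps_config(kernel = "linear", C = 1, p = 0.9,
                       scale_features = TRUE)
  grid <- trim_grid(0:1, c(4, 7, 9))
  topo <- auc_topogram(ds, grid, cfg)
  nm <- length(grid$m_values)
  for (i in seq_len(nrow(ds$values))) {
    for (mi in seq_along(grid$m_values)) {
      for (ki in seq_along(grid$k_values)) {
        tset <- trim(ds, i, grid$m_values[mi], grid$k_values[ki],
                     scale_features = TRUE)
        if (!tset$valid) {
          expect_true(is.na(topo$inner_pred[mi + nm * (ki - 1), i]))
        } else {
          ref <- svm_cell_predict(tset, ds, i, cfg)
          expect_equal(topo$inner_pred[mi + nm * (ki - 1), i], ref,
                       tolerance = 1e-9)
        }
      }
    }
  }
})

test_that("degenerate topogram corners behave as stated", {
  ds <- make_global_linear(n_samples = 16, n_features = 4, effect_size = 6,
                           seed = 9)
  N <- nrow(ds$values)
  # single-cell corner grid: plain-SVM inner LOO
  topo <- auc_topogram(ds, trim_grid(0, N - 1), cfg_lin)
  inner <- vapply(seq_len(N), function(i) {
    svm_cell_predict(trim(ds, i, 0, N - 1), ds, i, cfg_lin)
  }, numeric(1))
  expect_equal(unname(topo$auc[1, 1]), roc_auc(inner, ds$labels))
  # perfectly separable training data has corner AUC 1
  expect_equal(unname(topo$auc[1, 1]), 1)
  # an all-invalid grid errors
  expect_error(auc_topogram(ds, trim_grid(N, N - 1), cfg_lin), "invalid")
})

test_that("permuted labels drive all valid topogram cells toward chance", {
  ds <- make_global_linear(n_samples = 40, n_features = 5, effect_size = 6,
                           seed = 12)
  shuffled <- flowps_dataset(ds$values,
                             flowps:::local_seed(99, sample(ds$labels)))
  topo <- auc_topogram(shuffled, trim_grid(c(0, 2), c(20, 30, 39)), cfg_lin)
  expect_true(all(abs(topo$auc[!is.na(topo$auc)] - 0.5) <= 0.2))
})

test_that("accountable set applies theta = p * max(AUC) and nests in p", {
  topo <- structure(list(
    grid = trim_grid(0:1, 5:7),
    auc = matrix(c(0.80, 0.72, 0.70, 0.60, 0.75, NA), 2, 3),
    valid = matrix(c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE), 2, 3),
    n_inner = 10), class = "flowps_topogram")
  s90 <- accountable_set(topo, 0.9)
  expect_equal(attr(s90, "theta"), 0.72)
  expect_equal(nrow(s90), 3)  # 0.80, 0.72, 0.75 qualify
  expect_true(all(s90$auc >= 0.72))
  # p = 1 keeps exactly the argmax cell
  s100 <- accountable_set(topo, 1)
  expect_equal(nrow(s100), 1)
  expect_equal(s100$auc, 0.8)
  # the invalid cell can never enter
  expect_false(any(is.na(s90$auc)))
  # monotone nesting over a ladder of p values
  sizes <- vapply(c(1, 0.95, 0.9, 0.8, 0.5), function(p) {
    nrow(accountable_set(topo, p))
  }, numeric(1))
  expect_true(all(diff(sizes) >= 0))
  # an all-equal topogram keeps every valid cell
  topo$auc[!is.na(topo$auc)] <- 0.6
  expect_equal(nrow(accountable_set(topo, 0.99)), 5)
})

test_that("flowps_predict_one averages per-cell votes on the 0-100 scale", {
  ds <- make_global_linear(n_samples = 14, n_features = 4, effect_size = 5,
                           seed = 20)
  N <- nrow(ds$values)
  # forced single-cell corner: P_F equals the plain SVM prediction
  rec <- flowps_predict_one(ds, 1, cfg_lin, grid = trim_grid(0, N - 1))
  plain <- svm_cell_predict(trim(ds, 1, 0, N - 1), ds, 1, cfg_lin)
  expect_equal(rec$p_f, plain)
  expect_equal(rec$n_cells, 1L)

  # label mode: P_F * |S| / 100 counts the responder votes (an integer)
  rec2 <- flowps_predict_one(ds, 2, cfg_lin)
  votes <- rec2$p_f * rec2$n_cells / 100
  expect_equal(votes, round(votes))
  expect_gte(rec2$p_f, 0); expect_lte(rec2$p_f, 100)
})

test_that("leave-one-out evaluation separates separable data and is deterministic", {
  ds <- make_global_linear(n_samples = 40, n_features = 5, n_informative = 3,
                           effect_size = 6, noise_sd = 1, seed = 30)
  fit <- flowps_loo(ds, cfg_lin)
  expect_equal(fit$metrics$auc, 1)
  expect_true(all(fit$predictions$p_f >= 0 & fit$predictions$p_f <= 100))
  fit2 <- flowps_loo(ds, cfg_lin)
  expect_identical(fit$predictions$p_f, fit2$predictions$p_f)

  # permutation null stays near chance
  shuffled <- flowps_dataset(ds$values,
                             flowps:::local_seed(77, sample(ds$labels)))
  null_fit <- flowps_loo(shuffled, cfg_lin)
  expect_gte(null_fit$metrics$auc, 0.3)
  expect_lte(null_fit$metrics$auc, 0.7)
})

test_that("tidy, glance and autoplot expose the results", {
  ds <- make_global_linear(n_samples = 12, n_features = 3, effect_size = 5,
                           seed = 40)
  fit <- flowps_loo(ds, cfg_lin)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(tidy(fit)), 12)
  g <- glance(fit)
  expect_equal(g$classifier, "flowps")
  expect_true(all(c("auc", "fdr", "sn", "sp", "acc", "mcc", "tau") %in% names(g)))
  expect_s3_class(autoplot(fit), "ggplot")
  topo <- auc_topogram(ds, trim_grid(0:1, c(5, 8, 11)), cfg_lin)
  expect_s3_class(autoplot(topo, p = 0.9), "ggplot")
  expect_equal(nrow(tidy(topo)), 6)
})
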