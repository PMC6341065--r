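test_that("the m-condition counts strictly flanking training projections", {
  train <- matrix(c(1, 2, 3, 6, 7))
  for (m in 0:2) expect_true(feature_mask(5, train, m))
  for (m in 3:5) expect_false(feature_mask(5, train, m))
  expect_equal(max_valid_m(5, train), 2L)  # min(3 below, 2 above)

  # m = 0 keeps everything, whatever the geometry
  expect_true(all(feature_mask(c(-99, 99), matrix(rnorm(10), 5, 2), 0)))

  # validation outside the training cloud survives only m = 0
  expect_equal(max_valid_m(10, train), 0L)
  # values equal to the validation projection count as neither side
  expect_equal(max_valid_m(4, matrix(rep(4, 6))), 0L)
})

test_that("five flanking points on both sides pass exactly for m <= 5", {
  train <- matrix(c(seq(0.1, 0.5, 0.1), seq(1.5, 1.9, 0.1)))  # 5 below, 5 above
  v <- 1
  expect_equal(max_valid_m(v, train), 5L)
  for (m in 0:5) expect_true(feature_mask(v, train, m))
  expect_false(feature_mask(v, train, 6))
})

test_that("feature_mask agrees with the brute-force double loop", {
  set.seed(202)
  for (i in 1:200) {
    n <- sample(3:20, 1); s <- sample(1:8, 1)
    training <- matrix(sample(seq(0, 3, 0.5), n * s, replace = TRUE), n, s)
    v <- sample(seq(0, 3, 0.5), s, replace = TRUE)
    m <- sample(0:ceiling(n / 2), 1)
    expect_identical(feature_mask(v, training, m),
                     brute_feature_mask(v, training, m))
  }
})

test_that("mask monotonicity: surviving features shrink as m grows", {
  set.seed(13)
  for (i in 1:20) {
    training <- matrix(rnorm(12 * 5), 12, 5)
    v <- rnorm(5)
    masks <- lapply(0:6, function(m) feature_mask(v, training, m))
    for (m in 2:7) expect_true(all(masks[[m]] <= masks[[m - 1]]))
  }
})

test_that("knn_select uses masked Euclidean distance with index tie-breaking", {
  training <- rbind(c(0, 0), c(3, 0), c(1, 10))
  # full mask: nearest two to the origin-ish validation point
  expect_equal(knn_select(c(0, 1), training, c(TRUE, TRUE), 2), c(1, 2))
  # masking the second feature changes the geometry: point 3 gets close
  expect_equal(knn_select(c(0, 1), training, c(TRUE, FALSE), 2), c(1, 3))
  expect_equal(knn_select(c(2, 0), training, c(TRUE, FALSE), 1), 2)
  # exact distance tie resolves to the lower training index
  sym <- rbind(c(-1, 0), c(1, 0))
  expect_equal(knn_select(c(0, 0), sym, c(TRUE, TRUE), 1), 1)
  # k beyond the available training set returns everything
  expect_equal(knn_select(c(0, 0), training, c(TRUE, TRUE), 99), c(1, 2, 3))
  expect_error(knn_select(c(0, 0), training, c(FALSE, FALSE), 1), "masked")
})

test_that("optional z-scored distances reweight anisotropic features", {
  # feature 2 spans a 100x larger range; scaling flips the nearest neighbor
  tr <- rbind(c(0, 0), c(1, 100), c(20, 5))
  v <- c(18, 90)
  expect_equal(knn_select(v, tr, c(TRUE, TRUE), 1), 2)
  expect_equal(knn_select(v, tr, c(TRUE, TRUE), 1, scale = TRUE), 3)
  # zero-variance features drop out of the scaled distance instead of
  # dividing by zero
  tr0 <- rbind(c(5, 0), c(5, 10), c(5, 11))
  expect_equal(knn_select(c(5, 10.4), tr0, c(TRUE, TRUE), 1, scale = TRUE), 2)
  # the trim surface forwards the flag
  ds <- flowps_dataset(unname(rbind(v, tr)), c(0, 100, 0, 100))
  expect_equal(trim(ds, 1, m = 0, k = 1, scale_features = TRUE)$neighbor_indices,
               4L)
  expect_equal(trim(ds, 1, m = 0, k = 1)$neighbor_indices, 3L)
})

test_that("trim composes mask and knn and never includes the validation sample", {
  set.seed(404)
  ds <- make_global_linear(n_samples = 12, n_features = 4, seed = 4)
  N <- nrow(ds$values)
  # the classical corner keeps all features and all training samples
  corner <- trim(ds, 3, m = 0, k = N - 1)
  expect_true(all(corner$feature_mask))
  expect_setequal(corner$neighbor_indices, setdiff(1:N, 3))
  # m too large for every feature invalidates the cell
  dead <- trim(ds, 3, m = N, k = 5)
  expect_false(dead$valid)
  expect_length(dead$neighbor_indices, 0)
  # validation sample never among the neighbors; nestedness over m
  for (i in seq_len(N)) {
    t2 <- trim(ds, i, m = 2, k = 6)
    t3 <- trim(ds, i, m = 3, k = 6)
    expect_false(i %in% t2$neighbor_indices)
    expect_true(all(t3$feature_mask <= t2$feature_mask))
  }
})
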