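test_that("roc_auc reproduces hand-counted and degenerate cases", {
  expect_equal(roc_auc(c(10, 20, 80, 90), c(0, 0, 100, 100)), 1)
  expect_equal(roc_auc(c(4, 3, 2, 1), c(0, 0, 100, 100)), 0)
  expect_equal(roc_auc(c(1, 3, 2, 4), c(0, 0, 100, 100)), 0.75)
  expect_equal(roc_auc(rep(7, 6), rep(c(0, 100), 3)), 0.5)
  expect_error(roc_auc(1:3, c(100, 100, 100)), "both classes")
})

test_that("roc_auc equals brute-force concordant-pair counting (N <= 12)", {
  set.seed(101)
  for (i in 1:60) {
    n <- sample(4:12, 1)
    labels <- sample(c(0, 100), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- sample(1:6, n, replace = TRUE) + sample(c(0, 0.5), n, TRUE)
    expect_equal(roc_auc(scores, labels), brute_auc(scores, labels))
  }
})

test_that("roc_auc is invariant under strictly increasing transforms and flips", {
  set.seed(7)
  scores <- rnorm(20)
  labels <- rep(c(0, 100), 10)
  a <- roc_auc(scores, labels)
  expect_equal(roc_auc(exp(scores), labels), a)
  expect_equal(roc_auc(rank(scores), labels), a)
  expect_equal(roc_auc(-scores, labels), 1 - a)  # no ties in rnorm draws
})

test_that("optimal_threshold achieves the brute-force minimum of FP + FN", {
  tau <- optimal_threshold(c(10, 20, 80, 90), c(0, 0, 100, 100))
  expect_equal(tau, 50)
  set.seed(33)
  for (i in 1:60) {
    n <- sample(4:12, 1)
    labels <- sample(c(0, 100), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- sample(1:5, n, replace = TRUE)
    tau <- optimal_threshold(scores, labels)
    cost <- sum(scores > tau & labels == 0) + sum(scores <= tau & labels == 100)
    expect_equal(cost, brute_min_fpfn(scores, labels))
  }
  # inverted scores: the sentinel thresholds make "call everyone" reachable;
  # tie rule picks the smallest candidate
  scores <- c(90, 80, 20, 10); labels <- c(0, 0, 100, 100)
  tau <- optimal_threshold(scores, labels)
  expect_equal(tau, min(scores) - 1)
  expect_error(optimal_threshold(1:3, rep(100, 3)), "both classes")
})

test_that("confusion metrics fill the full panel with stated conventions", {
  m <- confusion_metrics(c(10, 20, 80, 90), c(0, 0, 100, 100))
  expect_equal(m$sn, 1); expect_equal(m$sp, 1); expect_equal(m$acc, 1)
  expect_equal(m$fdr, 0); expect_equal(m$mcc, 1)
  expect_equal(m$tp + m$fp + m$tn + m$fn, m$n)

  # everyone called responder on balanced data, via an explicit low tau
  m2 <- confusion_metrics(c(60, 70, 80, 90), c(0, 100, 0, 100), tau = 0)
  expect_equal(m2$sn, 1); expect_equal(m2$sp, 0)
  expect_equal(m2$acc, 0.5); expect_equal(m2$fdr, 0.5); expect_equal(m2$mcc, 0)

  # TP=3 FP=1 TN=3 FN=1 by direct construction
  scores <- c(1, 1, 1, 2, 2, 2, 2, 1)
  labels <- c(0, 0, 0, 100, 100, 100, 0, 100)
  m3 <- confusion_metrics(scores, labels, tau = 1.5)
  expect_equal(unlist(m3[c("tp", "fp", "tn", "fn")], use.names = FALSE),
               c(3, 1, 3, 1))
  expect_equal(m3$acc, 0.75); expect_equal(m3$fdr, 0.25)
  expect_equal(m3$mcc, 0.5)

  # zero-denominator conventions: nobody called responder
  m4 <- confusion_metrics(c(1, 2, 3, 4), c(0, 100, 0, 100), tau = 10)
  expect_equal(m4$fdr, 0); expect_equal(m4$mcc, 0)
})

test_that("confusion counts always sum to N on randomized instances", {
  set.seed(9)
  for (i in 1:25) {
    n <- sample(5:30, 1)
    labels <- sample(c(0, 100), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- rnorm(n)
    m <- metrics_report(scores, labels)
    expect_equal(m$tp + m$fp + m$tn + m$fn, n)
    expect_true(m$auc >= 0 && m$auc <= 1)
    expect_true(m$mcc >= -1 && m$mcc <= 1)
  }
})
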