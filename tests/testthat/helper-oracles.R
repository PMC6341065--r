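# Independent brute-force oracles used across the suite.

# AUC as the fraction of concordant (responder, non-responder) pairs,
# counted pair by pair with 0.5 credit for ties.
brute_auc <- function(scores, labels) {
  pos <- scores[labels %in% c(100, 1)]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# m-condition by explicit double loop over features and training samples.
brute_feature_mask <- function(v, training, m) {
  vapply(seq_along(v), function(j) {
    below <- 0; above <- 0
    for (r in seq_len(nrow(training))) {
      if (training[r, j] < v[j]) below <- below + 1
      if (training[r, j] > v[j]) above <- above + 1
    }
    below >= m && above >= m
  }, logical(1))
}

# Minimum achievable FP + FN over all real thresholds, by enumerating
# every inter-point threshold (rule: score > tau calls a responder).
brute_min_fpfn <- function(scores, labels) {
  # tau in {min - 1} U unique(scores) realizes every classification the
  # strict ">" rule can produce
  cand <- c(min(scores) - 1, sort(unique(scores)))
  min(vapply(cand, function(tau) {
    call_resp <- scores > tau
    sum(call_resp & labels == 0) + sum(!call_resp & labels == 100)
  }, numeric(1)))
}

# Soft-margin SVM decision values via quadprog's dual QP (independent of
# the package's SMO path).
qp_svm_decision <- function(Xtr, labels01, Xte, C, kernel = "linear",
                            degree = 3, coef0 = 0) {
  y <- ifelse(labels01 %in% c(100, 1), 1, -1)
  n <- nrow(Xtr); d <- ncol(Xtr); g <- 1 / d
  km <- function(A, B) {
    if (kernel == "linear") A %*% t(B) else (g * (A %*% t(B)) + coef0)^degree
  }
  K <- km(Xtr, Xtr)
  D <- (y %*% t(y)) * K + diag(n) * 1e-9
  sol <- quadprog::solve.QP(D, rep(1, n), cbind(y, diag(n), -diag(n)),
                            c(0, rep(0, n), rep(-C, n)), meq = 1)
  a <- pmin(pmax(sol$solution, 0), C)
  f0 <- as.vector(K %*% (a * y))
  free <- which(a > 0.02 * C & a < 0.98 * C)
  b <- if (length(free) > 0) stats::median(y[free] - f0[free]) else {
    # clamp b into the KKT interval when no strictly free vector exists
    lo <- suppressWarnings(max((y - f0)[(y > 0 & a < C) | (y < 0 & a > 0)]))
    hi <- suppressWarnings(min((y - f0)[(y < 0 & a < C) | (y > 0 & a > 0)]))
    mean(c(lo, hi))
  }
  as.vector(km(Xte, Xtr) %*% (a * y)) + b
}

# Dual alphas from quadprog (same parameterization as qp_svm_decision).
qp_svm_alpha <- function(Xtr, labels01, C, kernel = "linear", degree = 3,
                         coef0 = 0) {
  y <- ifelse(labels01 %in% c(100, 1), 1, -1)
  n <- nrow(Xtr); g <- 1 / ncol(Xtr)
  K <- if (kernel == "linear") tcrossprod(Xtr)
       else (g * tcrossprod(Xtr) + coef0)^degree
  D <- tcrossprod(y) * K + diag(n) * 1e-9
  sol <- quadprog::solve.QP(D, rep(1, n), cbind(y, diag(n), -diag(n)),
                            c(0, rep(0, n), rep(-C, n)), meq = 1)
  pmin(pmax(sol$solution, 0), C)
}

dual_objective <- function(alpha, labels01, Xtr, C, kernel = "linear",
                           degree = 3, coef0 = 0) {
  y <- ifelse(labels01 %in% c(100, 1), 1, -1)
  g <- 1 / ncol(Xtr)
  K <- if (kernel == "linear") Xtr %*% t(Xtr)
       else (g * (Xtr %*% t(Xtr)) + coef0)^degree
  sum(alpha) - 0.5 * sum((alpha * y) * (K %*% (alpha * y)))
}
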