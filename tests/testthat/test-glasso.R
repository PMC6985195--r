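test_that("the unpenalized solution matches direct matrix inversion", {
  for (seed in 1:10) {
    S <- fixture_correlation(4L, seed)
    fit <- glasso_fit(S, 0, tol = 1e-7)
    expect_lt(max(abs(fit$Theta - solve(S))), 1e-5)
  }
})

test_that("full shrinkage yields a diagonal precision matrix", {
  S <- fixture_correlation(5L, 3L)
  lam <- max(abs(S[upper.tri(S)])) * 1.01
  fit <- glasso_fit(S, lam)
  off <- fit$Theta; diag(off) <- 0
  expect_identical(max(abs(off)), 0)
})

test_that("an identity input gives an identity solution at any penalty", {
  S <- diag(4)
  for (lam in c(0, 0.1, 0.5)) {
    fit <- glasso_fit(S, lam)
    expect_equal(fit$Theta, diag(4), tolerance = 1e-10)
  }
})

test_that("the objective trace is non-decreasing and the solution is PD", {
  S <- fixture_correlation(6L, 5L, ridge = 1)
  fit <- glasso_fit(S, 0.1, trace_objective = TRUE)
  tr <- fit$objective_trace
  expect_true(all(diff(tr) >= -1e-8))
  expect_true(all(eigen(fit$Theta, symmetric = TRUE,
                        only.values = TRUE)$values > 0))
  expect_true(fit$converged)
})

test_that("per-edge penalty weights leave zero-weight edges unshrunk", {
  S <- fixture_correlation(4L, 8L)
  pw <- matrix(1, 4, 4); pw[1, 2] <- pw[2, 1] <- 0
  lam <- max(abs(S[upper.tri(S)])) * 1.01
  fit <- glasso_fit(S, lam, penalty_weights = pw)
  # all penalized edges are fully shrunk; the free edge survives
  off <- abs(fit$Theta); diag(off) <- 0
  expect_gt(off[1, 2], 1e-4)
  off[1, 2] <- off[2, 1] <- 0
  expect_identical(max(off), 0)
})

test_that("a non-PSD input is repaired with a warning", {
  S <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  expect_lt(min(eigen(S, only.values = TRUE)$values), 0)
  expect_warning(fit <- glasso_fit(S, 0.05), "positive semidefinite")
  expect_true(all(eigen(fit$Theta, only.values = TRUE)$values > 0))
})

test_that("EBIC scoring matches hand arithmetic and penalizes edges", {
  # hand-computed 2-node case: Theta with one edge, n = 100
  Theta <- matrix(c(2, -0.5, -0.5, 1.5), 2)
  S <- matrix(c(1, 0.3, 0.3, 1), 2)
  n <- 100; gamma <- 0.5
  ll <- (n / 2) * (log(det(Theta)) - sum(S * Theta))
  by_hand <- -2 * ll + 1 * log(n) + 4 * gamma * 1 * log(2)
  expect_equal(idionet:::ebic_score(Theta, S, n, gamma), by_hand)
  # gamma = 0 reduces to BIC
  expect_equal(idionet:::ebic_score(Theta, S, n, 0), -2 * ll + log(n))
  # with equal likelihood, fewer edges scores lower
  T2 <- diag(diag(Theta))
  ll2 <- (n / 2) * (log(det(T2)) - sum(S * T2))
  expect_lt(idionet:::ebic_score(T2, S, n, gamma) - (-2 * ll2),
            idionet:::ebic_score(Theta, S, n, gamma) - (-2 * ll))
})

test_that("edge count is non-increasing along the penalty path", {
  set.seed(12)
  Y <- matrix(rnorm(100 * 6), 100) %*% chol(cov2cor(solve(
    chain_precision(6, 0.3))))
  colnames(Y) <- paste0("V", 1:6)
  S <- correlation_matrix(Y)
  lams <- exp(seq(log(0.6), log(0.01), length.out = 30))
  warm <- NULL
  ecount <- vapply(lams, function(l) {
    f <- glasso_fit(S, l, warm = warm); warm <<- f
    A <- abs(f$Theta) > 1e-10
    sum(A[upper.tri(A)])
  }, numeric(1))
  expect_true(all(diff(ecount) >= 0)) # lams descend, so counts ascend
})

test_that("partial-correlation weights satisfy their defining transform", {
  set.seed(13)
  Y <- matrix(rnorm(400), 100, 4); colnames(Y) <- paste0("V", 1:4)
  Y[, 2] <- Y[, 1] + rnorm(100, 0, 0.6)
  net <- fit_ggm(Y)
  Th <- net$Theta
  W_manual <- -Th / sqrt(tcrossprod(diag(Th)))
  diag(W_manual) <- 0
  expect_equal(net$W, W_manual, tolerance = 1e-12)
  expect_equal(net$W, t(net$W))
  expect_identical(unname(diag(net$W)), rep(0, 4))
  expect_true(all(abs(net$W) <= 1))
  # zero pattern of W and Theta agree off-diagonal
  expect_identical(net$W == 0, Th == 0 | diag(4) == 1)
})
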