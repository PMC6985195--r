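test_that("correlation matrix preparation validates its input", {
  Y <- cbind(a = rnorm(50), b = rnorm(50))
  Y <- cbind(Y, c = Y[, "a"])
  S <- correlation_matrix(Y)
  expect_equal(S["a", "c"], 1)
  expect_equal(S, t(S))
  expect_error(correlation_matrix(cbind(a = rnorm(10), b = rep(1, 10))),
               "constant")
  expect_warning(correlation_matrix(matrix(rnorm(12), 3,
                                           dimnames = list(NULL, letters[1:4]))),
                 "fewer observations")
  # 2x2 case equals the sample correlation by definition
  set.seed(1); Y2 <- matrix(rnorm(40), 20)
  colnames(Y2) <- c("x", "y")
  expect_equal(correlation_matrix(Y2)[1, 2], cor(Y2)[1, 2])
})

test_that("independent noise yields near-zero correlations and empty networks", {
  set.seed(2)
  Y <- matrix(rnorm(1000 * 5), 1000); colnames(Y) <- paste0("V", 1:5)
  S <- correlation_matrix(Y)
  expect_lt(max(abs(S[upper.tri(S)])), 0.1)
  # EBIC selects the empty network for most pure-noise datasets
  empties <- vapply(1:20, function(i) {
    set.seed(100 + i)
    Yn <- matrix(rnorm(100 * 8), 100); colnames(Yn) <- paste0("V", 1:8)
    nrow(fit_ggm(Yn)$edges) == 0L
  }, logical(1))
  expect_gte(mean(empties), 0.9)
})

test_that("a chain graphical model is partially recovered at n = 100", {
  Om <- chain_precision(8, 0.3)
  ch <- chol(cov2cor(solve(Om)))
  hits <- vapply(1:20, function(i) {
    set.seed(200 + i)
    Y <- matrix(rnorm(100 * 8), 100) %*% ch
    colnames(Y) <- paste0("V", 1:8)
    net <- fit_ggm(Y)
    A <- net$W != 0; ut <- upper.tri(A)
    tA <- Om != 0; diag(tA) <- FALSE
    c(sens = sum(A[ut] & tA[ut]) / 7,
      fp = sum(A[ut] & !tA[ut]) / 21)
  }, numeric(2))
  expect_gt(mean(hits["sens", ]), 0.25)  # conservative EBIC, pilot-pinned
  expect_lt(mean(hits["fp", ]), 0.05)
  # detected true chain edges carry the true (positive) sign
  set.seed(300)
  Y <- matrix(rnorm(500 * 8), 500) %*% ch
  colnames(Y) <- paste0("V", 1:8)
  net <- fit_ggm(Y)
  chain_edges <- abs(match(net$edges$node_a, net$nodes) -
                       match(net$edges$node_b, net$nodes)) == 1L
  expect_gt(sum(chain_edges), 0L)
  expect_true(all(net$edges$weight[chain_edges] > 0))
})

test_that("embedded networks label node kinds and count nodes correctly", {
  ds <- fixture_dataset(n_days = 20L, symptoms = c("Headache", "Fatigue"),
                        seed = 31L)
  b <- standardize_basis(temporal_basis(ds$timestamps))
  net <- embedded_network(ds$ratings, b)
  expect_identical(length(net$nodes), 9L) # 2 symptom + 7 temporal
  expect_identical(sum(net$kinds == "temporal"), 7L)
  expect_named(edge_counts(net),
               c("symptom-symptom", "symptom-temporal", "temporal-temporal"))
})

test_that("residual networks handle the degenerate one-symptom case", {
  b <- standardize_basis(temporal_basis(fixture_timestamps(20L)))
  set.seed(5)
  fit <- refit_ols(rnorm(100), b$X, character(0), symptom = "Headache")
  net <- residual_network(list(Headache = fit))
  expect_identical(nrow(net$edges), 0L)
  expect_true(net$uninterpretable)
  expect_identical(net$nodes, "Headache")
})

test_that("two-node networks are estimated but flagged uninterpretable", {
  b <- standardize_basis(temporal_basis(fixture_timestamps(20L)))
  set.seed(6)
  e <- matrix(rnorm(200), 100) %*% chol(matrix(c(1, 0.6, 0.6, 1), 2))
  det <- list(
    Headache = refit_ols(e[, 1], b$X, character(0), symptom = "Headache"),
    Fatigue = refit_ols(e[, 2], b$X, character(0), symptom = "Fatigue"))
  net <- residual_network(det)
  expect_true(net$uninterpretable)
  expect_identical(length(net$nodes), 2L)
})

test_that("both approaches agree in sign on co-detected symptom edges", {
  # shared ground truth with temporal and network structure
  Om <- chain_precision(5, 0.35)
  gt <- ground_truth(symptoms = paste0("S", 1:5), Omega = Om,
                     target_r2 = 0.3, missing_rate = 0)
  agree <- 0L; total <- 0L
  for (i in 1:15) {
    ds <- simulate_person(gt, sim_config(), seed = 400 + i, likert = FALSE)
    b <- standardize_basis(temporal_basis(ds$timestamps))
    n1 <- embedded_network(ds$ratings, b)
    det <- detrend_symptoms(ds$ratings, b$X, seed = 500 + i)
    n2 <- residual_network(det)
    sym <- paste0("S", 1:5)
    W1 <- n1$W[sym, sym]; W2 <- n2$W[sym, sym]
    co <- which(upper.tri(W1) & W1 != 0 & W2 != 0)
    agree <- agree + sum(sign(W1[co]) == sign(W2[co]))
    total <- total + length(co)
  }
  expect_gt(total, 10L)
  expect_gte(agree / total, 0.95)
})
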