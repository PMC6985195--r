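test_that("strength and expected influence match hand-computed values", {
  # node with edges +0.3 and -0.2
  W <- matrix(0, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  W["A", "B"] <- W["B", "A"] <- 0.3
  W["A", "C"] <- W["C", "A"] <- -0.2
  tab <- compute_centrality(fixture_ggm(W))
  a <- tab[tab$node == "A", ]
  expect_equal(a$strength, 0.5)
  expect_equal(a$expected_influence, 0.1)

  # all-positive star: hub with 4 edges of 0.25
  W2 <- matrix(0, 5, 5, dimnames = list(LETTERS[1:5], LETTERS[1:5]))
  W2[1, 2:5] <- W2[2:5, 1] <- 0.25
  tab2 <- compute_centrality(fixture_ggm(W2))
  expect_equal(tab2$strength[1], 1)
  expect_equal(tab2$expected_influence[1], 1)
  expect_equal(tab2$strength[-1], rep(0.25, 4))

  # empty network: all centralities zero
  tab3 <- compute_centrality(fixture_ggm(matrix(0, 4, 4)))
  expect_identical(unname(tab3$strength), rep(0, 4))
  expect_identical(unname(tab3$expected_influence), rep(0, 4))
})

test_that("centrality properties hold on random networks", {
  set.seed(14)
  for (i in 1:25) {
    p <- sample(3:8, 1)
    W <- matrix(0, p, p)
    ut <- upper.tri(W)
    W[ut] <- rnorm(sum(ut)) * rbinom(sum(ut), 1, 0.5) * 0.3
    W <- W + t(W)
    dimnames(W) <- list(paste0("N", 1:p), paste0("N", 1:p))
    tab <- compute_centrality(fixture_ggm(W))
    # strength bounds expected influence
    expect_true(all(tab$strength >= abs(tab$expected_influence) - 1e-12))
    # strength invariant under sign flips, EI not (when negatives exist)
    tab_abs <- compute_centrality(fixture_ggm(abs(W)))
    expect_equal(tab_abs$strength, tab$strength)
    if (any(W < 0))
      expect_false(isTRUE(all.equal(tab_abs$expected_influence,
                                    tab$expected_influence)))
    # all-nonnegative network: strength equals expected influence
    expect_equal(tab_abs$strength, tab_abs$expected_influence)
  }
})

test_that("adding a disconnected component leaves centrality unchanged", {
  W <- matrix(0, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  W["A", "B"] <- W["B", "A"] <- 0.4
  big <- matrix(0, 5, 5, dimnames = list(LETTERS[1:5], LETTERS[1:5]))
  big[1:3, 1:3] <- W
  big["D", "E"] <- big["E", "D"] <- 0.2
  t1 <- compute_centrality(fixture_ggm(W))
  t2 <- compute_centrality(fixture_ggm(big))
  expect_equal(t2$strength[match(t1$node, t2$node)], t1$strength)
})

test_that("node ranking uses the lexicographic tie rule and kind filter", {
  W <- matrix(0, 3, 3, dimnames = list(c("B", "A", "C"), c("B", "A", "C")))
  W["A", "B"] <- W["B", "A"] <- 0.5
  W["C", "B"] <- W["B", "C"] <- 0   # C isolated
  W["A", "C"] <- W["C", "A"] <- 0
  tab <- compute_centrality(fixture_ggm(W))
  # A and B tie at 0.5; tie broken by label
  expect_identical(rank_nodes(tab, "strength"), c("A", "B", "C"))
  expect_error(rank_nodes(tab, "betweenness"))

  # kind filter drops temporal nodes from the ranking
  W4 <- matrix(0.2, 4, 4); diag(W4) <- 0
  dimnames(W4) <- list(c("S1", "S2", "t1", "t2"), c("S1", "S2", "t1", "t2"))
  tab4 <- compute_centrality(
    fixture_ggm(W4, kinds = c("symptom", "symptom", "temporal", "temporal")))
  expect_identical(rank_nodes(tab4, "strength", kinds = "symptom"),
                   c("S1", "S2"))
  expect_false(is.na(tab4$rank_strength_symptom[1]))
  expect_true(all(is.na(tab4$rank_strength_symptom[tab4$kind == "temporal"])))
})

test_that("raw-vs-detrended comparison reports shifts and rank correlation", {
  W <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  W["A", "B"] <- W["B", "A"] <- 0.6
  W["C", "D"] <- W["D", "C"] <- 0.1
  tab <- compute_centrality(fixture_ggm(W))
  same <- compare_centrality(tab, tab)
  expect_identical(unname(same$delta), rep(0, 4))
  expect_equal(attr(same, "rank_correlation"), 1)

  # the top raw node collapsing in the detrended network is flagged by a
  # large negative rank shift
  W2 <- matrix(0, 4, 4, dimnames = dimnames(W))
  W2["A", "B"] <- W2["B", "A"] <- 0.05
  W2["C", "D"] <- W2["D", "C"] <- 0.5
  tab2 <- compute_centrality(fixture_ggm(W2))
  cmp <- compare_centrality(tab, tab2)
  expect_lt(cmp$rank_shift[cmp$node == "A"], 0)

  # two-node comparison is emitted but uninterpretable
  W3 <- matrix(c(0, 0.3, 0.3, 0), 2, dimnames = list(c("A", "B"),
                                                     c("A", "B")))
  t3 <- compute_centrality(fixture_ggm(W3))
  cmp3 <- compare_centrality(t3, t3)
  expect_true(attr(cmp3, "uninterpretable"))
  expect_error(compare_centrality(tab, compute_centrality(
    fixture_ggm(matrix(0, 2, 2, dimnames = list(c("X", "Y"), c("X", "Y")))))),
    "no shared")
})
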