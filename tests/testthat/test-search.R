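test_that("branch and bound equals exhaustive search on small instances", {
  withr::local_seed(7)
  x <- load_ectateus_matrix()
  for (i in 1:8) {
    sub <- x[sample(x$taxa, sample(6:8, 1)), ]
    e <- exhaustive_search(sub)
    b <- branch_and_bound(sub)
    expect_equal(b$L, e$L)
    expect_equal(canonical_set(b$trees), canonical_set(e$trees))
  }
  for (i in 1:5) {
    sub <- random_matrix(sample(6:8, 1), 12, n_states = 3, p_missing = 0.2)
    e <- exhaustive_search(sub)
    b <- branch_and_bound(sub)
    expect_equal(canonical_set(b$trees), canonical_set(e$trees))
  }
})

test_that("one informative character decides a four-taxon problem", {
  m <- char_matrix(rbind(A = 1L, B = 1L, C = 0L, D = 0L),
                   taxa = LETTERS[1:4])
  res <- exhaustive_search(m)
  expect_equal(res$L, 1)
  expect_length(res$trees, 1)
  expect_true(has_clade(res$trees[[1]], c("A", "B")))
})

test_that("degenerate landscapes are reported truthfully", {
  const <- char_matrix(matrix(0L, 6, 4), taxa = LETTERS[1:6])
  res <- exhaustive_search(const)
  expect_equal(res$L, 0)
  expect_length(res$trees, 105)  # every topology is optimal
  # pure-autapomorphy matrix: equally flat at L = n_char
  aut <- char_matrix(diag(1L, 6, 6), taxa = LETTERS[1:6])
  res2 <- branch_and_bound(aut)
  expect_equal(res2$L, 6)
  expect_length(res2$trees, 105)
})

test_that("stepwise addition is deterministic and never beats the optimum", {
  x <- load_ectateus_matrix()
  t1 <- stepwise_addition(x, seed = 5)
  t2 <- stepwise_addition(x, seed = 5)
  expect_equal(canonical_newick(t1), canonical_newick(t2))
  expect_gte(attr(t1, "L"), 57)
  expect_equal(attr(t1, "L"), tree_length(t1, x))
})

test_that("branch swapping never returns a longer tree and fixes optima", {
  x <- load_ectateus_matrix()
  opt <- branch_and_bound(x)$trees[[1]]
  for (mv in c("NNI", "SPR", "TBR")) {
    sw <- branch_swap(opt, x, move = mv)
    expect_equal(attr(sw, "L"), 57)
  }
  start <- random_topology(x$taxa, seed = 31)
  L0 <- tree_length(start, x)
  sw <- branch_swap(start, x, move = "TBR")
  expect_lte(attr(sw, "L"), L0)
  expect_equal(attr(sw, "L"), tree_length(sw, x))
})

test_that("NNI reaches exactly the trees one split away", {
  # independent characterization: NNI neighbors of a binary tree are the
  # other binary trees at Robinson-Foulds distance 2, and there are
  # 2(n-3) of them
  tr <- random_topology(letters[1:6], seed = 12)
  all6 <- enumerate_topologies(letters[1:6])
  rf <- vapply(all6, function(t2)
    length(setdiff(bipartitions(tr), bipartitions(t2))) +
      length(setdiff(bipartitions(t2), bipartitions(tr))), 0)
  expect_equal(sum(rf == 2), 2 * (6 - 3))
  expect_equal(sum(rf == 0), 1)  # the tree itself
})

test_that("heuristic search finds the fixture optimum across many starts", {
  x <- load_ectateus_matrix()
  h <- heuristic_search(x, starts = 20, seed = 77)
  expect_equal(h$L, 57)
  expect_false(h$exact)
  h2 <- heuristic_search(x, starts = 20, seed = 77)
  expect_equal(h2$L, h$L)
  expect_equal(canonical_set(h2$trees), canonical_set(h$trees))
})

test_that("search output is independent of taxon input order", {
  withr::local_seed(88)
  x <- load_ectateus_matrix()
  sub <- x[sample(x$taxa, 8), ]
  res1 <- branch_and_bound(sub)
  sub2 <- sub[rev(sub$taxa), ]
  res2 <- branch_and_bound(sub2)
  expect_equal(res1$L, res2$L)
  expect_equal(canonical_set(res1$trees), canonical_set(res2$trees))
})

test_that("exact search on the full published matrix reaches length 57", {
  x <- load_ectateus_matrix()
  res <- branch_and_bound(x)
  expect_true(res$exact)
  expect_equal(res$L, 57)
  expect_false(res$overflow)
  # the optimum is confirmed by an independent engine on one tree
  expect_equal(tree_length(res$trees[[1]], x), 57)
})
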