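test_that("jackknife deletion behaves like independent column Bernoulli", {
  x <- load_ectateus_matrix()
  expect_true(isTRUE(all.equal(jackknife_matrix(x, 0, seed = 1), x)))
  expect_equal(n_char(jackknife_matrix(x, 1, seed = 1)), 0)
  withr::local_seed(14)
  kept <- replicate(2000, n_char(jackknife_matrix(x, 0.36)))
  # binomial expectation 40 x 0.64 = 25.6; 2000 draws pin the mean tightly
  expect_lt(abs(mean(kept) - 25.6), 0.3)
})

test_that("support runs are reproducible bit for bit from the seed", {
  x <- load_ectateus_matrix()
  a <- jackknife_support(x, replicates = 25, seed = 5, starts = 2)
  b <- jackknife_support(x, replicates = 25, seed = 5, starts = 2)
  expect_identical(a$split, b$split)
  expect_identical(a$support, b$support)
  expect_true(all(a$support >= 0 & a$support <= 100))
  # the trivial full-set split is never reported
  expect_true(all(a$size >= 2 & a$size <= n_taxa(x) - 2))
})

test_that("without deletion every consensus clade of the optima is certain", {
  x <- load_ectateus_matrix()
  js <- jackknife_support(x, p_remove = 0, replicates = 15, seed = 3)
  cl <- ectateus_clades()
  for (nm in c("ectateus_clade", "modestus_group", "planus_group"))
    expect_equal(clade_support(js, cl[[nm]], x$taxa), 100)
})

test_that("support grows as fewer characters are deleted", {
  x <- load_ectateus_matrix()
  cl <- ectateus_clades()$modestus_group
  s_low <- clade_support(
    jackknife_support(x, p_remove = 0.1, replicates = 60, seed = 21),
    cl, x$taxa)
  s_high <- clade_support(
    jackknife_support(x, p_remove = 0.6, replicates = 60, seed = 21),
    cl, x$taxa)
  expect_gte(s_low, s_high - 5)  # monotone in expectation, noisy at n = 60
  expect_gte(s_low, 95)
})

test_that("strict and majority consensus follow their split algebra", {
  top4 <- enumerate_topologies(LETTERS[1:4])
  star <- strict_consensus(top4)
  expect_length(bipartitions(star), 0)
  one <- random_topology(letters[1:8], seed = 4)
  expect_equal(canonical_newick(strict_consensus(list(one))),
               canonical_newick(one))
  withr::local_seed(99)
  trees <- replicate(4, random_topology(letters[1:8]), simplify = FALSE)
  sc <- strict_consensus(trees)
  expect_setequal(bipartitions(sc),
                  Reduce(intersect, lapply(trees, bipartitions)))
  # 3 identical + 1 different: majority keeps the identical tree's splits
  maj <- majority_consensus(c(trees[c(1, 1, 1)], trees[2]), threshold = 0.5)
  expect_setequal(bipartitions(maj), bipartitions(trees[[1]]))
  # threshold 1 coincides with the strict consensus
  expect_setequal(bipartitions(majority_consensus(trees, threshold = 1)),
                  bipartitions(sc))
  # majority splits are pairwise compatible: they fit on one tree
  expect_lte(length(bipartitions(maj)), 8 - 3)
})
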