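test_that("simulation is a pure function of its seed", {
  a <- simulate_matrix(n_taxa = 10, n_char = 12, seed = 4)
  b <- simulate_matrix(n_taxa = 10, n_char = 12, seed = 4)
  expect_equal(canonical_newick(a$tree), canonical_newick(b$tree))
  expect_true(isTRUE(all.equal(a$matrix, b$matrix)))
  c2 <- simulate_matrix(n_taxa = 10, n_char = 12, seed = 5)
  expect_false(isTRUE(all.equal(a$matrix, c2$matrix)))
})

test_that("clean-regime matrices are perfectly hierarchical", {
  for (seed in 1:25) {
    sim <- simulate_matrix(n_taxa = 8, n_char = 10, n_states = 3,
                           seed = seed)
    res <- branch_and_bound(sim$matrix)
    expect_length(res$trees, 1)
    expect_equal(canonical_newick(res$trees[[1]]),
                 canonical_newick(sim$tree))
    fs <- fit_statistics(sim$tree, sim$matrix)
    expect_equal(attr(fs, "CI_reported"), 100L)
    expect_equal(attr(fs, "RI_reported"), 100L)
    # outgroup is all-plesiomorphic by construction
    expect_true(all(sim$matrix$data["outgroup", ] == 0))
  }
})

test_that("mk-regime matrices carry homoplasy but still favor the truth", {
  withr::local_seed(123)
  wins <- 0
  for (seed in 1:30) {
    sim <- simulate_matrix(n_taxa = 12, n_char = 40, regime = "mk",
                           mean_changes = 1.5, seed = seed)
    fs <- fit_statistics(sim$tree, sim$matrix)
    rnd <- random_topology(sim$matrix$taxa)
    L_true <- attr(fs, "L")
    L_rand <- tree_length(rnd, sim$matrix)
    if (attr(fs, "CI") < 1) wins <- wins + 1
    expect_lte(L_true, L_rand)
  }
  expect_gte(wins, 25)  # mean 1.5 changes: most draws are homoplasious
})

test_that("injected missingness reproduces the holotype pattern", {
  sim <- simulate_matrix(n_taxa = 10, n_char = 40, seed = 6)
  expect_true(isTRUE(all.equal(
    inject_missing(sim$matrix, "taxon_03", 0, seed = 1), sim$matrix)))
  m <- inject_missing(sim$matrix, "taxon_03", 11 / 40, seed = 1)
  expect_equal(sum(is.na(m$data["taxon_03", ])), 11)
  expect_equal(sum(is.na(m$data)), 11)
  expect_error(inject_missing(sim$matrix, "nobody", 0.5), "unknown taxon")
})

test_that("recovery survives one quarter-missing taxon", {
  ok <- 0
  for (seed in 1:10) {
    sim <- simulate_matrix(n_taxa = 10, n_char = 24, seed = seed,
                           missing_taxon = "taxon_05",
                           missing_fraction = 0.25)
    res <- branch_and_bound(sim$matrix)
    # the induced topology on the fully coded taxa must be recovered
    keep <- setdiff(sim$matrix$taxa, "taxon_05")
    truth <- ape::keep.tip(sim$tree, keep)
    hit <- any(vapply(res$trees, function(tr)
      canonical_newick(ape::keep.tip(ape::unroot(tr), keep)) ==
        canonical_newick(truth), TRUE))
    if (hit) ok <- ok + 1
  }
  expect_gte(ok, 9)
})
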