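test_that("degenerate columns score zero and autapomorphies score one", {
  m <- char_matrix(rbind(A = c(0L, 0L, NA), B = c(0L, 0L, NA),
                         C = c(0L, 1L, NA), D = c(0L, 0L, NA),
                         E = c(0L, 0L, NA), F = c(0L, 0L, NA)))
  for (tr in enumerate_topologies(LETTERS[1:6]))
    expect_equal(fitch_steps(tr, m), c(0L, 1L, 0L))
})

test_that("Fitch steps equal the exhaustive assignment oracle", {
  withr::local_seed(101)
  for (i in 1:20) {
    n <- sample(4:6, 1)
    x <- random_matrix(n, n_char = 6, n_states = sample(2:3, 1),
                       p_missing = 0.15)
    tr <- random_topology(x$taxa)
    s <- fitch_steps(tr, x)
    for (j in seq_len(n_char(x))) {
      col <- x$data[match(tr$tip.label, x$taxa), j]
      alphabet <- sort(unique(col[!is.na(col)]))
      expected <- if (length(alphabet) < 2) 0L else {
        sbt <- lapply(col, function(v) if (is.na(v)) alphabet else v)
        as.integer(brute_force_steps(tr, sbt, alphabet))
      }
      expect_equal(s[j], expected)
    }
  }
})

test_that("m <= s <= g on every character and every binary tree", {
  withr::local_seed(202)
  for (i in 1:15) {
    x <- random_matrix(sample(5:9, 1), n_char = 10,
                       n_states = sample(2:3, 1), p_missing = 0.1)
    tr <- random_topology(x$taxa)
    s <- fitch_steps(tr, x)
    expect_true(all(min_steps(x) <= s))
    expect_true(all(s <= max_steps(x)))
  }
})

test_that("tree length is invariant to rerooting and input order", {
  x <- load_ectateus_matrix()
  tr <- random_topology(x$taxa, seed = 9)
  L <- tree_length(tr, x)
  for (og in x$taxa[c(1, 7, 20)])
    expect_equal(tree_length(reroot_outgroup(tr, og), x), L)
  perm <- sample(seq_len(n_taxa(x)))
  xp <- x[x$taxa[perm], ]
  expect_equal(tree_length(tr, xp), L)
  expect_error(tree_length(tr, x[1:10, ]), "without matrix row")
  expect_error(tree_length(ape::keep.tip(tr, x$taxa[1:10]), x),
               "absent from tree")
  expect_error(
    tree_length(random_topology(c(x$taxa[-1], "intruder")), x),
    "Zidalus_latipes")
})

test_that("per-character minima and maxima match their counting oracles", {
  x <- load_ectateus_matrix()
  m_oracle <- g_oracle <- integer(40)
  for (j in 1:40) {
    col <- x$data[, j]
    tab <- table(col[!is.na(col)])
    m_oracle[j] <- max(0L, length(tab) - 1L)
    g_oracle[j] <- sum(tab) - max(tab)
  }
  expect_equal(min_steps(x), m_oracle)
  expect_equal(max_steps(x), g_oracle)
  expect_equal(min_steps(x, 13), 2L)
  expect_equal(sum(min_steps(x)), 42L)
  # max steps also equals the worst-tree (star) interpretation, checked by
  # brute force on a handful of small subsamples
  withr::local_seed(33)
  for (k in 1:5) {
    sub <- x[sample(x$taxa, 6), sample(40, 4)]
    worst <- vapply(seq_len(4), function(j) {
      top <- enumerate_topologies(sub$taxa)
      max(vapply(top, function(tr) fitch_steps(tr, sub)[j], 0L))
    }, 0L)
    expect_equal(max_steps(sub), worst)
  }
})

test_that("ensemble CI and RI follow their definitions and edge cases", {
  # perfect-fit matrix: L == sum m, CI reported 100
  sim <- simulate_matrix(n_taxa = 8, n_char = 10, seed = 3)
  tr <- sim$tree
  fs <- fit_statistics(tr, sim$matrix)
  expect_equal(attr(fs, "CI"), 1)
  expect_equal(attr(fs, "CI_reported"), 100L)
  expect_equal(attr(fs, "RI"), 1)
  # a character at its worst possible fit retains nothing: RI = 0
  m <- char_matrix(rbind(A = 0L, B = 1L, C = 0L, D = 1L),
                   taxa = LETTERS[1:4])
  bad <- read_newick("((A,B),(C,D));")  # s = g = 2, m = 1
  fsb <- fit_statistics(bad, m)
  expect_equal(attr(fsb, "RI"), 0)
  # all-autapomorphy matrix: sum g == sum m, RI undefined (not zero)
  aut <- char_matrix(rbind(A = c(1L, 0L), B = c(0L, 1L), C = c(0L, 0L),
                           D = c(0L, 0L)), taxa = LETTERS[1:4])
  fsa <- fit_statistics(read_newick("((A,B),(C,D));"), aut)
  expect_true(is.na(attr(fsa, "RI")))
  expect_true(is.na(attr(fsa, "RI_reported")))
})

test_that("informative-only accounting excludes autapomorphies coherently", {
  # every one of the 40 published characters is parsimony-informative, so
  # the flag is a no-op there ...
  x <- load_ectateus_matrix()
  tr <- branch_and_bound(x)$trees[[1]]
  expect_equal(sum(max_steps(x) == min_steps(x)), 0)
  full <- fit_statistics(tr, x)
  info <- fit_statistics(tr, x, informative_only = TRUE)
  expect_equal(attr(info, "CI"), attr(full, "CI"))
  # ... but it bites once autapomorphies are added
  aug <- char_matrix(cbind(x$data, c(1L, rep(0L, 19))), taxa = x$taxa)
  fa <- fit_statistics(tr, aug)
  ia <- fit_statistics(tr, aug, informative_only = TRUE)
  expect_equal(attr(fa, "L"), 58L)
  expect_equal(attr(ia, "L"), 57L)
  expect_lt(attr(ia, "sum_m"), attr(fa, "sum_m"))
})
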