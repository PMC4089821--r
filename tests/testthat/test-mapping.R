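test_that("ancestral sets match the brute-force reconstruction oracle", {
  withr::local_seed(55)
  for (i in 1:12) {
    n <- sample(4:6, 1)
    x <- random_matrix(n, n_char = 4, n_states = sample(2:3, 1),
                       p_missing = 0.15)
    tr <- reroot_outgroup(random_topology(x$taxa), x$taxa[1])
    sets <- ancestral_sets(tr, x)
    trp <- ape::reorder.phylo(tr, "postorder")
    setsp <- ancestral_sets(trp, x)
    ord <- match(trp$tip.label, x$taxa)
    for (j in seq_len(n_char(x))) {
      col <- x$data[ord, j]
      alphabet <- sort(unique(col[!is.na(col)]))
      if (length(alphabet) < 1) next
      sbt <- lapply(col, function(v) if (is.na(v)) alphabet else v)
      oracle <- brute_force_mpr_sets(trp, sbt, alphabet)
      expect_equal(attr(setsp[[j]], "steps"), oracle$steps)
      for (node in seq_len(max(trp$edge))) {
        got <- alphabet[setsp[[j]][node, ]]
        expect_equal(got, oracle$sets[[node]],
                     label = sprintf("case %d char %d node %d", i, j, node))
      }
    }
  }
})

test_that("constant and single-derived characters map trivially", {
  m <- char_matrix(rbind(A = c(0L, 0L), B = c(0L, 1L), C = c(0L, 0L),
                         D = c(0L, 0L), Z = c(0L, 0L)))
  tr <- reroot_outgroup(read_newick("(Z,((A,B),(C,D)));"), "Z")
  sets <- ancestral_sets(tr, m)
  # constant character: every node's set is exactly {0}
  expect_true(all(sets[[1]][, "0"]))
  expect_equal(attr(sets[[1]], "steps"), 0)
  ch <- unambiguous_changes(tr, m)
  expect_equal(nrow(ch), 1)
  expect_equal(ch$char, 2L)
  expect_equal(ch$clade, "B")  # the autapomorphy's terminal branch
  expect_equal(ch$from, 0L)
  expect_equal(ch$to, 1L)
})

test_that("required changes never exceed the character's step count", {
  withr::local_seed(66)
  for (i in 1:10) {
    x <- random_matrix(sample(5:8, 1), n_char = 8, n_states = 3,
                       p_missing = 0.1)
    tr <- reroot_outgroup(random_topology(x$taxa), x$taxa[1])
    s <- fitch_steps(tr, x)
    ch <- unambiguous_changes(tr, x)
    if (nrow(ch))
      for (j in unique(ch$char))
        expect_lte(sum(ch$char == j), s[j])
    # and the total mapped changes of an acctran assignment equal L exactly
    ac <- unambiguous_changes(tr, x, mapping = "acctran")
    expect_equal(nrow(ac), sum(s))
    de <- unambiguous_changes(tr, x, mapping = "deltran")
    expect_equal(nrow(de), sum(s))
  }
})

test_that("the published stems carry their diagnostic states", {
  x <- load_ectateus_matrix()
  res <- branch_and_bound(x)
  cl <- ectateus_clades()
  fig <- res$trees[[which.max(vapply(res$trees, function(tr)
    sum(vapply(cl, function(g) has_clade(tr, g), TRUE)), 0))]]
  rt <- reroot_outgroup(fig, "Zidalus_latipes")
  map <- classify_homoplasy(unambiguous_changes(rt, x),
                            fit_statistics(fig, x))
  stem <- function(group) {
    key <- paste(sort(cl[[group]]), collapse = "|")
    map[map$clade == key, , drop = FALSE]
  }
  # genital clavae define the two redefined genera
  sel <- stem("selinus_clade")
  expect_true(any(sel$char == 34 & sel$to == 1 & !sel$homoplasy))
  ect <- stem("ectateus_clade")
  expect_true(any(ect$char == 30 & ect$to == 1 & !ect$homoplasy))
  expect_true(any(ect$char == 33 & ect$to == 1 & !ect$homoplasy))
  expect_true(any(ect$char == 28 & ect$to == 0 & ect$homoplasy))
  # pronotal-angle character 15 arises independently on two stems
  hits15 <- map[map$char == 15 & map$to == 1, ]
  expect_gte(nrow(hits15), 2)
  expect_true(all(hits15$homoplasy))
  expect_true(paste(sort(cl$modestus_group), collapse = "|") %in%
                hits15$clade)
  expect_true(paste(sort(cl$convexipennis_trio), collapse = "|") %in%
                hits15$clade)
})

test_that("clade diagnoses reproduce the published lists", {
  x <- load_ectateus_matrix()
  res <- branch_and_bound(x)
  cl <- ectateus_clades()
  fig <- res$trees[[which.max(vapply(res$trees, function(tr)
    sum(vapply(cl, function(g) has_clade(tr, g), TRUE)), 0))]]
  rt <- reroot_outgroup(fig, "Zidalus_latipes")
  diag_of <- function(group) {
    d <- diagnose_clade(rt, x, cl[[group]])$supporting
    sort(paste0(d$char, ":", d$to, ifelse(d$homoplasy, "h", "")))
  }
  expect_equal(diag_of("planus_group"),
               sort(c("39:1", "10:1h", "27:1h")))
  expect_equal(diag_of("ghesquierei_crenatus"), sort(c("22:1", "40:1")))
  expect_equal(diag_of("villiersi_group"),
               sort(c("1:1", "17:1", "25:1")))
  expect_equal(diag_of("modestus_calcaripes"), "2:1h")
  expect_equal(diag_of("malaisei_trio"),
               sort(c("24:1", "31:1", "37:2", "20:0h")))
  expect_equal(diag_of("convexipennis_group"),
               sort(c("26:1", "29:1", "32:1", "37:1", "38:1")))
  expect_error(diagnose_clade(rt, x, c("Selinus_planus", "Selinus_gravis")),
               "not a clade")
})
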