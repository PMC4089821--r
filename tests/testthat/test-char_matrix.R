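test_that("the packaged matrix matches its printed source cell for cell", {
  x <- load_ectateus_matrix()
  expect_equal(n_taxa(x), 20)
  expect_equal(n_char(x), 40)
  cell <- function(taxon, j) unname(x$data[match(taxon, x$taxa), j])
  expect_equal(cell("Zidalus_latipes", 12), 1L)
  expect_equal(cell("Zidalus_latipes", 1), 0L)
  expect_true(is.na(cell("Ectateus_curtulus", 2)))
  expect_equal(sum(is.na(x$data[match("Ectateus_curtulus", x$taxa), ])), 11)
  # the incompletely known holotype is the only taxon with missing cells
  rows_missing <- x$taxa[rowSums(is.na(x$data)) > 0]
  expect_equal(rows_missing, "Ectateus_curtulus")
  expect_s3_class(x$char_meta, "data.frame")
  expect_equal(nrow(x$char_meta), 40)
})

test_that("a corrupted fixture fails the integrity check by row", {
  x <- load_ectateus_matrix()
  x$data[3, 5] <- 2L
  cs <- cladistR:::row_checksums(x)
  ref <- cladistR:::ectateus_row_checksums
  expect_equal(names(ref)[cs[names(ref)] != ref],
               "Pseudoselinus_punctatostriatus")
})

test_that("column profiles count non-missing cells only", {
  x <- load_ectateus_matrix()
  p13 <- column_profile(x, 13)
  expect_equal(p13$observed_states, c(0L, 1L, 2L))
  expect_equal(sum(p13$counts), p13$n_observed)
  p37 <- column_profile(x, 37)
  expect_equal(p37$observed_states, c(0L, 1L, 2L))
  expect_equal(p37$n_observed, 19)  # curtulus unknown here
  m <- char_matrix(rbind(A = c(0L, NA), B = c(1L, NA)))
  p <- column_profile(m, 2)
  expect_equal(p$n_observed, 0)
  expect_length(p$observed_states, 0)
  expect_error(column_profile(m, 3), "out of range")
})

test_that("write/read round trip is the identity in every dialect", {
  x <- load_ectateus_matrix()
  for (f in c("nexus", "tnt", "table")) {
    y <- read_char_matrix(text = write_char_matrix(x, f), format = f)
    expect_true(isTRUE(all.equal(x, y)), label = paste("dialect", f))
  }
  # quoted labels with spaces survive the NEXUS dialect
  sp <- char_matrix(rbind(c(0L, 1L, NA), c(1L, 0L, 2L)),
                    taxa = c("Zidalus latipes", "Lechius abacoides"))
  y <- read_char_matrix(text = write_char_matrix(sp, "nexus"))
  expect_equal(y$taxa, sp$taxa)
  expect_true(isTRUE(all.equal(sp, y)))
  # single-cell document
  one <- char_matrix(matrix(0L, 1, 1), taxa = "solo")
  expect_true(isTRUE(all.equal(one,
    read_char_matrix(text = write_char_matrix(one, "nexus")))))
  # missing marks land at the same positions
  txt <- write_char_matrix(x, "table")
  expect_equal(which(is.na(read_char_matrix(text = txt)$data)),
               which(is.na(x$data)))
})

test_that("polymorphic cells round trip as bracketed sets", {
  m <- char_matrix(rbind(A = c(0L, 1L), B = c(1L, NA), C = c(0L, 0L)))
  m$poly <- data.frame(taxon = "B", char = 2L)
  m$poly$states <- list(c(0L, 1L))
  for (f in c("nexus", "tnt", "table")) {
    doc <- write_char_matrix(m, f)
    y <- read_char_matrix(text = doc, format = f)
    expect_equal(y$poly$taxon, "B")
    expect_equal(y$poly$states[[1]], c(0L, 1L))
    expect_identical(unname(y$data), unname(m$data))
  }
})

test_that("malformed documents are rejected with line information", {
  expect_error(read_char_matrix(
    text = "t1\t0 1\nt2\t0", format = "table"), "expected")
  expect_error(read_char_matrix(
    text = "t1\t01\nt1\t00", format = "table"), "duplicate")
  expect_error(read_char_matrix(
    text = "t1\t0X", format = "table"), "unknown state symbol")
  expect_error(read_char_matrix(
    text = "#NEXUS\nBEGIN CHARACTERS;\nMATRIX\n;\nEND;",
    format = "nexus"), "empty")
  expect_error(read_char_matrix(text = "xread 2 2\nt1 00\n;",
                                format = "nexus"), "NEXUS")
  # minimal NEXUS parses with one missing cell
  y <- read_char_matrix(text = paste0(
    "#NEXUS\nBEGIN CHARACTERS;\nDIMENSIONS NCHAR=3;\n",
    "FORMAT SYMBOLS=\"01\" MISSING=?;\nMATRIX\nta 010\ntb 0?1\n;\nEND;"))
  expect_equal(dim(y$data), c(2L, 3L))
  expect_equal(sum(is.na(y$data)), 1)
})

test_that("state codes beyond one symbol refuse to serialize", {
  m <- char_matrix(matrix(c(0L, 12L), 2, 1), taxa = c("a", "b"))
  expect_error(write_char_matrix(m, "tnt"), "exceed")
})
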