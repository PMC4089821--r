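#' Fitch parsimony steps per character
#'
#' Minimum number of unordered state changes each character requires on a
#' given binary topology (Fitch set-intersection/union optimization;
#' missing cells carry the full observed state set, so root placement and
#' rooting are irrelevant to the count).
#'
#' @param tree a binary `phylo` whose leaf set equals the matrix taxa
#' @param x a [char_matrix]
#' @return integer vector of length `n_char(x)`.
#' @examples
#' m <- char_matrix(rbind(A = c(0, 0), B = c(0, 1), C = c(1, 1),
#'                        D = c(1, 0)))
#' tr <- read_newick("((A,B),(C,D));")
#' fitch_steps(tr, m)   # 1 1
#' tree_length(tr, m)   # 2
#' @export
fitch_steps <- function(tree, x) {
  if (!ape::is.binary(tree))
    stop("Fitch scoring requires a binary tree (resolve polytomies first)")
  masks <- fitch_masks(x)
  ord <- align_tree_matrix(tree, x)
  .cpp_fitch_counts(tree$edge, n_taxa(x), masks$full[ord, , drop = FALSE],
                    rep(1L, n_char(x)))
}

#' Parsimony length of a tree
#'
#' Total number of state changes the matrix requires on the topology
#' (the sum of [fitch_steps()] over characters).
#'
#' @inheritParams fitch_steps
#' @export
tree_length <- function(tree, x) sum(fitch_steps(tree, x))

# map matrix rows onto tree tip numbering; errors name the culprit
align_tree_matrix <- function(tree, x) {
  miss <- setdiff(x$taxa, tree$tip.label)
  if (length(miss))
    stop("taxon in matrix absent from tree: ", paste(miss, collapse = ", "))
  extra <- setdiff(tree$tip.label, x$taxa)
  if (length(extra))
    stop("tree leaf without matrix row: ", paste(extra, collapse = ", "))
  match(tree$tip.label, x$taxa)
}

#' Per-character minimum and maximum conceivable steps
#'
#' For an unordered character scored over its non-missing taxa, the
#' minimum steps on *any* tree is `max(0, k - 1)` for `k` observed states,
#' and the maximum (the steps on the worst tree, equivalently a star
#' phylogeny) is `n_observed` minus the largest single-state count.
#' These are the per-character ingredients of the ensemble CI and RI.
#'
#' @param x a [char_matrix]
#' @param index optional single character index; when `NULL`, vectors over
#'   all characters are returned.
#' @return integer scalar or vector.
#' @export
min_steps <- function(x, index = NULL) {
  v <- vapply(seq_len(n_char(x)), function(j) {
    p <- column_profile(x, j)
    max(0L, length(p$observed_states) - 1L)
  }, 0L)
  if (is.null(index)) v else v[index]
}

#' @rdname min_steps
#' @export
max_steps <- function(x, index = NULL) {
  v <- vapply(seq_len(n_char(x)), function(j) {
    p <- column_profile(x, j)
    if (p$n_observed == 0L) 0L else p$n_observed - max(p$counts)
  }, 0L)
  if (is.null(index)) v else v[index]
}

#' Step accounting and ensemble fit statistics (CI, RI)
#'
#' Scores a tree on a matrix and assembles the full step accounting:
#' per-character observed steps `s`, minima `m`, maxima `g`, tree length
#' `L = sum(s)`, the ensemble consistency index `CI = sum(m)/L` and
#' retention index `RI = (sum(g) - L)/(sum(g) - sum(m))`, plus the
#' conventional reported forms (`x 100`, rounded half away from zero).
#' All variable characters are included, autapomorphies too; set
#' `informative_only = TRUE` to restrict every sum to
#' parsimony-informative characters (`g > m`).
#'
#' @inheritParams fitch_steps
#' @param informative_only restrict the ensemble sums to
#'   parsimony-informative characters?
#' @return a `step_accounting` object: a data.frame with columns `char`,
#'   `m`, `s`, `g`, `ci`, `ri` (per-character indices, `NA` where
#'   undefined) and attributes `L`, `CI`, `RI`, `CI_reported`,
#'   `RI_reported`.  `RI` is `NA` when `sum(g) == sum(m)` (no potential
#'   synapomorphy to retain).
#' @export
fit_statistics <- function(tree, x, informative_only = FALSE) {
  s <- fitch_steps(tree, x)
  m <- min_steps(x)
  g <- max_steps(x)
  df <- data.frame(char = seq_len(n_char(x)), m = m, s = s, g = g)
  df$ci <- ifelse(df$s > 0, df$m / df$s, NA_real_)
  df$ri <- ifelse(df$g > df$m, (df$g - df$s) / (df$g - df$m), NA_real_)
  use <- if (informative_only) df$g > df$m else rep(TRUE, nrow(df))
  L <- sum(df$s[use])
  sum_m <- sum(df$m[use])
  sum_g <- sum(df$g[use])
  CI <- if (L > 0) sum_m / L else NA_real_
  RI <- if (sum_g > sum_m) (sum_g - L) / (sum_g - sum_m) else NA_real_
  structure(df, class = c("step_accounting", "data.frame"),
            L = L, sum_m = sum_m, sum_g = sum_g, CI = CI, RI = RI,
            CI_reported = report_index(CI), RI_reported = report_index(RI),
            informative_only = informative_only)
}

# reporting convention: value x 100, rounded half away from zero
report_index <- function(v) {
  if (is.na(v)) return(NA_integer_)
  as.integer(sign(v) * floor(abs(v) * 100 + 0.5))
}

#' @export
print.step_accounting <- function(x, ...) {
  cat(sprintf("tree length L = %d over %d characters%s\n", attr(x, "L"),
              nrow(x),
              if (attr(x, "informative_only")) " (informative only)" else ""))
  cat(sprintf("  sum m = %d, sum g = %d\n", attr(x, "sum_m"),
              attr(x, "sum_g")))
  ri <- attr(x, "RI")
  cat(sprintf("  CI = %.4f (reported %d), RI = %s (reported %s)\n",
              attr(x, "CI"), attr(x, "CI_reported"),
              if (is.na(ri)) "undefined" else sprintf("%.4f", ri),
              if (is.na(ri)) "NA" else attr(x, "RI_reported")))
  invisible(x)
}
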