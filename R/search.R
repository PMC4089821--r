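#' Most parsimonious tree search
#'
#' Three engines share one contract: they return a `search_result` whose
#' `trees` all attain the reported optimal length `L`.
#'
#' * `branch_and_bound()` is exact ("implicit enumeration"): taxa are
#'   added sequentially in a distinctness-sorted order and a partial tree
#'   is abandoned as soon as its length plus an admissible per-character
#'   lower bound (states still to appear) exceeds the incumbent, which is
#'   seeded by stepwise addition plus TBR swapping.  Every binary
#'   most-parsimonious topology is returned.
#' * `exhaustive_search()` scores every topology outright (guarded; the
#'   oracle the branch-and-bound is tested against).
#' * `heuristic_search()` runs seeded random-addition stepwise starts,
#'   each polished by branch swapping; fast but not guaranteed optimal.
#'
#' @param x a [char_matrix]
#' @param order addition order (taxon labels). `NULL`: decreasing
#'   distinctness (characters conflicting with every taxon already
#'   placed), which tightens the bound early.
#' @param incumbent known upper bound on the optimum. `NULL`: obtained by
#'   a short heuristic run.
#' @param maxtrees cap on the number of optimal trees retained (the
#'   result flags `overflow` if hit).
#' @return a `search_result`: list with `trees` (`multiPhylo`, canonical
#'   deduplicated), `L`, `n_evaluated`, `exact`, `overflow`.
#' @examples
#' sim <- simulate_matrix(n_taxa = 8, n_char = 12, seed = 5)
#' res <- branch_and_bound(sim$matrix)
#' res$L
#' @export
branch_and_bound <- function(x, order = NULL, incumbent = NULL,
                             maxtrees = 100000L) {
  n <- n_taxa(x)
  if (n < 4) return(exhaustive_search(x, guard = max(3, n)))
  masks <- fitch_masks(x)
  pk <- pack_columns(masks)
  if (is.null(order)) {
    ord0 <- addition_order(pk)
  } else {
    ord0 <- match(order, x$taxa) - 1L
    if (anyNA(ord0) || length(ord0) != n)
      stop("`order` must be a permutation of the matrix taxa")
  }
  if (is.null(incumbent)) {
    h <- heuristic_search(x, starts = 3, seed = 1, collect_equal = FALSE)
    incumbent <- h$L
  }
  res <- .cpp_bab(pk$full, pk$obs, pk$weights, ord0,
                  incumbent = as.integer(incumbent), use_bound = TRUE,
                  maxtrees = as.integer(maxtrees))
  make_search_result(res$trees, x$taxa, res$L, res$n_evaluated,
                     exact = TRUE, overflow = res$overflow)
}

#' @rdname branch_and_bound
#' @param guard refuse instances with more taxa than this (the number of
#'   topologies is (2n-5)!!)
#' @export
exhaustive_search <- function(x, guard = 10) {
  n <- n_taxa(x)
  if (n < 3) stop("need at least 3 taxa")
  if (n > guard)
    stop(n, " taxa exceed the exhaustive-search guard (", guard, ")")
  masks <- fitch_masks(x)
  pk <- pack_columns(masks)
  res <- .cpp_bab(pk$full, pk$obs, pk$weights, seq_len(n) - 1L,
                  incumbent = .Machine$integer.max %/% 2L,
                  use_bound = FALSE, maxtrees = 2200000L)
  make_search_result(res$trees, x$taxa, res$L, res$n_evaluated,
                     exact = TRUE, overflow = res$overflow)
}

#' @rdname branch_and_bound
#' @param starts number of random-addition starts
#' @param move branch-swapping neighborhood: `"TBR"`, `"SPR"` or `"NNI"`
#' @param seed integer; fully determines the heuristic outcome
#' @param collect_equal also pool equally parsimonious neighbors of the
#'   best local optimum (a cheap plateau sample)
#' @param maxequal cap on the pooled equal-length neighbors
#' @export
heuristic_search <- function(x, starts = 5, move = c("TBR", "SPR", "NNI"),
                             seed = 1, collect_equal = TRUE,
                             maxequal = 50L) {
  move <- match.arg(move)
  n <- n_taxa(x)
  if (n < 3) stop("need at least 3 taxa")
  masks <- fitch_masks(x)
  pk <- pack_columns(masks)
  raw <- with_seed(seed, heuristic_core(pk, n, starts, move, collect_equal,
                                        maxequal))
  make_search_result(raw$trees, x$taxa, raw$L, raw$n_evaluated,
                     exact = FALSE, overflow = FALSE)
}

# core loop, assumes the RNG is already positioned; returns edge matrices
heuristic_core <- function(pk, n, starts, move, collect_equal, maxequal) {
  mv <- match(move, c("NNI", "SPR", "TBR")) - 1L
  bestL <- Inf
  pool <- list()
  neval <- 0
  for (s in seq_len(starts)) {
    ord0 <- sample.int(n) - 1L
    sw <- .cpp_stepwise(pk$full, pk$weights, ord0,
                        seed = sample.int(.Machine$integer.max, 1))
    hc <- .cpp_hillclimb(sw$edge, n, pk$full, pk$weights, mv,
                         collect_equal = FALSE, maxequal = 0L)
    neval <- neval + hc$n_evaluated
    if (hc$L < bestL) {
      bestL <- hc$L
      pool <- list(hc$edge)
    } else if (hc$L == bestL) {
      pool <- c(pool, list(hc$edge))
    }
  }
  if (collect_equal && n >= 4) {
    eq <- .cpp_hillclimb(pool[[1]], n, pk$full, pk$weights, mv,
                         collect_equal = TRUE, maxequal = as.integer(maxequal))
    pool <- c(pool, eq$equal)
  }
  list(trees = pool, L = bestL, n_evaluated = neval)
}

#' @rdname branch_and_bound
#' @export
stepwise_addition <- function(x, order = NULL, seed = 1) {
  n <- n_taxa(x)
  if (n < 3) stop("need at least 3 taxa")
  masks <- fitch_masks(x)
  pk <- pack_columns(masks)
  if (is.null(order)) {
    ord0 <- with_seed(seed, sample.int(n) - 1L)
  } else {
    ord0 <- match(order, x$taxa) - 1L
    if (anyNA(ord0)) stop("`order` must be a permutation of the matrix taxa")
  }
  sw <- .cpp_stepwise(pk$full, pk$weights, ord0, seed = as.integer(seed))
  tr <- as_phylo_edges(sw$edge, x$taxa)
  attr(tr, "L") <- sw$L
  tr
}

#' Branch swapping to a local optimum
#'
#' Hill-climbs from `tree` with the chosen neighborhood until no neighbor
#' is shorter (best-improvement, deterministic tie-break by enumeration
#' order); the result is never longer than the input.
#'
#' @inheritParams fitch_steps
#' @inheritParams heuristic_search
#' @export
branch_swap <- function(tree, x, move = c("TBR", "SPR", "NNI")) {
  move <- match.arg(move)
  mv <- match(move, c("NNI", "SPR", "TBR")) - 1L
  masks <- fitch_masks(x)
  ord <- align_tree_matrix(tree, x)
  pk <- pack_columns(list(full = masks$full[ord, , drop = FALSE],
                          obs = masks$obs[ord, , drop = FALSE]))
  # C++ works in tip-index space of the tree; map back afterwards
  hc <- .cpp_hillclimb(tree$edge, n_taxa(x), pk$full, pk$weights, mv,
                       collect_equal = FALSE, maxequal = 0L)
  tr <- as_phylo_edges(hc$edge, tree$tip.label)
  attr(tr, "L") <- hc$L
  tr
}

# distinctness-sorted addition order (0-based) for branch and bound
addition_order <- function(pk) {
  full <- pk$full
  w <- pk$weights
  n <- nrow(full)
  # pairwise weighted mismatch counts
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- sum(w[bitwAnd(full[i, ], full[j, ]) == 0L])
  placed <- which.max(rowSums(D))
  # conflict[t, c]: does t mismatch every placed taxon at character c?
  conflict <- matrix(TRUE, n, ncol(full))
  repeat {
    p <- placed[length(placed)]
    conflict <- conflict & sweep(full, 2, full[p, ],
                                 function(a, b) bitwAnd(a, b) == 0L)
    if (length(placed) == n) break
    score <- as.vector(conflict %*% w)
    score[placed] <- -1
    placed <- c(placed, which.max(score))
  }
  as.integer(placed - 1L)
}

make_search_result <- function(edges, taxa, L, neval, exact, overflow) {
  trees <- lapply(edges, as_phylo_edges, tip.label = taxa)
  if (length(trees) > 1) {
    key <- vapply(trees, canonical_newick, "")
    o <- order(key)
    trees <- trees[o][!duplicated(sort(key))]
  }
  class(trees) <- "multiPhylo"
  structure(list(trees = trees, L = L, n_evaluated = neval, exact = exact,
                 overflow = overflow),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("%s parsimony search: L = %d, %d optimal tree(s), %s trees scored%s\n",
              if (x$exact) "exact" else "heuristic", x$L, length(x$trees),
              format(x$n_evaluated, big.mark = ","),
              if (x$overflow) " [tree buffer overflowed]" else ""))
  invisible(x)
}
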