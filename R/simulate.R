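#' Simulate a character matrix with a known generating tree
#'
#' Emulates matrices of the shape analysed here — a handful of unordered
#' binary/ternary characters on a modest taxon set, with the first taxon
#' acting as an all-plesiomorphic outgroup (state 0 throughout, the
#' polarization anchor) — under two regimes:
#' \describe{
#'   \item{`clean`}{each character changes exactly once, on one internal
#'     branch of the true tree (never the outgroup's pendant branch).
#'     The first `n_taxa - 3` characters cycle through all internal
#'     branches so the tree is fully recoverable whenever
#'     `n_char >= n_taxa - 3`; the rest draw branches uniformly.  Zero
#'     homoplasy by construction: CI = RI = 1 on the true tree.}
#'   \item{`mk`}{character i receives `1 + rpois(mean_changes - 1)`
#'     changes (so the mean count is `mean_changes`, and no character is
#'     constant), placed on uniformly drawn branches; changes nearer the
#'     root are applied first and deeper ones overwrite within their
#'     subtree.  Derived states are uniform among the states the branch
#'     does not currently carry.  This yields moderate homoplasy without
#'     a rates-on-branch-lengths model, matching parsimony's data model
#'     of cladograms without branch lengths.}
#' }
#'
#' @param n_taxa number of taxa (>= 4); taxon 1 is the outgroup
#' @param n_char number of characters
#' @param n_states state alphabet size (2 or 3)
#' @param regime `"clean"` or `"mk"`
#' @param mean_changes mean change count per character (mk regime)
#' @param missing_taxon,missing_fraction optionally blank out a fraction
#'   of one taxon's cells (the *E. curtulus* pattern)
#' @param seed integer; fully determines the output
#' @return list with `tree` (the true topology, rooted on the outgroup)
#'   and `matrix` (a [char_matrix]).
#' @examples
#' sim <- simulate_matrix(n_taxa = 8, n_char = 10, seed = 1)
#' branch_and_bound(sim$matrix)$L   # 10: one step per character
#' @export
simulate_matrix <- function(n_taxa = 20, n_char = 40, n_states = 3,
                            regime = c("clean", "mk"), mean_changes = 1.5,
                            missing_taxon = NULL, missing_fraction = 0.275,
                            seed = 1) {
  regime <- match.arg(regime)
  stopifnot(n_taxa >= 4, n_char >= 1, n_states %in% c(2, 3),
            mean_changes >= 1)
  taxa <- c("outgroup", sprintf("taxon_%02d", seq_len(n_taxa - 1)))
  with_seed(seed, {
    tree <- random_topology(taxa)
    rtree <- ape::reorder.phylo(reroot_outgroup(tree, "outgroup"),
                                "postorder")
    ntip <- n_taxa
    nn <- max(rtree$edge)
    below <- matrix(FALSE, nn, ntip)
    below[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
    for (k in seq_len(nrow(rtree$edge)))
      below[rtree$edge[k, 1], ] <- below[rtree$edge[k, 1], ] |
        below[rtree$edge[k, 2], ]
    # depth of each edge's child (root = 0), for root-first application
    depth <- integer(nn)
    pre <- ape::reorder.phylo(rtree, "cladewise")$edge
    for (k in seq_len(nrow(pre)))
      depth[pre[k, 2]] <- depth[pre[k, 1]] + 1L
    og <- match("outgroup", rtree$tip.label)
    claden <- rowSums(below)
    # internal branches = those inducing a non-trivial split (n - 3 of them)
    internal_edges <- which(rtree$edge[, 2] > ntip &
                              claden[rtree$edge[, 2]] <= ntip - 2)
    usable_edges <- which(rtree$edge[, 2] != og)  # mk: any non-outgroup branch
    data <- matrix(0L, ntip, n_char)
    for (j in seq_len(n_char)) {
      if (regime == "clean") {
        e <- if (j <= length(internal_edges)) internal_edges[j]
             else internal_edges[sample.int(length(internal_edges), 1)]
        derived <- if (n_states == 2) 1L else sample(1:2, 1)
        data[below[rtree$edge[e, 2], ], j] <- derived
      } else {
        kch <- 1L + rpois(1, mean_changes - 1)
        ee <- usable_edges[sample.int(length(usable_edges), kch,
                                      replace = TRUE)]
        ee <- ee[order(depth[rtree$edge[ee, 2]])]  # rootward first
        state <- rep(0L, ntip)
        for (e in ee) {
          sub <- below[rtree$edge[e, 2], ]
          cur <- state[sub][1]
          alt <- setdiff(0:(n_states - 1), cur)
          state[sub] <- alt[sample.int(length(alt), 1)]
        }
        data[, j] <- state
      }
    }
    rownames(data) <- rtree$tip.label
    m <- char_matrix(data[match(taxa, rtree$tip.label), , drop = FALSE],
                     taxa = taxa)
    if (!is.null(missing_taxon))
      m <- inject_missing(m, missing_taxon, missing_fraction)
    list(tree = rtree, matrix = m)
  })
}

#' Blank out cells of one taxon
#'
#' Sets `round(fraction * n_char)` randomly chosen cells of the named
#' taxon to missing, emulating an incompletely known terminal (the
#' *Ectateus curtulus* row has 11 of 40 cells missing).
#'
#' @param x a [char_matrix]
#' @param taxon taxon label
#' @param fraction fraction of that taxon's cells to blank, in `[0, 1]`
#' @param seed optional integer; `NULL` draws from the caller's RNG
#' @export
inject_missing <- function(x, taxon, fraction, seed = NULL) {
  stopifnot(fraction >= 0, fraction <= 1)
  i <- match(taxon, x$taxa)
  if (is.na(i)) stop("unknown taxon: ", taxon)
  k <- round(fraction * n_char(x))
  pick <- function() sample.int(n_char(x), k)
  if (k > 0) {
    cols <- if (is.null(seed)) pick() else with_seed(seed, pick())
    x$data[i, cols] <- NA_integer_
  }
  x
}
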