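#' Character jackknife resampling of a matrix
#'
#' Deletes each character column independently with probability
#' `p_remove`, keeping all taxa — one pseudoreplicate of the character
#' jackknife.  With 40 characters and the study's p = 0.36, a replicate
#' retains 25.6 characters in expectation.
#'
#' @param x a [char_matrix]
#' @param p_remove per-character deletion probability in `[0, 1]`
#' @param seed optional integer; `NULL` draws from the caller's RNG
#' @return a [char_matrix] with the surviving columns (possibly none:
#'   a degenerate replicate, which [jackknife_support()] redraws).
#' @export
jackknife_matrix <- function(x, p_remove, seed = NULL) {
  stopifnot(p_remove >= 0, p_remove <= 1)
  pick <- function() which(runif(n_char(x)) >= p_remove)
  keep <- if (is.null(seed)) pick() else with_seed(seed, pick())
  x[, keep]
}

#' Jackknife clade support
#'
#' Estimates support for every clade as the percentage of character-
#' deletion pseudoreplicates whose inferred trees contain it ("absolute
#' frequencies"): each replicate deletes characters with probability
#' `p_remove`, runs a seeded heuristic search (random-addition stepwise
#' starts polished by branch swapping, plus a plateau sample of equally
#' parsimonious neighbors), and contributes the splits of the strict
#' consensus of its best trees.  Replicates that lose every character are
#' redrawn from a fresh substream and counted in attribute `"redrawn"`.
#'
#' The run is reproducible bit for bit from (`seed`, configuration):
#' one master seed spawns an independent substream per replicate, so any
#' single replicate can be reproduced in isolation.
#'
#' @param x a [char_matrix]
#' @param p_remove per-character deletion probability (study value 0.36)
#' @param replicates number of pseudoreplicates (study value 2000)
#' @param seed master seed
#' @param starts,move per-replicate search configuration (see
#'   [heuristic_search()])
#' @param floor report threshold: `print()` hides splits below this
#'   support (all entries stay in the table)
#' @return a `support_table`: data.frame with columns `split` (canonical
#'   key), `members` (list of taxa), `size`, and `support` (percent),
#'   sorted by decreasing support; configuration in attributes.
#' @export
jackknife_support <- function(x, p_remove = 0.36, replicates = 2000,
                              seed = 1, starts = 5,
                              move = c("TBR", "SPR", "NNI"), floor = 50) {
  move <- match.arg(move)
  stopifnot(replicates >= 1, p_remove >= 0, p_remove < 1)
  mv <- match(move, c("NNI", "SPR", "TBR")) - 1L
  n <- n_taxa(x)
  labs <- x$taxa
  refidx <- which(labs == sort(labs)[1])
  masks <- fitch_masks(x)
  counts <- new.env(parent = emptyenv())
  subseeds <- with_seed(seed,
                        sample.int(.Machine$integer.max - 1L, replicates))
  redrawn <- 0L
  for (r in seq_len(replicates)) {
    splits <- with_seed(subseeds[r], {
      keep <- which(runif(n_char(x)) >= p_remove)
      tries <- 0L
      while (!length(keep)) {  # degenerate: empty matrix supports nothing
        redrawn <- redrawn + 1L
        tries <- tries + 1L
        if (tries > 1000L) stop("p_remove too close to 1: no characters survive")
        keep <- which(runif(n_char(x)) >= p_remove)
      }
      pk <- pack_columns(list(full = masks$full[, keep, drop = FALSE],
                              obs = masks$obs[, keep, drop = FALSE]))
      res <- heuristic_core(pk, n, starts, move, collect_equal = TRUE,
                            maxequal = 20L)
      keysets <- lapply(res$trees, edge_split_keys, ntip = n, labs = labs,
                        refidx = refidx)
      Reduce(intersect, keysets)  # replicate strict consensus
    })
    for (k in splits)
      counts[[k]] <- (if (is.null(counts[[k]])) 0L else counts[[k]]) + 1L
  }
  keys <- ls(counts)
  support <- vapply(keys, function(k) counts[[k]], 0L) * 100 / replicates
  o <- order(-support, keys)
  out <- data.frame(split = keys[o], support = unname(support[o]),
                    stringsAsFactors = FALSE)
  out$members <- strsplit(out$split, "|", fixed = TRUE)
  out$size <- lengths(out$members)
  structure(out[, c("split", "members", "size", "support")],
            class = c("support_table", "data.frame"),
            p_remove = p_remove, replicates = replicates, seed = seed,
            starts = starts, move = move, floor = floor, redrawn = redrawn)
}

#' @export
print.support_table <- function(x, ...) {
  cat(sprintf(
    "jackknife support: %d replicates, p_remove = %.2f, seed = %d\n",
    attr(x, "replicates"), attr(x, "p_remove"), attr(x, "seed")))
  floor <- attr(x, "floor")
  show <- x[x$support >= floor, , drop = FALSE]
  cat(sprintf("  %d split(s) at or above the %g%% report floor (of %d seen)\n",
              nrow(show), floor, nrow(x)))
  for (i in seq_len(nrow(show)))
    cat(sprintf("  %5.1f  {%s}\n", show$support[i],
                paste(show$members[[i]], collapse = ", ")))
  invisible(x)
}

#' Query a support table for one clade
#'
#' @param tab a [jackknife_support()] table
#' @param members taxon labels of the clade
#' @param all_taxa full taxon set the table was computed over
#' @return support percentage (0 if the split was never seen).
#' @export
clade_support <- function(tab, members, all_taxa) {
  ref <- sort(all_taxa)[1]
  side <- if (ref %in% members) setdiff(all_taxa, members) else members
  key <- paste(sort(side), collapse = "|")
  hit <- match(key, tab$split)
  if (is.na(hit)) 0 else tab$support[hit]
}

# split keys straight from a C++ edge matrix (root = ntip+1, BFS order):
# reversing the rows makes every child row precede its parent's row
edge_split_keys <- function(edge, ntip, labs, refidx) {
  nn <- max(edge)
  below <- matrix(FALSE, nn, ntip)
  below[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  for (k in rev(seq_len(nrow(edge))))
    below[edge[k, 1], ] <- below[edge[k, 1], ] | below[edge[k, 2], ]
  keys <- character()
  if (nn < ntip + 2) return(keys)
  for (node in (ntip + 2):nn) {
    side <- below[node, ]
    if (side[refidx]) side <- !side
    sz <- sum(side)
    if (sz >= 2 && sz <= ntip - 2)
      keys <- c(keys, paste(sort(labs[side]), collapse = "|"))
  }
  unique(keys)
}

#' Consensus trees
#'
#' `strict_consensus()` keeps exactly the splits present in every input
#' tree; `majority_consensus()` keeps those above the given frequency
#' threshold (0.5 = classic majority rule; 1.0 coincides with the strict
#' consensus).  Both may return multifurcating trees.
#'
#' @param trees a `multiPhylo` (or list of `phylo`) on one leaf set
#' @export
strict_consensus <- function(trees) {
  trees <- as_multiphylo(trees)
  if (length(trees) == 1) return(trees[[1]])
  ape::consensus(trees, p = 1, rooted = FALSE)
}

#' @rdname strict_consensus
#' @param threshold minimum split frequency, in `[0.5, 1]`
#' @export
majority_consensus <- function(trees, threshold = 0.5) {
  stopifnot(threshold >= 0.5, threshold <= 1)
  trees <- as_multiphylo(trees)
  if (length(trees) == 1) return(trees[[1]])
  ape::consensus(trees, p = threshold, rooted = FALSE)
}

as_multiphylo <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) stop("no trees given")
  class(trees) <- "multiPhylo"
  trees
}
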