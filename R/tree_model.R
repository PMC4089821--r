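#' Cladogram I/O and canonical serialization
#'
#' Trees throughout the package are `ape` `phylo` cladograms: leaf-labeled
#' topologies without branch lengths.  `read_newick()` parses one Newick
#' string or file; `write_newick()` serializes, optionally in a canonical
#' rotation (children ordered by the lexicographically smallest leaf label
#' in their subtree, tree anchored on the smallest leaf) so that two
#' representations of the same unrooted topology always produce identical
#' text.
#'
#' @param text Newick text (alternative to `file`).
#' @param file path to a Newick file.
#' @return `read_newick()`: a `phylo`; `write_newick()`: a character
#'   scalar (invisibly, if `file` is given).
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text)) text <- paste(readLines(file, warn = FALSE),
                                   collapse = "")
  nopen <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  nclose <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (nopen != nclose)
    stop("unbalanced parentheses in Newick text")
  phy <- ape::read.tree(text = text)
  if (is.null(phy)) stop("could not parse Newick text")
  if (anyDuplicated(phy$tip.label))
    stop("duplicate leaf label: ",
         phy$tip.label[duplicated(phy$tip.label)][1])
  phy
}

#' @rdname read_newick
#' @param tree a `phylo`
#' @param canonical rotate into the canonical form before writing?
#' @export
write_newick <- function(tree, canonical = FALSE, file = NULL) {
  tree$edge.length <- NULL
  tree$node.label <- tree$node.label  # kept as-is (support annotations)
  out <- if (canonical) canonical_newick(tree) else ape::write.tree(tree)
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

# adjacency list (over ape node ids) from an edge matrix
phylo_adjacency <- function(tree) {
  nn <- max(tree$edge)
  adj <- vector("list", nn)
  for (k in seq_len(nrow(tree$edge))) {
    a <- tree$edge[k, 1]; b <- tree$edge[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

#' Canonical Newick text of a topology
#'
#' A total order on unrooted topologies: two trees are the same topology
#' iff their canonical text is identical.  The tree is (re)anchored at the
#' lexicographically smallest leaf and every internal node's children are
#' sorted by the smallest leaf label in their subtree.  Branch lengths and
#' internal labels are dropped.
#'
#' @param tree a `phylo`
#' @return a character scalar ending in `";"`.
#' @export
canonical_newick <- function(tree) {
  labs <- tree$tip.label
  ntip <- length(labs)
  if (ntip == 1) return(paste0(labs, ";"))
  if (ntip >= 3) tree <- ape::unroot(tree)  # rooting carries no information
  adj <- phylo_adjacency(tree)
  anchor <- which(labs == sort(labs)[1])
  ser <- function(node, parent) {
    if (node <= ntip) return(list(txt = labs[node], key = labs[node]))
    kids <- setdiff(adj[[node]], parent)
    parts <- lapply(kids, ser, parent = node)
    keys <- vapply(parts, `[[`, "", "key")
    o <- order(keys)
    list(txt = paste0("(", paste(vapply(parts[o], `[[`, "", "txt"),
                                 collapse = ","), ")"),
         key = keys[o][1])
  }
  if (ntip == 2) {
    o <- sort(labs)
    return(paste0("(", o[1], ",", o[2], ");"))
  }
  top <- ser(adj[[anchor]][1], anchor)
  paste0("(", labs[anchor], ",", substr(top$txt, 2, nchar(top$txt)), ";")
}

#' Root a cladogram on its outgroup
#'
#' Returns the rooted view with the outgroup taxon sister to all remaining
#' taxa; the underlying unrooted topology (and hence every parsimony
#' score) is unchanged.
#'
#' @param tree a `phylo`
#' @param outgroup a leaf label present in `tree`
#' @export
reroot_outgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label)
    stop("outgroup '", outgroup, "' is not a leaf of the tree")
  tree$edge.length <- NULL
  ape::root(ape::unroot(tree), outgroup = outgroup, resolve.root = TRUE)
}

#' Non-trivial bipartitions of a tree
#'
#' Every internal edge of an unrooted tree splits the leaves in two; the
#' canonical key of a split is the sorted, `"|"`-joined member list of the
#' side *not* containing the alphabetically first leaf.  Trivial splits
#' (single leaves) are excluded.  A binary unrooted tree on n leaves has
#' exactly n - 3 of them.
#'
#' @param tree a `phylo` (rooted or not; rooting does not affect the set)
#' @return sorted character vector of split keys.
#' @seealso [has_clade()]
#' @export
bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  if (ntip < 4) return(character())
  labs <- tree$tip.label
  ref <- sort(labs)[1]
  tree <- ape::reorder.phylo(tree, "postorder")
  nn <- max(tree$edge)
  below <- matrix(FALSE, nn, ntip)
  below[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  for (k in seq_len(nrow(tree$edge))) {
    e <- tree$edge[k, ]
    below[e[1], ] <- below[e[1], ] | below[e[2], ]
  }
  keys <- character()
  for (node in (ntip + 1):nn) {
    side <- labs[below[node, ]]
    if (ref %in% side) side <- setdiff(labs, side)
    if (length(side) >= 2 && length(side) <= ntip - 2)
      keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  sort(unique(keys))
}

#' @rdname bipartitions
#' @param members leaf labels forming the putative clade
#' @return `has_clade()`: `TRUE` iff the split separating `members` from
#'   the remaining leaves is an edge of the tree.
#' @export
has_clade <- function(tree, members) {
  labs <- tree$tip.label
  if (!all(members %in% labs))
    stop("unknown taxa: ", paste(setdiff(members, labs), collapse = ", "))
  ref <- sort(labs)[1]
  side <- if (ref %in% members) setdiff(labs, members) else members
  paste(sort(side), collapse = "|") %in% bipartitions(tree)
}

# build a phylo from an ape-style edge matrix produced by the C++ engine
as_phylo_edges <- function(edge, tip.label) {
  phy <- structure(list(edge = edge, Nnode = max(edge) - length(tip.label),
                        tip.label = tip.label), class = "phylo")
  ape::reorder.phylo(phy, "cladewise")
}

#' Enumerate all unrooted binary topologies
#'
#' Yields every distinct leaf-labeled unrooted binary tree on the given
#' leaves, each exactly once; there are (2n-5)!! of them.  Intended as the
#' ground-truth enumeration behind exhaustive search and as a test oracle.
#' Because the count explodes ((2*10-5)!! = 2,027,025), `guard` refuses
#' larger leaf sets.
#'
#' @param taxa leaf labels (3 or more)
#' @param guard hard ceiling on the number of leaves (default 10)
#' @return a `multiPhylo` list of trees.
#' @examples
#' length(enumerate_topologies(letters[1:5]))  # 15
#' @export
enumerate_topologies <- function(taxa, guard = 10) {
  n <- length(taxa)
  if (n < 3) stop("need at least 3 leaves")
  if (n > guard)
    stop(n, " leaves exceed the enumeration guard (", guard,
         "): (2n-5)!! topologies would be generated")
  const <- matrix(1L, n, 1)
  res <- .cpp_bab(const, const, 1L, seq_len(n) - 1L,
                  incumbent = .Machine$integer.max %/% 2L,
                  use_bound = FALSE, maxtrees = 2200000L)
  trees <- lapply(res$trees, as_phylo_edges, tip.label = taxa)
  class(trees) <- "multiPhylo"
  trees
}

#' Uniform random unrooted binary topology
#'
#' Draws a topology uniformly at random over all (2n-5)!! leaf-labeled
#' unrooted binary trees, by sequential insertion of each leaf on a
#' uniformly chosen edge of the growing tree.
#'
#' @param taxa leaf labels
#' @param seed optional integer; when given, the draw is a pure function
#'   of it (the caller's RNG state is untouched).
#' @export
random_topology <- function(taxa, seed = NULL) {
  n <- length(taxa)
  if (n < 3) stop("need at least 3 leaves")
  draw <- function() {
    edge <- rbind(c(n + 1L, 1L), c(n + 1L, 2L), c(n + 1L, 3L))
    if (n > 3) for (k in 4:n) {
      i <- sample.int(nrow(edge), 1)
      w <- n + k - 2L
      u <- edge[i, 1]; v <- edge[i, 2]
      edge[i, ] <- c(u, w)
      edge <- rbind(edge, c(w, v), c(w, k))
    }
    as_phylo_edges(edge, taxa)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# evaluate expr under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
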