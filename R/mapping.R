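# Ancestral-state reconstruction and synapomorphy mapping.
#
# All quantities derive from a unit-cost Sankoff dynamic program per
# character: D[v, s] = minimal subtree cost with node v in state s
# (down pass), E[v, s] = minimal cost of the rest of the tree with v in
# state s (up pass).  A state belongs to the MPR set of v iff
# D[v,s] + E[v,s] equals the character's minimal length; an edge carries
# a required change iff no most-parsimonious reconstruction assigns its
# endpoints equal states.

# per-character DP tables on a rooted binary tree (postorder-sorted)
char_dp <- function(tree, x, j) {
  ntip <- length(tree$tip.label)
  nn <- max(tree$edge)
  root <- ntip + 1L
  col <- x$data[match(tree$tip.label, x$taxa), j]
  pm <- x$poly[x$poly$char == j, , drop = FALSE]
  states <- sort(unique(c(col[!is.na(col)], unlist(pm$states))))
  if (!length(states)) return(NULL)  # all-missing column
  S <- length(states)
  INF <- 1e9
  allowed <- matrix(TRUE, ntip, S)
  obs <- match(col, states)
  for (i in seq_len(ntip)) if (!is.na(obs[i])) {
    allowed[i, ] <- FALSE
    allowed[i, obs[i]] <- TRUE
  }
  if (nrow(pm)) for (k in seq_len(nrow(pm))) {
    i <- match(pm$taxon[k], tree$tip.label)
    allowed[i, ] <- FALSE
    allowed[i, match(pm$states[[k]], states)] <- TRUE
  }
  kids <- vector("list", nn)
  for (k in seq_len(nrow(tree$edge)))
    kids[[tree$edge[k, 1]]] <- c(kids[[tree$edge[k, 1]]], tree$edge[k, 2])
  D <- matrix(INF, nn, S)
  tipcost <- matrix(INF, ntip, S)
  tipcost[allowed] <- 0
  D[seq_len(ntip), ] <- tipcost
  # edge matrix is postorder-sorted: every parent appears after all edges
  # of its subtree, so visiting parents in edge order is bottom-up
  for (u in unique(tree$edge[, 1])) {
    val <- rep(0, S)
    for (c2 in kids[[u]]) val <- val + pmin(D[c2, ], min(D[c2, ]) + 1)
    D[u, ] <- val
  }
  E <- matrix(INF, nn, S)
  E[root, ] <- 0
  # preorder sweep
  ord <- root
  i <- 1
  while (i <= length(ord)) {
    u <- ord[i]; i <- i + 1
    for (v in kids[[u]]) {
      sibs <- setdiff(kids[[u]], v)
      A <- E[u, ]
      for (w in sibs) A <- A + pmin(D[w, ], min(D[w, ]) + 1)
      E[v, ] <- pmin(A, min(A) + 1)
      if (v > ntip) ord <- c(ord, v)
    }
  }
  list(states = states, D = D, E = E, L = min(D[root, ]), kids = kids,
       root = root, ntip = ntip)
}

prep_rooted <- function(tree, x, outgroup) {
  if (!is.null(outgroup)) tree <- reroot_outgroup(tree, outgroup)
  if (!ape::is.binary(tree))
    stop("mapping requires a binary (rooted) tree")
  ape::reorder.phylo(tree, "postorder")
}

#' Most-parsimonious ancestral state sets
#'
#' For each character and each node of the rooted tree, the set of states
#' that node takes in at least one most-parsimonious reconstruction
#' (unit-cost unordered characters; missing leaves admit every observed
#' state).  Rooting on the outgroup performs the character polarization:
#' the root's set is driven by the outgroup's states.
#'
#' @param tree a binary `phylo`; rooted on `outgroup` if given
#' @param x a [char_matrix]
#' @param outgroup optional taxon label to root on
#' @return a list with one element per character: a nodes-by-states
#'   logical matrix (MPR sets), with the character's minimal length in
#'   attribute `"steps"`.  All-missing characters yield `NULL`.
#' @export
ancestral_sets <- function(tree, x, outgroup = NULL) {
  tree <- prep_rooted(tree, x, outgroup)
  lapply(seq_len(n_char(x)), function(j) {
    dp <- char_dp(tree, x, j)
    if (is.null(dp)) return(NULL)
    m <- (dp$D + dp$E) == dp$L
    colnames(m) <- dp$states
    attr(m, "steps") <- dp$L
    m
  })
}

# joint edge analysis for one character: which edges must change, which
# may, and with which (from, to) state pairs
edge_changes_char <- function(tree, dp) {
  res <- list()
  INF <- 1e9
  for (k in seq_len(nrow(tree$edge))) {
    u <- tree$edge[k, 1]; v <- tree$edge[k, 2]
    sibs <- setdiff(dp$kids[[u]], v)
    A <- dp$E[u, ]
    for (w in sibs) A <- A + pmin(dp$D[w, ], min(dp$D[w, ]) + 1)
    # J[t, s] = cost of the whole tree with u = t and v = s
    J <- outer(A, dp$D[v, ], `+`) + 1 - diag(length(dp$states))
    minEq <- min(A + dp$D[v, ])   # no change on the edge
    Jne <- J
    diag(Jne) <- INF
    minNe <- min(Jne)             # some change on the edge
    if (minNe > dp$L) next          # this edge never changes
    required <- minEq > dp$L
    pairs <- which(Jne == dp$L, arr.ind = TRUE)
    res[[length(res) + 1]] <- list(
      edge = k, node = v, required = required,
      from = if (nrow(pairs) == 1) dp$states[pairs[1, 1]] else NA_integer_,
      to = if (nrow(pairs) == 1) dp$states[pairs[1, 2]] else NA_integer_,
      to_set = sort(unique(dp$states[pairs[, 2]])))
  }
  res
}

#' Branch-by-branch character state transformations
#'
#' Maps character changes onto the branches of the rooted tree.  The
#' default `"unambiguous"` view lists exactly the changes present in
#' *every* most-parsimonious reconstruction (the mapping style of the
#' published tree figure); `"acctran"`/`"deltran"` list the changes of a
#' single reconstruction preferring, at ties, early (rootward) or late
#' (tipward) transformations respectively.
#'
#' @inheritParams ancestral_sets
#' @param mapping `"unambiguous"`, `"acctran"` or `"deltran"`
#' @return a `reconstruction_map`: data.frame with columns `char`, `node`
#'   (the branch's child node in the returned tree, available as
#'   attribute `"tree"`), `clade` (leaf set below the branch), `from`,
#'   `to` (`NA` when not uniquely determined), and for the unambiguous
#'   mapping nothing else is listed than required changes.
#' @export
unambiguous_changes <- function(tree, x, outgroup = NULL,
                                mapping = c("unambiguous", "acctran",
                                            "deltran")) {
  mapping <- match.arg(mapping)
  tree <- prep_rooted(tree, x, outgroup)
  ntip <- length(tree$tip.label)
  nn <- max(tree$edge)
  below <- matrix(FALSE, nn, ntip)
  below[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  for (k in seq_len(nrow(tree$edge)))
    below[tree$edge[k, 1], ] <- below[tree$edge[k, 1], ] | below[tree$edge[k, 2], ]
  clade_of <- function(node)
    paste(sort(tree$tip.label[below[node, ]]), collapse = "|")
  rows <- list()
  for (j in seq_len(n_char(x))) {
    dp <- char_dp(tree, x, j)
    if (is.null(dp) || dp$L == 0) next
    if (mapping == "unambiguous") {
      for (ch in edge_changes_char(tree, dp)) {
        if (!ch$required) next
        rows[[length(rows) + 1]] <- data.frame(
          char = j, node = ch$node, clade = clade_of(ch$node),
          from = ch$from, to = ch$to)
      }
    } else {
      st <- traceback_states(tree, dp, prefer_change = mapping == "acctran")
      for (k in seq_len(nrow(tree$edge))) {
        u <- tree$edge[k, 1]; v <- tree$edge[k, 2]
        if (st[u] != st[v])
          rows[[length(rows) + 1]] <- data.frame(
            char = j, node = v, clade = clade_of(v),
            from = dp$states[st[u]], to = dp$states[st[v]])
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(char = integer(), node = integer(),
                         clade = character(), from = integer(),
                         to = integer())
  structure(out, class = c("reconstruction_map", "data.frame"),
            tree = tree, mapping = mapping)
}

# one most-parsimonious assignment by preorder traceback; prefer_change
# breaks cost ties toward (ACCTRAN) or away from (DELTRAN) a change
traceback_states <- function(tree, dp, prefer_change) {
  nn <- nrow(dp$D)
  st <- integer(nn)
  rootcand <- which(dp$D[dp$root, ] == min(dp$D[dp$root, ]))
  st[dp$root] <- rootcand[1]
  ord <- dp$root
  i <- 1
  while (i <= length(ord)) {
    u <- ord[i]; i <- i + 1
    for (v in dp$kids[[u]]) {
      A <- dp$D[v, ] + (seq_along(dp$states) != st[u])
      cand <- which(A == min(A))
      eq <- cand[cand == st[u]]
      ne <- cand[cand != st[u]]
      st[v] <- if (prefer_change) {
        if (length(ne)) ne[1] else eq[1]
      } else {
        if (length(eq)) eq[1] else ne[1]
      }
      if (v > dp$ntip) ord <- c(ord, v)
    }
  }
  st
}

#' Flag mapped changes as homoplasious or not
#'
#' A change is non-homoplasious (a clean synapomorphy, the published
#' figure's black circle) iff its character needs no extra steps on this
#' tree: observed steps equal the character's theoretical minimum.
#' Otherwise every change of that character is flagged homoplasious
#' (white circle).
#'
#' @param map a [unambiguous_changes()] result
#' @param accounting a [fit_statistics()] result on the same tree/matrix
#' @return the map with a logical `homoplasy` column added.
#' @export
classify_homoplasy <- function(map, accounting) {
  extra <- accounting$s > accounting$m
  map$homoplasy <- extra[map$char]
  map
}

#' Diagnostic character changes of a clade
#'
#' Lists every character with an unambiguous change on the clade's stem
#' branch of the rooted tree, with the derived state and a homoplasy
#' flag — the per-clade synapomorphy/homoplasy lists of a cladistic
#' Results section.
#'
#' @inheritParams ancestral_sets
#' @param clade leaf labels of the clade (must be a clade of the rooted
#'   tree; otherwise an error, distinct from an empty diagnosis)
#' @return a `clade_diagnosis`: list with `clade`, `supporting`
#'   (data.frame `char`, `from`, `to`, `homoplasy`).
#' @export
diagnose_clade <- function(tree, x, clade, outgroup = NULL) {
  rtree <- prep_rooted(tree, x, outgroup)
  map <- unambiguous_changes(rtree, x, outgroup = NULL)
  map <- classify_homoplasy(map, fit_statistics(rtree, x))
  key <- paste(sort(clade), collapse = "|")
  if (!all(clade %in% rtree$tip.label))
    stop("unknown taxa in clade: ",
         paste(setdiff(clade, rtree$tip.label), collapse = ", "))
  hit <- map[map$clade == key, , drop = FALSE]
  # clade presence check independent of whether any change maps there
  ntip <- length(rtree$tip.label)
  present <- key %in% c(vapply(
    (ntip + 1):max(rtree$edge), function(node) {
      tips <- ape::extract.clade(rtree, node)$tip.label
      paste(sort(tips), collapse = "|")
    }, ""))
  if (!present)
    stop("clade {", paste(clade, collapse = ", "),
         "} is not a clade of the tree")
  structure(list(clade = sort(clade),
                 supporting = hit[, c("char", "from", "to", "homoplasy")]),
            class = "clade_diagnosis")
}

#' @export
print.clade_diagnosis <- function(x, ...) {
  cat("clade {", paste(x$clade, collapse = ", "), "}\n", sep = "")
  if (!nrow(x$supporting)) {
    cat("  no unambiguous stem changes\n")
    return(invisible(x))
  }
  s <- x$supporting
  cat(paste0("  ", ifelse(s$homoplasy, "homoplasy    ", "synapomorphy "),
             s$char, ":", ifelse(is.na(s$to), "?", s$to),
             collapse = "\n"), "\n")
  invisible(x)
}
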