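# Brute-force oracles and small fixtures shared across tests.
# The oracles deliberately share no code with the package's engines.

# minimal changes for one character on a tree by exhaustive enumeration of
# all ancestral (and missing-leaf) state assignments
brute_force_steps <- function(tree, states_by_tip, alphabet) {
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  nn <- max(edge)
  free <- c(which(lengths(states_by_tip) != 1), (ntip + 1):nn)
  fixed <- setdiff(seq_len(ntip), free)
  assign0 <- integer(nn)
  for (i in fixed) assign0[i] <- states_by_tip[[i]]
  choices <- lapply(free, function(i)
    if (i <= ntip) states_by_tip[[i]] else alphabet)
  best <- Inf
  grid_walk <- function(k, cur) {
    if (k > length(free)) {
      cost <- sum(cur[edge[, 1]] != cur[edge[, 2]])
      if (cost < best) best <<- cost
      return(invisible())
    }
    for (s in choices[[k]]) {
      cur[free[k]] <- s
      grid_walk(k + 1, cur)
    }
  }
  grid_walk(1, assign0)
  best
}

# set of states each node attains across all minimum-cost assignments
brute_force_mpr_sets <- function(tree, states_by_tip, alphabet) {
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  nn <- max(edge)
  free <- c(which(lengths(states_by_tip) != 1), (ntip + 1):nn)
  fixed <- setdiff(seq_len(ntip), free)
  assign0 <- integer(nn)
  for (i in fixed) assign0[i] <- states_by_tip[[i]]
  choices <- lapply(free, function(i)
    if (i <= ntip) states_by_tip[[i]] else alphabet)
  best <- Inf
  hits <- list()
  grid_walk <- function(k, cur) {
    if (k > length(free)) {
      cost <- sum(cur[edge[, 1]] != cur[edge[, 2]])
      if (cost < best) {
        best <<- cost
        hits <<- list(cur)
      } else if (cost == best) {
        hits[[length(hits) + 1]] <<- cur
      }
      return(invisible())
    }
    for (s in choices[[k]]) {
      cur[free[k]] <- s
      grid_walk(k + 1, cur)
    }
  }
  grid_walk(1, assign0)
  sets <- lapply(seq_len(nn), function(i)
    sort(unique(vapply(hits, `[`, 0L, i))))
  list(steps = best, sets = sets)
}

# score a whole matrix on a tree with the assignment oracle
brute_force_length <- function(tree, x) {
  ord <- match(tree$tip.label, x$taxa)
  sum(vapply(seq_len(n_char(x)), function(j) {
    col <- x$data[ord, j]
    alphabet <- sort(unique(col[!is.na(col)]))
    if (length(alphabet) < 2) return(0L)
    sbt <- lapply(col, function(v) if (is.na(v)) alphabet else v)
    as.integer(brute_force_steps(tree, sbt, alphabet))
  }, 0L))
}

# random char_matrix with controllable shape
random_matrix <- function(n_taxa, n_char, n_states = 2, p_missing = 0) {
  data <- matrix(sample(0:(n_states - 1), n_taxa * n_char, replace = TRUE),
                 n_taxa, n_char)
  if (p_missing > 0)
    data[runif(length(data)) < p_missing] <- NA_integer_
  char_matrix(data, taxa = paste0("t", seq_len(n_taxa)))
}

canonical_set <- function(trees) sort(vapply(trees, canonical_newick, ""))

# tiny worked example used in several files: 6 taxa, known structure
toy_matrix <- function() {
  char_matrix(rbind(
    A = c(0, 0, 0, 0, 1),
    B = c(0, 0, 1, 0, 0),
    C = c(1, 0, 1, 0, 0),
    D = c(1, 1, 0, 1, 0),
    E = c(1, 1, 0, 1, 0),
    F = c(0, 1, 0, NA, 0)))
}
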