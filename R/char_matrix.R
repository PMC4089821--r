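#' Discrete morphological character matrix
#'
#' Container for a taxa-by-characters matrix of discrete unordered states.
#' States are small non-negative integers (codes 0, 1, 2, ...); missing
#' entries ("?" in all file dialects) are `NA`.  Polymorphic cells
#' (several states observed in one taxon) are supported for I/O
#' round-tripping and Fitch scoring via the `poly` slot; they do not occur
#' in the packaged *Ectateus*/*Selinus* matrix.
#'
#' @param data integer matrix (taxa in rows, characters in columns),
#'   `NA` for missing.  A character matrix of single-digit codes is
#'   accepted and converted.
#' @param taxa taxon labels; defaults to `rownames(data)`.  Must be
#'   unique, non-empty strings.
#' @param char_meta optional `data.frame` of per-character metadata with
#'   at least a `description` column; row order is character order.
#' @param poly optional `data.frame` with columns `taxon`, `char` and a
#'   list-column `states` describing polymorphic cells.
#' @return an object of class `char_matrix`.
#' @examples
#' m <- char_matrix(rbind(A = c(0, 1, 0), B = c(0, NA, 1), C = c(1, 1, 1)))
#' n_taxa(m)
#' column_profile(m, 2)
#' @export
char_matrix <- function(data, taxa = rownames(data), char_meta = NULL,
                        poly = NULL) {
  if (is.character(data)) {
    dm <- dim(data)
    data[data == "?"] <- NA
    data <- matrix(as.integer(data), dm[1], dm[2])
  }
  if (!is.matrix(data)) stop("`data` must be a matrix")
  storage.mode(data) <- "integer"
  if (is.null(taxa)) stop("taxon labels are required")
  taxa <- as.character(taxa)
  if (length(taxa) != nrow(data))
    stop("length of `taxa` does not match the number of rows")
  if (anyDuplicated(taxa))
    stop("duplicate taxon label: ", taxa[duplicated(taxa)][1])
  if (any(!nzchar(taxa))) stop("empty taxon label")
  if (any(data < 0, na.rm = TRUE)) stop("negative state codes are not allowed")
  rownames(data) <- taxa
  colnames(data) <- NULL
  if (!is.null(char_meta)) {
    char_meta <- as.data.frame(char_meta)
    if (nrow(char_meta) != ncol(data))
      stop("`char_meta` must have one row per character")
  }
  if (is.null(poly)) {
    poly <- data.frame(taxon = character(), char = integer())
    poly$states <- list()
  }
  structure(list(taxa = taxa, data = data, char_meta = char_meta,
                 poly = poly),
            class = "char_matrix")
}

#' @rdname char_matrix
#' @param x a `char_matrix`
#' @export
n_taxa <- function(x) length(x$taxa)

#' @rdname char_matrix
#' @export
n_char <- function(x) ncol(x$data)

#' @export
print.char_matrix <- function(x, ...) {
  cat(sprintf("char_matrix: %d taxa x %d characters, %d missing cell(s)\n",
              n_taxa(x), n_char(x), sum(is.na(x$data))))
  if (nrow(x$poly)) cat(sprintf("  %d polymorphic cell(s)\n", nrow(x$poly)))
  cat("  taxa: ", paste(head(x$taxa, 4), collapse = ", "),
      if (n_taxa(x) > 4) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
`[.char_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(n_taxa(x))
  if (missing(j)) j <- seq_len(n_char(x))
  if (is.character(i)) i <- match(i, x$taxa)
  if (anyNA(i)) stop("unknown taxon")
  dat <- x$data[i, j, drop = FALSE]
  meta <- if (!is.null(x$char_meta)) x$char_meta[j, , drop = FALSE]
  char_matrix(dat, taxa = x$taxa[i], char_meta = meta)
}

#' @exportS3Method base::all.equal
all.equal.char_matrix <- function(target, current, ...) {
  if (!identical(target$taxa, current$taxa)) return("taxon labels differ")
  if (!identical(unname(target$data), unname(current$data)))
    return("cell values differ")
  TRUE
}

#' Per-character state profile
#'
#' Summarises one character column over its non-missing cells: the set of
#' observed state codes, the number of taxa bearing each state, and the
#' number of scored (non-missing) taxa.  Polymorphic cells are excluded
#' from the counts (none occur in the packaged matrix).
#'
#' @param x a [char_matrix]
#' @param index 1-based character index
#' @return a list of class `character_column` with elements `index`,
#'   `observed_states`, `counts` and `n_observed`.
#' @export
column_profile <- function(x, index) {
  index <- as.integer(index)
  if (length(index) != 1 || is.na(index) || index < 1 || index > n_char(x))
    stop("character index out of range: ", index)
  col <- x$data[, index]
  pm <- x$poly$taxon[x$poly$char == index]
  col[x$taxa %in% pm] <- NA
  obs <- col[!is.na(col)]
  counts <- if (length(obs)) table(factor(obs, levels = sort(unique(obs))))
            else table(integer())
  structure(list(index = index,
                 observed_states = sort(unique(obs)),
                 counts = as.integer(counts),
                 states = as.integer(names(counts)),
                 n_observed = length(obs)),
            class = "character_column")
}

#' @export
print.character_column <- function(x, ...) {
  cat(sprintf("character %d: %d scored taxa; states {%s}\n", x$index,
              x$n_observed, paste(x$observed_states, collapse = ",")))
  if (length(x$states))
    cat("  counts: ",
        paste(sprintf("%d:%d", x$states, x$counts), collapse = "  "), "\n")
  invisible(x)
}

# ---- internal: bitmask views used by the Fitch engine -----------------------

# full: missing/polymorphic cells carry the union of the column's observed
# states (the standard Fitch treatment of "?"); obs: missing = 0, used for
# the branch-and-bound lower bound where only required states may count.
fitch_masks <- function(x) {
  dat <- x$data
  nch <- ncol(dat)
  full <- obs <- matrix(0L, nrow(dat), nch)
  for (j in seq_len(nch)) {
    col <- dat[, j]
    colmask <- ifelse(is.na(col), 0L, bitwShiftL(1L, col))
    alphabet <- Reduce(bitwOr, colmask, 0L)
    if (alphabet == 0L) alphabet <- 1L  # all-missing column: arbitrary state
    obs[, j] <- colmask
    full[, j] <- ifelse(colmask == 0L, alphabet, colmask)
  }
  if (nrow(x$poly)) {
    for (k in seq_len(nrow(x$poly))) {
      i <- match(x$poly$taxon[k], x$taxa)
      j <- x$poly$char[k]
      mask <- Reduce(bitwOr, bitwShiftL(1L, x$poly$states[[k]]), 0L)
      full[i, j] <- mask
      obs[i, j] <- 0L  # uncertainty: contributes no required state
    }
  }
  rownames(full) <- rownames(obs) <- x$taxa
  list(full = full, obs = obs)
}

# collapse identical columns into weighted unique patterns (search speedup)
pack_columns <- function(masks) {
  key <- apply(masks$full, 2, paste, collapse = ",")
  keep <- !duplicated(key)
  w <- as.integer(table(factor(key, levels = key[keep])))
  list(full = masks$full[, keep, drop = FALSE],
       obs = masks$obs[, keep, drop = FALSE],
       weights = w)
}
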