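#' Read a character matrix from NEXUS, TNT/Hennig86 or a delimited table
#'
#' Dialects are deliberately small, matching how morphological matrices
#' circulate in practice:
#' \describe{
#'   \item{`nexus`}{`#NEXUS` file with a `CHARACTERS` (or `DATA`) block,
#'     `FORMAT SYMBOLS="012" MISSING=?`, and a `MATRIX` of rows
#'     `label states`.  Labels may be quoted (`'Zidalus latipes'`).
#'     Symbol order in `SYMBOLS` maps to integer codes 0, 1, 2, ...}
#'   \item{`tnt`}{Hennig86-style `xread ['title'] nchar ntax` followed by
#'     rows of `label statestring`, terminated by `;`.}
#'   \item{`table`}{one row per taxon: label, then one column per
#'     character, tab- or whitespace-separated.}
#' }
#' `?` denotes missing in every dialect.  Polymorphic cells are accepted
#' as `(01)`/`{01}` (NEXUS), `[01]` (TNT) or `0/1` (table).
#'
#' @param file path to the input file.
#' @param text literal document text (alternative to `file`).
#' @param format one of `"nexus"`, `"tnt"`, `"table"`; `NULL` auto-detects
#'   from the document head.
#' @return a [char_matrix].
#' @seealso [write_char_matrix()], [load_ectateus_matrix()]
#' @export
read_char_matrix <- function(file = NULL, text = NULL, format = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("supply `file` or `text`")
    text <- readLines(file, warn = FALSE)
  } else if (length(text) == 1) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  if (is.null(format)) {
    head1 <- toupper(trimws(text[nzchar(trimws(text))][1]))
    format <- if (startsWith(head1, "#NEXUS")) "nexus"
              else if (startsWith(head1, "XREAD")) "tnt"
              else "table"
  }
  format <- match.arg(format, c("nexus", "tnt", "table"))
  switch(format,
         nexus = parse_nexus(text),
         tnt = parse_tnt(text),
         table = parse_table(text))
}

#' Serialize a character matrix
#'
#' The writer is the exact inverse of [read_char_matrix()]: for every
#' dialect, re-reading the written document reproduces the taxon labels
#' and every cell (including missing and polymorphic marks) bit-exactly.
#'
#' @param x a [char_matrix]
#' @param format `"nexus"`, `"tnt"` or `"table"`
#' @param file optional path; when `NULL` the document is returned as a
#'   character scalar.
#' @export
write_char_matrix <- function(x, format = c("nexus", "tnt", "table"),
                              file = NULL) {
  format <- match.arg(format)
  smax <- suppressWarnings(max(x$data, na.rm = TRUE))
  if (is.finite(smax) && smax > 9)
    stop("state codes above 9 exceed the single-symbol dialects")
  doc <- switch(format,
                nexus = emit_nexus(x),
                tnt = emit_tnt(x),
                table = emit_table(x))
  if (!is.null(file)) {
    writeLines(doc, file)
    return(invisible(doc))
  }
  paste(doc, collapse = "\n")
}

#' The published Ectateus/Selinus character matrix
#'
#' Loads the packaged 20-taxon, 40-character morphological matrix for the
#' darkling beetle genera *Ectateus* and *Selinus* plus four outgroup taxa
#' (*Zidalus latipes* is the most distant outgroup used for character
#' polarization).  States are 0/1/2; the only taxon with missing cells is
#' *Ectateus curtulus* (11 of 40, known from a single female specimen).
#' Per-character descriptions ride along in `char_meta`.
#'
#' The packaged file is checksummed at load time; a corrupted fixture
#' raises an error naming the offending row.
#'
#' @return a [char_matrix] with 20 taxa and 40 characters.
#' @examples
#' m <- load_ectateus_matrix()
#' n_taxa(m); n_char(m)
#' @export
load_ectateus_matrix <- function() {
  path <- system.file("extdata", "ectateus_selinus.tnt", package = "cladistR",
                      mustWork = TRUE)
  x <- read_char_matrix(path, format = "tnt")
  csum <- row_checksums(x)
  ref <- ectateus_row_checksums
  bad <- names(ref)[is.na(csum[names(ref)]) | csum[names(ref)] != ref]
  if (length(bad) || n_taxa(x) != 20 || n_char(x) != 40)
    stop("packaged matrix failed its integrity check at row: ",
         paste(bad, collapse = ", "))
  meta_path <- system.file("extdata", "ectateus_characters.tsv",
                           package = "cladistR", mustWork = TRUE)
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  x$char_meta <- meta
  x
}

# simple per-row additive checksum over state codes (NA -> 3)
row_checksums <- function(x) {
  d <- x$data
  d[is.na(d)] <- 3L
  pos <- seq_len(ncol(d))
  setNames(as.integer(d %*% (pos * 7L + 1L)) %% 99991L, x$taxa)
}

# ---- parsing helpers --------------------------------------------------------

# split a state string into per-cell tokens, honouring bracketed sets
tokenize_states <- function(s, open, close, line) {
  s <- gsub("[[:space:]]", "", s)
  out <- character()
  i <- 1
  n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch %in% open) {
      j <- regexpr(sprintf("[%s]", paste(close, collapse = "")),
                   substr(s, i + 1, n))
      if (j < 0) stop("line ", line, ": unterminated state set")
      out <- c(out, substr(s, i + 1, i + j - 1))
      i <- i + j + 1
    } else {
      out <- c(out, ch)
      i <- i + 1
    }
  }
  out
}

cells_from_tokens <- function(rows, labels, symbols, lines) {
  ntax <- length(rows)
  nch <- length(rows[[1]])
  lens <- lengths(rows)
  if (any(lens != nch)) {
    bad <- which(lens != nch)[1]
    stop("line ", lines[bad], ": row '", labels[bad], "' has ", lens[bad],
         " cells; expected ", nch)
  }
  code_of <- function(tok, line) {
    v <- match(strsplit(tok, "", fixed = TRUE)[[1]], symbols) - 1L
    if (anyNA(v))
      stop("line ", line, ": unknown state symbol in '", tok, "'")
    v
  }
  data <- matrix(NA_integer_, ntax, nch)
  poly <- list()
  for (i in seq_len(ntax)) {
    for (j in seq_len(nch)) {
      tok <- rows[[i]][j]
      if (tok == "?") next
      v <- code_of(tok, lines[i])
      if (length(v) == 1) data[i, j] <- v
      else poly[[length(poly) + 1]] <- list(taxon = labels[i], char = j,
                                            states = sort(v))
    }
  }
  pdf <- data.frame(taxon = vapply(poly, `[[`, "", "taxon"),
                    char = vapply(poly, `[[`, 0L, "char"))
  pdf$states <- lapply(poly, `[[`, "states")
  char_matrix(data, taxa = labels, poly = pdf)
}

parse_tnt <- function(lines) {
  txt <- trimws(lines)
  start <- which(toupper(substr(txt, 1, 5)) == "XREAD")
  if (!length(start)) stop("not a TNT xread document")
  body <- paste(lines[start[1]:length(lines)], collapse = "\n")
  body <- sub("(?i)^\\s*xread\\s*", "", body, perl = TRUE)
  body <- sub("^'[^']*'\\s*", "", body)  # optional title
  hdr <- regmatches(body, regexec("^\\s*(\\d+)\\s+(\\d+)", body))[[1]]
  if (length(hdr) != 3) stop("malformed xread header (need nchar ntax)")
  nch <- as.integer(hdr[2]); ntax <- as.integer(hdr[3])
  body <- sub("^\\s*\\d+\\s+\\d+", "", body)
  semi <- regexpr(";", body, fixed = TRUE)
  if (semi < 0) stop("xread block not terminated by ';'")
  rowtext <- strsplit(trimws(substr(body, 1, semi - 1)), "\n")[[1]]
  rowtext <- rowtext[nzchar(trimws(rowtext))]
  labels <- character(); rows <- list(); lineno <- integer()
  for (k in seq_along(rowtext)) {
    parts <- strsplit(trimws(rowtext[k]), "[[:space:]]+")[[1]]
    lab <- parts[1]
    states <- paste(parts[-1], collapse = "")
    idx <- match(lab, labels)
    if (is.na(idx)) {
      labels <- c(labels, lab)
      rows[[length(labels)]] <- tokenize_states(states, "[", "]", k)
      lineno <- c(lineno, k)
    } else {  # interleaved continuation
      rows[[idx]] <- c(rows[[idx]], tokenize_states(states, "[", "]", k))
    }
  }
  if (length(labels) != ntax)
    stop("xread declares ", ntax, " taxa but ", length(labels), " rows found")
  x <- cells_from_tokens(rows, labels, symbols = as.character(0:9),
                         lines = lineno)
  if (n_char(x) != nch)
    stop("xread declares ", nch, " characters but rows carry ", n_char(x))
  x
}

parse_nexus <- function(lines) {
  txt <- paste(lines, collapse = "\n")
  if (!grepl("^\\s*#NEXUS", txt, ignore.case = TRUE))
    stop("not a NEXUS document")
  blk <- regmatches(txt, regexec(
    "(?is)BEGIN\\s+(?:CHARACTERS|DATA)\\s*;(.*?)END\\s*;", txt, perl = TRUE))[[1]]
  if (length(blk) < 2) stop("no CHARACTERS block found")
  blk <- blk[2]
  symbols <- as.character(0:9)
  sm <- regmatches(blk, regexec('(?is)SYMBOLS\\s*=\\s*"([^"]*)"', blk,
                                perl = TRUE))[[1]]
  if (length(sm) == 2)
    symbols <- strsplit(gsub("\\s", "", sm[2]), "")[[1]]
  missing_sym <- "?"
  mm <- regmatches(blk, regexec("(?is)MISSING\\s*=\\s*(\\S)", blk,
                                perl = TRUE))[[1]]
  if (length(mm) == 2) missing_sym <- mm[2]
  mat <- regmatches(blk, regexec("(?is)MATRIX(.*?);", blk, perl = TRUE))[[1]]
  if (length(mat) < 2 || !nzchar(trimws(mat[2])))
    stop("empty or missing MATRIX in CHARACTERS block")
  rowtext <- strsplit(mat[2], "\n")[[1]]
  rowtext <- rowtext[nzchar(trimws(rowtext))]
  labels <- character(); rows <- list(); lineno <- integer()
  for (k in seq_along(rowtext)) {
    line <- trimws(rowtext[k])
    if (startsWith(line, "'")) {
      close <- regexpr("'", substr(line, 2, nchar(line)), fixed = TRUE)
      if (close < 0) stop("line ", k, ": unterminated quoted label")
      lab <- substr(line, 2, close)
      states <- trimws(substr(line, close + 2, nchar(line)))
    } else {
      parts <- regmatches(line, regexec("^(\\S+)\\s+(.*)$", line))[[1]]
      if (length(parts) != 3) stop("line ", k, ": malformed matrix row")
      lab <- parts[2]; states <- parts[3]
    }
    states <- gsub(missing_sym, "?", states, fixed = TRUE)
    idx <- match(lab, labels)
    if (is.na(idx)) {
      labels <- c(labels, lab)
      rows[[length(labels)]] <- tokenize_states(states, c("(", "{"),
                                                c(")", "}"), k)
      lineno <- c(lineno, k)
    } else {
      rows[[idx]] <- c(rows[[idx]], tokenize_states(states, c("(", "{"),
                                                    c(")", "}"), k))
    }
  }
  if (!length(labels)) stop("empty MATRIX in CHARACTERS block")
  cells_from_tokens(rows, labels, symbols, lineno)
}

parse_table <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty table")
  labels <- character(); rows <- list()
  for (k in seq_along(lines)) {
    parts <- strsplit(trimws(lines[k]), "[\t ]+")[[1]]
    if (length(parts) < 2) stop("line ", k, ": need label plus cells")
    if (parts[1] %in% labels) stop("line ", k, ": duplicate taxon '",
                                   parts[1], "'")
    labels <- c(labels, parts[1])
    cells <- parts[-1]
    cells <- gsub("/", "", cells, fixed = TRUE)  # 0/1 polymorphism
    rows[[k]] <- cells
  }
  cells_from_tokens(rows, labels, symbols = as.character(0:9),
                    lines = seq_along(lines))
}

# ---- emitters ---------------------------------------------------------------

cell_token <- function(x, i, j, open, close, sep = "") {
  hit <- which(x$poly$taxon == x$taxa[i] & x$poly$char == j)
  if (length(hit))
    return(paste0(open, paste(x$poly$states[[hit[1]]], collapse = sep), close))
  v <- x$data[i, j]
  if (is.na(v)) "?" else as.character(v)
}

row_string <- function(x, i, open, close, sep = "") {
  paste(vapply(seq_len(n_char(x)), function(j)
    cell_token(x, i, j, open, close, sep), ""), collapse = "")
}

emit_tnt <- function(x) {
  labs <- gsub(" ", "_", x$taxa)
  if (anyDuplicated(labs)) stop("labels collide after space substitution")
  c(sprintf("xread '%s' %d %d", "character matrix", n_char(x), n_taxa(x)),
    sprintf("%-*s %s", max(nchar(labs)), labs,
            vapply(seq_len(n_taxa(x)), function(i)
              row_string(x, i, "[", "]"), "")),
    ";")
}

emit_nexus <- function(x) {
  smax <- max(1L, suppressWarnings(max(x$data, na.rm = TRUE)))
  quote_lab <- function(l) if (grepl("[] '(){};[]", l))
    paste0("'", l, "'") else l
  labs <- vapply(x$taxa, quote_lab, "")
  c("#NEXUS",
    "BEGIN TAXA;",
    sprintf("  DIMENSIONS NTAX=%d;", n_taxa(x)),
    paste0("  TAXLABELS ", paste(labs, collapse = " "), ";"),
    "END;",
    "BEGIN CHARACTERS;",
    sprintf("  DIMENSIONS NCHAR=%d;", n_char(x)),
    sprintf('  FORMAT SYMBOLS="%s" MISSING=?;',
            paste(0:smax, collapse = "")),
    "  MATRIX",
    sprintf("  %-*s %s", max(nchar(labs)), labs,
            vapply(seq_len(n_taxa(x)), function(i)
              row_string(x, i, "(", ")"), "")),
    "  ;",
    "END;")
}

emit_table <- function(x) {
  vapply(seq_len(n_taxa(x)), function(i) {
    cells <- vapply(seq_len(n_char(x)), function(j)
      cell_token(x, i, j, "", "", sep = "/"), "")
    paste(c(x$taxa[i], cells), collapse = "\t")
  }, "")
}
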