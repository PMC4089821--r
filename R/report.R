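#' Named clades of the Ectateus/Selinus analysis
#'
#' The groupings named in the Results of the original study, as taxon
#' sets over the packaged matrix: the redefined *Ectateus* and *Selinus*
#' clades, their species groups (modestus, villiersi, convexipennis,
#' planus), and the smaller subclades discussed in the text.  Used by
#' [reproduce_analysis()] for the clade-by-clade diagnosis report.
#'
#' @return named list of character vectors of taxon labels.
#' @export
ectateus_clades <- function() {
  list(
    ectateus_selinus = c(
      "Ectateus_crenatus", "Ectateus_curtulus", "Ectateus_ghesquierei",
      "Ectateus_modestus", "Selinus_calcaripes", "Ectateus_ursynowiensis",
      "Ectateus_villiersi", "Ectateus_laevistriatus", "Ectateus_lamottei",
      "Selinus_convexipennis", "Selinus_gravis", "Selinus_malaisei",
      "Selinus_medius", "Selinus_plicicollis", "Selinus_planus",
      "Selinus_striatus"),
    ectateus_clade = c(
      "Ectateus_crenatus", "Ectateus_curtulus", "Ectateus_ghesquierei",
      "Ectateus_modestus", "Selinus_calcaripes", "Ectateus_ursynowiensis",
      "Ectateus_villiersi"),
    selinus_clade = c(
      "Ectateus_laevistriatus", "Ectateus_lamottei", "Selinus_convexipennis",
      "Selinus_gravis", "Selinus_malaisei", "Selinus_medius",
      "Selinus_plicicollis", "Selinus_planus", "Selinus_striatus"),
    modestus_group = c(
      "Ectateus_crenatus", "Ectateus_curtulus", "Ectateus_ghesquierei",
      "Ectateus_modestus", "Selinus_calcaripes"),
    modestus_core = c(  # E. curtulus sister to these four
      "Ectateus_crenatus", "Ectateus_ghesquierei", "Ectateus_modestus",
      "Selinus_calcaripes"),
    ghesquierei_crenatus = c("Ectateus_ghesquierei", "Ectateus_crenatus"),
    modestus_calcaripes = c("Ectateus_modestus", "Selinus_calcaripes"),
    villiersi_group = c("Ectateus_ursynowiensis", "Ectateus_villiersi"),
    convexipennis_group = c(
      "Selinus_convexipennis", "Selinus_gravis", "Ectateus_laevistriatus",
      "Ectateus_lamottei", "Selinus_malaisei", "Selinus_medius",
      "Selinus_plicicollis"),
    convexipennis_core = c(  # S. gravis sister to these six
      "Selinus_convexipennis", "Ectateus_laevistriatus", "Ectateus_lamottei",
      "Selinus_malaisei", "Selinus_medius", "Selinus_plicicollis"),
    malaisei_trio = c("Selinus_malaisei", "Selinus_medius",
                      "Selinus_plicicollis"),
    convexipennis_trio = c("Selinus_convexipennis", "Ectateus_laevistriatus",
                           "Ectateus_lamottei"),
    planus_group = c("Selinus_planus", "Selinus_striatus")
  )
}

#' Reproduce the full Ectateus/Selinus cladistic analysis
#'
#' One call drives the whole pipeline on the packaged matrix: exact
#' branch-and-bound search under equal weights, step accounting with
#' ensemble CI/RI, jackknife support (p = 0.36), and synapomorphy/
#' homoplasy diagnoses for every named clade on the figure-matching
#' most-parsimonious tree (the optimum containing the largest number of
#' named clades), rooted on *Zidalus latipes*.
#'
#' @param seed master seed for the jackknife
#' @param replicates jackknife pseudoreplicates (study value 2000; lower
#'   it for a quick look)
#' @param p_remove jackknife deletion probability
#' @param outdir optional directory: writes `mpt.nwk` (figure-matching
#'   tree), `consensus.nwk` (strict consensus of all optima),
#'   `step_accounting.tsv`, `support.tsv` and `summary.txt`
#' @return an `analysis_report` list: `matrix_summary`, `search`,
#'   `accounting`, `support`, `tree` (figure-matching MPT, rooted),
#'   `diagnoses`, `config`.
#' @export
reproduce_analysis <- function(seed = 1, replicates = 2000,
                               p_remove = 0.36, outdir = NULL) {
  x <- load_ectateus_matrix()
  outgroup <- "Zidalus_latipes"
  clades <- ectateus_clades()

  search <- branch_and_bound(x)
  n_named <- vapply(search$trees, function(tr)
    sum(vapply(clades, function(cl) has_clade(tr, cl), TRUE)), 0)
  best <- search$trees[[which.max(n_named)]]
  rtree <- reroot_outgroup(best, outgroup)
  accounting <- fit_statistics(best, x)

  support <- jackknife_support(x, p_remove = p_remove,
                               replicates = replicates, seed = seed)

  diagnoses <- lapply(clades, function(cl) {
    if (has_clade(best, cl)) diagnose_clade(rtree, x, cl) else NULL
  })

  rep <- structure(list(
    matrix_summary = list(taxa = n_taxa(x), characters = n_char(x),
                          missing = sum(is.na(x$data))),
    search = search,
    accounting = accounting,
    support = support,
    tree = rtree,
    consensus = strict_consensus(search$trees),
    diagnoses = diagnoses,
    config = list(seed = seed, replicates = replicates,
                  p_remove = p_remove, outgroup = outgroup)),
    class = "analysis_report")

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_newick(rtree, file = file.path(outdir, "mpt.nwk"))
    write_newick(rep$consensus, file = file.path(outdir, "consensus.nwk"))
    acc <- as.data.frame(accounting)
    write.table(acc, file.path(outdir, "step_accounting.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    sup <- data.frame(split = support$split, size = support$size,
                      support = support$support)
    write.table(sup, file.path(outdir, "support.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeLines(utils::capture.output(print(rep)),
               file.path(outdir, "summary.txt"))
  }
  rep
}

#' @export
print.analysis_report <- function(x, ...) {
  ms <- x$matrix_summary
  cat(sprintf("matrix: %d taxa x %d characters (%d missing cells)\n",
              ms$taxa, ms$characters, ms$missing))
  print(x$search)
  print(x$accounting)
  cat(sprintf("jackknife: %d replicates, p = %.2f\n",
              attr(x$support, "replicates"), attr(x$support, "p_remove")))
  clades <- ectateus_clades()
  for (nm in names(x$diagnoses)) {
    d <- x$diagnoses[[nm]]
    sup <- clade_support(x$support, clades[[nm]],
                         all_taxa = x$tree$tip.label)
    if (is.null(d)) {
      cat(sprintf("%-22s not on the reported tree (jackknife %.0f)\n",
                  nm, sup))
      next
    }
    s <- d$supporting
    lab <- if (nrow(s)) paste0(
      ifelse(s$homoplasy, "hom ", "syn "), s$char, ":",
      ifelse(is.na(s$to), "?", s$to), collapse = ", ") else "-"
    cat(sprintf("%-22s jackknife %5.1f  %s\n", nm, sup, lab))
  }
  invisible(x)
}
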