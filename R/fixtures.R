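#' Specification for a synthetic validation fixture
#'
#' Describes a synthetic study: a universe of genes with standard-normal
#' association statistics, a collection of chemicals each annotated with a
#' random gene set, and a subset of "planted" chemicals whose member
#' statistics are shifted upward by `effect_delta` so that their sets
#' concentrate at the top of a signed ranking. The defaults describe the
#' planted-signal validation condition used throughout the package's tests:
#' 1000 genes, 50 chemicals with 20-gene sets, one planted chemical with a
#' shift of 2 (in Z-score units).
#'
#' @param n_genes Number of genes in the universe.
#' @param n_chemicals Number of chemicals (gene sets).
#' @param set_size_range Length-2 integer vector, inclusive bounds on set
#'   sizes (drawn uniformly per chemical). Sizes must lie in
#'   `[1, n_genes - 1]`.
#' @param planted_chemical_count Number of chemicals carrying a planted
#'   signal.
#' @param effect_delta Additive shift applied to planted members'
#'   statistics, in units of the standard-normal noise SD.
#' @param seed Integer RNG seed; fixtures are byte-reproducible from it.
#' @return A `cgsea_fixture_spec` list.
#' @export
fixture_spec <- function(n_genes = 1000L, n_chemicals = 50L,
                         set_size_range = c(20L, 20L),
                         planted_chemical_count = 1L,
                         effect_delta = 2, seed = 1L) {
  if (length(set_size_range) != 2L || any(set_size_range < 1L) ||
      set_size_range[2L] < set_size_range[1L] ||
      set_size_range[2L] > n_genes - 1L) {
    cgsea_config_error(
      "set_size_range must be increasing and lie within [1, n_genes - 1]")
  }
  if (planted_chemical_count > n_chemicals || planted_chemical_count < 0L) {
    cgsea_config_error(
      "planted_chemical_count must lie in [0, n_chemicals]")
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_chemicals = as.integer(n_chemicals),
                 set_size_range = as.integer(set_size_range),
                 planted_chemical_count = as.integer(planted_chemical_count),
                 effect_delta = effect_delta,
                 seed = as.integer(seed)),
            class = "cgsea_fixture_spec")
}

#' Generate a synthetic annotation + statistics fixture
#'
#' Emits the same dialects the parsers consume: a CTD-style chemical-gene
#' annotation file (organism 9606, interaction action
#' `increases^expression`), a generic two-column gene-statistic TSV, and a
#' truth table listing the planted chemicals. Gene statistics are drawn
#' from a standard normal; each planted chemical then has `effect_delta`
#' added to its members' statistics (membership is drawn before the shift,
#' so only planted sets are associated with the statistics). Planted and
#' decoy sets may overlap, as real chemical annotations do; the truth table
#' is the arbiter.
#'
#' @param spec A [fixture_spec()].
#' @param dir Directory to write into (created if needed). File contents
#'   depend only on `spec`, so the same spec yields byte-identical files.
#' @return List with paths `annotations`, `stats`, `truth`, the `dir`, the
#'   `spec`, and `planted_keys` (chemical IDs carrying signal).
#' @export
make_fixture <- function(spec = fixture_spec(),
                         dir = tempfile("cgsea_fixture_")) {
  stopifnot(inherits(spec, "cgsea_fixture_spec"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(spec$seed)

  genes <- sprintf("G%05d", seq_len(spec$n_genes))
  stats <- rnorm(spec$n_genes)
  chem_names <- sprintf("chem%03d", seq_len(spec$n_chemicals))
  chem_ids <- sprintf("D%06d", seq_len(spec$n_chemicals))

  sizes <- if (spec$set_size_range[1L] == spec$set_size_range[2L]) {
    rep(spec$set_size_range[1L], spec$n_chemicals)
  } else {
    sample(seq.int(spec$set_size_range[1L], spec$set_size_range[2L]),
           spec$n_chemicals, replace = TRUE)
  }
  members <- lapply(sizes, function(s) sort(sample.int(spec$n_genes, s)))
  planted <- if (spec$planted_chemical_count > 0L) {
    sort(sample.int(spec$n_chemicals, spec$planted_chemical_count))
  } else integer()

  for (i in planted) stats[members[[i]]] <- stats[members[[i]]] +
    spec$effect_delta

  paths <- c(annotations = file.path(dir, "annotations.tsv"),
             stats = file.path(dir, "stats.tsv"),
             truth = file.path(dir, "truth.tsv"))

  header <- paste0("# ", paste(c("ChemicalName", "ChemicalID", "CasRN",
                                 "GeneSymbol", "GeneID", "GeneForms",
                                 "Organism", "OrganismID", "Interaction",
                                 "InteractionActions", "PubMedIDs"),
                               collapse = "\t"))
  rows <- unlist(lapply(seq_len(spec$n_chemicals), function(i) {
    g <- genes[members[[i]]]
    paste(chem_names[i], chem_ids[i], "", g, as.character(members[[i]]),
          "gene", "Homo sapiens", "9606",
          paste0(chem_names[i], " affects expression of ", g),
          "increases^expression", "12345",
          sep = "\t")
  }))
  writeLines(c(header, rows), paths[["annotations"]])

  writeLines(c("gene\tstatistic",
               paste(genes, format(stats, digits = 15, trim = TRUE,
                                   scientific = FALSE), sep = "\t")),
             paths[["stats"]])

  writeLines(c("chemical_id\tchemical_name\teffect_delta\tset_size",
               if (length(planted))
                 paste(chem_ids[planted], chem_names[planted],
                       spec$effect_delta, sizes[planted], sep = "\t")),
             paths[["truth"]])

  list(annotations = paths[["annotations"]], stats = paths[["stats"]],
       truth = paths[["truth"]], dir = dir, spec = spec,
       planted_keys = chem_ids[planted])
}
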