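#' Read a CTD-style chemical-gene interaction file
#'
#' Parses the Comparative Toxicogenomics Database `chem_gene_ixns`
#' tab-separated dialect: lines starting with `#` are header/comment lines,
#' and data rows carry at least the 11 canonical columns (ChemicalName,
#' ChemicalID, CasRN, GeneSymbol, GeneID, GeneForms, Organism, OrganismID,
#' Interaction, InteractionActions, PubMedIDs). Gzip-compressed files are
#' read transparently.
#'
#' Records are restricted to the organisms in `organism_filter` (by NCBI
#' taxonomy ID equality; rows with an empty or unlisted OrganismID are
#' dropped). Gene symbols are whitespace-stripped and uppercased on ingest,
#' which doubles as the mouse-to-human symbol harmonization: no ortholog
#' table is consulted, a documented simplification.
#'
#' @param path Path to a `chem_gene_ixns`-dialect TSV (optionally `.gz`).
#' @param organism_filter Character vector of NCBI taxonomy IDs to keep.
#'   Default `c("9606", "10090")`: human and mouse.
#' @param expression_only If `TRUE`, keep only rows whose InteractionActions
#'   string mentions `"expression"` (e.g. `increases^expression`); the
#'   default keeps every interaction type.
#'
#' @return A `data.table` with one row per retained interaction record and
#'   columns `chemical_name`, `chemical_id`, `gene_symbol`, `gene_id`,
#'   `organism_id`, `interaction_actions`. Malformed rows (fewer than 11
#'   fields, or an empty chemical key or gene symbol) are skipped with a
#'   single counted warning; the count is also available as
#'   `attr(x, "n_skipped")`.
#' @seealso [build_gene_sets()] to turn records into per-chemical gene sets.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c(
#'   "# ChemicalName\tChemicalID\tCasRN\tGeneSymbol\tGeneID\tGeneForms\tOrganism\tOrganismID\tInteraction\tInteractionActions\tPubMedIDs",
#'   "benzene\tD001554\t71-43-2\tJun\t3725\tgene\tMus musculus\t10090\tx\tincreases^expression\t1"),
#'   tf)
#' read_ctd(tf)
read_ctd <- function(path, organism_filter = c("9606", "10090"),
                     expression_only = FALSE) {
  stopifnot(is.character(organism_filter), length(organism_filter) >= 1L)
  lines <- read_input_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]

  empty <- data.table(chemical_name = character(), chemical_id = character(),
                      gene_symbol = character(), gene_id = character(),
                      organism_id = character(),
                      interaction_actions = character())
  if (length(lines) == 0L) {
    setattr(empty, "n_skipped", 0L)
    return(empty)
  }

  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 11L
  fields <- fields[!short]

  pick <- function(i) vapply(fields, `[[`, character(1L), i)
  rec <- if (length(fields)) {
    data.table(chemical_name       = pick(1L),
               chemical_id         = trimws(pick(2L)),
               gene_symbol         = toupper(trimws(pick(4L))),
               gene_id             = trimws(pick(5L)),
               organism_id         = trimws(pick(8L)),
               interaction_actions = pick(10L))
  } else {
    copy(empty)
  }

  # rows violating the record invariants are malformed, not silently dropped
  bad_key <- !nzchar(rec$chemical_id) & !nzchar(trimws(rec$chemical_name))
  bad_sym <- !nzchar(rec$gene_symbol)
  n_skipped <- sum(short) + sum(bad_key | bad_sym)
  if (n_skipped > 0L) {
    warning(sprintf("read_ctd: skipped %d malformed row(s) in '%s'",
                    n_skipped, path), call. = FALSE)
  }
  rec <- rec[!(bad_key | bad_sym)]

  rec <- rec[organism_id %chin% organism_filter]
  if (isTRUE(expression_only)) {
    rec <- rec[grepl("expression", interaction_actions, fixed = TRUE)]
  }
  setattr(rec, "n_skipped", n_skipped)
  rec[]
}

#' Build chemical gene sets from interaction records
#'
#' Groups interaction records by chemical and collapses duplicate
#' (chemical, gene) pairs into set membership. The chemical key is the
#' ChemicalID (MeSH-style accession) when present, else the chemical name;
#' both are kept. Grouping does not depend on record order.
#'
#' @param records A record table as returned by [read_ctd()].
#' @param min_size,max_size Inclusive bounds on set size; sets outside the
#'   bounds are dropped. `min_size` must be at least 1; `max_size` may be
#'   `Inf`.
#'
#' @return A named list (sorted by chemical key) of `cgsea_gene_set`
#'   objects, each a list with `chemical_key`, `chemical_name`, `members`
#'   (sorted unique uppercase gene symbols) and `size`.
#' @export
build_gene_sets <- function(records, min_size = 5L, max_size = Inf) {
  if (!is.numeric(min_size) || length(min_size) != 1L || min_size < 1) {
    cgsea_config_error("min_size must be a single integer >= 1")
  }
  if (!is.numeric(max_size) || length(max_size) != 1L || max_size < min_size) {
    cgsea_config_error("max_size must be >= min_size")
  }
  rec <- as.data.table(records)
  if (nrow(rec) == 0L) return(structure(list(), names = character()))

  rec[, chemical_key := fifelse(nzchar(chemical_id), chemical_id,
                                chemical_name)]
  # lexicographically smallest display name per key: order-independent
  grouped <- rec[, .(chemical_name = min(chemical_name),
                     members = list(sort(unique(gene_symbol)))),
                 by = chemical_key]
  setorder(grouped, chemical_key)

  sets <- lapply(seq_len(nrow(grouped)), function(i) {
    members <- grouped$members[[i]]
    structure(list(chemical_key  = grouped$chemical_key[i],
                   chemical_name = grouped$chemical_name[i],
                   members       = members,
                   size          = length(members)),
              class = "cgsea_gene_set")
  })
  names(sets) <- grouped$chemical_key
  sizes <- vapply(sets, `[[`, integer(1L), "size")
  sets[sizes >= min_size & sizes <= max_size]
}

#' Restrict a gene set to a gene universe
#'
#' The enrichment score is defined only over genes present in the ranked
#' list, so each set is intersected with that universe before scoring. A
#' restricted size of zero is allowed here; downstream code decides whether
#' to skip the chemical.
#'
#' @param gene_set A `cgsea_gene_set` (see [build_gene_sets()]).
#' @param universe Non-empty character vector of gene symbols.
#' @return The gene set with `members` replaced by the intersection, `size`
#'   updated, and the pre-restriction size in `original_size`.
#' @export
restrict_to_universe <- function(gene_set, universe) {
  stopifnot(inherits(gene_set, "cgsea_gene_set"))
  if (length(universe) == 0L) {
    cgsea_config_error("universe must be non-empty")
  }
  kept <- gene_set$members[gene_set$members %chin% universe]
  gene_set$original_size <- gene_set$size
  gene_set$members <- kept
  gene_set$size <- length(kept)
  gene_set
}

#' @export
print.cgsea_gene_set <- function(x, ...) {
  cat(sprintf("<cgsea_gene_set> %s (%s): %d gene(s)\n",
              x$chemical_key, x$chemical_name, x$size))
  invisible(x)
}

#' Export gene sets in GMT format
#'
#' One line per chemical: key, description (the chemical name), then the
#' member gene symbols, tab-separated. GMT is the common gene-set exchange
#' format, so exported sets can be fed to other enrichment tools.
#'
#' @param gene_sets Named list of `cgsea_gene_set` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(gene_sets, function(gs) {
    paste(c(gs$chemical_key, gs$chemical_name, gs$members), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
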