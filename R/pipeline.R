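#' Run the full chemical enrichment pipeline
#'
#' End-to-end orchestration: parse the chemical-gene annotation, build one
#' gene set per chemical, read and collapse the gene-level statistics, rank
#' the genes, restrict every set to the ranked universe, and score each
#' testable set (enrichment score, shared permutation null, NES, empirical
#' P, BH q). Chemicals that cannot be tested are never silently dropped:
#' every chemical in the annotation ends up exactly once in either the
#' results or the skipped table, with a reason.
#'
#' @param annotation_path CTD-dialect chemical-gene interaction file.
#' @param stats_paths One or more gene-statistic files. Format is detected
#'   per file (a header containing `TWAS.Z` means FUSION output, anything
#'   else is read as a generic two-column table) unless forced via
#'   `stats_format`.
#' @param config A [cgsea_config()]; defaults are `w = 1` and 5000
#'   permutations.
#' @param stats_format `"auto"`, `"fusion"` or `"generic"`.
#' @return A `cgsea_run` list: `results` (a `data.table` sorted by
#'   empirical P ascending, ties by `|NES|` descending then chemical key),
#'   `skipped` (chemical key, name, reason) and `manifest` (inputs with
#'   checksums, configuration echo, counts, wall time, version).
#' @seealso [write_results()] to serialize a run.
#' @export
run_cgsea <- function(annotation_path, stats_paths, config = cgsea_config(),
                      stats_format = c("auto", "fusion", "generic")) {
  stopifnot(inherits(config, "cgsea_config"))
  stats_format <- match.arg(stats_format)
  t0 <- proc.time()[["elapsed"]]

  records <- read_ctd(annotation_path, organism_filter = config$organisms,
                      expression_only = config$expression_only)
  all_sets <- build_gene_sets(records, min_size = 1L, max_size = Inf)
  if (length(all_sets) == 0L) {
    cgsea_input_error("annotation stage: no chemical gene sets could be built")
  }

  stats <- rbindlist(lapply(stats_paths, function(p) {
    fmt <- stats_format
    if (fmt == "auto") {
      first <- read_input_lines(p)[1L]
      fmt <- if (length(first) && grepl("TWAS.Z", first, fixed = TRUE))
        "fusion" else "generic"
    }
    if (fmt == "fusion") read_fusion_twas(p) else read_generic_stats(p)
  }))
  collapsed <- collapse_duplicates(stats, config$collapse)
  ranked <- rank_genes(collapsed, config$ranking_mode)

  skipped <- list()
  testable <- list()
  es_obs <- numeric()
  for (key in names(all_sets)) {
    gs <- all_sets[[key]]
    if (gs$size < config$min_size) {
      skipped[[key]] <- "below_min_size"; next
    }
    if (gs$size > config$max_size) {
      skipped[[key]] <- "above_max_size"; next
    }
    gs <- restrict_to_universe(gs, ranked$genes)
    if (gs$size == 0L) {
      skipped[[key]] <- "empty_after_restriction"; next
    }
    if (gs$size == ranked$n) {
      skipped[[key]] <- "spans_entire_universe"; next
    }
    es <- tryCatch(compute_es(ranked, gs$members, config$w),
                   cgsea_degenerate_weight_error = function(e) NULL)
    if (is.null(es)) {
      skipped[[key]] <- "zero_weight"; next
    }
    testable[[key]] <- gs
    es_obs[key] <- es
  }
  if (length(testable) == 0L) {
    warning("no testable chemicals: every gene set was degenerate; results are empty",
            call. = FALSE)
    null_mat <- NULL
  } else {
    null_mat <- permute_null(ranked, testable, config)
  }

  rows <- list()
  for (key in names(testable)) {
    gs <- testable[[key]]
    norm <- tryCatch(normalize_es(es_obs[[key]], null_mat[, key]),
                     cgsea_degenerate_null_error = function(e) NULL)
    if (is.null(norm)) {
      skipped[[key]] <- "degenerate_null"; next
    }
    rows[[key]] <- data.table(
      chemical_id = gs$chemical_key,
      chemical_name = gs$chemical_name,
      set_size_annotated = gs$original_size,
      set_size_used = gs$size,
      es = es_obs[[key]],
      nes = norm$nes_obs,
      p_empirical = empirical_p(norm$nes_obs, norm$nes_null))
  }
  results <- rbindlist(rows)
  if (nrow(results) > 0L) {
    results[, q_bh := bh_fdr(p_empirical)]
    results <- results[order(p_empirical, -abs(nes), chemical_id)]
  } else {
    results <- data.table(chemical_id = character(),
                          chemical_name = character(),
                          set_size_annotated = integer(),
                          set_size_used = integer(),
                          es = numeric(), nes = numeric(),
                          p_empirical = numeric(), q_bh = numeric())
  }

  skipped_dt <- if (length(skipped)) {
    data.table(chemical_id = names(skipped),
               chemical_name = vapply(names(skipped), function(k)
                 all_sets[[k]]$chemical_name, character(1L)),
               reason = unlist(skipped, use.names = FALSE))[order(chemical_id)]
  } else {
    data.table(chemical_id = character(), chemical_name = character(),
               reason = character())
  }

  manifest <- list(
    tool = "cgsea",
    version = as.character(packageVersion("cgsea")),
    inputs = list(
      annotations = list(path = annotation_path,
                         md5 = unname(md5sum(annotation_path))),
      statistics = lapply(stats_paths, function(p)
        list(path = p, md5 = unname(md5sum(p))))),
    config = unclass(config),
    n_genes_ranked = ranked$n,
    n_chemicals_annotated = length(all_sets),
    n_chemicals_tested = nrow(results),
    n_chemicals_skipped = nrow(skipped_dt),
    wall_time_sec = round(proc.time()[["elapsed"]] - t0, 3))

  structure(list(results = results, skipped = skipped_dt,
                 manifest = manifest),
            class = "cgsea_run")
}

#' @export
print.cgsea_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<cgsea_run> %d genes ranked; %d chemical(s) tested, %d skipped (%.1fs)\n",
              m$n_genes_ranked, m$n_chemicals_tested, m$n_chemicals_skipped,
              m$wall_time_sec))
  if (nrow(x$results)) {
    cat("Top chemicals by empirical P:\n")
    print(utils::head(x$results, 5L))
  }
  invisible(x)
}

#' Write pipeline results to disk
#'
#' Serializes a run as three sidecar files: `<prefix>_results.tsv` (columns
#' `chemical_id`, `chemical_name`, `set_size_annotated`, `set_size_used`,
#' `es`, `nes`, `p_empirical`, `q_bh`, floats at 6 significant digits),
#' `<prefix>_skipped.tsv` (untested chemicals with reasons) and
#' `<prefix>_manifest.json`. The two TSVs are byte-deterministic for a
#' fixed run; the manifest records wall time and so is not.
#'
#' @param run A `cgsea_run` from [run_cgsea()].
#' @param out_prefix Output path prefix.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_results <- function(run, out_prefix) {
  stopifnot(inherits(run, "cgsea_run"))
  dir <- dirname(out_prefix)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(results  = paste0(out_prefix, "_results.tsv"),
             skipped  = paste0(out_prefix, "_skipped.tsv"),
             manifest = paste0(out_prefix, "_manifest.json"))
  res <- copy(run$results)
  for (col in c("es", "nes", "p_empirical", "q_bh")) {
    res[, (col) := signif(get(col), 6L)]
  }
  tryCatch({
    fwrite(res, paths[["results"]], sep = "\t", quote = FALSE)
    fwrite(run$skipped, paths[["skipped"]], sep = "\t", quote = FALSE)
    jsonlite::write_json(run$manifest, paths[["manifest"]],
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }, error = function(e) {
    cgsea_input_error(sprintf("cannot write results under prefix '%s': %s",
                              out_prefix, conditionMessage(e)))
  })
  invisible(paths)
}
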