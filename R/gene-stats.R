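#' Read FUSION TWAS association output
#'
#' Reads one or more FUSION-style TWAS result tables (whitespace- or
#' tab-delimited, with a header). The gene identifier is taken from the
#' first of the columns `ID`, `GENE` that is present, and the association
#' statistic from `TWAS.Z`. Column lookup is by name, never by position, so
#' extra columns are ignored. Gzip-compressed files are read transparently.
#'
#' @param paths Character vector of file paths.
#' @return A `data.table` with columns `gene_symbol` (uppercased),
#'   `statistic` (finite numeric TWAS Z-score) and `source_panel` (from a
#'   `PANEL` column if present, else the file name). Rows with a missing or
#'   non-numeric Z are skipped with a counted warning. Duplicate genes
#'   (e.g. the same gene tested in several tissue panels) pass through;
#'   collapse them with [collapse_duplicates()] before ranking.
#' @export
read_fusion_twas <- function(paths) {
  stopifnot(is.character(paths), length(paths) >= 1L)
  parts <- lapply(paths, function(path) {
    if (!file.exists(path)) {
      cgsea_input_error(sprintf("cannot read input file '%s': no such file",
                                path))
    }
    df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                            check.names = FALSE, comment.char = "")
    gene_col <- intersect(c("ID", "GENE"), names(df))[1L]
    if (is.na(gene_col)) {
      cgsea_format_error(sprintf(
        "'%s': no gene identifier column (expected 'ID' or 'GENE')", path))
    }
    if (!"TWAS.Z" %in% names(df)) {
      cgsea_format_error(sprintf("'%s': missing statistic column 'TWAS.Z'",
                                 path))
    }
    z <- suppressWarnings(as.numeric(df[["TWAS.Z"]]))
    gene <- toupper(trimws(as.character(df[[gene_col]])))
    panel <- if ("PANEL" %in% names(df)) as.character(df[["PANEL"]])
             else rep(basename(path), nrow(df))
    keep <- is.finite(z) & nzchar(gene)
    if (any(!keep)) {
      warning(sprintf("read_fusion_twas: skipped %d row(s) of '%s' with missing or non-numeric TWAS.Z",
                      sum(!keep), path), call. = FALSE)
    }
    data.table(gene_symbol = gene[keep], statistic = z[keep],
               source_panel = panel[keep])
  })
  out <- rbindlist(parts)
  if (nrow(out) == 0L) {
    cgsea_input_error("no usable gene statistics after filtering: nothing to rank")
  }
  out[]
}

#' Read a generic two-column gene statistic table
#'
#' Accepts any tab-separated gene-to-statistic table (for instance Z or t
#' statistics from a differential-expression analysis), with or without a
#' header row. A header is auto-detected: if the second field of the first
#' row is not numeric, that row is treated as a header and dropped.
#'
#' @param path Path to a two-column TSV (optionally `.gz`).
#' @return A `data.table` with columns `gene_symbol`, `statistic`,
#'   `source_panel` (the file name). Data rows with a non-numeric statistic
#'   are skipped with a counted warning; duplicate genes pass through.
#' @export
read_generic_stats <- function(path) {
  lines <- read_input_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    cgsea_input_error(sprintf("'%s' contains no data rows: nothing to rank",
                              path))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  two <- lengths(fields) >= 2L
  gene <- character(length(fields))
  stat_raw <- rep(NA_character_, length(fields))
  gene[two] <- vapply(fields[two], `[[`, character(1L), 1L)
  stat_raw[two] <- vapply(fields[two], `[[`, character(1L), 2L)
  stat <- suppressWarnings(as.numeric(stat_raw))

  start <- 1L
  if (!is.finite(stat[1L])) start <- 2L  # header row
  idx <- seq.int(start, length.out = max(0L, length(fields) - start + 1L))
  keep <- idx[is.finite(stat[idx]) & nzchar(trimws(gene[idx]))]
  n_bad <- length(idx) - length(keep)
  if (n_bad > 0L) {
    warning(sprintf("read_generic_stats: skipped %d row(s) of '%s' with a missing or non-numeric statistic",
                    n_bad, path), call. = FALSE)
  }
  if (length(keep) == 0L) {
    cgsea_input_error(sprintf("'%s' contains no usable gene statistics", path))
  }
  data.table(gene_symbol = toupper(trimws(gene[keep])),
             statistic = stat[keep],
             source_panel = rep(basename(path), length(keep)))
}

#' Collapse duplicate gene entries to one statistic per gene
#'
#' A gene measured in several tissue panels carries several statistics;
#' ranking needs exactly one. `max_abs` (the default elsewhere in the
#' package) keeps the entry with the largest absolute statistic - the
#' strongest tissue signal - with ties resolved in favor of the first
#' occurrence; `mean` averages the statistics; `first` keeps the first
#' occurrence.
#'
#' @param stats A statistic table from [read_fusion_twas()] or
#'   [read_generic_stats()].
#' @param policy One of `"max_abs"`, `"mean"`, `"first"`.
#' @return A `data.table` with one row per gene symbol, in first-occurrence
#'   order.
#' @export
collapse_duplicates <- function(stats, policy = c("max_abs", "mean", "first")) {
  if (length(policy) == 1L && !policy %in% c("max_abs", "mean", "first")) {
    cgsea_config_error(sprintf("unknown duplicate-collapse policy '%s'",
                               policy))
  }
  policy <- match.arg(policy)
  dt <- as.data.table(stats)
  dt[, .row__ := .I]
  out <- switch(policy,
    max_abs = dt[dt[, .I[which.max(abs(statistic))], by = gene_symbol]$V1],
    first   = dt[dt[, .I[1L], by = gene_symbol]$V1],
    mean    = dt[, .(statistic = mean(statistic),
                     source_panel = source_panel[1L],
                     .row__ = .row__[1L]),
                 by = gene_symbol]
  )
  # output in first-occurrence order of each gene, whichever row was kept
  first_seen <- dt$gene_symbol[!duplicated(dt$gene_symbol)]
  out <- out[order(match(gene_symbol, first_seen))]
  out[, .row__ := NULL]
  setcolorder(out, c("gene_symbol", "statistic", "source_panel"))
  out[]
}

#' Rank genes by their association statistic
#'
#' Produces the ranked gene list the enrichment score walks down. In
#' `signed` mode (the default elsewhere) genes are sorted by the raw
#' statistic from maximum to minimum; in `absolute` mode by the absolute
#' statistic, so that strong negative associations also rise to the top.
#' Ties are broken by ascending gene symbol, which makes the ranking - and
#' everything downstream - bit-reproducible across runs and platforms.
#'
#' @param stats A statistic table with exactly one row per gene (run
#'   [collapse_duplicates()] first).
#' @param ranking_mode `"signed"` or `"absolute"`.
#' @return A `cgsea_ranked` object: list with `genes` (ordered symbols),
#'   `stats` (the statistics in the same order), `n` and `ranking_mode`.
#' @export
rank_genes <- function(stats, ranking_mode = c("signed", "absolute")) {
  ranking_mode <- match.arg(ranking_mode)
  dt <- as.data.table(stats)
  if (nrow(dt) == 0L) cgsea_input_error("no gene statistics to rank")
  if (anyDuplicated(dt$gene_symbol)) {
    cgsea_input_error(
      "duplicate gene symbols in statistics: run collapse_duplicates() first")
  }
  if (any(!is.finite(dt$statistic))) {
    cgsea_input_error("non-finite statistics cannot be ranked")
  }
  key <- if (ranking_mode == "signed") dt$statistic else abs(dt$statistic)
  ord <- order(-key, dt$gene_symbol, method = "radix")
  structure(list(genes = dt$gene_symbol[ord],
                 stats = dt$statistic[ord],
                 n = nrow(dt),
                 ranking_mode = ranking_mode),
            class = "cgsea_ranked")
}

#' @export
print.cgsea_ranked <- function(x, ...) {
  cat(sprintf("<cgsea_ranked> %d genes, %s ranking; top: %s (%.3g) ... bottom: %s (%.3g)\n",
              x$n, x$ranking_mode, x$genes[1L], x$stats[1L],
              x$genes[x$n], x$stats[x$n]))
  invisible(x)
}
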