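# Independent oracles: deliberately naive re-derivations used to check the
# production code. They never share code with R/.

# Brute-force enrichment score: evaluate the running sum at EVERY prefix
# j = 1..N of the ranked list and take the maximum over the first N-1
# prefixes (the terminal prefix is identically zero).
brute_es <- function(stats_ranked, member_mask, w = 1) {
  N <- length(stats_ranked)
  hitw <- abs(stats_ranked)^w
  nr <- sum(hitw[member_mask])
  k <- sum(member_mask)
  miss <- 1 / (N - k)
  vals <- numeric(N)
  for (j in seq_len(N)) {
    in_set <- member_mask[seq_len(j)]
    vals[j] <- sum(hitw[seq_len(j)][in_set]) / nr - sum(!in_set) * miss
  }
  max(vals[-N])
}

# Same walk but returning the whole trajectory (for conservation checks).
brute_running_sum <- function(stats_ranked, member_mask, w = 1) {
  N <- length(stats_ranked)
  hitw <- abs(stats_ranked)^w
  nr <- sum(hitw[member_mask])
  k <- sum(member_mask)
  s <- numeric(N)
  acc <- 0
  for (j in seq_len(N)) {
    acc <- acc + if (member_mask[j]) hitw[j] / nr else -1 / (N - k)
    s[j] <- acc
  }
  s
}

# Unweighted (classic KS-like) score: hit increments are 1/NC.
brute_es_unweighted <- function(member_mask) {
  N <- length(member_mask)
  k <- sum(member_mask)
  inc <- ifelse(member_mask, 1 / k, -1 / (N - k))
  s <- cumsum(inc)
  max(s[-N])
}

# Naive nested-loop group-by of (chemical, gene) records.
naive_group_by <- function(keys, genes) {
  out <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (is.null(out[[k]])) out[[k]] <- character()
    if (!genes[i] %in% out[[k]]) out[[k]] <- c(out[[k]], genes[i])
  }
  lapply(out, sort)
}

# Naive per-gene duplicate collapse.
naive_collapse <- function(genes, stats, policy) {
  ug <- unique(genes)
  vapply(ug, function(g) {
    v <- stats[genes == g]
    switch(policy,
           max_abs = v[which.max(abs(v))],
           mean = mean(v),
           first = v[1L])
  }, numeric(1L))
}

# Build a ranked list from a named statistic vector.
make_ranked <- function(stats, ranking_mode = "signed") {
  rank_genes(data.frame(gene_symbol = names(stats),
                        statistic = unname(stats),
                        source_panel = "test",
                        stringsAsFactors = FALSE),
             ranking_mode = ranking_mode)
}

# Write a CTD-dialect annotation file from a data.frame of the 11 columns
# (missing columns filled with placeholders).
write_ctd_fixture <- function(rows, path = tempfile(fileext = ".tsv"),
                              header = TRUE) {
  lines <- character()
  if (header) {
    lines <- paste0("# ", paste(c("ChemicalName", "ChemicalID", "CasRN",
                                  "GeneSymbol", "GeneID", "GeneForms",
                                  "Organism", "OrganismID", "Interaction",
                                  "InteractionActions", "PubMedIDs"),
                                collapse = "\t"))
  }
  lines <- c(lines, rows)
  writeLines(lines, path)
  path
}

ctd_row <- function(chem_name, chem_id, gene, organism = "9606",
                    actions = "increases^expression") {
  paste(chem_name, chem_id, "cas", gene, "1", "gene", "org", organism,
        "ixn", actions, "999", sep = "\t")
}
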