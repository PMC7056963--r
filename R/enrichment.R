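#' Enrichment run configuration
#'
#' Bundles the tunable parameters of a chemical enrichment run.
#'
#' @param w Non-negative weight exponent on the ranked statistics. `w = 1`
#'   (the default) weights each set member by its absolute statistic;
#'   `w = 0` gives the classic unweighted KS-like statistic.
#' @param permutations Number of gene-label permutations used to build the
#'   null distribution. Default 5000.
#' @param seed Integer RNG seed; every source of randomness in a run flows
#'   from it.
#' @param ranking_mode `"signed"` (sort by raw statistic, the default) or
#'   `"absolute"`.
#' @param min_size,max_size Bounds on the annotated gene-set size; chemicals
#'   outside the bounds are reported as skipped, not tested.
#' @param per_set_null If `TRUE`, each gene set gets its own independent
#'   label shuffles; the default shares one shuffle per permutation round
#'   across all sets, which is marginally equivalent per set and much
#'   cheaper.
#' @param collapse Duplicate-gene policy passed to [collapse_duplicates()].
#' @param organisms Taxonomy IDs passed to [read_ctd()].
#' @param expression_only Passed to [read_ctd()].
#' @return A `cgsea_config` list.
#' @export
cgsea_config <- function(w = 1, permutations = 5000L, seed = 1L,
                         ranking_mode = c("signed", "absolute"),
                         min_size = 5L, max_size = Inf,
                         per_set_null = FALSE,
                         collapse = c("max_abs", "mean", "first"),
                         organisms = c("9606", "10090"),
                         expression_only = FALSE) {
  if (!is.numeric(w) || length(w) != 1L || !is.finite(w) || w < 0) {
    cgsea_config_error("w must be a single non-negative number")
  }
  if (!is.numeric(permutations) || length(permutations) != 1L ||
      permutations < 1) {
    cgsea_config_error("permutations must be a single integer >= 1")
  }
  structure(list(w = w,
                 permutations = as.integer(permutations),
                 seed = as.integer(seed),
                 ranking_mode = match.arg(ranking_mode),
                 min_size = min_size,
                 max_size = max_size,
                 per_set_null = isTRUE(per_set_null),
                 collapse = match.arg(collapse),
                 organisms = as.character(organisms),
                 expression_only = isTRUE(expression_only)),
            class = "cgsea_config")
}

# ES from the sorted member positions in the ranked list.
#
# The running sum rises by |L|^w / NR at a member and falls by 1/(N - NC)
# otherwise; it returns to zero exactly at the end of the list, so the score
# is the maximum over the first N-1 prefixes. That maximum is attained
# either immediately after a hit or at the very first position (the start of
# the initial descent), which reduces the walk to O(NC) arithmetic on the
# hit positions. `hitw` are the |statistic|^w values at `pos`.
es_from_positions <- function(pos, hitw, N) {
  k <- length(pos)
  nr <- sum(hitw)
  miss <- 1 / (N - k)
  hit_cum <- if (nr > 0) cumsum(hitw) / nr else numeric(k)
  s_hit <- hit_cum - (pos - seq_len(k)) * miss
  cand <- s_hit[pos < N]
  if (pos[1L] > 1L) cand <- c(-miss, cand)
  max(cand)
}

#' Weighted KS-like enrichment score of a gene set
#'
#' Walks down the ranked gene list, increasing a running sum by
#' `|L_i|^w / NR` when gene `i` belongs to the set (where `NR` is the sum of
#' `|L|^w` over the set members present in the list) and decreasing it by
#' `1/(N - NC)` otherwise. The full walk returns to zero at the end of the
#' list, so the enrichment score is the maximum of the running sum over the
#' first `N - 1` prefixes: near +1 when the members crowd the top of the
#' ranking, and negative when they crowd the bottom.
#'
#' @param ranked A `cgsea_ranked` list from [rank_genes()].
#' @param members Character vector of member gene symbols. At least one
#'   member and at least one non-member must be present in the ranked
#'   universe.
#' @param w Non-negative weight exponent (default 1).
#' @return The enrichment score, a single number in (-1, 1].
#' @export
#' @examples
#' rk <- rank_genes(data.frame(gene_symbol = paste0("G", 1:5),
#'                             statistic = c(3, 2, 1, -1, -2),
#'                             source_panel = "toy"))
#' compute_es(rk, c("G1", "G3"))  # 0.75
compute_es <- function(ranked, members, w = 1) {
  stopifnot(inherits(ranked, "cgsea_ranked"))
  if (!is.numeric(w) || length(w) != 1L || w < 0) {
    cgsea_config_error("w must be a single non-negative number")
  }
  pos <- which(ranked$genes %chin% members)
  k <- length(pos)
  if (k == 0L) {
    cgsea_degenerate_error("gene set has no members in the ranked universe",
                           "set")
  }
  if (k == ranked$n) {
    cgsea_degenerate_error(
      "gene set covers the entire ranked universe: miss term undefined",
      "set")
  }
  hitw <- abs(ranked$stats[pos])^w
  if (sum(hitw) == 0) {
    cgsea_degenerate_error(
      "all member statistics are zero: hit weights sum to zero", "weight")
  }
  es_from_positions(pos, hitw, ranked$n)
}

#' Full enrichment running sum (diagnostic)
#'
#' Returns the running-sum statistic at every prefix of the ranked list.
#' Its maximum over the first `n - 1` entries is [compute_es()]; its final
#' entry is zero up to floating error (hit mass and miss mass both total 1).
#'
#' @inheritParams compute_es
#' @return Numeric vector of length `ranked$n`.
#' @export
running_sum <- function(ranked, members, w = 1) {
  stopifnot(inherits(ranked, "cgsea_ranked"))
  hit <- ranked$genes %chin% members
  k <- sum(hit)
  if (k == 0L || k == ranked$n) {
    cgsea_degenerate_error("running sum needs a non-trivial member split",
                           "set")
  }
  hitw <- abs(ranked$stats)^w
  nr <- sum(hitw[hit])
  if (nr == 0) {
    cgsea_degenerate_error(
      "all member statistics are zero: hit weights sum to zero", "weight")
  }
  inc <- ifelse(hit, hitw / nr, -1 / (ranked$n - k))
  cumsum(inc)
}

#' Permutation null distributions of the enrichment score
#'
#' Builds the null by randomly shuffling the gene labels of the ranked
#' list: a shuffle breaks the association between set membership and
#' statistic while preserving the statistic profile, so each set's members
#' land at uniformly random positions. By default one shuffle per
#' permutation round is shared by every gene set (marginally equivalent for
#' each set, since a set's null score depends only on where its own members
#' land); `config$per_set_null` requests fully independent shuffles per set.
#'
#' Sets are processed in sorted-key order and all randomness flows from
#' `config$seed`, so the output is bit-reproducible.
#'
#' @param ranked A `cgsea_ranked` list.
#' @param gene_sets Named list of `cgsea_gene_set` objects, each already
#'   restricted to the ranked universe with `1 <= size < n`.
#' @param config A [cgsea_config()].
#' @return A numeric matrix with `config$permutations` rows and one named
#'   column of null enrichment scores per gene set.
#' @export
permute_null <- function(ranked, gene_sets, config) {
  stopifnot(inherits(ranked, "cgsea_ranked"), inherits(config, "cgsea_config"))
  P <- config$permutations
  if (P < 1L) cgsea_config_error("permutations must be >= 1")
  keys <- sort(names(gene_sets))
  gene_sets <- gene_sets[keys]
  N <- ranked$n
  pos0 <- lapply(gene_sets, function(gs) {
    pos <- which(ranked$genes %chin% gs$members)
    if (length(pos) == 0L || length(pos) == N) {
      cgsea_degenerate_error(sprintf(
        "gene set '%s' is degenerate in the ranked universe",
        gs$chemical_key), "set")
    }
    pos
  })
  absw <- abs(ranked$stats)^config$w
  out <- matrix(NA_real_, nrow = P, ncol = length(gene_sets),
                dimnames = list(NULL, keys))
  set.seed(config$seed)
  inv <- integer(N)
  for (t in seq_len(P)) {
    if (config$per_set_null) {
      for (j in seq_along(pos0)) {
        pos <- sort.int(sample.int(N, length(pos0[[j]])))
        out[t, j] <- es_from_positions(pos, absw[pos], N)
      }
    } else {
      sigma <- sample.int(N)
      inv[sigma] <- seq_len(N)   # position each original label moved to
      for (j in seq_along(pos0)) {
        pos <- sort.int(inv[pos0[[j]]])
        out[t, j] <- es_from_positions(pos, absw[pos], N)
      }
    }
  }
  out
}

#' Standardize an enrichment score against its permutation null
#'
#' The observed score and each null score are centered on the null mean and
#' scaled by the null standard deviation (sample SD, n-1 divisor), giving
#' the normalized enrichment score NES and its standardized null, which by
#' construction has mean 0 and SD 1.
#'
#' @param es_obs Observed enrichment score.
#' @param es_null Numeric vector of permutation scores (length >= 2).
#' @return List with `nes_obs`, `nes_null`, `mean_es`, `sd_es`.
#' @export
normalize_es <- function(es_obs, es_null) {
  if (length(es_null) < 2L) {
    cgsea_config_error("need at least 2 permutation scores to normalize")
  }
  m <- mean(es_null)
  s <- sd(es_null)
  if (!is.finite(s) || s == 0) {
    cgsea_degenerate_error(
      "permutation null has zero spread: NES undefined", "null")
  }
  list(nes_obs = (es_obs - m) / s,
       nes_null = (es_null - m) / s,
       mean_es = m, sd_es = s)
}

#' Upper-tail empirical permutation P value
#'
#' `p = (1 + #\{null >= observed\}) / (P + 1)`: the add-one correction counts
#' the observed configuration among the permutations, so `p` is never zero
#' and its floor is `1 / (P + 1)`. One-sided: small `p` means the set is
#' enriched at the top of the ranking.
#'
#' @param nes_obs Observed normalized enrichment score.
#' @param nes_null Numeric vector of standardized null scores.
#' @return A single number in `[1/(P+1), 1]`.
#' @export
empirical_p <- function(nes_obs, nes_null) {
  P <- length(nes_null)
  if (P < 1L) cgsea_config_error("need at least 1 permutation score")
  (1 + sum(nes_null >= nes_obs)) / (P + 1)
}

#' Benjamini-Hochberg false discovery rates
#'
#' Adjusts a vector of empirical P values for multiple testing across
#' chemicals, returning q values in the input order with BH monotonicity
#' enforced (delegates to [stats::p.adjust()]).
#'
#' @param p_values Numeric vector of P values in (0, 1].
#' @return Adjusted values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric())
  if (any(!is.finite(p_values) | p_values <= 0 | p_values > 1)) {
    cgsea_input_error("p values must lie in (0, 1]")
  }
  p.adjust(p_values, method = "BH")
}
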