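---
title: "Methods: scoring chemical-trait associations by gene set enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring chemical-trait associations by gene set enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgsea)
```

## The problem and the model

Chemicals in the environment influence disease partly by perturbing gene
expression. Curated chemical-gene interaction annotations (the CTD
`chem_gene_ixns` tables) tell us *which* genes each chemical touches; a
transcriptome-wide association study (TWAS) tells us *which* genes'
expression is associated with a trait, as one Z-score per gene. If the
genes a chemical interacts with crowd the top of the trait's gene ranking,
that chemical is a candidate player in the trait - and this can be asked
with summary statistics alone, with no exposure measurements and no
individual-level data.

`cgsea` casts this as preranked gene set enrichment. Genes are ranked by
their statistic $L_1^s \ge L_2^s \ge \dots \ge L_N^s$ (signed sort by
default). For a chemical's gene set $C$ with $N_C$ members present in the
ranking, a running sum walks down the list, rising by
$|L_i^s|^w / N_R$ at members (with $N_R = \sum_{g_i \in C} |L_i^s|^w$) and
falling by $1/(N - N_C)$ at non-members. The enrichment score $ES^C$ is the
maximum of this walk. Because the hit mass and miss mass each total 1, the
walk returns to zero exactly at the end of the list; we therefore take the
maximum over the first $N - 1$ prefixes, so that a set concentrated at the
*bottom* of the ranking scores negatively instead of being pinned at the
terminal zero. On the toy ranking $[3, 2, 1, -1, -2]$ this gives
$ES = 0.75$ for members $\{G_1, G_3\}$ and $ES = -0.25$ for $\{G_5\}$:

```{r toy}
rk <- rank_genes(data.frame(gene_symbol = paste0("G", 1:5),
                            statistic = c(3, 2, 1, -1, -2),
                            source_panel = "toy"))
compute_es(rk, c("G1", "G3"))
compute_es(rk, "G5")
```

Significance comes from gene-label permutation: shuffling which gene
carries which ranked statistic breaks the membership-statistic association
while preserving the statistic profile. After $P$ shuffles the observed
score is standardized against its null,
$NES^C = (ES^C - \mathrm{mean}(ES^{nullC})) / \mathrm{SD}(ES^{nullC})$,
and the one-sided empirical P value is
$p = (1 + \#\{t : NES_t^{nullC} \ge NES^C\})/(P + 1)$, with floor
$1/(P+1)$. Benjamini-Hochberg q values are added across chemicals.

## Parameters that matter

* **`w` (weight exponent, default 1, unitless).** `w = 1` weights each
  member by its absolute statistic, so extreme genes dominate; `w = 0`
  gives the classic unweighted KS-like statistic (increments $1/N_C$). At
  `w = 1` the score is invariant to rescaling all statistics by a positive
  constant.
* **`permutations` (default 5000).** Sets the resolution of the empirical
  P value: the smallest attainable value is $1/5001 \approx 2\times10^{-4}$.
* **`ranking_mode` (default `"signed"`).** The signed sort follows the
  ranking notation above literally; note that under it the hit weights are
  still $|L|^w$, so a set whose members are all strongly *negative* sits at
  the bottom of the list and scores negatively rather than significantly.
  `"absolute"` ranking is provided for users who want strong associations
  of either sign at the top. This is a genuinely open design point; both
  modes ship and the default is documented rather than guessed to be the
  universally right choice.
* **`min_size` / `max_size` (default 5 / unbounded).** Annotated set-size
  bounds. Very small sets produce coarse, near-degenerate permutation
  nulls; the floor of 5 trades a little coverage for stable NES values.
  Out-of-bounds chemicals are reported as skipped, never silently dropped.
* **`collapse` (default `"max_abs"`).** TWAS runs over several tissue
  panels yield several Z-scores per gene; `max_abs` keeps the strongest
  tissue signal (ties to the first occurrence), with `mean` and `first` as
  alternatives.
* **`per_set_null` (default `FALSE`).** By default one label shuffle per
  permutation round is shared by all chemicals. Marginally, each set's
  null depends only on where its own members land, so the shared shuffle is
  per-set equivalent to independent shuffling while costing
  $O(P \times N)$ rather than $O(\text{chemicals} \times P \times N)$
  shuffles; the flag restores fully independent draws for purists.

## Numerical and degenerate-input choices

* The running-sum maximum is computed from the member positions only
  (the walk rises only at hits, so its maximum sits immediately after a hit
  or at the first position), reducing each evaluation to $O(N_C)$
  arithmetic. Tests check bit-level agreement with full-prefix enumeration
  on small universes and 1e-12-level agreement elsewhere.
* NES uses the sample standard deviation ($n - 1$ divisor); at thousands of
  permutations the divisor choice is immaterial, but it is pinned down for
  reproducibility.
* The empirical P uses the add-one convention $(1 + \text{count})/(P + 1)$,
  so P values are never zero.
* Ties in the ranking are broken by ascending gene symbol, and chemicals
  are processed in sorted key order with all randomness flowing from one
  seed, so a run is byte-reproducible.
* Degenerate cases are skipped per chemical with a recorded reason rather
  than failing the run: sets empty after restriction to the ranked
  universe, sets spanning the whole universe (the miss term $1/(N - N_C)$
  is undefined), all-zero member statistics ($N_R = 0$), and
  zero-spread permutation nulls. Every annotated chemical appears exactly
  once across the results and skipped tables.

## What the synthetic fixtures emulate

`make_fixture()` generates the package's validation world: standard-normal
gene statistics (emulating TWAS Z-scores under the null), random chemical
gene sets written in the CTD dialect, and "planted" chemicals whose member
statistics are shifted upward by `effect_delta` before ranking - the
simplest mechanism that concentrates a set at the top of a signed ranking.
The default spec (1000 genes, 50 chemicals with 20-gene sets, one planted
chemical at a shift of 2) is the study condition used by the test suite and
the acceptance script; those sizes keep the full suite in tens of seconds
while leaving the planted signal comfortably detectable.

What the fixtures do **not** emulate: correlation between genes (LD and
co-expression make real TWAS Z-scores locally dependent, so real null
distributions are wider than exchangeable shuffles suggest), the long-tailed
and overlapping size structure of real CTD sets, annotation noise, and any
TWAS/GWAS mechanics upstream of the Z-scores. Passing the calibration and
power tests therefore demonstrates the statistic and its permutation
machinery are implemented correctly, not that gene-label permutation is a
perfectly calibrated null for correlated real data - a caveat this method
shares with all gene-permuting enrichment tests.

## Other design choices

* **Chemical identity** is keyed on the ChemicalID accession when present
  (names are not stable across CTD revisions), falling back to the name;
  both are reported.
* **Mouse genes** are folded in by symbol identity after uppercasing; no
  ortholog table is consulted. This is the minimal reading of a human+mouse
  annotation filter and is a documented limitation - symbols that differ
  between species are simply not merged.
* **`expression_only`** (default `FALSE`) optionally restricts annotation
  rows to interaction actions mentioning `expression`. CTD mixes
  expression, activity, binding and other interaction types, and either
  universe is defensible; the flag leaves the choice to the user.
* **One-sided scoring.** Only the upper tail of the NES null is tested:
  the question is enrichment at the top of the ranking. No two-sided
  max-deviation variant is offered.

## Known limitations

* The permutation engine is pure R; at the scale of a full CTD annotation
  (~10^4 chemicals) with thousands of permutations a run takes on the order
  of hours, not minutes. The shared-shuffle null keeps this linear in
  $P \times N$ plus $P \times \sum N_C \log N_C$.
* Symbol-identity mouse mapping and the gene-label (rather than
  phenotype-label) permutation null, both discussed above.
* Statistics are consumed as given: no imputation for missing genes, rows
  with non-finite statistics are dropped with a counted warning.
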