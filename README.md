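# cgsea

Chemical gene set enrichment analysis: scan for chemicals associated with a
complex disease or trait using only genome-wide summary statistics.

## What it does

Environmental chemicals influence disease largely by perturbing gene
expression, and curated chemical-gene interaction annotations (the
Comparative Toxicogenomics Database `chem_gene_ixns` tables) record which
genes each chemical touches. A transcriptome-wide association study (TWAS)
independently assigns each gene a Z-score for its expression association
with a trait. `cgsea` asks, for every chemical, whether its gene set is
enriched at the top of the TWAS ranking.

Genes are ranked by their statistic, $L^s_1 \ge \dots \ge L^s_N$. For a
chemical's set $C$ with $N_C$ genes in the ranking, a weighted
Kolmogorov-Smirnov-like running sum rises by $|L^s_i|^w / N_R$ at members
(where $N_R = \sum_{g_i \in C} |L^s_i|^w$, default $w = 1$) and falls by
$1/(N - N_C)$ at non-members; the enrichment score $ES^C$ is the maximum
excursion of the walk. Gene-label permutations give a null distribution,
the observed score is standardized against it
($NES^C$), and a one-sided empirical P value is computed as
$p = (1 + \#\{NES^{null} \ge NES^C\}) / (P + 1)$ with Benjamini-Hochberg
q values across chemicals. Any gene-level statistic table works in place of
TWAS output (e.g. differential-expression Z or t statistics).

## Worked example

The package ships a synthetic-fixture generator that emits the same file
dialects the parsers consume, with a known planted signal:

```r
library(cgsea)

# 1000 genes, 50 chemicals with 20-gene sets, one chemical's members
# shifted +2 in Z before ranking
fx  <- make_fixture(fixture_spec(seed = 7))
run <- run_cgsea(fx$annotations, fx$stats,
                 cgsea_config(permutations = 5000, seed = 7))
run
#> <cgsea_run> 1000 genes ranked; 50 chemical(s) tested, 0 skipped (17.5s)
#> Top chemicals by empirical P:
#>    chemical_id chemical_name set_size_annotated set_size_used        es
#>         <char>        <char>              <int>         <int>     <num>
#> 1:     D000007       chem007                 20            20 0.8616354
#> 2:     D000028       chem028                 20            20 0.4868567
#> 3:     D000012       chem012                 20            20 0.4492324
#> ...
#>         nes p_empirical      q_bh
#> 1: 4.808103  0.00019996 0.0099980
#> 2: 1.903445  0.03119376 0.6938612
#> 3: 1.608250  0.05878824 0.6938612
fx$planted_keys
#> [1] "D000007"
```

The planted chemical `D000007` ranks first with a strongly positive
enrichment score (its 20 genes crowd the top of the ranking), a normalized
score far outside the permutation null, and the smallest attainable
empirical P at 5000 permutations, $1/5001 \approx 2\times 10^{-4}$. The
decoy chemicals hover near null NES values and large P. `write_results()`
serializes the results, the skipped-chemicals table and a JSON run
manifest; `inst/cli/cgsea.R` wraps the same pipeline for shell use:

```sh
Rscript inst/cli/cgsea.R --annotations chem_gene_ixns.tsv.gz \
    --stats trait.twas.dat --out results/trait --permutations 5000 --seed 1
```

Point `--annotations` at a CTD `chem_gene_ixns` download (the file is not
redistributed here); `--stats` accepts FUSION TWAS output (`ID`/`GENE` +
`TWAS.Z` columns) or any two-column gene/statistic TSV.

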