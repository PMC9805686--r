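# phenoverlap

Phenotype and disease enrichment for gene sets, and statistically tested
phenotype-level similarity between two gene sets, over flat gene–term
annotation databases (HPO-style phenotype annotations, Mammalian
Phenotype annotations mapped through orthology, curated gene–disease
tables, CRISPR screen hit tables).

The package is aimed at clinical geneticists and computational
biologists who work with gene panels: it answers "which phenotype and
disease terms are over-represented in this gene set?", "how similar are
two panels at the phenotype level, and is that similarity more than
chance?", and "which significant terms separate them?".

## The model

**Enrichment.** Databases are standardized against a protein-coding
gene universe (HGNC-style symbols, uppercased, exact-matched). Each
database receives a sentinel "no annotation" term linked to every
otherwise-unannotated universe gene, so the hypergeometric population is
the full universe `GDB`. For a term annotating `gdb` universe genes,
tested in a query set `G` of which `g` genes carry the term, the
enrichment P value is the exact upper tail

    P(X >= g),  X ~ Hypergeometric(GDB, gdb, |G|)

Only terms with `g >= 1` are tested. Raw, Bonferroni and
Benjamini–Hochberg adjusted values are reported, pooled across all
selected databases by default.

**Phenotypic Overlap Ratio (POR).** Let `Gp` and `G'p` be the sets of
significantly enriched terms of two gene sets (raw `P < 0.05` by
default). With `a = |Gp ∩ G'p|`, `b = |Gp \ G'p|`, `c = |G'p \ Gp|`,
`n = a + b + c`:

* Jaccard: `POR = a / n`
* Forbes–Alroy: `POR = a(n + √n) / [(a+b)(a+c) + a√n + bc/2]`

Both lie in `[0, 1]`; the Forbes coefficient is exactly 1 whenever one
term set contains the other. A relaxed variant (RPOR) applies the same
coefficients to all annotated terms. Significance is assessed by
randomization: random gene sets drawn uniformly from the universe, with
an *overlapping* mode (either side randomized in turn, `2m` null values)
and a *conditional* mode for a set derived from the other (only the
derived side randomized, `m` null values). The empirical P value is the
proportion of null PORs strictly greater than the observed one.

**Differential phenotypes and relevance.** Terms significant in exactly
one of the two sets are reported with the term's P value in the other
set; the shared terms feed an OLS regression of per-term gene counts
(adjusted R² measures whether shared terms have similar relevance in
both sets).

A seed-deterministic synthetic database generator (negative-binomial
per-gene annotation counts, Zipf-weighted term popularity, optional
planted disease module) backs two calibration experiments: a
type-I-error grid over random gene sets and a POR sensitivity study on
artificial panel/filler mixtures.

## Worked example

```r
library(phenoverlap)
d  <- file.path(tempdir(), "toy"); fx <- make_fixtures(d)
u       <- read_gene_universe(fx$universe)
pheno   <- standardize_db(load_association_table(fx$pheno,   "two_col", "phenotype", name = "TOYPHENO"),   u)
disease <- standardize_db(load_association_table(fx$disease, "two_col", "disease",   name = "TOYDISEASE"), u)

enrich(read_gene_list(fx$genes_a), list(pheno, disease))
#> <pheno_enrichment> 'genes_a.txt': 19 tested terms across TOYPHENO, TOYDISEASE (alpha = 0.05, upper_tail)
#>     database term_id       term_name genes_in_set term_size        p_raw p_bonferroni        q_fdr
#> 1   TOYPHENO TP:0001 toy phenotype 1            8        11 2.145513e-06 4.076475e-05 4.076475e-05
#> 2 TOYDISEASE TD:0002   toy disease 2            5        12 3.857418e-02 7.329094e-01 3.664547e-01
#> ...

por_significance(read_gene_list(fx$genes_a), read_gene_list(fx$genes_b),
                 list(pheno, disease), m = 1000, seed = 42)
#> <pheno_comparison>
#>   Gene sets 'genes_a.txt' and 'genes_b.txt' share 2 of 2 significant terms
#>   (jaccard POR = 1.000; empirical P = 0 from 2000 null sets).
#>   mode = overlapping, m = 1000, criterion = raw P < 0.05
```

The first table reads: 8 of the 8 input genes carry `TP:0001`, which
annotates 11 of the 40 universe genes, giving an upper-tail
hypergeometric P of `2.1e-06` (Bonferroni-adjusted over the 19 tested
terms). The comparison message reports the two panels' significant-term
sets coincide (POR = 1), and none of 2000 random gene sets reached that
overlap.

A command-line interface with the same functionality is installed as
`exec/phenoverlap` (subcommands `enrich`, `compare`, `simulate-type1`,
`simulate-por-sensitivity`, `db-stats`, `fixtures`).

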