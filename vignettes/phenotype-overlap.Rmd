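---
title: "Phenotype enrichment and gene-set overlap scores: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotype enrichment and gene-set overlap scores: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoverlap)
```

This vignette explains the statistical machinery of `phenoverlap`, the
assumptions behind it, and the design decisions taken where more than
one reasonable implementation existed.

## Annotation model

A database is a flat set of gene–term associations. Terms are treated
as independent labels: no ontology-graph reasoning (ancestor
propagation, semantic similarity) is performed, and none is implied.
Consequences of that choice surface below in *Limitations*.

Standardization against a gene universe does three things:

1. **Symbol normalization.** Symbols are uppercased, trimmed and
   exact-matched against the universe; anything else is dropped with a
   counted warning. No alias resolution is attempted — with HGNC-style
   input the failure mode of silent mis-mapping is worse than a counted
   drop, and keeping the universe fixed keeps the hypergeometric
   population `GDB` well defined.
2. **Sentinel completion.** Every database gets exactly one sentinel
   "no annotation" term, linked to each universe gene without any real
   association. After completion every universe gene carries at least
   one association, so `GDB` equals the universe size for every test,
   and "having no annotation" is itself testable (a gene set may be
   significantly depleted of annotation knowledge). Sentinels are
   flagged, tested like any other term, and excluded by default from
   similarity and differential outputs.
3. **Orthology re-keying** (mouse databases): each mouse-gene
   association expands to *all* mapped human symbols — the union over a
   many-to-many map — before sentinel completion. Unmapped mouse genes
   are dropped with a warning.

CRISPR screen hit tables are encoded as three class terms per screen
(`association`, `positive`, `negative`); an empty class term is omitted
because a term annotating zero genes can never be tested.

## Enrichment test

For a term annotating `gdb` of `GDB` universe genes, observed in `g` of
a query set's `|G|` genes, the P value is the exact hypergeometric
upper tail `P(X >= g)` — no normal approximation at any size. The point
probability `P(X = g)` is available as `mode = "pmf"` for literal
comparison with tools that report it, but it is not the default: the
point mass is not a valid tail P value when `g` is near its
expectation.

Only terms with `g >= 1` are tested (an untested term has upper-tail P
value 1 by convention wherever a value is needed downstream). Bonferroni
and Benjamini–Hochberg adjustments are computed jointly over all tested
terms of all selected databases — one analysis, one family — with a
per-database scope available via `adjust_scope = "per_db"`. The
"significant term" rule feeding the similarity machinery defaults to
raw `P < alpha` with `alpha = 0.05`, switchable to the adjusted values.

Output tables are sorted by raw P value with ties broken by database
name then term identifier, so identical inputs give byte-identical
tables.

## Overlap scores and their null

The Phenotypic Overlap Ratio compares the significant-term sets `Gp`,
`G'p` of two gene sets, with `a`, `b`, `c` the shared and exclusive
counts and `n = a + b + c`:

* **Jaccard**: `a / n`, defined as 0 when both sets are empty.
* **Forbes–Alroy**: `a(n + √n) / [(a+b)(a+c) + a√n + bc/2]`. The
  subset cases (`b = 0` or `c = 0`) simplify algebraically to exactly 1;
  the implementation returns the literal constants 0 and 1 in the
  degenerate cases rather than relying on floating-point cancellation.

The relaxed variant (RPOR) applies the same coefficient to all
non-sentinel terms with `g >= 1` in each set. No ordering between POR
and RPOR is guaranteed and none is asserted.

**Randomization.** Null gene sets are drawn uniformly, without
replacement, from the *intersection* of the selected databases'
universes. Two modes:

* *Overlapping* (sets that may share genes): the published description
  compares the observed score against scores involving one random set
  at a time. We randomize one side while the other keeps its real
  phenotype structure, and pool both directions: per replicate,
  `POR(G, R')` and `POR(R, G')`, giving `2m` null values (the
  per-direction breakdown is kept in the result object).
* *Conditional* (`G'` derived from `G`): only the derived side is
  randomized, `m` values `POR(G, R)`.

The empirical P value counts null values **strictly greater** than the
observed score; ties do not count as exceeding. With coarse null
distributions this makes the empirical P conservative in a specific
direction, and it can be exactly 0. An add-one variant
`(1 + #{null >= obs}) / (m + 1)` is available behind
`pseudocount = TRUE` for users who need a strictly positive P value.
Given a seed, the null is bit-reproducible.

**Relevance regression.** Over shared terms, OLS of per-term gene
counts in one set on the other. The fit is declared undefined below 3
shared terms or with a constant predictor; a constant response reports
slope 0, R² = 0 and a `low_information` flag instead of meaningless
inferential statistics. The adjusted R² is the headline number; the
plain R² is also stored.

## Synthetic databases

`generate_synthetic_db()` emulates the gross shape of real annotation
databases:

* per-gene annotation counts are negative binomial around the target
  mean (`density_dispersion` is the NB size; default 2 gives the
  heavy-tailed per-gene densities seen in curated sources). Real
  disease databases span means from roughly 4.4 (sparse panel-style
  sources) through 7 to about 17.7 (dense curated sources), and those
  are the reference densities used throughout the experiments;
* term popularity is Zipf-weighted (`term_size_skew`, default 0.8), so
  term sizes are heavy-tailed;
* an optional planted disease module co-associates a block of genes and
  terms. `p_within` may be a range `c(lo, hi)`, in which case module
  terms receive geometrically spaced association probabilities. The
  geometric grading mirrors the heavy-tailed strengths of real disease
  annotations — a few near-pathognomonic terms, many weak ones — and it
  is what makes the recovery of module terms gradual as a mixed gene
  set gains module genes; a single homogeneous probability makes all
  module terms cross their significance threshold together, which
  produces a step-shaped rather than a gradual overlap response.

Token assignment works by global weighted draws with per-gene
deduplication and top-up rounds, so realized per-gene counts hit their
targets without per-gene weighted sampling loops; at
`mean_terms_per_gene = n_terms` the generator saturates every gene with
every term. Everything is determined by the spec seed.

**What the generator does not emulate.** Term–term correlation beyond
the single planted module; ontology structure; gene families and
correlated annotation between paralogs; database-specific curation
biases; symbol aliasing noise. Experiments passing on synthetic
databases therefore validate the *statistical machinery* (test
validity, calibration of the randomization null, sensitivity of the
overlap score), not version-specific numbers of any real database
release, which shift with every curation cycle.

## The two calibration experiments

**Type-I error.** `type1_experiment()` draws random gene sets per
(database, size) cell and reports a false-positive rate. The published
description of this experiment leaves the metric ambiguous, so three
readings are implemented. The default, `per_term_all` (significant
non-sentinel terms over *all* non-sentinel terms, untested terms
counting as negative), is the only reading mathematically guaranteed to
stay at or below `alpha` in expectation for a valid test, and is the
acceptance metric. `per_term_tested` conditions on testability and
reproduces the known inflation on sparse databases at small set sizes
(few tested terms, each with a discrete, conservative-or-liberal
tail), and `any_hit_adjusted` is the family-wise reading. The test
suite exercises the dense reference condition (≈19,000 genes, 5,000
terms, mean ≈17.7, 1,000 sets of size 320) and the sparse-vs-dense
contrast at size 5.

**POR sensitivity.** `build_artificial_set()` reproduces the
artificial-panel design: a fixed-size set mixing a proportion `p` of
panel genes, a 5% noise fraction (genes outside the panel annotated to
at least one panel-enriched term — "noise" because they drag the
panel's own phenotypes in), and filler genes matched to the panel's
per-gene annotation-count deciles. "Similar phenotypic connectivity" is
not operationally defined in the published description; decile matching
on the total non-sentinel annotation count is this package's
operationalization. Fillers exclude both panel and noise genes, so at
`p = 0`, `noise = 0` the artificial set avoids the panel's enriched
terms by construction and the POR is near 0.
`por_sensitivity_experiment()` sweeps an 11-point grid at 100
replicates (the desk-scale version of the published 1,000), fits OLS of
the replicate-level POR on `p`, and runs Welch t-tests between adjacent
grid points. The reference conditions for the planted-module study are
a 5,000-gene, 800-term, mean-8 database with a 300-gene/100-term module
graded over `p_within = c(0.02, 0.5)` and a 261-gene panel, the panel
size of the reference epilepsy study.

## Numerical and degenerate-input conventions

* `POR = 0` when both term sets are empty; Forbes returns 0 at `a = 0`
  and 1 at `b = 0` or `c = 0` by the algebraic limits.
* Empirical P lives on the lattice `{0, 1/k, ..., 1}`, `k` the number
  of null values.
* All enrichment bounds (`0 <= g <= min(gdb, |G|)`,
  `gdb <= GDB`) are validated and violations raise domain errors rather
  than returning `NaN`.
* Every stochastic routine takes an explicit seed and restores the
  caller's RNG state; no hidden global state.
* Gene sets are deduplicated and sorted at construction, so set
  semantics (not input order) determine all results.

## Limitations

* Flat-label treatment understates similarity between gene sets
  annotated to *related but distinct* ontology terms; this is the
  intended trade-off of the approach, not an oversight.
* The strictly-greater empirical P is conservative on tie-heavy null
  distributions (small databases, small `m`).
* Symbol matching is exact; panels using aliases or previous symbols
  should be mapped to current HGNC symbols upstream.
* Enrichment of very small sets against sparse databases rests on few
  testable terms; the type-I grid quantifies exactly when that becomes
  a problem, and mirrors the published recommendation to use dense
  databases for small gene sets.
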