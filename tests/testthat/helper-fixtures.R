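# Fixtures built in code: tiny universes and databases with hand-countable
# structure, plus independent oracles used across tests.

toy_universe <- function(n = 10L, prefix = "U") {
  gene_universe(sprintf("%s%02d", prefix, seq_len(n)))
}

# A db over a 10-gene universe with one 5-gene term; genes U06..U10 end up
# sentinel-only.
toy_term_db <- function(name = "TOY") {
  u <- toy_universe(10L)
  assoc <- data.frame(gene = sprintf("U%02d", 1:5), term_id = "TT:0001",
                      stringsAsFactors = FALSE)
  db <- phenoverlap:::new_annotation_db(
    name = name, kind = "phenotype", associations = assoc,
    terms = data.frame(term_id = "TT:0001", term_name = "toy term",
                       is_sentinel = FALSE))
  standardize_db(db, u)
}

# Build a standardized db from a gene -> terms list, in code.
db_from_list <- function(gene_terms, universe, name = "LISTDB",
                         kind = "phenotype") {
  assoc <- do.call(rbind, lapply(names(gene_terms), function(g)
    data.frame(gene = g, term_id = gene_terms[[g]], stringsAsFactors = FALSE)))
  terms <- data.frame(term_id = sort(unique(assoc$term_id)),
                      stringsAsFactors = FALSE)
  terms$term_name <- terms$term_id
  terms$is_sentinel <- FALSE
  db <- phenoverlap:::new_annotation_db(name = name, kind = kind,
                                        associations = assoc, terms = terms)
  standardize_db(db, universe)
}

write_tsv_fixture <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# Independent oracle: upper-tail hypergeometric probability by exhaustive
# enumeration of every size-`set_size` subset of the universe.
brute_upper_tail <- function(g, gdb, set_size, universe_size) {
  if (set_size == 0L) return(as.numeric(g <= 0L))
  subsets <- utils::combn(universe_size, set_size)
  in_term <- subsets <= gdb   # term genes taken as labels 1..gdb
  mean(colSums(in_term) >= g)
}

# Direct transcription of the Forbes-Alroy formula, independent of the
# package implementation's shortcuts.
brute_forbes <- function(a, b, c) {
  n <- a + b + c
  if (n == 0) return(0)
  num <- a * (n + sqrt(n))
  den <- (a + b) * (a + c) + a * sqrt(n) + (b * c) / 2
  if (den == 0) return(0)
  num / den
}

# Benjamini-Hochberg step-up adjustment written out longhand.
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  out <- numeric(n)
  out[o] <- pmin(1, adj)
  out
}
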