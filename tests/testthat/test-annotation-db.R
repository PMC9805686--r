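test_that("association tables load with set semantics across dialects", {
  path <- write_tsv_fixture(c("A\tT1", "B\tT1", "B\tT2"))
  db <- load_association_table(path, "two_col", "phenotype", name = "X")
  expect_equal(length(unique(db$associations$gene)), 2L)
  expect_equal(nrow(db$terms), 2L)
  expect_equal(nrow(db$associations), 3L)

  dup <- write_tsv_fixture(c("A\tT1", "A\tT1", "B\tT1", "B\tT2"))
  expect_equal(nrow(load_association_table(dup, name = "X")$associations), 3L)

  hpo <- write_tsv_fixture(c("# comment", "HP:1\tSeizure\tSCN1A",
                             "HP:2\tAtaxia\tSCN1A"))
  db_h <- load_association_table(hpo, "hpo_g2p", name = "H")
  expect_setequal(db_h$associations$term_id, c("HP:1", "HP:2"))
  expect_equal(unique(db_h$associations$gene), "SCN1A")
  expect_equal(db_h$terms$term_name[db_h$terms$term_id == "HP:1"], "Seizure")

  mgi <- write_tsv_fixture(c("SCN1A\tMP:1\tabnormal gait"))
  db_m <- load_association_table(mgi, "mgi_rpt", name = "M")
  expect_equal(db_m$associations$gene, "SCN1A")
  expect_equal(db_m$terms$term_name, "abnormal gait")
})

test_that("empty and malformed association files are rejected with context", {
  empty <- write_tsv_fixture(c("# gene\tterm_id"))
  expect_error(load_association_table(empty, name = "X"), "no associations")
  bad <- write_tsv_fixture(c("A\tT1", "LONELYFIELD"))
  expect_error(load_association_table(bad, name = "X"), "line 2")
  expect_error(load_association_table(tempfile(), name = "X"), "not found")
})

test_that("standardization completes the universe with a sentinel term", {
  u <- gene_universe(c("A", "B", "C"))
  raw <- phenoverlap:::new_annotation_db(
    "D1", "phenotype",
    associations = data.frame(gene = "A", term_id = "T1"),
    terms = data.frame(term_id = "T1", term_name = "t", is_sentinel = FALSE))
  db <- standardize_db(raw, u)
  sent <- db$terms$term_id[db$terms$is_sentinel]
  expect_length(sent, 1L)
  expect_setequal(db$associations$gene[db$associations$term_id == sent],
                  c("B", "C"))
  expect_equal(length(db$universe), 3L)
  # every universe gene has at least one association, exactly
  expect_setequal(unique(db$associations$gene), u$symbols)
})

test_that("standardization normalizes case and drops out-of-universe genes", {
  u <- gene_universe("X1")
  raw <- phenoverlap:::new_annotation_db(
    "D1", "phenotype",
    associations = data.frame(gene = c("x1", "zz9"), term_id = c("T1", "T1")),
    terms = data.frame(term_id = "T1", term_name = "t", is_sentinel = FALSE))
  expect_warning(db <- standardize_db(raw, u), "dropped 1 gene")
  expect_true("X1" %in% db$associations$gene)
  expect_false("ZZ9" %in% db$associations$gene)
})

test_that("standardization is idempotent", {
  db <- toy_term_db()
  again <- standardize_db(db, gene_universe(db$universe))
  expect_identical(db$associations[order(db$associations$gene,
                                         db$associations$term_id), ],
                   again$associations[order(again$associations$gene,
                                            again$associations$term_id), ])
  expect_identical(db$terms, again$terms)
})

test_that("ortholog mapping expands to every mapped human symbol", {
  hu <- gene_universe(c("H1", "H2", "H3"))
  raw <- phenoverlap:::new_annotation_db(
    "MDB", "phenotype", organism = "mouse",
    associations = data.frame(gene = c("m1", "m2"), term_id = c("T1", "T2")),
    terms = data.frame(term_id = c("T1", "T2"), term_name = c("t1", "t2"),
                       is_sentinel = FALSE))
  map <- ortholog_map(mouse = c("m1", "m1"), human = c("H1", "H2"))
  expect_warning(db <- map_orthologs(raw, map, hu), "without ortholog")
  real <- db$associations[db$associations$term_id == "T1", ]
  expect_setequal(real$gene, c("H1", "H2"))
  # m2 unmapped: T2 gone; H3 untargeted: sentinel only
  expect_false("T2" %in% db$associations$term_id)
  sent <- db$terms$term_id[db$terms$is_sentinel]
  expect_true("H3" %in% db$associations$gene[db$associations$term_id == sent])
})

test_that("ortholog expansion count matches brute-force pair expansion", {
  hu <- gene_universe(sprintf("H%d", 1:6))
  mouse_genes <- c("m1", "m2", "m3")
  pairs <- data.frame(mouse = c("m1", "m1", "m2", "m3", "m3", "m3"),
                      human = c("H1", "H2", "H3", "H4", "H5", "H1"))
  assoc <- data.frame(gene = c("m1", "m2", "m3", "m3"),
                      term_id = c("T1", "T1", "T1", "T2"))
  raw <- phenoverlap:::new_annotation_db(
    "MDB", "phenotype", organism = "mouse", associations = assoc,
    terms = data.frame(term_id = c("T1", "T2"), term_name = c("t1", "t2"),
                       is_sentinel = FALSE))
  db <- map_orthologs(raw, ortholog_map(pairs$mouse, pairs$human), hu)
  # brute force: expand every association through every matching pair
  expected <- unique(merge(within(assoc, gene <- toupper(gene)),
                           within(pairs, mouse <- toupper(mouse)),
                           by.x = "gene", by.y = "mouse")[c("human", "term_id")])
  real <- db$associations[!db$associations$term_id %in%
                            db$terms$term_id[db$terms$is_sentinel], ]
  expect_equal(nrow(real), nrow(expected))
  expect_setequal(paste(real$gene, real$term_id),
                  paste(toupper(expected$human), expected$term_id))
})

test_that("CRISPR screens encode three class terms and omit empty classes", {
  u <- gene_universe(c("A", "B", "C"))
  scr <- data.frame(screen = "S", gene = c("A", "B"),
                    hit_class = c("Positive-Hit", "Negative-Hit"))
  db <- encode_crispr_screens(scr, u)
  by_term <- split(db$associations$gene, db$associations$term_id)
  expect_setequal(by_term[["S::association"]], c("A", "B"))
  expect_equal(by_term[["S::positive"]], "A")
  expect_equal(by_term[["S::negative"]], "B")
  sent <- db$terms$term_id[db$terms$is_sentinel]
  expect_equal(db$associations$gene[db$associations$term_id == sent], "C")

  only_pos <- encode_crispr_screens(
    data.frame(screen = "S", gene = "A", hit_class = "Positive-Hit"), u)
  expect_false("S::negative" %in% only_pos$terms$term_id)

  two <- encode_crispr_screens(
    data.frame(screen = c("S1", "S2"), gene = c("A", "B"),
               hit_class = c("Positive-Hit", "Negative-Hit")), u)
  expect_equal(sum(!two$terms$is_sentinel), 4L)  # 2 non-empty classes each
  expect_error(
    encode_crispr_screens(data.frame(screen = "S", gene = "A",
                                     hit_class = "Maybe-Hit"), u),
    "Maybe-Hit")
})

test_that("db_stats excludes the sentinel from its counts", {
  db <- toy_term_db()
  st <- db_stats(db)
  expect_equal(st$n_genes, 5L)
  expect_equal(st$n_terms, 1L)
  expect_equal(st$n_associations, 5L)
  expect_equal(st$n_sentinel_genes, 5L)
  expect_equal(st$universe_size, 10L)
})

test_that("two-column round trip reproduces the association set", {
  db <- toy_term_db()
  path <- tempfile(fileext = ".tsv")
  write_association_table(db, path)
  back <- load_association_table(path, "two_col", "phenotype", name = db$name)
  back <- standardize_db(back, gene_universe(db$universe))
  key <- function(d) sort(paste(d$associations$gene, d$associations$term_id))
  expect_identical(key(back), key(db))
})
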