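test_that("significant-term selection respects alpha, criterion and sentinels", {
  db <- toy_term_db()
  res <- enrich(sprintf("U%02d", 1:4), db)
  expect_length(significant_terms(res, alpha = 1e-6)$keys, 0L)
  raw <- significant_terms(res, criterion = "raw")
  bon <- significant_terms(res, criterion = "bonferroni")
  expect_true(all(bon$keys %in% raw$keys))
  # the sentinel term is tested (P = 10/45 here) but excluded by default
  sent_res <- enrich(c("U06", "U07"), db)
  expect_length(significant_terms(sent_res, alpha = 0.5)$keys, 0L)
  expect_length(significant_terms(sent_res, alpha = 0.5,
                                  include_sentinels = TRUE)$keys, 1L)
})

test_that("Jaccard POR matches its definition and the reported case ratios", {
  expect_equal(por_jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(por_jaccard(character(0), character(0)), 0)
  expect_equal(por_jaccard(c("a", "b"), c("b", "c")), 1 / 3)
  expect_equal(round(jaccard_from_counts(139, 273), 3), 0.509)
  expect_equal(round(jaccard_from_counts(106, 734), 3), 0.144)
})

test_that("Forbes-Alroy coefficient matches the printed formula and its limits", {
  expect_equal(por_forbes(overlap_counts(2, 1, 1)), 12 / 13.5, tolerance = 1e-12)
  expect_equal(por_forbes(overlap_counts(0, 5, 3)), 0)
  expect_equal(por_forbes(overlap_counts(3, 0, 2)), 1)
  expect_equal(por_forbes(overlap_counts(0, 0, 0)), 0)
  for (a in 0:12) for (b in 0:6) for (c in 0:6) {
    if (a + b + c > 12 || (b == 0 || c == 0)) next
    expect_equal(por_forbes(overlap_counts(a, b, c)), brute_forbes(a, b, c),
                 tolerance = 1e-12)
  }
})

test_that("both coefficients lie in [0,1] and increase in the shared count", {
  for (n in c(5L, 12L, 30L)) {
    prev_j <- -1; prev_f <- -1
    for (a in 0:n) {
      rest <- n - a
      b <- ceiling(rest / 2); c <- rest - b
      if (b == 0 || c == 0) next
      j <- a / n
      f <- por_forbes(overlap_counts(a, b, c))
      expect_gte(f, 0); expect_lte(f, 1)
      expect_gt(j, prev_j); expect_gt(f, prev_f)
      prev_j <- j; prev_f <- f
    }
  }
})

test_that("empirical P counts strictly greater null values", {
  expect_equal(empirical_pvalue(c(0.1, 0.2, 0.9), 0.5), 1 / 3)
  expect_equal(empirical_pvalue(c(0.5, 0.5), 0.5), 0)  # ties don't exceed
  expect_equal(empirical_pvalue(c(0.5, 0.5), 0.5, pseudocount = TRUE), 1)
  expect_equal(empirical_pvalue(c(0.1, 0.9), 0.5, pseudocount = TRUE), 2 / 3)
})

test_that("identical gene sets give POR 1 with empirical P 0 unless a null ties", {
  db <- toy_term_db()
  g <- sprintf("U%02d", 1:4)
  cmp <- por_significance(g, g, db, m = 20, mode = "overlapping", seed = 5)
  expect_equal(cmp$por, 1)
  expect_equal(cmp$empirical_p, 0)
  expect_length(cmp$null_values, 40L)  # 2m in overlapping mode
})

test_that("conditional mode randomizes only the derived side (m null values)", {
  db <- toy_term_db()
  cmp <- por_significance(sprintf("U%02d", 1:4), sprintf("U%02d", 2:5), db,
                          m = 15, mode = "conditional", seed = 9)
  expect_length(cmp$null_values, 15L)
  expect_true(cmp$empirical_p %in% ((0:15) / 15))
})

test_that("randomization is bit-reproducible under a fixed seed", {
  u <- gene_universe(sprintf("P%02d", 1:12))
  gl <- setNames(lapply(1:12, function(i)
    unique(sprintf("T%d", c(i %% 5, (i * 3) %% 7)))), u$symbols)
  db <- db_from_list(gl, u)
  a <- sprintf("P%02d", 1:4); b <- sprintf("P%02d", 3:6)
  c1 <- por_significance(a, b, db, m = 30, relaxed = TRUE, seed = 123)
  c2 <- por_significance(a, b, db, m = 30, relaxed = TRUE, seed = 123)
  expect_identical(c1$null_values, c2$null_values)
  expect_identical(c1$empirical_p, c2$empirical_p)
  c3 <- por_significance(a, b, db, m = 30, relaxed = TRUE, seed = 124)
  expect_false(identical(c1$null_values, c3$null_values))
})

test_that("m below 1 is rejected", {
  db <- toy_term_db()
  expect_error(por_significance("U01", "U02", db, m = 0), "at least 1")
})

test_that("RPOR applies the coefficient to all annotated terms", {
  u <- gene_universe(c("A", "B"))
  db <- db_from_list(list(A = c("T1", "T2"), B = c("T2", "T3")), u)
  expect_equal(rpor("A", "B", db), 1 / 3)
  db2 <- db_from_list(list(A = c("T1"), B = c("T2")), u, name = "L2")
  expect_equal(rpor("A", "B", db2), 0)
})

test_that("differential terms partition the union of significant terms", {
  db <- toy_term_db()
  res_a <- enrich(sprintf("U%02d", 1:4), db)
  res_b <- enrich(sprintf("U%02d", 2:5), db)
  d <- differential_terms(res_a, res_b)
  union_n <- length(union(significant_terms(res_a)$keys,
                          significant_terms(res_b)$keys))
  expect_equal(nrow(d$shared) + nrow(d$exclusive_a) + nrow(d$exclusive_b),
               union_n)
  same <- differential_terms(res_a, res_a)
  expect_equal(nrow(same$exclusive_a), 0L)
  expect_equal(nrow(same$exclusive_b), 0L)
})

test_that("exclusive rows carry the other set's P value (1 when untested)", {
  u <- gene_universe(sprintf("P%d", 1:20))
  db <- db_from_list(list(P1 = "TA", P2 = "TA", P3 = "TB", P4 = "TB",
                          P5 = "TC"), u)
  res_a <- enrich(c("P1", "P2"), db)   # TA strongly enriched
  res_b <- enrich(c("P5"), db)         # only TC tested
  d <- differential_terms(res_a, res_b, alpha = 0.05)
  ta <- d$exclusive_a[d$exclusive_a$term_id == "TA", ]
  expect_equal(nrow(ta), 1L)
  expect_equal(ta$p_raw_other, 1)      # untested in B -> upper-tail P 1
  other <- db_from_list(list(P1 = "TZ"), u, name = "OTHER")
  expect_error(differential_terms(res_a, enrich("P1", other)),
               "different databases")
})

test_that("relevance regression matches closed-form OLS", {
  perfect <- relevance_regression(c(1, 2, 3), c(2, 4, 6))
  expect_equal(perfect$slope, 2)
  expect_equal(perfect$r2_adj, 1)
  hand <- relevance_regression(c(1, 2, 3), c(1, 3, 2))
  expect_equal(hand$r2, 0.25, tolerance = 1e-12)
  expect_equal(hand$r2_adj, -0.5, tolerance = 1e-12)
  flat <- relevance_regression(c(1, 2, 3), c(2, 2, 2))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r2, 0)
  expect_true(flat$low_information)
  expect_false(relevance_regression(c(1, 2), c(1, 2))$defined)
  expect_false(relevance_regression(c(2, 2, 2), c(1, 3, 2))$defined)
})

test_that("summary messages state counts, POR and omit undefined clauses", {
  db <- toy_term_db()
  g <- sprintf("U%02d", 1:4)
  cmp <- por_significance(g, g, db, m = 10, seed = 2)
  expect_match(cmp$summary_message, "share 1 of 1 significant terms")
  expect_match(cmp$summary_message, "POR = 1.000")
  expect_false(grepl("R-squared", cmp$summary_message))  # < 3 shared terms
  none <- por_significance(c("U06", "U07"), c("U08", "U09"), db, m = 5,
                           seed = 3)
  expect_match(none$summary_message, "no significant terms")
})
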