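test_that("synthetic databases hit the target annotation density", {
  spec <- synthetic_db_spec(1000, 500, 10, seed = 1)
  db <- generate_synthetic_db(spec)
  st <- db_stats(db)
  realized <- st$n_associations / st$universe_size
  expect_lt(abs(realized - 10) / 10, 0.05)
  expect_equal(st$universe_size, 1000L)
})

test_that("the generator is seed-deterministic", {
  spec <- synthetic_db_spec(300, 80, 5, seed = 7)
  d1 <- generate_synthetic_db(spec)
  d2 <- generate_synthetic_db(spec)
  expect_identical(d1$associations, d2$associations)
  expect_identical(d1$terms, d2$terms)
  d3 <- generate_synthetic_db(synthetic_db_spec(300, 80, 5, seed = 8))
  expect_false(identical(d1$associations, d3$associations))
})

test_that("saturated and infeasible density specs behave as stated", {
  sat <- generate_synthetic_db(synthetic_db_spec(20, 6, 6, seed = 1))
  st <- db_stats(sat)
  expect_equal(st$n_associations, 20L * 6L)  # every gene carries every term
  expect_error(synthetic_db_spec(20, 6, 7), "infeasible")
})

test_that("a planted disease module adds co-associated genes and terms", {
  spec <- synthetic_db_spec(400, 100, 4, seed = 3,
                            disease_module = list(n_module_genes = 40,
                                                  n_module_terms = 10,
                                                  p_within = 0.5))
  db <- generate_synthetic_db(spec)
  mg <- attr(db, "module_genes"); mt <- attr(db, "module_terms")
  expect_length(mg, 40L)
  expect_length(mt, 10L)
  inside <- db$associations$gene %in% mg & db$associations$term_id %in% mt
  # ~ 40 * 10 * 0.5 within-module pairs, far above the background rate
  expect_gt(sum(inside), 100)
})

test_that("type-I grid is zero at alpha 0 and controlled at alpha 0.05", {
  db <- generate_synthetic_db(synthetic_db_spec(800, 150, 8, seed = 5))
  zero <- type1_experiment(db, sizes = c(10, 40), replicates = 20,
                           alpha = 0, seed = 11)
  expect_true(all(zero$fpr == 0))
  grid <- type1_experiment(db, sizes = c(10, 40), replicates = 300,
                           alpha = 0.05, metric = "per_term_all", seed = 12)
  # E[fpr] <= alpha for a valid exact test; allow 3 Monte-Carlo s.e.
  mc_se <- sqrt(0.05 * 0.95 / (300 * 150))
  expect_true(all(grid$fpr <= 0.05 + 3 * mc_se))
  expect_named(attr(grid, "size_correlation"), c("estimate", "p_value"))
})

test_that("per-term-tested FPR on sparse databases exceeds the dense-db rate", {
  sparse <- generate_synthetic_db(synthetic_db_spec(800, 300, 4.4, seed = 21,
                                                    name = "sparse"))
  dense <- generate_synthetic_db(synthetic_db_spec(800, 300, 17.7, seed = 21,
                                                   name = "dense"))
  grid <- type1_experiment(list(sparse, dense), sizes = 5, replicates = 400,
                           metric = "per_term_tested", seed = 22)
  expect_gt(grid$fpr[grid$database == "sparse"],
            grid$fpr[grid$database == "dense"])
})

test_that("artificial sets honour the mixture contract at the boundaries", {
  db <- generate_synthetic_db(synthetic_db_spec(1500, 250, 8, seed = 31))
  panel <- gene_set(db$universe[1:80], label = "panel")
  pure <- build_artificial_set(panel, db,
                               mixture_spec(60, 1, noise_rate = 0.05, seed = 1))
  expect_length(pure$genes, 60L)
  expect_true(all(pure$genes %in% panel$genes))
  off <- build_artificial_set(panel, db,
                              mixture_spec(60, 0, noise_rate = 0, seed = 2))
  expect_length(off$genes, 60L)
  expect_length(intersect(off$genes, panel$genes), 0L)
  for (p in seq(0, 1, 0.1)) {
    art <- build_artificial_set(panel, db,
                                mixture_spec(60, p, seed = 100 + round(10 * p)))
    expect_length(art$genes, 60L)
  }
  expect_error(
    build_artificial_set(panel, db, mixture_spec(2000, 1, seed = 1)),
    "seed panel too small")
})

test_that("mixture builds are deterministic in the spec seed", {
  db <- generate_synthetic_db(synthetic_db_spec(1000, 200, 8, seed = 41))
  panel <- gene_set(db$universe[1:70])
  ms <- mixture_spec(50, 0.5, seed = 9)
  expect_identical(build_artificial_set(panel, db, ms)$genes,
                   build_artificial_set(panel, db, ms)$genes)
})

test_that("POR rises with the seed-gene proportion on a planted-module db", {
  spec <- synthetic_db_spec(2000, 300, 8, seed = 51,
                            disease_module = list(n_module_genes = 120,
                                                  n_module_terms = 30,
                                                  p_within = 0.4))
  db <- generate_synthetic_db(spec)
  panel <- gene_set(attr(db, "module_genes"), label = "panel")
  sens <- por_sensitivity_experiment(panel, db, p_grid = c(0, 0.5, 1),
                                     replicates = 20, seed = 52)
  expect_equal(nrow(sens$table), 3L)
  expect_true(all(diff(sens$table$mean_por) > 0))
  expect_equal(sens$table$mean_por[3], 1)   # p = 1 reproduces the panel
  expect_gt(sens$fit$slope, 0)
  expect_equal(nrow(sens$welch), 2L)
})
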