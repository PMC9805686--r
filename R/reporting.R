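# File-level workflows and the command-line surface.
#
# The canonical machine outputs are TSV tables plus one JSON summary per
# analysis; all randomness flows from the single seed recorded in every
# summary, so outputs are reproducible byte-for-byte given (inputs,
# config, seed). A run log keeps timestamps, input checksums and the
# warnings raised while loading (e.g. dropped out-of-universe genes).

new_run_log <- function() {
  env <- new.env(parent = emptyenv())
  env$lines <- character(0)
  env$warnings <- character(0)
  env
}

log_event <- function(log, ...) {
  log$lines <- c(log$lines,
                 sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                         paste0(...)))
  invisible(log)
}

log_inputs <- function(log, paths) {
  for (p in paths) {
    log_event(log, sprintf("input %s md5=%s", p, unname(tools::md5sum(p))))
  }
  invisible(log)
}

write_run_log <- function(log, path) {
  writeLines(c(log$lines,
               if (length(log$warnings))
                 paste0("[warning] ", unique(log$warnings))), path)
  invisible(path)
}

collect_warnings <- function(log, expr) {
  withCallingHandlers(expr, warning = function(w) {
    log$warnings <- c(log$warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
}

#' Read an analysis configuration from YAML
#'
#' The file mirrors the command-line flags: fields such as `genes`,
#' `genes2`, `universe`, `databases` (a named map of
#' `{path, dialect, kind}`), `alpha`, `criterion`, `method`,
#' `permutations`, `conditional`, `relaxed`, `top`, `seed`, `out_prefix`.
#'
#' @param path Path to a YAML file.
#' @return A named list.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop_usage("config file not found: ", path)
  yaml::read_yaml(path)
}

config_defaults <- function(config) {
  defaults <- list(alpha = 0.05, mode = "upper_tail", criterion = "raw",
                   method = "jaccard", permutations = 1000L,
                   conditional = FALSE, relaxed = FALSE, top = 25L,
                   organism = "human", seed = 1L, out_prefix = "phenoverlap")
  utils::modifyList(defaults, config[!vapply(config, is.null, logical(1))])
}

load_config_databases <- function(config, log = NULL) {
  if (is.null(config$universe)) stop_usage("a universe file is required")
  if (is.null(config$databases) || length(config$databases) == 0L) {
    stop_usage("at least one database must be configured")
  }
  universe <- read_gene_universe(config$universe, organism = config$organism)
  dbs <- vector("list", length(config$databases))
  names(dbs) <- names(config$databases)
  for (nm in names(config$databases)) {
    entry <- config$databases[[nm]]
    db <- load_association_table(entry$path, dialect = entry$dialect %||% "two_col",
                                 kind = entry$kind %||% "phenotype", name = nm)
    dbs[[nm]] <- if (is.null(log)) suppressWarnings(standardize_db(db, universe))
      else collect_warnings(log, standardize_db(db, universe))
    if (!is.null(log)) {
      log_event(log, sprintf("database %s: %d terms, %d associations", nm,
                             nrow(dbs[[nm]]$terms), nrow(dbs[[nm]]$associations)))
    }
  }
  dbs
}

#' Run a file-level enrichment analysis
#'
#' Reads the gene list and configured databases, runs [enrich()] and
#' writes `<out_prefix>_enrichment.tsv` (full table),
#' `<out_prefix>_summary.json` (run parameters plus the `top` most
#' enriched terms) and `<out_prefix>_log.txt`.
#'
#' @param config A named list (see [read_analysis_config()]).
#' @return Invisibly, a list with the `pheno_enrichment` result and the
#'   output `paths`.
#' @export
run_enrich <- function(config) {
  config <- config_defaults(config)
  if (is.null(config$genes)) stop_usage("an input gene list ('genes') is required")
  log <- new_run_log()
  log_event(log, "enrich analysis started (seed ", config$seed, ")")
  log_inputs(log, c(config$genes, config$universe,
                    vapply(config$databases, `[[`, character(1), "path")))
  dbs <- load_config_databases(config, log)
  gs <- read_gene_list(config$genes, organism = config$organism)
  known <- unique(unlist(lapply(dbs, `[[`, "universe")))
  unknown <- setdiff(gs$genes, known)
  if (length(unknown)) {
    log$warnings <- c(log$warnings,
                      sprintf("%d input symbol(s) not in any universe: %s",
                              length(unknown), paste(unknown, collapse = ",")))
  }
  res <- enrich(gs, dbs, alpha = config$alpha, mode = config$mode)
  paths <- list(table = paste0(config$out_prefix, "_enrichment.tsv"),
                summary = paste0(config$out_prefix, "_summary.json"),
                log = paste0(config$out_prefix, "_log.txt"))
  write_tsv(res$table, paths$table)
  top_n <- min(as.integer(config$top), nrow(res$table))
  summary <- list(analysis = "enrich", set_label = res$set_label,
                  n_genes = length(gs$genes), n_unknown = length(unknown),
                  databases = res$databases, n_tested = res$n_tested,
                  alpha = config$alpha, mode = config$mode,
                  criterion = config$criterion, seed = config$seed,
                  top_terms = res$table[seq_len(top_n),
                                        c("database", "term_id", "term_name",
                                          "genes_in_set", "term_size", "p_raw",
                                          "p_bonferroni", "q_fdr")])
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  log_event(log, sprintf("tested %d terms; wrote %s", res$n_tested, paths$table))
  write_run_log(log, paths$log)
  invisible(list(result = res, paths = paths))
}

#' Run a file-level gene set comparison
#'
#' Reads two gene lists, runs [por_significance()] (conditional or
#' overlapping mode per the config) and writes `<out_prefix>_shared.tsv`,
#' `<out_prefix>_exclusive_set1.tsv`, `<out_prefix>_exclusive_set2.tsv`, a
#' JSON summary including the summary message, POR, empirical P value and
#' the full null distribution, and a log.
#'
#' @inheritParams run_enrich
#' @return Invisibly, a list with the `pheno_comparison` result and the
#'   output `paths`.
#' @export
run_compare <- function(config) {
  config <- config_defaults(config)
  if (is.null(config$genes1) || is.null(config$genes2)) {
    stop_usage("two input gene lists ('genes1', 'genes2') are required")
  }
  if (as.integer(config$permutations) < 1L) {
    stop_usage("permutations must be at least 1")
  }
  log <- new_run_log()
  log_event(log, "compare analysis started (seed ", config$seed, ")")
  log_inputs(log, c(config$genes1, config$genes2, config$universe,
                    vapply(config$databases, `[[`, character(1), "path")))
  dbs <- load_config_databases(config, log)
  g1 <- read_gene_list(config$genes1, organism = config$organism)
  g2 <- read_gene_list(config$genes2, organism = config$organism)
  cmp <- por_significance(g1, g2, dbs,
                          m = as.integer(config$permutations),
                          mode = if (isTRUE(config$conditional)) "conditional"
                                 else "overlapping",
                          method = config$method,
                          relaxed = isTRUE(config$relaxed),
                          alpha = config$alpha, criterion = config$criterion,
                          seed = as.integer(config$seed))
  paths <- list(shared = paste0(config$out_prefix, "_shared.tsv"),
                exclusive_a = paste0(config$out_prefix, "_exclusive_set1.tsv"),
                exclusive_b = paste0(config$out_prefix, "_exclusive_set2.tsv"),
                summary = paste0(config$out_prefix, "_summary.json"),
                log = paste0(config$out_prefix, "_log.txt"))
  write_tsv(cmp$shared, paths$shared)
  write_tsv(cmp$exclusive_a, paths$exclusive_a)
  write_tsv(cmp$exclusive_b, paths$exclusive_b)
  summary <- list(analysis = "compare",
                  set1 = g1$label, set2 = g2$label,
                  mode = cmp$mode, method = cmp$method, relaxed = cmp$relaxed,
                  m = cmp$m, n_null = length(cmp$null_values),
                  seed = config$seed, alpha = cmp$alpha,
                  criterion = cmp$criterion,
                  por = cmp$por, empirical_p = cmp$empirical_p,
                  counts = unclass(cmp$counts),
                  relevance = unclass(cmp$relevance),
                  message = cmp$summary_message,
                  null_values = cmp$null_values)
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  log_event(log, sprintf("POR = %.4f, empirical P = %.4g; wrote %s",
                         cmp$por, cmp$empirical_p, paths$summary))
  write_run_log(log, paths$log)
  invisible(list(result = cmp, paths = paths))
}

#' Write the bundled toy fixture set
#'
#' Generates a small deterministic fixture family used in the test suite
#' and documentation: a 40-gene universe, a toy phenotype database and a
#' toy disease database in the canonical two-column dialect, two gene
#' lists that each carry at least one strongly enriched term, and a YAML
#' config wiring them together.
#'
#' @param dir Output directory (created if needed).
#' @param seed Unused placeholder kept for interface stability; the
#'   fixtures are fully deterministic.
#' @return Invisibly, a named list of file paths.
#' @export
make_fixtures <- function(dir, seed = 42L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genes <- sprintf("FG%02d", 1:40)
  p <- function(...) file.path(dir, ...)
  paths <- list(universe = p("universe.txt"),
                pheno = p("toy_phenotype.tsv"),
                disease = p("toy_disease.tsv"),
                genes_a = p("genes_a.txt"),
                genes_b = p("genes_b.txt"),
                config = p("config.yaml"))
  writeLines(genes, paths$universe)

  i <- 1:40
  pheno <- rbind(
    data.frame(gene = genes, term = sprintf("TP:%04d", (i %% 12) + 1)),
    data.frame(gene = genes, term = sprintf("TP:%04d", ((i * 7) %% 12) + 1)),
    data.frame(gene = genes[1:8], term = "TP:0001"))
  pheno <- unique(pheno)
  writeLines(c("# gene\tterm_id\tterm_name",
               sprintf("%s\t%s\ttoy phenotype %s", pheno$gene, pheno$term,
                       sub("TP:0*", "", pheno$term))), paths$pheno)

  disease <- unique(rbind(
    data.frame(gene = genes, term = sprintf("TD:%04d", ((i * 3) %% 8) + 1)),
    data.frame(gene = genes[5:12], term = "TD:0002")))
  writeLines(c("# gene\tterm_id\tterm_name",
               sprintf("%s\t%s\ttoy disease %s", disease$gene, disease$term,
                       sub("TD:0*", "", disease$term))), paths$disease)

  writeLines(genes[1:8], paths$genes_a)
  writeLines(genes[5:12], paths$genes_b)
  yaml::write_yaml(list(
    universe = paths$universe,
    databases = list(
      TOYPHENO = list(path = paths$pheno, dialect = "two_col",
                      kind = "phenotype"),
      TOYDISEASE = list(path = paths$disease, dialect = "two_col",
                        kind = "disease")),
    genes = paths$genes_a, genes1 = paths$genes_a, genes2 = paths$genes_b,
    alpha = 0.05, permutations = 100, seed = as.integer(seed),
    out_prefix = p("toy")), paths$config)
  invisible(paths)
}

# ---- command-line surface ---------------------------------------------

BOOLEAN_FLAGS <- c("conditional", "relaxed", "pmf")

parse_cli_flags <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop_usage("unexpected argument: ", a)
    key <- gsub("-", "_", substring(a, 3L))
    if (key %in% BOOLEAN_FLAGS) {
      out[[key]] <- TRUE
      i <- i + 1L
    } else {
      if (i == length(args)) stop_usage("flag ", a, " needs a value")
      if (key == "db") {
        out$db <- c(out$db, args[i + 1L])
      } else {
        out[[key]] <- args[i + 1L]
      }
      i <- i + 2L
    }
  }
  out
}

# NAME=PATH[:DIALECT[:KIND]] -> config database entry
parse_db_flag <- function(specs) {
  out <- list()
  for (s in specs) {
    eq <- regexpr("=", s, fixed = TRUE)
    if (eq < 0) stop_usage("--db expects NAME=PATH[:DIALECT[:KIND]], got: ", s)
    name <- substring(s, 1L, eq - 1L)
    rest <- strsplit(substring(s, eq + 1L), ":", fixed = TRUE)[[1L]]
    out[[name]] <- list(path = rest[1L],
                        dialect = if (length(rest) >= 2L) rest[2L] else "two_col",
                        kind = if (length(rest) >= 3L) rest[3L] else "phenotype")
  }
  out
}

flags_to_config <- function(flags) {
  config <- if (!is.null(flags$config)) read_analysis_config(flags$config) else list()
  if (!is.null(flags$db)) config$databases <- parse_db_flag(flags$db)
  for (k in c("genes", "genes1", "genes2", "universe", "mode", "criterion",
              "method", "out_prefix", "organism")) {
    if (!is.null(flags[[k]])) config[[k]] <- flags[[k]]
  }
  for (k in c("alpha", "noise")) {
    if (!is.null(flags[[k]])) config[[k]] <- as.numeric(flags[[k]])
  }
  for (k in c("permutations", "seed", "top", "reps")) {
    if (!is.null(flags[[k]])) config[[k]] <- as.integer(flags[[k]])
  }
  for (k in BOOLEAN_FLAGS) {
    if (isTRUE(flags[[k]])) config[[k]] <- TRUE
  }
  config
}

cli_usage <- function() {
  paste(
    "usage: phenoverlap <command> [flags]",
    "commands:",
    "  enrich                  --genes FILE --universe FILE --db NAME=PATH[:DIALECT[:KIND]] ...",
    "                          [--alpha A] [--mode upper_tail|pmf] [--top N]",
    "                          [--out-prefix P] [--seed N] [--config YAML]",
    "  compare                 --genes1 FILE --genes2 FILE --universe FILE --db ...",
    "                          [--method jaccard|forbes] [--permutations M]",
    "                          [--conditional] [--relaxed] [--alpha A] [--seed N]",
    "                          [--out-prefix P] [--config YAML]",
    "  simulate-type1          --n-genes N --n-terms T --mean M --sizes 5,10,...",
    "                          [--reps R] [--metric ...] [--alpha A] [--seed N] --out TSV",
    "  simulate-por-sensitivity --n-genes N --n-terms T --mean M [--p-grid 0,0.1,...]",
    "                          [--reps R] [--noise X] [--seed N] --out TSV",
    "  db-stats                --universe FILE --db ... [--json OUT]",
    "  fixtures                --dir DIR [--seed N]",
    sep = "\n")
}

parse_grid <- function(s) {
  if (grepl(":", s, fixed = TRUE)) {
    parts <- as.numeric(strsplit(s, ":", fixed = TRUE)[[1L]])
    if (length(parts) != 3L || anyNA(parts)) stop_usage("bad grid: ", s)
    seq(parts[1L], parts[2L], by = parts[3L])
  } else {
    out <- as.numeric(strsplit(s, ",", fixed = TRUE)[[1L]])
    if (anyNA(out)) stop_usage("bad grid: ", s)
    out
  }
}

cli_simulate_type1 <- function(flags) {
  for (k in c("n_genes", "n_terms", "mean", "sizes", "out")) {
    if (is.null(flags[[k]])) stop_usage("simulate-type1 requires --",
                                        gsub("_", "-", k))
  }
  seed <- as.integer(flags$seed %||% 1L)
  spec <- synthetic_db_spec(as.integer(flags$n_genes), as.integer(flags$n_terms),
                            as.numeric(flags$mean), seed = seed)
  db <- generate_synthetic_db(spec)
  grid <- type1_experiment(db, sizes = as.integer(parse_grid(flags$sizes)),
                           replicates = as.integer(flags$reps %||% 1000L),
                           alpha = as.numeric(flags$alpha %||% 0.05),
                           metric = flags$metric %||% "per_term_all",
                           seed = child_seed(seed, 1L))
  write_tsv(grid, flags$out)
  message("wrote ", flags$out)
  0L
}

cli_simulate_por_sensitivity <- function(flags) {
  for (k in c("n_genes", "n_terms", "mean", "out")) {
    if (is.null(flags[[k]])) stop_usage("simulate-por-sensitivity requires --",
                                        gsub("_", "-", k))
  }
  seed <- as.integer(flags$seed %||% 1L)
  spec <- synthetic_db_spec(
    as.integer(flags$n_genes), as.integer(flags$n_terms),
    as.numeric(flags$mean), seed = seed,
    disease_module = list(n_module_genes = max(50L, as.integer(flags$n_genes) %/% 20L),
                          n_module_terms = max(20L, as.integer(flags$n_terms) %/% 25L),
                          p_within = 0.35))
  db <- generate_synthetic_db(spec)
  panel_size <- min(length(attr(db, "module_genes")), 261L)
  panel <- gene_set(attr(db, "module_genes")[seq_len(panel_size)],
                    label = "planted panel")
  sens <- por_sensitivity_experiment(
    panel, db, p_grid = parse_grid(flags$p_grid %||% "0:1:0.1"),
    replicates = as.integer(flags$reps %||% 100L),
    noise_rate = as.numeric(flags$noise %||% 0.05),
    seed = child_seed(seed, 2L))
  write_tsv(sens$table, flags$out)
  message(sprintf("wrote %s (fit R2 = %.4f, slope P = %.3g)", flags$out,
                  sens$fit$r2, sens$fit$p_value))
  0L
}

#' Command-line entry point
#'
#' Dispatches the subcommands `enrich`, `compare`, `simulate-type1`,
#' `simulate-por-sensitivity`, `db-stats` and `fixtures`. Used by the
#' installed `phenoverlap` script; callable directly for testing.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status: 0 success, 2 usage error, 3 data error.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0L) stop_usage(cli_usage())
    cmd <- args[1L]
    flags <- parse_cli_flags(args[-1L])
    switch(cmd,
      enrich = { run_enrich(flags_to_config(flags)); 0L },
      compare = { run_compare(flags_to_config(flags)); 0L },
      `simulate-type1` = cli_simulate_type1(flags),
      `simulate-por-sensitivity` = cli_simulate_por_sensitivity(flags),
      `db-stats` = {
        config <- config_defaults(flags_to_config(flags))
        dbs <- load_config_databases(config)
        stats <- lapply(dbs, function(d) unclass(db_stats(d)))
        if (!is.null(flags$json)) {
          jsonlite::write_json(stats, flags$json, auto_unbox = TRUE,
                               digits = NA, pretty = TRUE)
          message("wrote ", flags$json)
        } else {
          for (s in stats) print(structure(s, class = "db_stats"))
        }
        0L
      },
      fixtures = {
        if (is.null(flags$dir)) stop_usage("fixtures requires --dir")
        make_fixtures(flags$dir, seed = as.integer(flags$seed %||% 42L))
        message("fixtures written to ", flags$dir)
        0L
      },
      stop_usage("unknown command '", cmd, "'\n", cli_usage()))
  },
  phenoverlap_usage_error = function(e) { message(conditionMessage(e)); 2L },
  error = function(e) { message("error: ", conditionMessage(e)); 3L })
  invisible(status)
}
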