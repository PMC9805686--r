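# Hypergeometric term enrichment of one gene set against one or more
# standardized annotation databases.
#
# For a term annotating gdb of the GDB universe genes, and a query set of
# |G| genes of which g carry the term, the enrichment P value is the exact
# hypergeometric upper tail P(X >= g). The point probability P(X = g) is
# retained as an alternative mode; it is not a valid tail P value for g
# near its expectation but allows literal comparison with tools that
# report it.

#' Exact hypergeometric term P value
#'
#' @param g Number of query genes annotated to the term.
#' @param gdb Number of universe genes annotated to the term.
#' @param set_size Query set size |G| (genes inside the universe).
#' @param universe_size Universe size GDB.
#' @param mode `"upper_tail"` for P(X >= g) (default) or `"pmf"` for the
#'   point probability P(X = g).
#' @return A probability. Vectorized over `g`, `gdb`.
#' @examples
#' term_pvalue(4, 5, 4, 10)            # 5/210
#' term_pvalue(1, 3, 2, 6, mode = "pmf")  # 9/15
#' @export
term_pvalue <- function(g, gdb, set_size, universe_size,
                        mode = c("upper_tail", "pmf")) {
  mode <- match.arg(mode)
  g <- as.integer(g); gdb <- as.integer(gdb)
  set_size <- as.integer(set_size); universe_size <- as.integer(universe_size)
  if (any(g < 0L) || any(g > pmin(gdb, set_size)) ||
      any(gdb > universe_size) || any(set_size > universe_size) ||
      any(gdb < 0L) || any(set_size < 0L) || any(universe_size < 1L)) {
    stop_data("term_pvalue: arguments violate 0 <= g <= min(gdb, set_size) <= universe_size")
  }
  if (mode == "upper_tail") {
    stats::phyper(g - 1L, gdb, universe_size - gdb, set_size,
                  lower.tail = FALSE)
  } else {
    stats::dhyper(g, gdb, universe_size - gdb, set_size)
  }
}

#' Adjust a vector of P values for multiple testing
#'
#' `"bonferroni"` returns `min(1, n * p)`; `"bh_fdr"` the
#' Benjamini-Hochberg step-up adjusted values.
#'
#' @param p Numeric vector of probabilities in \[0, 1\].
#' @param method `"bonferroni"` or `"bh_fdr"`.
#' @return Adjusted values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh_fdr")) {
  method <- match.arg(method)
  if (length(p) && (any(!is.finite(p)) || any(p < 0) || any(p > 1))) {
    stop_data("adjust_pvalues: p values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = c(bonferroni = "bonferroni", bh_fdr = "BH")[[method]])
}

# Tested-term counts for one database: integer vector g over all term
# positions, given genes already inside the universe. The hot path of every
# randomization replicate.
.term_counts <- function(db, genes) {
  idx <- unlist(db$index$gene_terms[genes], use.names = FALSE)
  tabulate(idx %||% integer(0), nbins = length(db$index$term_id))
}

# P values for all tested (g >= 1) terms of one db. Returns positions,
# counts and raw P values.
.tested_pvalues <- function(db, genes, mode = "upper_tail") {
  cnt <- .term_counts(db, genes)
  pos <- which(cnt > 0L)
  gdb <- db$index$gdb[pos]
  n <- length(genes)
  N <- length(db$universe)
  p <- if (mode == "upper_tail") {
    stats::phyper(cnt[pos] - 1L, gdb, N - gdb, n, lower.tail = FALSE)
  } else {
    stats::dhyper(cnt[pos], gdb, N - gdb, n)
  }
  list(pos = pos, g = cnt[pos], gdb = gdb, p = p)
}

check_db_list <- function(dbs) {
  if (inherits(dbs, "annotation_db")) dbs <- list(dbs)
  stopifnot(length(dbs) >= 1L, all(vapply(dbs, inherits, logical(1), "annotation_db")))
  for (db in dbs) {
    if (!db$standardized) {
      stop_data("database '", db$name, "' must be standardized before analysis")
    }
  }
  names(dbs) <- vapply(dbs, `[[`, character(1), "name")
  if (anyDuplicated(names(dbs))) stop_data("database names must be unique")
  dbs
}

#' Phenotype / disease enrichment of a gene set
#'
#' Tests every term annotated to at least one query gene (terms with
#' `g = 0` are not tested). Bonferroni and Benjamini-Hochberg adjustment is
#' computed jointly across all tested terms of all selected databases
#' (`adjust_scope = "pooled"`, the default) or within each database
#' (`"per_db"`). Sentinel terms are tested like any other and flagged via
#' `is_sentinel`.
#'
#' @param genes A [gene_set()] or character vector of symbols.
#' @param dbs A standardized `annotation_db` or list of them.
#' @param alpha Significance level attached to the result (default 0.05).
#' @param mode Tail convention passed to [term_pvalue()].
#' @param adjust_scope `"pooled"` or `"per_db"`.
#' @param keep_genes Record the contributing gene symbols per term
#'   (comma-separated) in the table? Default `TRUE`.
#' @return An object of class `pheno_enrichment`: a list with `table`
#'   (one row per tested (database, term), sorted by raw P value with ties
#'   broken by database then term id), `set_label`, `alpha`, `mode`,
#'   `adjust_scope` and `n_tested`.
#' @export
enrich <- function(genes, dbs, alpha = 0.05,
                   mode = c("upper_tail", "pmf"),
                   adjust_scope = c("pooled", "per_db"),
                   keep_genes = TRUE) {
  mode <- match.arg(mode)
  adjust_scope <- match.arg(adjust_scope)
  gs <- as_gene_set(genes)
  dbs <- check_db_list(dbs)
  blocks <- lapply(dbs, function(db) {
    inside <- intersect(gs$genes, db$universe)
    tp <- .tested_pvalues(db, inside, mode = mode)
    if (length(tp$pos) == 0L) return(NULL)
    tab <- data.frame(
      database = db$name,
      term_id = db$index$term_id[tp$pos],
      term_name = db$terms$term_name[tp$pos],
      kind = db$kind,
      is_sentinel = db$index$is_sentinel[tp$pos],
      genes_in_set = tp$g,
      term_size = tp$gdb,
      set_size = length(inside),
      universe_size = length(db$universe),
      p_raw = tp$p,
      stringsAsFactors = FALSE)
    if (keep_genes) {
      hits <- db$associations[db$associations$gene %in% inside, , drop = FALSE]
      by_term <- vapply(split(hits$gene, hits$term_id), function(gv)
        paste(sort(gv), collapse = ","), character(1))
      tab$genes <- unname(by_term[tab$term_id])
    }
    tab
  })
  blocks <- blocks[!vapply(blocks, is.null, logical(1))]
  if (length(blocks) == 0L) {
    stop_data("gene set '", gs$label, "' is disjoint from every database universe")
  }
  tab <- do.call(rbind, blocks)
  rownames(tab) <- NULL
  if (adjust_scope == "pooled") {
    tab$p_bonferroni <- adjust_pvalues(tab$p_raw, "bonferroni")
    tab$q_fdr <- adjust_pvalues(tab$p_raw, "bh_fdr")
  } else {
    tab$p_bonferroni <- NA_real_
    tab$q_fdr <- NA_real_
    for (d in unique(tab$database)) {
      i <- tab$database == d
      tab$p_bonferroni[i] <- adjust_pvalues(tab$p_raw[i], "bonferroni")
      tab$q_fdr[i] <- adjust_pvalues(tab$p_raw[i], "bh_fdr")
    }
  }
  ord <- order(tab$p_raw, tab$database, tab$term_id)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, set_label = gs$label, alpha = alpha,
                 mode = mode, adjust_scope = adjust_scope,
                 databases = names(dbs), n_tested = nrow(tab)),
            class = "pheno_enrichment")
}

#' @export
print.pheno_enrichment <- function(x, n = 10L, ...) {
  cat(sprintf("<pheno_enrichment> '%s': %d tested terms across %s (alpha = %g, %s)\n",
              x$set_label, x$n_tested, paste(x$databases, collapse = ", "),
              x$alpha, x$mode))
  cols <- c("database", "term_id", "term_name", "genes_in_set", "term_size",
            "p_raw", "p_bonferroni", "q_fdr")
  print(utils::head(x$table[cols], n))
  invisible(x)
}
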