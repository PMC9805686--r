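# Phenotype-level similarity between two gene sets.
#
# Two gene sets are compared through the sets of terms significantly
# enriched in each (the Phenotypic Overlap Ratio, POR) or through all
# annotated terms (the relaxed variant, RPOR). The agreement between the
# two term sets is scored with the Jaccard index or the Forbes similarity
# coefficient with Alroy's correction, and tested by randomization against
# gene sets drawn uniformly from the universe.

#' Select the significant terms of an enrichment result
#'
#' @param result A `pheno_enrichment` from [enrich()].
#' @param alpha Significance level; defaults to the level stored in
#'   `result`.
#' @param criterion Which P value is thresholded: `"raw"` (default, the
#'   rule "a term with P < alpha is enriched"), `"bonferroni"` or `"fdr"`.
#' @param include_sentinels Keep sentinel no-annotation terms? They are
#'   excluded by default from similarity and differential analyses.
#' @return An object of class `significant_terms`: a list with `label`,
#'   `keys` (character vector of `database<TAB>term_id`), `table` (the
#'   matching enrichment rows), `alpha` and `criterion`.
#' @export
significant_terms <- function(result, alpha = NULL,
                              criterion = c("raw", "bonferroni", "fdr"),
                              include_sentinels = FALSE) {
  stopifnot(inherits(result, "pheno_enrichment"))
  criterion <- match.arg(criterion)
  alpha <- alpha %||% result$alpha
  tab <- result$table
  p <- switch(criterion, raw = tab$p_raw, bonferroni = tab$p_bonferroni,
              fdr = tab$q_fdr)
  keep <- p < alpha
  if (!include_sentinels) keep <- keep & !tab$is_sentinel
  tab <- tab[keep, , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(label = result$set_label,
                 keys = term_key(tab$database, tab$term_id),
                 table = tab, alpha = alpha, criterion = criterion),
            class = "significant_terms")
}

#' @export
print.significant_terms <- function(x, ...) {
  cat(sprintf("<significant_terms> '%s': %d terms (%s P < %g)\n",
              x$label, length(x$keys), x$criterion, x$alpha))
  invisible(x)
}

as_term_keys <- function(x) {
  if (inherits(x, "significant_terms")) return(x$keys)
  if (is.character(x)) return(unique(x))
  stop_data("expected a significant_terms object or character vector of term keys")
}

#' Overlap counts between two term sets
#'
#' @param a Number of terms in both sets.
#' @param b Number of terms only in the first set.
#' @param c Number of terms only in the second set.
#' @return A list of class `overlap_counts` with `a`, `b`, `c` and
#'   `n = a + b + c`.
#' @export
overlap_counts <- function(a, b, c) {
  a <- as.integer(a); b <- as.integer(b); c <- as.integer(c)
  stopifnot(length(a) == 1L, length(b) == 1L, length(c) == 1L)
  if (any(c(a, b, c) < 0L)) stop_data("overlap counts must be non-negative")
  structure(list(a = a, b = b, c = c, n = a + b + c), class = "overlap_counts")
}

#' Count the overlap between two significant-term sets
#' @param A,B `significant_terms` objects or character key vectors.
#' @return An [overlap_counts()] object.
#' @export
count_overlap <- function(A, B) {
  ka <- as_term_keys(A); kb <- as_term_keys(B)
  a <- length(intersect(ka, kb))
  overlap_counts(a, length(ka) - a, length(kb) - a)
}

#' Jaccard Phenotypic Overlap Ratio
#'
#' `|A n B| / |A u B|`; defined as 0 when both sets are empty.
#'
#' @inheritParams count_overlap
#' @return A value in \[0, 1\].
#' @export
por_jaccard <- function(A, B) {
  cnt <- count_overlap(A, B)
  if (cnt$n == 0L) return(0)
  cnt$a / cnt$n
}

#' Jaccard ratio from printed overlap counts
#'
#' Convenience for reproducing reported overlap ratios when only the
#' shared and union term counts are known.
#'
#' @param n_shared Number of terms significant in both sets.
#' @param n_union Number of unique significant terms across both sets.
#' @return `n_shared / n_union` (0 when the union is empty).
#' @export
jaccard_from_counts <- function(n_shared, n_union) {
  stopifnot(n_shared >= 0, n_union >= n_shared)
  if (n_union == 0) return(0)
  n_shared / n_union
}

#' Forbes similarity coefficient with Alroy's correction
#'
#' With `a = |A n B|`, `b = |A \\ B|`, `c = |B \\ A|` and `n = a + b + c`:
#' `a (n + sqrt(n)) / ((a + b)(a + c) + a sqrt(n) + b c / 2)`.
#' The coefficient is 0 when nothing is shared and exactly 1 whenever one
#' set is a subset of the other (`b = 0` or `c = 0`).
#'
#' @param A An [overlap_counts()] object, a `significant_terms` object or
#'   key vector.
#' @param B Second term set; omitted when `A` is an `overlap_counts`.
#' @return A value in \[0, 1\].
#' @export
por_forbes <- function(A, B = NULL) {
  cnt <- if (inherits(A, "overlap_counts")) A else count_overlap(A, B)
  a <- cnt$a; b <- cnt$b; c <- cnt$c; n <- cnt$n
  if (n == 0L || a == 0L) return(0)
  if (b == 0L || c == 0L) return(1)
  a * (n + sqrt(n)) / ((a + b) * (a + c) + a * sqrt(n) + b * c / 2)
}

por_value <- function(A, B, method) {
  switch(method, jaccard = por_jaccard(A, B), forbes = por_forbes(A, B))
}

#' Empirical P value from a randomization null
#'
#' The proportion of null statistics strictly greater than the observed
#' one; ties do not count as exceeding. With `pseudocount = TRUE` the
#' add-one variant `(1 + #\{null >= obs\}) / (m + 1)` is returned, which is
#' never exactly zero.
#'
#' @param null_values Numeric vector of null statistics.
#' @param observed Observed statistic.
#' @param pseudocount Use the add-one correction? Default `FALSE`.
#' @return A probability.
#' @export
empirical_pvalue <- function(null_values, observed, pseudocount = FALSE) {
  stopifnot(length(null_values) >= 1L, length(observed) == 1L)
  if (pseudocount) {
    (1 + sum(null_values >= observed)) / (length(null_values) + 1)
  } else {
    sum(null_values > observed) / length(null_values)
  }
}

# Significant-term keys for a gene set already normalized per database,
# without building a result table: the randomization hot path.
# `genes` must lie inside every database's universe.
.sig_keys <- function(dbs, genes, alpha = 0.05, criterion = "raw",
                      relaxed = FALSE, include_sentinels = FALSE,
                      mode = "upper_tail") {
  pos_l <- vector("list", length(dbs)); p_l <- pos_l; db_l <- pos_l
  for (i in seq_along(dbs)) {
    db <- dbs[[i]]
    tp <- .tested_pvalues(db, genes, mode = mode)
    keep <- if (include_sentinels) rep(TRUE, length(tp$pos)) else
      !db$index$is_sentinel[tp$pos]
    pos_l[[i]] <- tp$pos[keep]
    p_l[[i]] <- tp$p[keep]
    db_l[[i]] <- rep.int(i, sum(keep))
  }
  pos <- unlist(pos_l, use.names = FALSE)
  if (length(pos) == 0L) return(character(0))
  p <- unlist(p_l, use.names = FALSE)
  dbi <- unlist(db_l, use.names = FALSE)
  keep <- if (relaxed) {
    rep(TRUE, length(p))
  } else {
    switch(criterion,
           raw = p < alpha,
           bonferroni = adjust_pvalues(p, "bonferroni") < alpha,
           fdr = adjust_pvalues(p, "bh_fdr") < alpha)
  }
  pos <- pos[keep]; dbi <- dbi[keep]
  if (length(pos) == 0L) return(character(0))
  nm <- vapply(dbs, `[[`, character(1), "name")
  keys <- vector("list", length(dbs))
  for (i in unique(dbi)) {
    keys[[i]] <- term_key(nm[i], dbs[[i]]$index$term_id[pos[dbi == i]])
  }
  unlist(keys, use.names = FALSE)
}

#' Randomization significance of the Phenotypic Overlap Ratio
#'
#' Computes the POR between `G` and `G2` and its empirical P value under
#' random gene sets drawn uniformly, without replacement, from the
#' intersection of the selected databases' universes.
#'
#' Two null modes are available. In `"overlapping"` mode (sets that may
#' share genes) each of the `m` replicates draws a random set of size
#' `|G|` and one of size `|G2|`, and records both `POR(G, R'_i)` and
#' `POR(R_i, G2)` — one side randomized at a time while the other keeps its
#' real phenotype structure — giving `2m` null values. In `"conditional"`
#' mode (`G2` derived from `G`, sets disjoint) only the derived side is
#' randomized: `m` values `POR(G, R_i)` with `|R_i| = |G2|`. The empirical
#' P value is the proportion of null values strictly greater than the
#' observed POR.
#'
#' @param G,G2 [gene_set()] objects or character vectors.
#' @param dbs Standardized `annotation_db` or list of them.
#' @param m Number of random replicates (>= 1).
#' @param mode `"overlapping"` or `"conditional"`.
#' @param method `"jaccard"` or `"forbes"`.
#' @param relaxed Use all annotated terms instead of significant ones
#'   (RPOR)? Default `FALSE`.
#' @param alpha,criterion Significance rule defining the term sets (see
#'   [significant_terms()]).
#' @param seed Integer seed; the null is fully determined by it.
#' @param pseudocount Passed to [empirical_pvalue()].
#' @param include_sentinels Keep sentinel terms in the term sets?
#' @return An object of class `pheno_comparison`; see
#'   [pheno_message()] for the one-paragraph summary. Fields include
#'   `por`, `empirical_p`, `null_values`, `counts`, `shared`,
#'   `exclusive_a`, `exclusive_b`, `relevance`, `summary_message`.
#' @export
por_significance <- function(G, G2, dbs, m = 1000L,
                             mode = c("overlapping", "conditional"),
                             method = c("jaccard", "forbes"),
                             relaxed = FALSE, alpha = 0.05,
                             criterion = c("raw", "bonferroni", "fdr"),
                             seed = NULL, pseudocount = FALSE,
                             include_sentinels = FALSE) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  criterion <- match.arg(criterion)
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop_data("m must be at least 1")
  dbs <- check_db_list(dbs)
  G <- as_gene_set(G, label = "G")
  G2 <- as_gene_set(G2, label = "G2")
  universe <- Reduce(intersect, lapply(dbs, `[[`, "universe"))
  size_g <- length(intersect(G$genes, universe))
  size_g2 <- length(intersect(G2$genes, universe))
  if (size_g == 0L || size_g2 == 0L) {
    stop_data("both gene sets must intersect the shared database universe")
  }
  if (length(universe) < max(size_g, size_g2)) {
    stop_data("shared universe smaller than the larger gene set")
  }

  res_a <- enrich(G, dbs, alpha = alpha)
  res_b <- enrich(G2, dbs, alpha = alpha)
  keys_a <- .sig_keys(dbs, intersect(G$genes, universe), alpha, criterion,
                      relaxed, include_sentinels)
  keys_b <- .sig_keys(dbs, intersect(G2$genes, universe), alpha, criterion,
                      relaxed, include_sentinels)
  observed <- por_value(keys_a, keys_b, method)
  counts <- count_overlap(keys_a, keys_b)

  null_fixed_g <- numeric(0)
  null_fixed_g2 <- numeric(0)
  with_seed(seed, {
    if (mode == "conditional") {
      null_fixed_g <- vapply(seq_len(m), function(i) {
        r <- sample(universe, size_g2)
        por_value(keys_a,
                  .sig_keys(dbs, r, alpha, criterion, relaxed, include_sentinels),
                  method)
      }, numeric(1))
    } else {
      null_fixed_g <- numeric(m)
      null_fixed_g2 <- numeric(m)
      for (i in seq_len(m)) {
        r2 <- sample(universe, size_g2)
        null_fixed_g[i] <- por_value(
          keys_a, .sig_keys(dbs, r2, alpha, criterion, relaxed, include_sentinels),
          method)
        r1 <- sample(universe, size_g)
        null_fixed_g2[i] <- por_value(
          .sig_keys(dbs, r1, alpha, criterion, relaxed, include_sentinels),
          keys_b, method)
      }
    }
  })
  null_values <- c(null_fixed_g, null_fixed_g2)
  emp_p <- empirical_pvalue(null_values, observed, pseudocount = pseudocount)

  diff <- differential_terms(res_a, res_b, alpha = alpha,
                             criterion = criterion,
                             include_sentinels = include_sentinels)
  relevance <- relevance_regression(diff$shared$genes_in_set_a,
                                    diff$shared$genes_in_set_b)
  out <- structure(list(
    label_a = G$label, label_b = G2$label,
    por = observed, method = method, relaxed = relaxed,
    mode = mode, m = m, seed = seed,
    empirical_p = emp_p, pseudocount = pseudocount,
    null_values = null_values,
    null_fixed_g = null_fixed_g, null_fixed_g2 = null_fixed_g2,
    counts = counts,
    shared = diff$shared, exclusive_a = diff$exclusive_a,
    exclusive_b = diff$exclusive_b,
    relevance = relevance,
    alpha = alpha, criterion = criterion,
    summary_message = NULL), class = "pheno_comparison")
  out$summary_message <- pheno_message(out)
  out
}

#' Relaxed Phenotypic Overlap Ratio
#'
#' The POR coefficient applied to the sets of all non-sentinel terms
#' annotated to at least one gene of each set, whether significantly
#' enriched or not. Significance is available through
#' [por_significance()] with `relaxed = TRUE`.
#'
#' @inheritParams por_significance
#' @return A value in \[0, 1\].
#' @export
rpor <- function(G, G2, dbs, method = c("jaccard", "forbes"),
                 include_sentinels = FALSE) {
  method <- match.arg(method)
  dbs <- check_db_list(dbs)
  G <- as_gene_set(G, label = "G")
  G2 <- as_gene_set(G2, label = "G2")
  universe <- Reduce(intersect, lapply(dbs, `[[`, "universe"))
  keys_a <- .sig_keys(dbs, intersect(G$genes, universe), relaxed = TRUE,
                      include_sentinels = include_sentinels)
  keys_b <- .sig_keys(dbs, intersect(G2$genes, universe), relaxed = TRUE,
                      include_sentinels = include_sentinels)
  por_value(keys_a, keys_b, method)
}

#' Differential phenotypes between two enrichment results
#'
#' Splits the union of significant terms into terms significant in both
#' results (`shared`), only in the first (`exclusive_a`) and only in the
#' second (`exclusive_b`). Exclusive rows carry the term's raw P value in
#' the other gene set; a term not tested there (no annotated gene) has
#' upper-tail P value 1.
#'
#' @param res_a,res_b `pheno_enrichment` results computed over the same
#'   databases.
#' @inheritParams significant_terms
#' @return A list with data frames `shared`, `exclusive_a`, `exclusive_b`.
#' @export
differential_terms <- function(res_a, res_b, alpha = NULL,
                               criterion = c("raw", "bonferroni", "fdr"),
                               include_sentinels = FALSE) {
  stopifnot(inherits(res_a, "pheno_enrichment"),
            inherits(res_b, "pheno_enrichment"))
  criterion <- match.arg(criterion)
  if (!identical(sort(res_a$databases), sort(res_b$databases))) {
    stop_data("results were computed over different databases")
  }
  sa <- significant_terms(res_a, alpha, criterion, include_sentinels)
  sb <- significant_terms(res_b, alpha, criterion, include_sentinels)
  ta <- res_a$table; tb <- res_b$table
  key_a_all <- term_key(ta$database, ta$term_id)
  key_b_all <- term_key(tb$database, tb$term_id)

  shared_keys <- intersect(sa$keys, sb$keys)
  ia <- match(shared_keys, key_a_all)
  ib <- match(shared_keys, key_b_all)
  shared <- data.frame(
    database = ta$database[ia], term_id = ta$term_id[ia],
    term_name = ta$term_name[ia],
    genes_in_set_a = ta$genes_in_set[ia],
    genes_in_set_b = tb$genes_in_set[ib],
    p_raw_a = ta$p_raw[ia], p_raw_b = tb$p_raw[ib],
    stringsAsFactors = FALSE)
  shared <- shared[order(pmin(shared$p_raw_a, shared$p_raw_b),
                         shared$database, shared$term_id), , drop = FALSE]
  rownames(shared) <- NULL

  exclusive <- function(keys_mine, tab_mine, key_mine_all, tab_other, key_other_all) {
    i <- match(keys_mine, key_mine_all)
    j <- match(keys_mine, key_other_all)
    out <- data.frame(
      database = tab_mine$database[i], term_id = tab_mine$term_id[i],
      term_name = tab_mine$term_name[i],
      genes_in_set = tab_mine$genes_in_set[i],
      p_raw = tab_mine$p_raw[i],
      p_raw_other = ifelse(is.na(j), 1, tab_other$p_raw[j]),
      stringsAsFactors = FALSE)
    out <- out[order(out$p_raw, out$database, out$term_id), , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  list(shared = shared,
       exclusive_a = exclusive(setdiff(sa$keys, sb$keys), ta, key_a_all,
                               tb, key_b_all),
       exclusive_b = exclusive(setdiff(sb$keys, sa$keys), tb, key_b_all,
                               ta, key_a_all))
}

#' Relevance regression over shared terms
#'
#' Ordinary least-squares fit of the per-term gene counts in the second
#' set on the counts in the first: a high R-squared says the shared terms
#' have similar relevance (number of supporting genes) in both sets.
#'
#' @param g_a,g_b Integer vectors: genes per shared term in each set.
#' @return A list of class `relevance_regression` with `defined`,
#'   `n_terms`, `slope`, `intercept`, `r2`, `r2_adj`, `p_value` and
#'   `low_information` (constant response).
#' @export
relevance_regression <- function(g_a, g_b) {
  n <- length(g_a)
  stopifnot(length(g_b) == n)
  undefined <- function(reason) {
    structure(list(defined = FALSE, reason = reason, n_terms = n,
                   slope = NA_real_, intercept = NA_real_, r2 = NA_real_,
                   r2_adj = NA_real_, p_value = NA_real_,
                   low_information = FALSE),
              class = "relevance_regression")
  }
  if (n < 3L) return(undefined("fewer than 3 shared terms"))
  if (stats::var(g_a) == 0) return(undefined("constant predictor"))
  if (stats::var(g_b) == 0) {
    return(structure(list(defined = TRUE, reason = NULL, n_terms = n,
                          slope = 0, intercept = mean(g_b), r2 = 0,
                          r2_adj = NA_real_, p_value = NA_real_,
                          low_information = TRUE),
                     class = "relevance_regression"))
  }
  fit <- stats::lm(g_b ~ g_a)
  sm <- suppressWarnings(summary(fit))  # perfect fits warn harmlessly
  structure(list(defined = TRUE, reason = NULL, n_terms = n,
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r2 = sm$r.squared, r2_adj = sm$adj.r.squared,
                 p_value = unname(sm$coefficients[2L, 4L]),
                 low_information = FALSE),
            class = "relevance_regression")
}

#' @export
print.relevance_regression <- function(x, ...) {
  if (!x$defined) {
    cat(sprintf("<relevance_regression> undefined (%s)\n", x$reason))
  } else {
    cat(sprintf("<relevance_regression> n = %d, slope = %.3f, adj. R2 = %s, P = %s\n",
                x$n_terms, x$slope,
                if (is.na(x$r2_adj)) "NA" else sprintf("%.3f", x$r2_adj),
                if (is.na(x$p_value)) "NA" else format(x$p_value, digits = 3)))
  }
  invisible(x)
}

#' One-paragraph summary of a comparison
#'
#' A fixed template so outputs are diffable: shared and union term counts,
#' the POR and its empirical P value, and — when defined — the adjusted
#' R-squared of the relevance regression.
#'
#' @param x A `pheno_comparison` from [por_significance()].
#' @return A character scalar.
#' @export
pheno_message <- function(x) {
  stopifnot(inherits(x, "pheno_comparison"))
  cnt <- x$counts
  union_n <- cnt$n
  score <- sprintf("%s %s = %.3f", x$method,
                   if (x$relaxed) "RPOR" else "POR", x$por)
  p_part <- sprintf("empirical P = %.4g from %d null sets",
                    x$empirical_p, length(x$null_values))
  head <- if (union_n == 0L) {
    sprintf("Gene sets '%s' and '%s' have no %s terms to compare (%s; %s).",
            x$label_a, x$label_b,
            if (x$relaxed) "annotated" else "significant", score, p_part)
  } else if (cnt$a == 0L) {
    sprintf("Gene sets '%s' and '%s' share no %s terms out of %d in the union (%s; %s).",
            x$label_a, x$label_b,
            if (x$relaxed) "annotated" else "significant",
            union_n, score, p_part)
  } else {
    sprintf("Gene sets '%s' and '%s' share %d of %d %s terms (%s; %s).",
            x$label_a, x$label_b, cnt$a, union_n,
            if (x$relaxed) "annotated" else "significant", score, p_part)
  }
  rel <- x$relevance
  tail_msg <- if (!is.null(rel) && rel$defined && !is.na(rel$r2_adj)) {
    sprintf(" Shared-term relevance: adjusted R-squared = %.3f (P = %.3g).",
            rel$r2_adj, rel$p_value)
  } else ""
  paste0(head, tail_msg)
}

#' @export
print.pheno_comparison <- function(x, ...) {
  cat("<pheno_comparison>\n")
  cat(strwrap(x$summary_message, width = 78, prefix = "  "), sep = "\n")
  cat(sprintf("  mode = %s, m = %d, criterion = %s P < %g\n",
              x$mode, x$m, x$criterion, x$alpha))
  invisible(x)
}
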