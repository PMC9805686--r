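# Synthetic annotation databases and the two calibration experiments
# built on them: the type-I-error grid over random gene sets and the POR
# sensitivity study on artificial gene-set mixtures.
#
# The generator emulates the gross shape of real gene-term databases:
# per-gene annotation counts are drawn from an overdispersed (negative
# binomial) distribution around a target mean, and terms are assigned with
# Zipf-like popularity weights so term sizes are heavy-tailed. An optional
# planted "disease module" (a block of genes and terms with elevated
# co-association) gives comparison experiments a recoverable signal.

#' Specification of a synthetic annotation database
#'
#' @param n_genes,n_terms Universe and term counts (>= 1).
#' @param mean_terms_per_gene Target mean annotations per gene; real
#'   gene-disease databases range from about 4.4 (sparse panels) to about
#'   17.7 (dense curated sources). Must not exceed `n_terms`; equality
#'   saturates every gene with every term.
#' @param density_dispersion Negative-binomial size parameter of the
#'   per-gene annotation counts; smaller values give heavier-tailed
#'   densities. Default 2.
#' @param term_size_skew Exponent of the Zipf popularity weights over
#'   terms; 0 makes term sizes uniform. Default 0.8.
#' @param disease_module Optional planted module: a list with
#'   `n_module_genes`, `n_module_terms` and `p_within`, the probability of
#'   each within-module gene-term association. `p_within` may be a single
#'   probability or a `c(lo, hi)` range; with a range the module terms get
#'   probabilities spaced geometrically across it, mimicking the
#'   heavy-tailed term strengths of real disease annotations (a few strong
#'   pathognomonic terms, many weakly associated ones).
#' @param seed Integer seed; the database is fully determined by it.
#' @param name,kind Database name and kind.
#' @return A list of class `synthetic_db_spec`.
#' @export
synthetic_db_spec <- function(n_genes, n_terms, mean_terms_per_gene,
                              density_dispersion = 2, term_size_skew = 0.8,
                              disease_module = NULL, seed = 1L,
                              name = "synthdb", kind = "phenotype") {
  stopifnot(n_genes >= 1, n_terms >= 1, mean_terms_per_gene > 0,
            density_dispersion > 0, term_size_skew >= 0)
  if (mean_terms_per_gene > n_terms) {
    stop_data("infeasible spec: mean_terms_per_gene exceeds n_terms")
  }
  if (!is.null(disease_module)) {
    stopifnot(all(c("n_module_genes", "n_module_terms", "p_within") %in%
                    names(disease_module)),
              disease_module$n_module_genes <= n_genes,
              disease_module$n_module_terms <= n_terms,
              length(disease_module$p_within) %in% 1:2,
              all(disease_module$p_within >= 0),
              all(disease_module$p_within <= 1))
  }
  structure(list(n_genes = as.integer(n_genes), n_terms = as.integer(n_terms),
                 mean_terms_per_gene = mean_terms_per_gene,
                 density_dispersion = density_dispersion,
                 term_size_skew = term_size_skew,
                 disease_module = disease_module,
                 seed = seed, name = name, kind = kind),
            class = "synthetic_db_spec")
}

#' Generate a synthetic annotation database
#'
#' Draws per-gene annotation counts from a negative binomial with the
#' spec's target mean and dispersion (clamped to `[0, n_terms]`), assigns
#' terms with Zipf-weighted sampling without within-gene replacement, adds
#' the optional planted disease module, and standardizes against the
#' generated universe (sentinel completion). Genes drawing zero
#' annotations end up linked to the sentinel only.
#'
#' @param spec A [synthetic_db_spec()].
#' @return A standardized `annotation_db`. The planted module's gene and
#'   term identifiers, if any, are stored in attributes `module_genes` and
#'   `module_terms`.
#' @export
generate_synthetic_db <- function(spec) {
  stopifnot(inherits(spec, "synthetic_db_spec"))
  ng <- spec$n_genes; nt <- spec$n_terms
  gene_ids <- sprintf("G%0*d", nchar(ng), seq_len(ng))
  width_t <- max(4L, nchar(nt))
  term_ids <- sprintf("ST:%0*d", width_t, seq_len(nt))
  module_genes <- character(0); module_terms <- character(0)

  pairs <- with_seed(spec$seed, {
    if (spec$mean_terms_per_gene == nt) {
      cbind(gene = rep(seq_len(ng), each = nt), term = rep(seq_len(nt), ng))
    } else {
      k <- stats::rnbinom(ng, mu = spec$mean_terms_per_gene,
                          size = spec$density_dispersion)
      k <- pmin(k, nt)
      w <- seq_len(nt)^(-spec$term_size_skew)
      w <- w / sum(w)
      gene_idx <- rep.int(seq_len(ng), k)
      term_idx <- sample.int(nt, length(gene_idx), replace = TRUE, prob = w)
      key <- (gene_idx - 1) * as.double(nt) + term_idx
      dup <- duplicated(key)
      gene_idx <- gene_idx[!dup]; term_idx <- term_idx[!dup]; key <- key[!dup]
      # top up genes whose draws collided until each reaches its count
      for (iter in seq_len(100L)) {
        have <- tabulate(gene_idx, nbins = ng)
        deficit <- k - have
        if (!any(deficit > 0L)) break
        add_gene <- rep.int(which(deficit > 0L), deficit[deficit > 0L])
        add_term <- sample.int(nt, length(add_gene), replace = TRUE, prob = w)
        add_key <- (add_gene - 1) * as.double(nt) + add_term
        gene_idx <- c(gene_idx, add_gene)
        term_idx <- c(term_idx, add_term)
        key <- c(key, add_key)
        dup <- duplicated(key)
        gene_idx <- gene_idx[!dup]; term_idx <- term_idx[!dup]; key <- key[!dup]
      }
      out <- cbind(gene = gene_idx, term = term_idx)
      if (!is.null(spec$disease_module)) {
        dm <- spec$disease_module
        mg <- sample.int(ng, dm$n_module_genes)
        mt <- sample.int(nt, dm$n_module_terms)
        p_term <- if (length(dm$p_within) == 2L) {
          exp(seq(log(max(dm$p_within[1L], 1e-6)), log(dm$p_within[2L]),
                  length.out = dm$n_module_terms))
        } else {
          rep(dm$p_within, dm$n_module_terms)
        }
        grid_gene <- rep(mg, each = dm$n_module_terms)
        grid_term <- rep(mt, dm$n_module_genes)
        hit <- stats::runif(length(grid_gene)) <
          rep.int(p_term, dm$n_module_genes)
        out <- rbind(out, cbind(gene = grid_gene[hit], term = grid_term[hit]))
        module_genes <- gene_ids[sort(mg)]
        module_terms <- term_ids[sort(mt)]
      }
      out
    }
  })
  assoc <- unique(data.frame(gene = gene_ids[pairs[, "gene"]],
                             term_id = term_ids[pairs[, "term"]],
                             stringsAsFactors = FALSE))
  terms <- data.frame(term_id = term_ids,
                      term_name = sprintf("synthetic term %d", seq_len(nt)),
                      is_sentinel = FALSE, stringsAsFactors = FALSE)
  terms <- terms[terms$term_id %in% assoc$term_id, , drop = FALSE]
  db <- new_annotation_db(name = spec$name, kind = spec$kind,
                          associations = assoc, terms = terms)
  db <- suppressWarnings(standardize_db(db, gene_universe(gene_ids)))
  attr(db, "module_genes") <- module_genes
  attr(db, "module_terms") <- module_terms
  db
}

#' Type-I-error grid over random gene sets
#'
#' For each (database, set size) cell, draws `replicates` gene sets
#' uniformly from the database universe, runs the hypergeometric
#' enrichment, and summarizes the false-positive rate under the chosen
#' metric:
#' \describe{
#'   \item{`per_term_all`}{mean over replicates of (number of non-sentinel
#'     terms with raw P < alpha) / (number of all non-sentinel terms);
#'     untested terms count as non-significant. The only reading
#'     guaranteed <= alpha for a valid test.}
#'   \item{`per_term_tested`}{same numerator over the number of terms
#'     actually tested (at least one annotated gene) in that replicate.}
#'   \item{`any_hit_adjusted`}{fraction of replicates with at least one
#'     Bonferroni-significant non-sentinel term.}
#' }
#'
#' @param dbs Standardized `annotation_db` or list of them.
#' @param sizes Integer vector of gene set sizes.
#' @param replicates Random sets per cell (default 1000).
#' @param alpha Significance level (default 0.05).
#' @param metric One of `"per_term_all"`, `"per_term_tested"`,
#'   `"any_hit_adjusted"`.
#' @param mode Tail convention passed to the enrichment test.
#' @param seed Integer seed.
#' @return A data frame with one row per cell (`database`, `set_size`,
#'   `replicates`, `metric`, `alpha`, `fpr`) carrying the Pearson
#'   correlation between set size and FPR across cells in attribute
#'   `size_correlation` (list with `estimate` and `p_value`, `NA` when
#'   fewer than 3 distinct sizes).
#' @export
type1_experiment <- function(dbs, sizes, replicates = 1000L, alpha = 0.05,
                             metric = c("per_term_all", "per_term_tested",
                                        "any_hit_adjusted"),
                             mode = c("upper_tail", "pmf"), seed = NULL) {
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  dbs <- check_db_list(dbs)
  sizes <- as.integer(sizes)
  stopifnot(all(sizes >= 1L), replicates >= 1L)
  cells <- expand.grid(database = names(dbs), set_size = sizes,
                       stringsAsFactors = FALSE)
  fpr <- numeric(nrow(cells))
  with_seed(seed, {
    for (ci in seq_len(nrow(cells))) {
      db <- dbs[[cells$database[ci]]]
      size <- cells$set_size[ci]
      if (size > length(db$universe)) {
        stop_data("set size ", size, " exceeds universe of '", db$name, "'")
      }
      nonsent <- !db$index$is_sentinel
      n_all <- sum(nonsent)
      vals <- numeric(replicates)
      for (r in seq_len(replicates)) {
        genes <- sample(db$universe, size)
        tp <- .tested_pvalues(db, genes, mode = mode)
        keep <- nonsent[tp$pos]
        vals[r] <- switch(metric,
          per_term_all = sum(tp$p[keep] < alpha) / n_all,
          per_term_tested = {
            nt <- sum(keep)
            if (nt == 0L) 0 else sum(tp$p[keep] < alpha) / nt
          },
          any_hit_adjusted = {
            p_adj <- pmin(1, tp$p * length(tp$p))
            as.numeric(any(p_adj[keep] < alpha))
          })
      }
      fpr[ci] <- mean(vals)
    }
  })
  out <- data.frame(database = cells$database, set_size = cells$set_size,
                    replicates = as.integer(replicates), metric = metric,
                    alpha = alpha, fpr = fpr, stringsAsFactors = FALSE)
  corr <- list(estimate = NA_real_, p_value = NA_real_)
  if (length(unique(out$set_size)) >= 3L && stats::sd(out$fpr) > 0) {
    ct <- stats::cor.test(out$set_size, out$fpr)
    corr <- list(estimate = unname(ct$estimate), p_value = ct$p.value)
  }
  attr(out, "size_correlation") <- corr
  out
}

#' Specification of an artificial gene-set mixture
#'
#' @param target_size Size of the artificial set (the reference disease
#'   panel size, e.g. 261).
#' @param prop_seed Proportion of the set drawn from the seed panel, in
#'   \[0, 1\].
#' @param noise_rate Fraction of the non-seed remainder drawn from "noise"
#'   genes — genes outside the panel annotated to at least one term
#'   significantly enriched in it. Default 0.05.
#' @param seed Integer seed.
#' @return A list of class `mixture_spec`.
#' @export
mixture_spec <- function(target_size, prop_seed, noise_rate = 0.05,
                         seed = NULL) {
  stopifnot(target_size >= 1, prop_seed >= 0, prop_seed <= 1,
            noise_rate >= 0, noise_rate <= 1)
  structure(list(target_size = as.integer(target_size),
                 prop_seed = prop_seed, noise_rate = noise_rate, seed = seed),
            class = "mixture_spec")
}

# Non-sentinel annotation count per universe gene, summed across dbs.
.annotation_counts <- function(dbs, genes) {
  total <- integer(length(genes))
  for (db in dbs) total <- total + unname(db$index$nonsent_count[genes])
  names(total) <- genes
  total
}

# Genes (outside `exclude`) annotated to at least one of the given term
# keys.
.genes_of_keys <- function(dbs, keys, exclude) {
  hits <- character(0)
  for (db in dbs) {
    pref <- paste0(db$name, "\t")
    ids <- sub(pref, "", keys[startsWith(keys, pref)], fixed = TRUE)
    if (length(ids) == 0L) next
    hits <- c(hits, db$associations$gene[db$associations$term_id %in% ids])
  }
  setdiff(unique(hits), exclude)
}

#' Build an artificial gene set mixing panel, noise and matched filler genes
#'
#' The artificial set has exactly `spec$target_size` genes:
#' `round(prop_seed * target_size)` sampled from the seed panel; of the
#' remainder, a `noise_rate` fraction sampled from noise genes (genes
#' outside the panel annotated to at least one term enriched in it at raw
#' P < `alpha`), and the rest from a filler pool matched to the panel's
#' per-gene annotation-count deciles ("similar phenotypic connectivity").
#' Filler genes are never panel or noise genes, so at `prop_seed = 0`,
#' `noise_rate = 0` the result is disjoint from the panel and avoids its
#' enriched terms by construction.
#'
#' @param seed_set The reference panel, a [gene_set()].
#' @param dbs Standardized databases providing the annotation context.
#' @param spec A [mixture_spec()].
#' @param filler_pool Optional [gene_set()] restricting the filler genes;
#'   defaults to the whole shared universe.
#' @param alpha Significance level defining the panel's enriched terms.
#' @return A [gene_set()] of size `spec$target_size`.
#' @export
build_artificial_set <- function(seed_set, dbs, spec, filler_pool = NULL,
                                 alpha = 0.05) {
  stopifnot(inherits(spec, "mixture_spec"))
  dbs <- check_db_list(dbs)
  seed_set <- as_gene_set(seed_set, label = "seed panel")
  universe <- Reduce(intersect, lapply(dbs, `[[`, "universe"))
  seed_genes <- intersect(seed_set$genes, universe)
  if (length(seed_genes) == 0L) stop_data("seed panel disjoint from universe")

  n_seed <- round(spec$prop_seed * spec$target_size)
  n_rest <- spec$target_size - n_seed
  n_noise <- round(spec$noise_rate * n_rest)
  n_filler <- n_rest - n_noise

  sig_keys <- .sig_keys(dbs, seed_genes, alpha = alpha, criterion = "raw")
  noise_pool <- intersect(.genes_of_keys(dbs, sig_keys, exclude = seed_genes),
                          universe)
  filler_cand <- if (is.null(filler_pool)) universe else
    intersect(as_gene_set(filler_pool, label = "filler pool")$genes, universe)
  filler_cand <- setdiff(filler_cand, c(seed_genes, noise_pool))

  if (n_seed > length(seed_genes)) {
    stop_data("seed panel too small: need ", n_seed, ", have ",
              length(seed_genes))
  }
  if (n_noise > length(noise_pool)) {
    stop_data("noise pool too small: need ", n_noise, ", have ",
              length(noise_pool))
  }
  if (n_filler > length(filler_cand)) {
    stop_data("filler pool too small: need ", n_filler, ", have ",
              length(filler_cand))
  }

  with_seed(spec$seed, {
    picked_seed <- if (n_seed > 0L) sample(seed_genes, n_seed) else character(0)
    picked_noise <- if (n_noise > 0L) sample(noise_pool, n_noise) else character(0)
    picked_filler <- character(0)
    if (n_filler > 0L) {
      counts_seed <- .annotation_counts(dbs, seed_genes)
      counts_pool <- .annotation_counts(dbs, filler_cand)
      breaks <- unique(stats::quantile(counts_seed, probs = 0:10 / 10,
                                       type = 1, names = FALSE))
      dec_of <- if (length(breaks) < 2L) {
        function(x) rep(1L, length(x))
      } else {
        function(x) findInterval(x, breaks, rightmost.closed = TRUE,
                                 all.inside = TRUE)
      }
      pool_dec <- dec_of(counts_pool)
      need <- tabulate(dec_of(counts_seed)[sample.int(length(seed_genes),
                                                      n_filler, replace = TRUE)],
                       nbins = length(breaks))
      taken <- logical(length(filler_cand))
      for (d in order(-need)) {
        if (need[d] == 0L) next
        avail <- which(pool_dec == d & !taken)
        take <- min(need[d], length(avail))
        if (take > 0L) {
          sel <- if (length(avail) == 1L) avail else sample(avail, take)
          taken[sel] <- TRUE
          need[d] <- need[d] - take
        }
      }
      short <- sum(need)
      if (short > 0L) {           # spill into nearest deciles
        avail <- which(!taken)
        sel <- if (length(avail) == 1L) avail else sample(avail, short)
        taken[sel] <- TRUE
      }
      picked_filler <- filler_cand[taken]
    }
    gene_set(c(picked_seed, picked_noise, picked_filler),
             label = sprintf("artificial p=%.2f", spec$prop_seed))
  })
}

#' POR sensitivity to the seed-gene proportion of artificial sets
#'
#' Sweeps a grid of seed-gene proportions; for each proportion builds
#' `replicates` artificial sets with [build_artificial_set()] and computes
#' the POR between each and the seed panel. Fits an ordinary
#' least-squares line of the replicate-level POR on the proportion and
#' runs Welch t-tests between the POR distributions of adjacent grid
#' points.
#'
#' @inheritParams build_artificial_set
#' @param p_grid Proportions in \[0, 1\] (default `seq(0, 1, 0.1)`).
#' @param replicates Artificial sets per proportion (>= 2).
#' @param target_size Artificial set size; defaults to the panel size.
#' @param noise_rate Mixture noise rate (default 0.05).
#' @param method POR coefficient, `"jaccard"` or `"forbes"`.
#' @param criterion Significance rule for the term sets.
#' @param seed Integer seed driving all replicates.
#' @return An object of class `por_sensitivity`: list with `values`
#'   (replicate-level data frame), `table` (per-proportion mean/sd),
#'   `fit` (slope, intercept, r2, r2_adj, p_value) and `welch`
#'   (adjacent-proportion t-tests).
#' @export
por_sensitivity_experiment <- function(seed_set, dbs, p_grid = seq(0, 1, 0.1),
                                       replicates = 100L, target_size = NULL,
                                       noise_rate = 0.05,
                                       method = c("jaccard", "forbes"),
                                       alpha = 0.05,
                                       criterion = c("raw", "bonferroni", "fdr"),
                                       seed = NULL) {
  method <- match.arg(method)
  criterion <- match.arg(criterion)
  stopifnot(all(p_grid >= 0), all(p_grid <= 1), replicates >= 2L)
  dbs <- check_db_list(dbs)
  seed_set <- as_gene_set(seed_set, label = "seed panel")
  universe <- Reduce(intersect, lapply(dbs, `[[`, "universe"))
  seed_genes <- intersect(seed_set$genes, universe)
  target_size <- as.integer(target_size %||% length(seed_genes))
  seed_keys <- .sig_keys(dbs, seed_genes, alpha = alpha, criterion = criterion)

  p_grid <- sort(unique(p_grid))
  values <- expand.grid(rep = seq_len(replicates), p = p_grid)
  values <- values[c("p", "rep")]
  values$por <- NA_real_
  for (i in seq_len(nrow(values))) {
    ms <- mixture_spec(target_size, values$p[i], noise_rate = noise_rate,
                       seed = child_seed(seed, i))
    art <- build_artificial_set(seed_set, dbs, ms, alpha = alpha)
    art_keys <- .sig_keys(dbs, intersect(art$genes, universe), alpha = alpha,
                          criterion = criterion)
    values$por[i] <- por_value(seed_keys, art_keys, method)
  }
  tab <- do.call(rbind, lapply(split(values$por, values$p), function(v)
    data.frame(mean_por = mean(v), sd_por = stats::sd(v))))
  tab <- data.frame(p = as.numeric(rownames(tab)), tab, row.names = NULL)

  fit_lm <- stats::lm(por ~ p, data = values)
  sm <- summary(fit_lm)
  fit <- list(slope = unname(stats::coef(fit_lm)[2L]),
              intercept = unname(stats::coef(fit_lm)[1L]),
              r2 = sm$r.squared, r2_adj = sm$adj.r.squared,
              p_value = unname(sm$coefficients[2L, 4L]))

  welch <- NULL
  if (length(p_grid) >= 2L) {
    welch <- data.frame(p_low = p_grid[-length(p_grid)], p_high = p_grid[-1L],
                        t = NA_real_, p_value = NA_real_)
    for (j in seq_len(nrow(welch))) {
      x <- values$por[values$p == welch$p_low[j]]
      y <- values$por[values$p == welch$p_high[j]]
      tt <- tryCatch(stats::t.test(x, y), error = function(e) NULL)
      if (!is.null(tt)) {
        welch$t[j] <- unname(tt$statistic)
        welch$p_value[j] <- tt$p.value
      }
    }
  }
  structure(list(values = values, table = tab, fit = fit, welch = welch,
                 method = method, noise_rate = noise_rate,
                 target_size = target_size, seed = seed),
            class = "por_sensitivity")
}

#' @export
print.por_sensitivity <- function(x, ...) {
  cat(sprintf("<por_sensitivity> %s POR over %d proportions x %d reps; R2 = %.3f\n",
              x$method, nrow(x$table), max(x$values$rep), x$fit$r2))
  print(x$table)
  invisible(x)
}
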