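# Annotation databases: flat gene -> term association stores.
#
# A database is treated as a flat label set (no ontology-graph propagation):
# terms are compared and tested as independent annotation labels. Every
# database, once standardized against a gene universe, carries exactly one
# sentinel "no annotation" term to which all otherwise-unannotated universe
# genes are linked, so the universe is fully covered and the hypergeometric
# population is the whole universe.

DB_KINDS <- c("phenotype", "disease")
DIALECTS <- c("two_col", "hpo_g2p", "mgi_rpt")

sentinel_term_id <- function(name) {
  sprintf("%s:XXX", gsub("[[:space:]]+", "_", name))
}

sentinel_term_name <- function(name, kind) {
  sprintf("No %s %s associated", name,
          if (kind == "phenotype") "phenotype" else "disease")
}

new_annotation_db <- function(name, kind, associations, terms,
                              organism = "human", universe = NULL,
                              standardized = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  kind <- match.arg(kind, DB_KINDS)
  associations <- unique(data.frame(gene = as.character(associations$gene),
                                    term_id = as.character(associations$term_id),
                                    stringsAsFactors = FALSE))
  terms <- data.frame(term_id = as.character(terms$term_id),
                      term_name = as.character(terms$term_name),
                      is_sentinel = as.logical(terms$is_sentinel),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(terms$term_id)) {
    stop_data("duplicate term_id in database '", name, "'")
  }
  db <- structure(list(name = name, kind = kind, organism = organism,
                       associations = associations, terms = terms,
                       universe = universe, standardized = standardized,
                       index = NULL),
                  class = "annotation_db")
  if (standardized) db$index <- build_db_index(db)
  db
}

# Fast-lookup index: term order frozen from db$terms; per-gene integer
# vectors of term positions; per-term annotated-gene counts (gdb).
build_db_index <- function(db) {
  term_pos <- seq_len(nrow(db$terms))
  names(term_pos) <- db$terms$term_id
  idx <- unname(term_pos[db$associations$term_id])
  gene_f <- factor(db$associations$gene, levels = db$universe)
  gene_terms <- split(idx, gene_f)
  real <- !db$terms$is_sentinel[idx]
  nonsent_count <- tabulate(as.integer(gene_f)[real],
                            nbins = length(db$universe))
  names(nonsent_count) <- db$universe
  list(term_id = db$terms$term_id,
       is_sentinel = db$terms$is_sentinel,
       gdb = tabulate(idx, nbins = nrow(db$terms)),
       gene_terms = gene_terms,
       nonsent_count = nonsent_count)
}

#' @export
print.annotation_db <- function(x, ...) {
  cat(sprintf("<annotation_db> '%s' (%s, %s): %d terms, %d associations%s\n",
              x$name, x$kind, x$organism, nrow(x$terms), nrow(x$associations),
              if (x$standardized)
                sprintf(", universe %d genes", length(x$universe)) else
                " (not standardized)"))
  invisible(x)
}

parse_association_lines <- function(lines, dialect, path) {
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
  line_no <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  min_cols <- c(two_col = 2L, hpo_g2p = 3L, mgi_rpt = 3L)[[dialect]]
  bad <- which(lengths(fields) < min_cols)
  if (length(bad)) {
    stop_data(sprintf("malformed row in %s (line %d): expected >= %d tab-separated fields, found %d",
                      path, line_no[bad[1L]], min_cols, length(fields[[bad[1L]]])))
  }
  col <- function(i) vapply(fields, `[[`, character(1), i)
  switch(dialect,
    two_col = data.frame(
      gene = col(1L), term_id = col(2L),
      term_name = if (all(lengths(fields) >= 3L)) col(3L) else col(2L),
      stringsAsFactors = FALSE),
    hpo_g2p = data.frame(gene = col(3L), term_id = col(1L),
                         term_name = col(2L), stringsAsFactors = FALSE),
    mgi_rpt = data.frame(gene = col(1L), term_id = col(2L),
                         term_name = col(3L), stringsAsFactors = FALSE))
}

#' Load a gene-term association table
#'
#' Reads one tab-delimited association file into an (unstandardized)
#' annotation database. Three dialects are understood:
#' \describe{
#'   \item{`two_col`}{`gene<TAB>term_id[<TAB>term_name]` — the package's
#'     canonical exchange format.}
#'   \item{`hpo_g2p`}{`term_id<TAB>term_name<TAB>gene`, the layout of HPO
#'     "phenotype to genes" exports.}
#'   \item{`mgi_rpt`}{`gene<TAB>term_id<TAB>term_name` with human-mapped or
#'     mouse symbols in column 1, a pre-joined MGI-report style table.}
#' }
#' Lines starting with `#` are comments. Associations are deduplicated
#' (set semantics); term names are captured when the dialect carries them.
#'
#' @param path Path to a UTF-8 TSV file.
#' @param dialect One of `"two_col"`, `"hpo_g2p"`, `"mgi_rpt"`.
#' @param kind `"phenotype"` or `"disease"`.
#' @param name Database name used in reports and as the sentinel prefix.
#' @param organism Organism of the gene symbols in the file.
#' @return An `annotation_db`, not yet standardized against a universe
#'   (see [standardize_db()]).
#' @export
load_association_table <- function(path, dialect = c("two_col", "hpo_g2p", "mgi_rpt"),
                                   kind = c("phenotype", "disease"),
                                   name = basename(path), organism = "human") {
  dialect <- match.arg(dialect)
  kind <- match.arg(kind)
  if (!file.exists(path)) stop_data("association file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  assoc <- parse_association_lines(lines, dialect, path)
  if (nrow(assoc) == 0L) stop_data("no associations in ", path)
  terms <- assoc[!duplicated(assoc$term_id), c("term_id", "term_name")]
  terms$is_sentinel <- FALSE
  new_annotation_db(name = name, kind = kind, organism = organism,
                    associations = assoc[c("gene", "term_id")],
                    terms = terms[order(terms$term_id), ])
}

#' Standardize a database against a gene universe
#'
#' Gene symbols are uppercased and exact-matched against the universe;
#' associations whose gene falls outside the universe are dropped (a
#' warning reports the count). A sentinel "no annotation" term is then
#' added and every universe gene without any remaining association is
#' linked to it, so that after standardization each universe gene carries
#' at least one association. The operation is idempotent.
#'
#' @param db An `annotation_db`.
#' @param universe A [gene_universe()].
#' @return A standardized `annotation_db` whose `universe` is set and whose
#'   fast lookup index is built.
#' @export
standardize_db <- function(db, universe) {
  stopifnot(inherits(db, "annotation_db"), inherits(universe, "gene_universe"))
  assoc <- db$associations
  assoc$gene <- toupper(trimws(assoc$gene))
  sent_id <- sentinel_term_id(db$name)
  # strip any previous sentinel state so standardize(standardize(x)) == standardize(x)
  assoc <- assoc[assoc$term_id != sent_id, , drop = FALSE]
  terms <- db$terms[!db$terms$is_sentinel & db$terms$term_id != sent_id, ,
                    drop = FALSE]
  inside <- assoc$gene %in% universe$symbols
  n_dropped <- length(unique(assoc$gene[!inside]))
  if (n_dropped > 0L) {
    warning(sprintf("database '%s': dropped %d gene(s) outside the universe",
                    db$name, n_dropped), call. = FALSE)
  }
  assoc <- unique(assoc[inside, , drop = FALSE])
  # drop terms that lost every association
  terms <- terms[terms$term_id %in% assoc$term_id, , drop = FALSE]
  terms <- terms[order(terms$term_id), , drop = FALSE]
  unannotated <- setdiff(universe$symbols, assoc$gene)
  if (length(unannotated)) {
    assoc <- rbind(assoc,
                   data.frame(gene = unannotated, term_id = sent_id,
                              stringsAsFactors = FALSE))
  }
  terms <- rbind(terms,
                 data.frame(term_id = sent_id,
                            term_name = sentinel_term_name(db$name, db$kind),
                            is_sentinel = TRUE, stringsAsFactors = FALSE))
  new_annotation_db(name = db$name, kind = db$kind, organism = universe$organism,
                    associations = assoc, terms = terms,
                    universe = universe$symbols, standardized = TRUE)
}

#' Construct an ortholog map
#'
#' @param mouse,human Parallel character vectors of mouse and human
#'   symbols; many-to-many pairs are allowed.
#' @return An object of class `ortholog_map`.
#' @export
ortholog_map <- function(mouse, human) {
  pairs <- unique(data.frame(mouse = toupper(trimws(as.character(mouse))),
                             human = toupper(trimws(as.character(human))),
                             stringsAsFactors = FALSE))
  pairs <- pairs[nzchar(pairs$mouse) & nzchar(pairs$human), , drop = FALSE]
  if (nrow(pairs) == 0L) stop_data("ortholog map is empty")
  structure(list(pairs = pairs), class = "ortholog_map")
}

#' Read an ortholog map from a two-column TSV (mouse, human)
#' @param path Path to a TSV with mouse symbols in column 1 and human
#'   symbols in column 2; `#` lines are comments.
#' @return An `ortholog_map`.
#' @export
read_ortholog_map <- function(path) {
  if (!file.exists(path)) stop_data("ortholog map file not found: ", path)
  df <- parse_association_lines(readLines(path, warn = FALSE), "two_col", path)
  ortholog_map(df$gene, df$term_id)
}

#' Re-key a mouse database to human symbols via orthology
#'
#' Each (mouse gene, term) association is expanded to all mapped human
#' symbols (union over many-to-many pairs). Associations of unmapped mouse
#' genes are dropped with a warning. The result is standardized against
#' `human_universe`, so human genes never targeted by any mapping end up
#' linked to the sentinel term only.
#'
#' @param db A mouse-keyed `annotation_db`.
#' @param map An [ortholog_map()].
#' @param human_universe A human [gene_universe()].
#' @return A human-keyed, standardized `annotation_db`.
#' @export
map_orthologs <- function(db, map, human_universe) {
  stopifnot(inherits(db, "annotation_db"), inherits(map, "ortholog_map"),
            inherits(human_universe, "gene_universe"))
  assoc <- db$associations
  assoc$gene <- toupper(trimws(assoc$gene))
  sent_id <- sentinel_term_id(db$name)
  assoc <- assoc[assoc$term_id != sent_id, , drop = FALSE]
  merged <- merge(assoc, map$pairs, by.x = "gene", by.y = "mouse")
  unmapped <- setdiff(unique(assoc$gene), map$pairs$mouse)
  if (length(unmapped)) {
    warning(sprintf("database '%s': %d mouse gene(s) without ortholog mapping dropped",
                    db$name, length(unmapped)), call. = FALSE)
  }
  human_assoc <- data.frame(gene = merged$human, term_id = merged$term_id,
                            stringsAsFactors = FALSE)
  terms <- db$terms[!db$terms$is_sentinel, , drop = FALSE]
  out <- new_annotation_db(name = db$name, kind = db$kind, organism = "human",
                           associations = human_assoc, terms = terms)
  standardize_db(out, human_universe)
}

#' Encode CRISPR screen hit tables as an annotation database
#'
#' Each screen contributes up to three class terms: `association`
#' (Positive-Hit and Negative-Hit genes pooled), `positive` (Positive-Hit
#' genes) and `negative` (Negative-Hit genes). Class terms that would be
#' empty are omitted — a term no gene carries can never be tested. The
#' result is standardized, so un-hit universe genes link to the sentinel.
#'
#' @param screens Data frame with columns `screen`, `gene`, `hit_class`
#'   (values `"Positive-Hit"` / `"Negative-Hit"`).
#' @param universe A [gene_universe()].
#' @param name Database name (default `"CRISPR"`).
#' @return A standardized `annotation_db` of kind `"phenotype"`.
#' @export
encode_crispr_screens <- function(screens, universe, name = "CRISPR") {
  stopifnot(is.data.frame(screens),
            all(c("screen", "gene", "hit_class") %in% names(screens)))
  bad <- setdiff(unique(screens$hit_class), c("Positive-Hit", "Negative-Hit"))
  if (length(bad)) {
    stop_data("unknown hit_class value(s): ", paste(bad, collapse = ", "))
  }
  one_class <- function(df, class_label, class_name) {
    if (nrow(df) == 0L) return(NULL)
    data.frame(gene = df$gene,
               term_id = sprintf("%s::%s", df$screen, class_label),
               term_name = sprintf("%s with %s", class_name, df$screen),
               stringsAsFactors = FALSE)
  }
  assoc <- rbind(
    one_class(screens, "association", "Association"),
    one_class(screens[screens$hit_class == "Positive-Hit", , drop = FALSE],
              "positive", "Positive hit"),
    one_class(screens[screens$hit_class == "Negative-Hit", , drop = FALSE],
              "negative", "Negative hit"))
  if (is.null(assoc) || nrow(assoc) == 0L) stop_data("no screen hits provided")
  terms <- assoc[!duplicated(assoc$term_id), c("term_id", "term_name")]
  terms$is_sentinel <- FALSE
  db <- new_annotation_db(name = name, kind = "phenotype",
                          associations = assoc[c("gene", "term_id")],
                          terms = terms)
  standardize_db(db, universe)
}

#' Database size statistics
#'
#' Counts exclude the sentinel term and its associations, which are
#' reported separately: `n_genes` is the number of genes carrying at least
#' one real annotation, `n_terms` the number of non-sentinel terms and
#' `n_associations` the number of non-sentinel gene-term pairs.
#'
#' @param db A standardized `annotation_db`.
#' @return A list of class `db_stats` with fields `database`, `n_genes`,
#'   `n_terms`, `n_associations`, `n_sentinel_genes`, `universe_size`.
#' @export
db_stats <- function(db) {
  stopifnot(inherits(db, "annotation_db"))
  if (!db$standardized) stop_data("db_stats requires a standardized database")
  sent <- db$terms$term_id[db$terms$is_sentinel]
  real <- db$associations[!db$associations$term_id %in% sent, , drop = FALSE]
  structure(list(database = db$name,
                 n_genes = length(unique(real$gene)),
                 n_terms = sum(!db$terms$is_sentinel),
                 n_associations = nrow(real),
                 n_sentinel_genes = sum(db$associations$term_id %in% sent),
                 universe_size = length(db$universe)),
            class = "db_stats")
}

#' @export
print.db_stats <- function(x, ...) {
  cat(sprintf("<db_stats> %s: %d genes, %d terms, %d associations (universe %d, %d sentinel-only)\n",
              x$database, x$n_genes, x$n_terms, x$n_associations,
              x$universe_size, x$n_sentinel_genes))
  invisible(x)
}

#' Write a database in the canonical two-column dialect
#'
#' Emits `gene<TAB>term_id<TAB>term_name` rows (sentinel associations
#' included unless `sentinel = FALSE`), sorted for byte-stable output, with
#' a leading `#` comment naming the columns. Re-reading with
#' [load_association_table()] reproduces the association set.
#'
#' @param db An `annotation_db`.
#' @param path Output path.
#' @param sentinel Include sentinel associations? Default `TRUE`.
#' @return Invisibly, `path`.
#' @export
write_association_table <- function(db, path, sentinel = TRUE) {
  stopifnot(inherits(db, "annotation_db"))
  assoc <- db$associations
  if (!sentinel) {
    sent <- db$terms$term_id[db$terms$is_sentinel]
    assoc <- assoc[!assoc$term_id %in% sent, , drop = FALSE]
  }
  name_of <- db$terms$term_name
  names(name_of) <- db$terms$term_id
  assoc <- assoc[order(assoc$gene, assoc$term_id), , drop = FALSE]
  lines <- c("# gene\tterm_id\tterm_name",
             sprintf("%s\t%s\t%s", assoc$gene, assoc$term_id,
                     name_of[assoc$term_id]))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
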