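# Gene universes and gene sets.
#
# All human symbols are handled HGNC-style: uppercased, exact-matched. No
# alias resolution is attempted; a symbol either matches the universe or is
# dropped (with a count), which keeps the hypergeometric population GDB
# well defined.

ORGANISMS <- c("human", "mouse")

normalize_symbols <- function(symbols) {
  x <- toupper(trimws(as.character(symbols)))
  x[nzchar(x)]
}

#' Construct a gene universe
#'
#' The universe is the population of protein-coding genes an annotation
#' database covers; it is the denominator population of every
#' hypergeometric enrichment test run against that database.
#'
#' @param symbols Character vector of gene symbols. Symbols are uppercased,
#'   trimmed and deduplicated.
#' @param organism `"human"` or `"mouse"`.
#' @return An object of class `gene_universe`: a list with `symbols`
#'   (sorted character vector) and `organism`.
#' @examples
#' u <- gene_universe(c("Snca", "LRRK2", "PRKN"))
#' u$symbols
#' @export
gene_universe <- function(symbols, organism = "human") {
  organism <- match.arg(organism, ORGANISMS)
  symbols <- sort(unique(normalize_symbols(symbols)))
  if (length(symbols) == 0L) {
    stop_data("a gene universe must contain at least one symbol")
  }
  structure(list(symbols = symbols, organism = organism),
            class = "gene_universe")
}

#' @export
print.gene_universe <- function(x, ...) {
  cat(sprintf("<gene_universe> %d %s genes\n", length(x$symbols), x$organism))
  invisible(x)
}

#' Construct a labelled gene set
#'
#' @param genes Character vector of gene symbols (normalized and
#'   deduplicated).
#' @param label Short label used in reports.
#' @param organism `"human"` or `"mouse"`.
#' @return An object of class `gene_set` with `label`, `genes`, `organism`.
#' @examples
#' gene_set(c("SNCA", "PRKN", "LRRK2"), label = "PD")
#' @export
gene_set <- function(genes, label = "gene set", organism = "human") {
  organism <- match.arg(organism, ORGANISMS)
  genes <- sort(unique(normalize_symbols(genes)))
  if (length(genes) == 0L) {
    stop_data("gene set '", label, "' is empty after symbol normalization")
  }
  structure(list(label = label, genes = genes, organism = organism),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> '%s': %d %s genes\n",
              x$label, length(x$genes), x$organism))
  invisible(x)
}

as_gene_set <- function(x, label = "gene set", organism = "human") {
  if (inherits(x, "gene_set")) return(x)
  gene_set(x, label = label, organism = organism)
}

#' Read a gene list from a plain-text file
#'
#' One symbol per line; blank lines and lines starting with `#` are
#' ignored.
#'
#' @param path Path to the file.
#' @param label Label for the resulting set; defaults to the file name.
#' @param organism `"human"` or `"mouse"`.
#' @return A [gene_set()].
#' @export
read_gene_list <- function(path, label = NULL, organism = "human") {
  if (!file.exists(path)) stop_data("gene list file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  gene_set(lines, label = label %||% basename(path), organism = organism)
}

#' Read a gene universe from a plain-text file
#'
#' Accepts either a bare symbol-per-line file or a tab-delimited table
#' whose first column holds the symbols (HGNC download style); a header
#' line is detected by the literal column name `symbol`.
#'
#' @inheritParams read_gene_list
#' @return A [gene_universe()].
#' @export
read_gene_universe <- function(path, organism = "human") {
  if (!file.exists(path)) stop_data("universe file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  first <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
  if (length(first) && tolower(first[[1L]]) %in% c("symbol", "gene", "gene_symbol")) {
    first <- first[-1L]
  }
  gene_universe(first, organism = organism)
}
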