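# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code under a temporary RNG state
#'
#' Runs `code` with the RNG seeded at `seed` and restores the caller's
#' `.Random.seed` afterwards, so seeded operations never perturb global
#' random state. A `NULL` seed evaluates `code` under the current stream.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible child seed from a base seed; keeps results from
# separate sub-experiments independent while still fully determined by the
# user-facing seed. Stays inside 32-bit integer range.
child_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + offset) %% 2147483647L)
}

# Composite key identifying a term within an analysis spanning databases.
term_key <- function(database, term_id) paste(database, term_id, sep = "\t")

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("phenoverlap_data_error", "error")))
}

stop_usage <- function(...) {
  stop(errorCondition(paste0(...), class = c("phenoverlap_usage_error", "error")))
}

# Tab-separated writers/readers used everywhere: UTF-8, no quoting surprises,
# deterministic column order.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path, header = TRUE, col.names = NULL) {
  args <- list(file = path, sep = "\t", quote = "", comment.char = "#",
               header = header, stringsAsFactors = FALSE,
               blank.lines.skip = TRUE, check.names = FALSE)
  if (!is.null(col.names)) args$col.names <- col.names
  do.call(utils::read.table, args)
}
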