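#' @importFrom data.table data.table setDT setorder := .N .SD setnames rbindlist fread fwrite
#' @importFrom stats rnorm rmultinom runif prcomp wilcox.test t.test quantile sd setNames
#' @importFrom utils head modifyList
NULL

# data.table NSE column names
utils::globalVariables(c(
  ".", "chrom", "strand", "five_prime", "cluster_id", "read_count", "rpm",
  "rep_pos", "min_pos", "pos", "condition", "match_id", "n_hits", "count"
))

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state afterwards
# so simulation helpers never perturb an enclosing analysis.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_reads <- function(reads) {
  needed <- c("chrom", "strand", "start", "length", "unique", "five_prime")
  missing <- setdiff(needed, names(reads))
  if (length(missing))
    stopf("alignment table lacks column(s): %s", paste(missing, collapse = ", "))
  if (nrow(reads) && !all(reads$strand %in% c("+", "-")))
    stopf("strand must be '+' or '-'")
  invisible(reads)
}
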