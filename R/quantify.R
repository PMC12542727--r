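#' Attach RPM values to a cluster table
#'
#' Normalises each cluster's read count to reads per million:
#' `RPM = read_count / total_mapped * 1e6`. The recommended denominator is
#' the number of reads that survived all filters and entered clustering for
#' the condition (those are the reads "used for downstream analysis"); an
#' externally supplied denominator may be passed instead.
#'
#' @param clusters Cluster table from [cluster_reads()].
#' @param total_mapped Denominator read count (> 0).
#' @param condition Optional condition label (e.g. `"BA"`, `"LS"`, `"HS"`,
#'   `"NC"`), carried through downstream stages.
#' @return A `condition_table`: list with `condition`, `clusters` (the input
#'   table plus an `rpm` column) and `total_mapped`.
#' @export
compute_rpm <- function(clusters, total_mapped, condition = NA_character_) {
  if (!is.numeric(total_mapped) || length(total_mapped) != 1L || total_mapped <= 0)
    stopf("total_mapped must be a single count > 0")
  cl <- clusters
  cl$rpm <- cl$read_count / total_mapped * 1e6
  structure(list(condition = condition, clusters = cl,
                 total_mapped = as.numeric(total_mapped)),
            class = "condition_table")
}

#' @export
print.condition_table <- function(x, ...) {
  cat(sprintf("condition_table '%s': %d clusters, %.0f mapped reads\n",
              x$condition, nrow(x$clusters), x$total_mapped))
  invisible(x)
}

#' RPM cut-off capturing a target fraction of reads
#'
#' Defines "highly associated" clusters: sort clusters by RPM in decreasing
#' order and take the shortest prefix whose summed read count strictly
#' exceeds `fraction` of all reads in the table. The cut-off RPM is the RPM
#' of the last cluster in that prefix, and any cluster tied with it at the
#' boundary is also selected, so membership is well defined under ties.
#'
#' @param table A `condition_table` from [compute_rpm()].
#' @param fraction Target read fraction, default 0.90 (selection covers
#'   `> 90%` of reads).
#' @return A list with `condition`, `cutoff_rpm`, `selected` (cluster ids),
#'   and `covered_fraction`.
#' @export
select_cutoff <- function(table, fraction = 0.90) {
  stopifnot(inherits(table, "condition_table"))
  cl <- table$clusters
  if (nrow(cl) == 0L) stopf("empty condition table")
  ord <- order(-cl$rpm)
  counts <- cl$read_count[ord]
  total <- sum(counts)
  k <- which(cumsum(counts) > fraction * total)[1L]
  if (is.na(k)) k <- nrow(cl)  # fraction = 1 is unattainable strictly; take all
  cutoff_rpm <- cl$rpm[ord[k]]
  sel <- cl$rpm >= cutoff_rpm
  list(condition = table$condition,
       cutoff_rpm = cutoff_rpm,
       selected = cl$cluster_id[sel],
       covered_fraction = sum(cl$read_count[sel]) / total)
}

#' Top-n clusters by RPM
#'
#' Returns the ids of the `n` clusters with highest RPM. Ties at rank `n`
#' are resolved deterministically by (read count decreasing, chrom,
#' representative position) so that exactly `n` ids are returned.
#'
#' @param table A `condition_table`.
#' @param n Number of clusters, default 148.
#' @return Character vector of cluster ids (length `min(n, nrow)`).
#' @export
top_n <- function(table, n = 148L) {
  stopifnot(inherits(table, "condition_table"))
  if (n < 1L) stopf("n must be >= 1")
  cl <- table$clusters
  if (n > nrow(cl)) {
    warning(sprintf("n = %d exceeds the %d available clusters; returning all",
                    n, nrow(cl)))
    n <- nrow(cl)
  }
  ord <- order(-cl$rpm, -cl$read_count, cl$chrom, cl$rep_pos)
  cl$cluster_id[ord[seq_len(n)]]
}
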