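#' Group reads into clusters by 5'-end proximity
#'
#' Reads on the same chromosome and strand are joined into one cluster when
#' the distance between their 5' ends is less than `max_gap` nt, applied
#' transitively (single-linkage chaining over the sorted 5' ends). 15 nt —
#' the minimal length of annotated mouse miRNAs — is the default radius, so
#' two reads whose 5' ends are 14 nt apart merge while 15 nt apart they do
#' not. Reads on opposite strands are never merged: small-RNA species are
#' strand-specific.
#'
#' Each cluster is summarised by its representative position (the
#' highest-frequency 5' end, see [representative_position()]) and its
#' 5--95% quantile span (see [cluster_length()]).
#'
#' @param reads Filtered read table ([filter_reads()]).
#' @param max_gap Chaining threshold in nt; 5' ends at distance `< max_gap`
#'   are linked. Default 15.
#' @return A `data.frame` sorted by (chrom, strand, min position) with
#'   columns `cluster_id`, `chrom`, `strand`, `rep_pos`, `read_count`,
#'   `length_5_95`, `min_pos`, `max_pos`.
#' @export
cluster_reads <- function(reads, max_gap = 15L) {
  assert_reads(reads)
  if (nrow(reads) == 0L) {
    return(data.frame(cluster_id = character(), chrom = character(),
                      strand = character(), rep_pos = integer(),
                      read_count = integer(), length_5_95 = integer(),
                      min_pos = integer(), max_pos = integer(),
                      stringsAsFactors = FALSE))
  }
  dt <- data.table(chrom = reads$chrom, strand = reads$strand,
                   five_prime = as.integer(reads$five_prime))
  setorder(dt, chrom, strand, five_prime)
  new_grp <- c(TRUE, dt$chrom[-1L] != dt$chrom[-nrow(dt)] |
                 dt$strand[-1L] != dt$strand[-nrow(dt)] |
                 diff(dt$five_prime) >= max_gap)
  dt[, cluster_id := cumsum(new_grp)]
  # positions are sorted within cluster, so order statistics index directly
  cl <- dt[, {
    n <- .N
    q05 <- five_prime[ceiling(0.05 * n)]
    q95 <- five_prime[ceiling(0.95 * n)]
    list(chrom = chrom[1L], strand = strand[1L],
         rep_pos = mode_position(five_prime, strand[1L]),
         read_count = n, length_5_95 = q95 - q05,
         min_pos = five_prime[1L], max_pos = five_prime[n])
  }, by = cluster_id]
  setorder(cl, chrom, strand, min_pos)
  out <- as.data.frame(cl)
  out$cluster_id <- sprintf("cl%06d", seq_len(nrow(out)))
  out[, c("cluster_id", "chrom", "strand", "rep_pos", "read_count",
          "length_5_95", "min_pos", "max_pos")]
}

# mode of sorted integer positions; ties resolved 5'-most in transcript
# orientation (smallest coordinate on +, largest on -)
mode_position <- function(sorted_pos, strand) {
  r <- rle(sorted_pos)
  idx <- which(r$lengths == max(r$lengths))
  cand <- r$values[idx]
  if (strand == "+") cand[1L] else cand[length(cand)]
}

#' Representative position of a cluster
#'
#' The 5'-end coordinate carried by the most reads defines where the cluster
#' sits in the genome. When several positions are equally frequent, the
#' 5'-most position in transcript orientation wins: the smallest coordinate
#' on the `+` strand, the largest on the `-` strand.
#'
#' @param positions Integer vector of 5'-end coordinates (multiset).
#' @param strand `"+"` or `"-"`; only used to break ties.
#' @return The modal coordinate.
#' @export
representative_position <- function(positions, strand = "+") {
  if (length(positions) == 0L) stopf("empty cluster")
  mode_position(sort(as.integer(positions)), strand)
}

#' 5--95% quantile span of a cluster
#'
#' Cluster length is the distance between the 5% and 95% quantiles of the
#' cluster's 5'-end multiset, a spread measure robust to stray outlier
#' reads. Quantiles are nearest-rank order statistics (the
#' `ceiling(p * n)`-th sorted value), which keeps coordinates integral; a
#' single-read cluster has length 0.
#'
#' @param positions Integer vector of 5'-end coordinates.
#' @return Span in nt (q95 - q05).
#' @export
cluster_length <- function(positions) {
  if (length(positions) == 0L) stopf("empty cluster")
  s <- sort(as.integer(positions))
  n <- length(s)
  s[ceiling(0.95 * n)] - s[ceiling(0.05 * n)]
}
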