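#' Match clusters across conditions
#'
#' Links clusters from different libraries that represent the same small-RNA
#' species. Representative positions from all conditions are pooled and
#' re-clustered with the same single-linkage `< tol` nt rule used for reads,
#' which makes the matching symmetric and transitive and independent of the
#' order in which conditions are supplied. Each original cluster belongs to
#' exactly one matched cluster; a condition with no member contributes an
#' RPM of 0.
#'
#' The anchor position of a matched cluster is the representative position
#' of its deepest member (ties: smallest coordinate). If one condition
#' contributes several clusters to a match group, their counts and RPMs are
#' summed.
#'
#' @param tables List of `condition_table` objects (>= 2), one per
#'   condition; condition names must be distinct.
#' @param tol Matching radius in nt, default 15 (same rule as read
#'   clustering).
#' @return A `matched_clusters` object: list with `matched` (data.frame:
#'   `match_id`, `chrom`, `strand`, `anchor_pos`, one `rpm_<cond>` and
#'   `count_<cond>` column per condition), `members` (data.frame:
#'   `match_id`, `condition`, `cluster_id`) and `conditions`.
#' @export
match_clusters <- function(tables, tol = 15L) {
  if (length(tables) < 2L) stopf("need at least two condition tables")
  conds <- vapply(tables, function(t) t$condition, character(1))
  if (anyNA(conds) || anyDuplicated(conds))
    stopf("condition tables must carry distinct condition names")
  names(tables) <- conds
  pool <- rbindlist(lapply(tables, function(t) {
    data.table(condition = t$condition, cluster_id = t$clusters$cluster_id,
               chrom = t$clusters$chrom, strand = t$clusters$strand,
               pos = as.integer(t$clusters$rep_pos),
               read_count = t$clusters$read_count, rpm = t$clusters$rpm)
  }))
  setorder(pool, chrom, strand, pos)
  new_grp <- c(TRUE, pool$chrom[-1L] != pool$chrom[-nrow(pool)] |
                 pool$strand[-1L] != pool$strand[-nrow(pool)] |
                 diff(pool$pos) >= tol)
  pool[, match_id := sprintf("m%06d", cumsum(new_grp))]

  anchors <- pool[, {
    # anchor at the deepest member; among equals the smallest coordinate
    cand <- which(read_count == max(read_count))
    list(chrom = chrom[1L], strand = strand[1L],
         anchor_pos = min(pos[cand]))
  }, by = match_id]

  rpmw <- data.table::dcast(pool, match_id ~ condition, value.var = "rpm",
                            fun.aggregate = sum, fill = 0)
  cntw <- data.table::dcast(pool, match_id ~ condition, value.var = "read_count",
                            fun.aggregate = sum, fill = 0)
  setnames(rpmw, conds, paste0("rpm_", conds))
  setnames(cntw, conds, paste0("count_", conds))
  matched <- merge(merge(anchors, rpmw, by = "match_id"), cntw, by = "match_id")
  setorder(matched, chrom, strand, anchor_pos)

  structure(list(matched = as.data.frame(matched),
                 members = as.data.frame(pool[, list(match_id, condition, cluster_id)]),
                 conditions = conds),
            class = "matched_clusters")
}

#' @export
print.matched_clusters <- function(x, ...) {
  cat(sprintf("matched_clusters: %d matched clusters across %s\n",
              nrow(x$matched), paste(x$conditions, collapse = "/")))
  invisible(x)
}

rpm_of <- function(matched, cond) {
  col <- paste0("rpm_", cond)
  if (!col %in% names(matched$matched)) stopf("condition '%s' not matched", cond)
  matched$matched[[col]]
}

#' Cross-condition stability filter
#'
#' A cluster is "stably associated" when its abundance varies little between
#' wash conditions: for each condition pair (X, Y) the RPM ratio
#' `R = RPM_X / RPM_Y` must lie strictly inside `(lo, hi)`
#' (default the open interval (0.5, 2), i.e. less than a two-fold change in
#' either direction). A cluster absent from either condition (RPM 0) fails
#' every pair involving that condition: stability presupposes presence, and
#' no pseudocount is added.
#'
#' @param matched A `matched_clusters` object.
#' @param pairs List of length-2 character vectors of condition names;
#'   default the three wash-condition pairs BA/LS, LS/HS, BA/HS.
#' @param lo,hi Open-interval ratio bounds, defaults 0.5 and 2.
#' @return Named list (one element per pair, name `"X-Y"`) of match-id
#'   character vectors passing that pair's criterion.
#' @export
stability_filter <- function(matched,
                             pairs = list(c("BA", "LS"), c("LS", "HS"), c("BA", "HS")),
                             lo = 0.5, hi = 2) {
  stopifnot(inherits(matched, "matched_clusters"))
  out <- lapply(pairs, function(p) {
    x <- rpm_of(matched, p[1]); y <- rpm_of(matched, p[2])
    ok <- x > 0 & y > 0 & (x / y) > lo & (x / y) < hi
    matched$matched$match_id[ok]
  })
  names(out) <- vapply(pairs, paste, character(1), collapse = "-")
  out
}

# match ids whose members include a selected cluster of `cond`
above_cutoff_matches <- function(matched, cutoff, cond) {
  m <- matched$members
  unique(m$match_id[m$condition == cond & m$cluster_id %in% cutoff$selected])
}

#' Intersect highly and stably associated cluster sets
#'
#' Combines the RPM cut-off with the stability filter. For each condition
#' pair, the pair set holds matched clusters that are above the cut-off in
#' both members of the pair and pass that pair's ratio criterion. The final
#' catalogue is the intersection of all pair sets: clusters both highly and
#' stably associated under every wash condition. When per-condition top-n
#' sets are supplied, their three-way Venn counts are reported as well.
#'
#' @param matched A `matched_clusters` object.
#' @param cutoffs Named list (by condition) of [select_cutoff()] results for
#'   the wash conditions.
#' @param pair_sets Output of [stability_filter()].
#' @param topn_sets Optional named list (by condition) of cluster-id sets
#'   from [top_n()] for Venn reporting.
#' @param require_all_conditions If `TRUE`, every pair set additionally
#'   requires above-cut-off status in all cut-off conditions, not only the
#'   two of the pair. Default `FALSE`.
#' @return A list with `pair_sets` (cut-off-filtered, per pair),
#'   `above_cutoff` (match ids per condition), `final` (match ids), and
#'   `venn` (list of per-set sizes, pairwise and triple intersection counts;
#'   `NULL` unless `topn_sets` given).
#' @export
high_stable_intersection <- function(matched, cutoffs, pair_sets,
                                     topn_sets = NULL,
                                     require_all_conditions = FALSE) {
  stopifnot(inherits(matched, "matched_clusters"))
  pair_conds <- strsplit(names(pair_sets), "-", fixed = TRUE)
  needed <- unique(unlist(pair_conds))
  missing <- setdiff(needed, names(cutoffs))
  if (length(missing))
    stopf("no cutoff supplied for condition(s): %s", paste(missing, collapse = ", "))
  above <- lapply(cutoffs[needed], function(co)
    above_cutoff_matches(matched, co, co$condition))
  names(above) <- needed

  filtered <- mapply(function(ids, p) {
    req <- if (require_all_conditions) needed else p
    Reduce(intersect, above[req], ids)
  }, pair_sets, pair_conds, SIMPLIFY = FALSE)

  final <- Reduce(intersect, filtered)

  venn <- NULL
  if (!is.null(topn_sets)) {
    tn <- lapply(names(topn_sets), function(cond) {
      m <- matched$members
      unique(m$match_id[m$condition == cond & m$cluster_id %in% topn_sets[[cond]]])
    })
    names(tn) <- names(topn_sets)
    cmb <- utils::combn(names(tn), 2, simplify = FALSE)
    venn <- list(
      sizes = vapply(tn, length, integer(1)),
      pairwise = vapply(cmb, function(p) length(intersect(tn[[p[1]]], tn[[p[2]]])),
                        integer(1)),
      common = length(Reduce(intersect, tn)),
      sets = tn
    )
    names(venn$pairwise) <- vapply(cmb, paste, character(1), collapse = "-")
  }

  list(pair_sets = filtered, above_cutoff = above, final = final, venn = venn)
}

#' Permutation test for multi-set overlap
#'
#' Monte-Carlo significance of the observed k-way intersection: k random
#' sets of the observed sizes are drawn uniformly from a universe of
#' `universe` matched clusters, and the p-value is the add-one-corrected
#' fraction of draws whose intersection is at least as large as observed,
#' `p = (exceed + 1) / (n_perm + 1)`.
#'
#' @param sets List of k cluster-id sets.
#' @param universe Size of the universe the sets were drawn from (total
#'   matched clusters); must be at least the largest set.
#' @param n_perm Number of permutations, default 10000.
#' @param seed Optional RNG seed for reproducibility.
#' @return List with `observed` intersection size, `p_value`, `n_perm`.
#' @export
overlap_significance <- function(sets, universe, n_perm = 10000L, seed = NULL) {
  sizes <- vapply(sets, length, integer(1))
  if (any(sizes > universe)) stopf("universe smaller than a set")
  observed <- length(Reduce(intersect, sets))
  if (length(sets) == 1L)
    return(list(observed = observed, p_value = 1, n_perm = 0L))
  run <- function() {
    exceed <- 0L
    for (i in seq_len(n_perm)) {
      draw <- lapply(sizes, function(s) sample.int(universe, s))
      if (length(Reduce(intersect, draw)) >= observed) exceed <- exceed + 1L
    }
    (exceed + 1) / (n_perm + 1)
  }
  p <- if (is.null(seed)) run() else with_seed(seed, run())
  list(observed = observed, p_value = p, n_perm = n_perm)
}
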