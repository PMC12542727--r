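#' Read a TSS table
#'
#' A plain TSV with columns `gene_id`, `chrom`, `strand`, `tss_pos`, where
#' `tss_pos` is the 1-based coordinate of the transcription start base on
#' the gene's strand.
#'
#' @param path TSV path.
#' @return data.frame with those four columns.
#' @export
read_tss_table <- function(path) {
  tss <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  needed <- c("gene_id", "chrom", "strand", "tss_pos")
  missing <- setdiff(needed, names(tss))
  if (length(missing))
    stopf("TSS table lacks column(s): %s", paste(missing, collapse = ", "))
  tss
}

#' Build TSS-associated RNA windows
#'
#' TSSa RNAs are short transcripts found in fixed windows around
#' transcription start sites: -100 nt to +200 nt on the same strand as the
#' gene, and -400 nt to 0 nt on the opposite strand, with signed offsets in
#' transcript orientation. The TSS base itself (offset 0) is included in
#' both windows. Windows falling off the chromosome start are clipped at
#' base 1 with a warning.
#'
#' For a `+` strand gene with TSS t, the same-strand window covers
#' `[t-100, t+200]` on `+` and the opposite-strand window `[t-400, t]` on
#' `-`. For a `-` strand gene the arithmetic mirrors: same-strand
#' `[t-200, t+100]` on `-`, opposite-strand `[t, t+400]` on `+`.
#'
#' @param tss data.frame from [read_tss_table()] (or equivalent).
#' @return A `GRanges` (1-based, closed) with metadata columns
#'   `source_gene` and `window_kind` (`"same_strand"` / `"opposite_strand"`).
#' @export
build_tssa_windows <- function(tss) {
  if (nrow(tss) == 0L)
    return(GenomicRanges::GRanges(source_gene = character(), window_kind = character()))
  t <- as.integer(tss$tss_pos)
  plus <- tss$strand == "+"
  same_start <- ifelse(plus, t - 100L, t - 200L)
  same_end <- ifelse(plus, t + 200L, t + 100L)
  opp_start <- ifelse(plus, t - 400L, t)
  opp_end <- ifelse(plus, t, t + 400L)
  same_strand <- tss$strand
  opp_strand <- ifelse(plus, "-", "+")
  starts <- c(same_start, opp_start)
  if (any(starts < 1L)) {
    warning("TSSa window extends past chromosome start; clipped at base 1")
    same_start <- pmax(same_start, 1L)
    opp_start <- pmax(opp_start, 1L)
  }
  GenomicRanges::GRanges(
    seqnames = rep(tss$chrom, 2L),
    ranges = IRanges::IRanges(start = c(same_start, opp_start),
                              end = c(same_end, opp_end)),
    strand = c(same_strand, opp_strand),
    source_gene = rep(tss$gene_id, 2L),
    window_kind = rep(c("same_strand", "opposite_strand"), each = nrow(tss))
  )
}

read_mirna_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  mc <- S4Vectors::mcols(gr)
  nm <- if (!is.null(mc$Name)) as.character(mc$Name) else as.character(mc$ID)
  nm[is.na(nm) | nm == ""] <- sprintf("mirna_%d", which(is.na(nm) | nm == ""))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(name = nm)
  gr
}

read_pirna_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- S4Vectors::mcols(gr)$name
  if (is.null(nm)) nm <- sprintf("pirna_%d", seq_along(gr))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(name = as.character(nm))
  gr
}

#' Assemble an annotation set for classification
#'
#' Loads miRNA annotations (miRBase-dialect GFF3; both precursor and mature
#' records are candidate intervals), piRNA annotations (BED6) and a TSS
#' table (TSV, see [read_tss_table()]) from which TSSa windows are derived
#' with [build_tssa_windows()]. Any component may be omitted.
#'
#' @param mirna_gff3,pirna_bed,tss_tsv File paths, or `NULL`.
#' @return An `annotation_set`: list of `GRanges` (`mirna`, `pirna`,
#'   `tssa`), each possibly empty.
#' @export
annotation_set <- function(mirna_gff3 = NULL, pirna_bed = NULL, tss_tsv = NULL) {
  empty <- GenomicRanges::GRanges()
  structure(list(
    mirna = if (is.null(mirna_gff3)) empty else read_mirna_gff3(mirna_gff3),
    pirna = if (is.null(pirna_bed)) empty else read_pirna_bed(pirna_bed),
    tssa = if (is.null(tss_tsv)) empty else build_tssa_windows(read_tss_table(tss_tsv))
  ), class = "annotation_set")
}

# strand-matched containment hits of anchor points in `ann`; returns the
# annotation label (nearest interval midpoint on multiple hits) or NA
hit_label <- function(points, ann, label_col) {
  if (length(ann) == 0L) return(rep(NA_character_, length(points)))
  hits <- GenomicRanges::findOverlaps(points, ann, ignore.strand = FALSE)
  if (length(hits) == 0L) return(rep(NA_character_, length(points)))
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  mid <- (GenomicRanges::start(ann) + GenomicRanges::end(ann)) / 2
  d <- abs(mid[s] - GenomicRanges::start(points)[q])
  ord <- order(q, d)
  first <- !duplicated(q[ord])
  out <- rep(NA_character_, length(points))
  lab <- as.character(S4Vectors::mcols(ann)[[label_col]])
  out[q[ord][first]] <- lab[s[ord][first]]
  out
}

#' Classify clusters as miRNA, piRNA, TSSa or unannotated
#'
#' Each cluster is tested sequentially against miRNA regions, then piRNA
#' regions, then TSSa windows; the first category containing the cluster's
#' anchor point (its representative 5' position, on the matching strand)
#' wins, and clusters hitting nothing are `unannotated`. Within a category,
#' multiple overlapping intervals are resolved to the one whose midpoint is
#' nearest the anchor.
#'
#' @param clusters data.frame with columns `match_id` (or `cluster_id`),
#'   `chrom`, `strand` and `anchor_pos` (or `rep_pos`; 0-based coordinate).
#' @param annotations An [annotation_set()].
#' @param precedence Category order; default `c("miRNA", "piRNA", "TSSa")`.
#' @return data.frame with `match_id`, `assigned_class`
#'   (`miRNA`/`piRNA`/`TSSa`/`unannotated`) and `matched_annotation`
#'   (annotation name, or `""` when unannotated).
#' @export
classify_clusters <- function(clusters, annotations,
                              precedence = c("miRNA", "piRNA", "TSSa")) {
  stopifnot(inherits(annotations, "annotation_set"))
  id <- clusters$match_id %||% clusters$cluster_id
  pos0 <- clusters$anchor_pos %||% clusters$rep_pos
  if (nrow(clusters) == 0L)
    return(data.frame(match_id = character(), assigned_class = character(),
                      matched_annotation = character(), stringsAsFactors = FALSE))
  points <- GenomicRanges::GRanges(
    seqnames = clusters$chrom,
    ranges = IRanges::IRanges(start = as.integer(pos0) + 1L, width = 1L),
    strand = clusters$strand)
  ann_of <- list(miRNA = annotations$mirna, piRNA = annotations$pirna,
                 TSSa = annotations$tssa)
  label_of <- list(miRNA = "name", piRNA = "name", TSSa = "source_gene")
  cls <- rep("unannotated", length(points))
  lab <- rep("", length(points))
  for (cat in precedence) {
    open <- cls == "unannotated"
    if (!any(open)) break
    h <- hit_label(points[open], ann_of[[cat]], label_of[[cat]])
    got <- !is.na(h)
    cls[open][got] <- cat
    lab[open][got] <- h[got]
  }
  data.frame(match_id = id, assigned_class = cls, matched_annotation = lab,
             stringsAsFactors = FALSE)
}

#' Classify a final cluster set and tally classes
#'
#' @param final_clusters data.frame of clusters (see [classify_clusters()]).
#' @param annotations An [annotation_set()].
#' @param ... Passed to [classify_clusters()].
#' @return List with `classified` (per-cluster data.frame), `counts` (named
#'   integer vector over miRNA/piRNA/TSSa/unannotated, summing to the number
#'   of clusters) and `unannotated_pct` (percentage, one decimal).
#' @export
classify_all <- function(final_clusters, annotations, ...) {
  classified <- classify_clusters(final_clusters, annotations, ...)
  levels <- c("miRNA", "piRNA", "TSSa", "unannotated")
  counts <- table(factor(classified$assigned_class, levels = levels))
  counts <- stats::setNames(as.integer(counts), levels)
  n <- nrow(classified)
  list(classified = classified, counts = counts,
       unannotated_pct = if (n) round(100 * counts[["unannotated"]] / n, 1) else 0)
}
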