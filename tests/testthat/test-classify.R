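library(GenomicRanges)

tss_df <- function(gene = "g1", chrom = "chr1", strand = "+", tss = 10000L) {
  data.frame(gene_id = gene, chrom = chrom, strand = strand, tss_pos = tss,
             stringsAsFactors = FALSE)
}

window_of <- function(w, kind) w[w$window_kind == kind]

test_that("TSSa windows span -100..+200 sense and -400..0 antisense", {
  w <- build_tssa_windows(tss_df(strand = "+", tss = 10000L))
  same <- window_of(w, "same_strand")
  expect_equal(c(start(same), end(same)), c(9900L, 10200L))
  expect_equal(as.character(strand(same)), "+")
  opp <- window_of(w, "opposite_strand")
  expect_equal(c(start(opp), end(opp)), c(9600L, 10000L))
  expect_equal(as.character(strand(opp)), "-")

  # minus-strand gene mirrors the arithmetic in transcript orientation
  wm <- build_tssa_windows(tss_df(strand = "-", tss = 10000L))
  same_m <- window_of(wm, "same_strand")
  expect_equal(c(start(same_m), end(same_m)), c(9800L, 10100L))
  expect_equal(as.character(strand(same_m)), "-")
  opp_m <- window_of(wm, "opposite_strand")
  expect_equal(c(start(opp_m), end(opp_m)), c(10000L, 10400L))

  expect_warning(wc <- build_tssa_windows(tss_df(tss = 50L)), "clipped")
  expect_equal(start(window_of(wc, "opposite_strand")), 1L)
  expect_equal(end(window_of(wc, "opposite_strand")), 50L)
})

anchor_df <- function(pos0, strand = "+", chrom = "chr1",
                      id = sprintf("x%02d", seq_along(pos0))) {
  n <- length(pos0)
  data.frame(match_id = id, chrom = rep_len(chrom, n),
             strand = rep_len(strand, n), anchor_pos = as.integer(pos0),
             stringsAsFactors = FALSE)
}

write_test_annotations <- function(dir = tempfile()) {
  dir.create(dir)
  gff <- file.path(dir, "mirna.gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tmiRNA_primary_transcript\t1001\t1080\t.\t+\t.\tID=mir1;Name=mir1",
               "chr1\tsrc\tmiRNA\t1010\t1031\t.\t+\t.\tID=mir1m;Name=mir1-5p"),
             gff)
  bed <- file.path(dir, "pirna.bed")
  writeLines(c("chr1\t1000\t1100\tpi1\t0\t+",
               "chr1\t5000\t5100\tpi2\t0\t-"), bed)
  tsv <- file.path(dir, "tss.tsv")
  utils::write.table(tss_df(tss = 10000L), tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(gff = gff, bed = bed, tsv = tsv)
}

test_that("classification applies miRNA > piRNA > TSSa precedence on the matching strand", {
  p <- write_test_annotations()
  ann <- annotation_set(p$gff, p$bed, p$tsv)

  res <- classify_clusters(anchor_df(c(
    1019L,   # inside both mir1 and pi1 -> miRNA wins
    1049L,   # inside pi1 only (outside the mature, inside precursor) -> still miRNA via precursor
    1090L,   # pi1 only -> piRNA
    10149L,  # +150 nt downstream of the TSS, same strand -> TSSa
    30000L   # nothing -> unannotated
  )), ann)
  expect_equal(res$assigned_class,
               c("miRNA", "miRNA", "piRNA", "TSSa", "unannotated"))
  expect_equal(res$matched_annotation[4], "g1")
  expect_equal(res$matched_annotation[5], "")

  # strand mismatch is not a hit: pi2 lives on minus
  expect_equal(classify_clusters(anchor_df(5050L, strand = "+"), ann)$assigned_class,
               "unannotated")
  expect_equal(classify_clusters(anchor_df(5050L, strand = "-"), ann)$assigned_class,
               "piRNA")
  # antisense TSSa window: upstream on the opposite strand
  expect_equal(classify_clusters(anchor_df(9799L, strand = "-"), ann)$assigned_class,
               "TSSa")

  empty <- annotation_set()
  expect_equal(classify_clusters(anchor_df(1019L), empty)$assigned_class,
               "unannotated")
})

test_that("class counts partition the final set with the expected arithmetic", {
  # 132 clusters spaced far apart: 72 miRNA, 6 piRNA, 6 TSSa, rest unannotated
  n <- 132L
  pos1 <- seq(10000L, by = 5000L, length.out = n)  # 1-based anchors
  dir <- tempfile(); dir.create(dir)
  gff <- file.path(dir, "m.gff3")
  writeLines(c("##gff-version 3",
               sprintf("chr1\ts\tmiRNA\t%d\t%d\t.\t+\t.\tID=mir%d;Name=mir%d",
                       pos1[1:72] - 5L, pos1[1:72] + 16L, 1:72, 1:72)), gff)
  bed <- file.path(dir, "p.bed")
  writeLines(sprintf("chr1\t%d\t%d\tpi%d\t0\t+", pos1[73:78] - 11L,
                     pos1[73:78] + 10L, 1:6), bed)
  tsv <- file.path(dir, "t.tsv")
  utils::write.table(
    data.frame(gene_id = sprintf("g%d", 1:6), chrom = "chr1", strand = "+",
               tss_pos = pos1[79:84] - 50L), tsv,
    sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- annotation_set(gff, bed, tsv)
  out <- classify_all(anchor_df(pos1 - 1L, id = sprintf("c%03d", 1:n)), ann)
  expect_equal(unname(out$counts), c(72L, 6L, 6L, 48L))
  expect_equal(sum(out$counts), n)
  expect_equal(out$unannotated_pct, 36.4)

  none <- classify_all(anchor_df(integer(0), id = character(0)), ann)
  expect_equal(sum(none$counts), 0L)
})

test_that("classification is invariant under an orientation flip", {
  cfg <- small_sim_config(seed = 5, jitter_sd = 0)
  truth <- generate_truth(cfg)
  d1 <- tempfile(); p1 <- write_fixture(truth, list(), d1)
  ann <- annotation_set(p1$mirna_gff3, p1$pirna_bed, p1$tss_tsv)
  loci <- truth$loci
  clusters <- data.frame(match_id = loci$locus_id, chrom = loci$chrom,
                         strand = loci$strand, anchor_pos = loci$pos5p,
                         stringsAsFactors = FALSE)
  base_counts <- classify_all(clusters, ann)$counts

  # mirror every coordinate around the chromosome and swap every strand
  L <- max(cfg$chrom_lengths) + 1000L
  flip1 <- function(x) L + 1L - x          # 1-based reflection
  flip_strand <- function(s) ifelse(s == "+", "-", "+")
  clusters_f <- clusters
  clusters_f$anchor_pos <- (L - 1L) - clusters$anchor_pos  # 0-based reflection
  clusters_f$strand <- flip_strand(clusters$strand)

  d2 <- tempfile(); dir.create(d2)
  m <- truth$mirna
  writeLines(c("##gff-version 3",
               sprintf("%s\tsim\t%s\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                       m$chrom, m$type, flip1(m$end), flip1(m$start),
                       flip_strand(m$strand), m$name, m$name)),
             file.path(d2, "m.gff3"))
  pi <- truth$pirna
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", pi$chrom,
                     (L - 1L) - (pi$end0 - 1L), (L - 1L) - pi$start0 + 1L,
                     pi$name, flip_strand(pi$strand)),
             file.path(d2, "p.bed"))
  ts <- truth$tss
  utils::write.table(
    data.frame(gene_id = ts$gene_id, chrom = ts$chrom,
               strand = flip_strand(ts$strand), tss_pos = flip1(ts$tss_pos)),
    file.path(d2, "t.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  ann_f <- annotation_set(file.path(d2, "m.gff3"), file.path(d2, "p.bed"),
                          file.path(d2, "t.tsv"))
  expect_equal(classify_all(clusters_f, ann_f)$counts, base_counts)
})
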