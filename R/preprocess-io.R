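#' Read aligned small-RNA reads from SAM, BAM or BED
#'
#' Loads an alignment file into the package's read table. Each row is one
#' mapped read with its biological 5' end: the leftmost coordinate on the
#' `+` strand, the rightmost on the `-` strand. Coordinates are 0-based
#' internally (BED convention); SAM/BAM 1-based positions are converted.
#'
#' Uniqueness of mapping is taken from the `NH` tag when present
#' (`NH == 1`), otherwise from mapping quality (`MAPQ >= mapq_unique`).
#' Alignments produced with Bowtie `-m 1` are unique by construction, so the
#' MAPQ fallback only matters for foreign inputs. BED input carries no
#' mapping metadata and every record is treated as uniquely mapped.
#'
#' @param path Path to the alignment file.
#' @param format One of `"auto"` (by file extension), `"sam"`, `"bam"`,
#'   `"bed"`.
#' @param mapq_unique MAPQ threshold used as the uniqueness fallback when no
#'   `NH` tag is present. Default 20.
#' @return A `data.frame` with columns `chrom`, `strand`, `start` (0-based),
#'   `length` (nt), `unique` (logical), `five_prime` (0-based).
#' @export
read_alignments <- function(path, format = c("auto", "sam", "bam", "bed"),
                            mapq_unique = 20L) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("alignment file not found: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, sam = "sam", bam = "bam", bed = "bed",
                     stopf("cannot infer format from extension '.%s'; pass format=", ext))
  }
  if (format == "bed") return(read_alignments_bed(path))
  read_alignments_sambam(path, format, mapq_unique)
}

read_alignments_bed <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stopf("malformed BED '%s': %s", path, conditionMessage(e)))
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*"))
    stopf("BED record without strand (column 6) in %s", path)
  start0 <- GenomicRanges::start(gr) - 1L
  len <- GenomicRanges::width(gr)
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = strand,
    start = start0,
    length = len,
    unique = TRUE,
    five_prime = ifelse(strand == "+", start0, start0 + len - 1L),
    stringsAsFactors = FALSE
  )
}

read_alignments_sambam <- function(path, format, mapq_unique) {
  bam <- path
  if (format == "sam") {
    dest <- tempfile(fileext = "")
    bam <- tryCatch(
      Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                       indexDestination = FALSE),
      error = function(e) stopf("malformed SAM '%s': %s", path, conditionMessage(e)))
  }
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE),
    what = "mapq", tag = "NH")
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  strand <- as.character(GenomicAlignments::strand(ga))
  start0 <- GenomicAlignments::start(ga) - 1L
  len <- GenomicAlignments::width(ga)  # reference span of the alignment
  nh <- S4Vectors::mcols(ga)$NH
  mapq <- S4Vectors::mcols(ga)$mapq
  uniq <- if (!is.null(nh) && !all(is.na(nh))) {
    ifelse(is.na(nh), !is.na(mapq) & mapq >= mapq_unique, nh == 1L)
  } else {
    !is.na(mapq) & mapq >= mapq_unique
  }
  data.frame(
    chrom = as.character(GenomicAlignments::seqnames(ga)),
    strand = strand,
    start = start0,
    length = len,
    unique = as.logical(uniq),
    five_prime = ifelse(strand == "+", start0, start0 + len - 1L),
    stringsAsFactors = FALSE
  )
}

#' Filter reads by length and mapping uniqueness
#'
#' Applies the read-level filters used before clustering: reads longer than
#' `max_len` nt are removed (library size selection targets inserts below
#' ~30 nt, so longer alignments are background), and only uniquely mapped
#' reads are kept. For the removal accounting, a read that is both too long
#' and multi-mapped counts as removed-for-length, mirroring the upstream
#' order of the processing pipeline (length filter precedes alignment
#' bookkeeping).
#'
#' @param reads Read table from [read_alignments()].
#' @param max_len Maximum retained read length in nt (default 30; reads of
#'   exactly `max_len` are retained).
#' @param unique_only Drop non-uniquely mapped reads (default `TRUE`).
#' @return A list with `reads` (the retained rows, input order preserved) and
#'   `stats`, a list with `input_reads`, `removed_long`, `removed_nonunique`
#'   and `retained` satisfying
#'   `input_reads == removed_long + removed_nonunique + retained`.
#' @export
filter_reads <- function(reads, max_len = 30L, unique_only = TRUE) {
  assert_reads(reads)
  too_long <- reads$length > max_len
  nonuniq <- if (unique_only) !reads$unique & !too_long else rep(FALSE, nrow(reads))
  keep <- !too_long & !nonuniq
  list(
    reads = reads[keep, , drop = FALSE],
    stats = list(
      input_reads = nrow(reads),
      removed_long = sum(too_long),
      removed_nonunique = sum(nonuniq),
      retained = sum(keep)
    )
  )
}
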