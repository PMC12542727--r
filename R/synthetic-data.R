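#' Default planted-locus roster
#'
#' The roster encodes the retention archetypes the wash experiment is built
#' around, with per-condition abundance weights (arbitrary units; they are
#' normalised per condition together with the noise fraction):
#'
#' * `stable_high` — a handful of very abundant loci retained across all
#'   three washes (BA/LS/HS weights within less than two-fold of each
#'   other) and nearly absent from interphase nuclei (NC). These are the
#'   ground-truth "highly and stably associated" clusters.
#' * `hs_labile` — abundant under the no-salt and low-salt washes but
#'   stripped by high salt (HS weight 25-fold lower), so they fail the
#'   stability criterion.
#' * `nc_specific` — interphase-enriched loci, essentially absent from the
#'   mitotic chromosome washes.
#' * `low_background` — many weak loci forming the long tail of the
#'   abundance distribution.
#'
#' The weights produce the heavy skew seen in chromosome-associated
#' small-RNA libraries: the 8 `stable_high` loci (0.5% of the 1600-locus
#' roster) carry >= 90% of the expected reads in every wash condition.
#' Each archetype cycles through the annotation classes listed in
#' `classes`, so every truth class (miRNA/piRNA/TSSa/novel) is planted.
#'
#' @return Named list of archetype specifications (`n`, `weight`,
#'   `classes`).
#' @export
default_locus_roster <- function() {
  list(
    stable_high = list(
      n = 8L,
      weight = c(BA = 1.0, LS = 0.95, HS = 0.90, NC = 0.05),
      classes = c("miRNA", "miRNA", "miRNA", "miRNA", "piRNA", "TSSa",
                  "novel", "novel")),
    hs_labile = list(
      n = 6L,
      weight = c(BA = 0.05, LS = 0.05, HS = 0.002, NC = 0.002),
      classes = c("miRNA", "miRNA", "miRNA", "piRNA", "TSSa", "novel")),
    nc_specific = list(
      n = 6L,
      weight = c(BA = 0.002, LS = 0.002, HS = 0.002, NC = 1.0),
      classes = c("miRNA", "miRNA", "piRNA", "piRNA", "TSSa", "novel")),
    low_background = list(
      n = 1580L,
      weight = c(BA = 6.9e-5, LS = 6.9e-5, HS = 6.9e-5, NC = 6.9e-5),
      classes = "novel")
  )
}

#' Simulation configuration
#'
#' @param chrom_lengths Named integer vector of chromosome lengths in bp.
#' @param conditions Condition names; default the four libraries BA (buffer
#'   A, no salt), LS (low salt), HS (high salt) and NC (interphase nuclei).
#' @param n_reads Reads per condition (scalar, or named per condition).
#' @param jitter_sd Standard deviation (nt) of the rounded Gaussian scatter
#'   of read 5' ends around a locus's canonical 5' end; offsets are
#'   truncated to +/- 7 nt so a planted locus always stays inside the 15-nt
#'   clustering radius. Default 1.
#' @param noise_fraction Fraction of reads drawn uniformly over the genome
#'   (scalar or named per condition), default 0.02.
#' @param seed Integer seed; the same configuration always yields identical
#'   output.
#' @param roster Locus roster, see [default_locus_roster()].
#' @param read_length_mean Default planted read length in nt (miRNA-sized);
#'   piRNA-class loci use 27 nt.
#' @return A `sim_config` list.
#' @export
sim_config <- function(chrom_lengths = c(chr1 = 1000000L, chr2 = 800000L,
                                         chr3 = 600000L),
                       conditions = c("BA", "LS", "HS", "NC"),
                       n_reads = 100000L,
                       jitter_sd = 1,
                       noise_fraction = 0.02,
                       seed = 1L,
                       roster = default_locus_roster(),
                       read_length_mean = 22L) {
  if (is.null(names(chrom_lengths))) stopf("chrom_lengths must be named")
  expand <- function(x, what) {
    if (length(x) == 1L && is.null(names(x)))
      x <- stats::setNames(rep(x, length(conditions)), conditions)
    if (!all(conditions %in% names(x)))
      stopf("%s must cover every condition", what)
    x[conditions]
  }
  n_reads <- expand(n_reads, "n_reads")
  noise_fraction <- expand(noise_fraction, "noise_fraction")
  if (any(n_reads <= 0)) stopf("n_reads must be > 0")
  if (any(noise_fraction < 0 | noise_fraction > 1))
    stopf("noise_fraction must lie in [0, 1]")
  for (a in roster)
    if (!all(conditions %in% names(a$weight)))
      stopf("roster weights must cover every condition")
  structure(list(chrom_lengths = chrom_lengths, conditions = conditions,
                 n_reads = n_reads, jitter_sd = jitter_sd,
                 noise_fraction = noise_fraction, seed = as.integer(seed),
                 roster = roster, read_length_mean = as.integer(read_length_mean)),
            class = "sim_config")
}

# placement geometry: candidate slots every SLOT_SPACING bp with +/- 50 bp
# scatter and a 500 bp margin from chromosome ends, so any two loci are
# >= 500 nt apart on either strand — planted clusters can never merge under
# the 15-nt rule and no locus can stray into another locus's annotation
# (the widest window, TSSa opposite-strand, spans 450 nt from an anchor).
SLOT_SPACING <- 600L
SLOT_MARGIN <- 500L

#' Generate ground-truth loci and annotation sources
#'
#' Places the roster's loci on the synthetic genome (well separated, so the
#' clustering stage recovers them one-to-one), assigns per-condition
#' expected read fractions, and derives annotation records consistent with
#' each locus's truth class: miRNA loci get miRBase-style precursor+mature
#' GFF3 records containing the locus 5' end, piRNA loci get a BED interval
#' around it, TSSa loci get a TSS placed so the locus falls 50 nt
#' downstream of it inside the same-strand TSSa window, and `novel` loci
#' overlap no annotation.
#'
#' @param config A [sim_config()].
#' @return A `sim_truth` list: `loci` (data.frame with `locus_id`,
#'   `archetype`, `truth_class`, `chrom`, `strand`, `pos5p` (0-based),
#'   `read_length_mean`, and one `ab_<condition>` expected-fraction column
#'   per condition), `mirna`, `pirna`, `tss` annotation data.frames, and
#'   the `config`.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  roster <- config$roster
  n_loci <- sum(vapply(roster, function(a) a$n, integer(1)))
  slots <- rbindlist(lapply(names(config$chrom_lengths), function(ch) {
    len <- config$chrom_lengths[[ch]]
    if (len < 2L * SLOT_MARGIN + SLOT_SPACING) return(NULL)
    data.table(chrom = ch, pos = seq(SLOT_MARGIN, len - SLOT_MARGIN,
                                     by = SLOT_SPACING))
  }))
  if (is.null(slots) || nrow(slots) < n_loci)
    stopf("chromosomes too small to place %d loci (only %d candidate sites)",
          n_loci, if (is.null(slots)) 0L else nrow(slots))

  loci <- with_seed(config$seed, {
    pick <- sample.int(nrow(slots), n_loci)
    df <- data.frame(
      locus_id = sprintf("locus%04d", seq_len(n_loci)),
      archetype = rep(names(roster), vapply(roster, function(a) a$n, integer(1))),
      truth_class = unlist(lapply(roster, function(a)
        rep_len(a$classes, a$n)), use.names = FALSE),
      chrom = slots$chrom[pick],
      strand = sample(c("+", "-"), n_loci, replace = TRUE),
      pos5p = slots$pos[pick] + sample(-50:50, n_loci, replace = TRUE),
      stringsAsFactors = FALSE)
    df$read_length_mean <- ifelse(df$truth_class == "piRNA", 27L,
                                  config$read_length_mean)
    df
  })

  # expected read fraction per condition: weights normalised to 1 - noise
  w <- do.call(rbind, lapply(seq_along(roster), function(i)
    matrix(roster[[i]]$weight[config$conditions], nrow = roster[[i]]$n,
           ncol = length(config$conditions), byrow = TRUE)))
  colnames(w) <- config$conditions
  for (cond in config$conditions)
    loci[[paste0("ab_", cond)]] <-
      w[, cond] / sum(w[, cond]) * (1 - config$noise_fraction[[cond]])

  p1 <- loci$pos5p + 1L  # 1-based anchor coordinate
  is_mi <- loci$truth_class == "miRNA"
  mirna <- if (any(is_mi)) {
    plus <- loci$strand[is_mi] == "+"
    rbind(
      data.frame(chrom = loci$chrom[is_mi], type = "miRNA_primary_transcript",
                 start = p1[is_mi] - 30L, end = p1[is_mi] + 30L,
                 strand = loci$strand[is_mi],
                 name = paste0(loci$locus_id[is_mi], "_pre"),
                 stringsAsFactors = FALSE),
      data.frame(chrom = loci$chrom[is_mi], type = "miRNA",
                 start = ifelse(plus, p1[is_mi], p1[is_mi] - 21L),
                 end = ifelse(plus, p1[is_mi] + 21L, p1[is_mi]),
                 strand = loci$strand[is_mi],
                 name = paste0(loci$locus_id[is_mi], "_mature"),
                 stringsAsFactors = FALSE))
  } else data.frame()

  is_pi <- loci$truth_class == "piRNA"
  pirna <- if (any(is_pi)) {
    data.frame(chrom = loci$chrom[is_pi], start0 = loci$pos5p[is_pi] - 20L,
               end0 = loci$pos5p[is_pi] + 21L,
               name = paste0(loci$locus_id[is_pi], "_pi"), score = 0L,
               strand = loci$strand[is_pi], stringsAsFactors = FALSE)
  } else data.frame()

  is_ts <- loci$truth_class == "TSSa"
  tss <- if (any(is_ts)) {
    plus <- loci$strand[is_ts] == "+"
    data.frame(gene_id = paste0(loci$locus_id[is_ts], "_gene"),
               chrom = loci$chrom[is_ts], strand = loci$strand[is_ts],
               tss_pos = ifelse(plus, p1[is_ts] - 50L, p1[is_ts] + 50L),
               stringsAsFactors = FALSE)
  } else data.frame()

  structure(list(loci = loci, mirna = mirna, pirna = pirna, tss = tss,
                 config = config),
            class = "sim_truth")
}

# rounded Gaussian offsets truncated (by rejection) to +/- `bound` nt
truncated_jitter <- function(n, sd, bound = 7L) {
  if (n == 0L || sd == 0) return(integer(n))
  off <- as.integer(round(rnorm(n, 0, sd)))
  bad <- which(abs(off) > bound)
  while (length(bad)) {
    off[bad] <- as.integer(round(rnorm(length(bad), 0, sd)))
    bad <- bad[abs(off[bad]) > bound]
  }
  off
}

#' Simulate aligned reads for one condition
#'
#' Reads are allocated multinomially across the planted loci and the
#' uniform-noise component according to the condition's expected fractions.
#' Planted reads scatter their 5' ends around the locus's canonical 5' end
#' by a rounded truncated Gaussian (see [sim_config()]); noise reads fall
#' uniformly over the genome with random strand. All reads are <= 30 nt and
#' flagged uniquely mapped; `nonunique_fraction` flips the uniqueness flag
#' (only the flag — there is no second alignment) on a random subset, to
#' exercise the uniqueness filter.
#'
#' @param truth A `sim_truth` from [generate_truth()].
#' @param condition Condition name (must exist in the configuration).
#' @param config Optional override of `truth$config`.
#' @param nonunique_fraction Fraction of reads flagged non-unique, default 0.
#' @return Read table as from [read_alignments()], plus a `locus_id` column
#'   (`NA` for noise reads).
#' @export
simulate_reads <- function(truth, condition, config = truth$config,
                           nonunique_fraction = 0) {
  stopifnot(inherits(truth, "sim_truth"))
  if (!condition %in% config$conditions)
    stopf("unknown condition '%s'", condition)
  loci <- truth$loci
  ab <- loci[[paste0("ab_", condition)]]
  if (is.null(ab)) stopf("condition '%s' missing from abundance map", condition)
  n <- config$n_reads[[condition]]
  seed_c <- (config$seed * 1000L + match(condition, config$conditions)) %% 2147483629L

  with_seed(seed_c, {
    probs <- c(ab, config$noise_fraction[[condition]])
    counts <- as.vector(rmultinom(1L, n, probs))
    n_noise <- counts[length(counts)]
    counts <- counts[-length(counts)]

    idx <- rep.int(seq_len(nrow(loci)), counts)
    np <- length(idx)
    fp <- loci$pos5p[idx] + truncated_jitter(np, config$jitter_sd)
    len <- pmin(30L, pmax(18L, as.integer(round(
      rnorm(np, loci$read_length_mean[idx], 1.2)))))
    planted <- data.frame(
      chrom = loci$chrom[idx], strand = loci$strand[idx],
      start = ifelse(loci$strand[idx] == "+", fp, fp - len + 1L),
      length = len, unique = TRUE, five_prime = fp,
      locus_id = loci$locus_id[idx], stringsAsFactors = FALSE)

    noise <- if (n_noise > 0L) {
      chs <- sample(names(config$chrom_lengths), n_noise, replace = TRUE,
                    prob = config$chrom_lengths)
      lens <- sample(18:28, n_noise, replace = TRUE)
      maxlen <- config$chrom_lengths[chs]
      fpn <- as.integer(floor(runif(n_noise, 40, maxlen - 40)))
      stn <- sample(c("+", "-"), n_noise, replace = TRUE)
      data.frame(chrom = chs, strand = stn,
                 start = ifelse(stn == "+", fpn, fpn - lens + 1L),
                 length = lens, unique = TRUE, five_prime = fpn,
                 locus_id = NA_character_, stringsAsFactors = FALSE)
    } else NULL

    reads <- rbind(planted, noise)
    rownames(reads) <- NULL
    if (nonunique_fraction > 0) {
      flip <- sample.int(nrow(reads), floor(nonunique_fraction * nrow(reads)))
      reads$unique[flip] <- FALSE
    }
    reads
  })
}

#' Write a complete synthetic fixture to disk
#'
#' Emits, per condition, a minimal valid SAM file (`@HD`/`@SQ` header,
#' FLAG bit 0x10 for strand, `NH:i` tag for uniqueness) and a BED6
#' alignment table; plus the miRNA GFF3 (1-based), piRNA BED6 (0-based),
#' TSS TSV and a ground-truth locus TSV. All files round-trip losslessly
#' through [read_alignments()] and [annotation_set()].
#'
#' @param truth A `sim_truth`.
#' @param reads_by_condition Named list of read tables from
#'   [simulate_reads()].
#' @param out_dir Output directory (created if needed).
#' @return Named list of written file paths, invisibly.
#' @export
write_fixture <- function(truth, reads_by_condition, out_dir) {
  stopifnot(inherits(truth, "sim_truth"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stopf("cannot create output directory '%s'", out_dir)
  cfg <- truth$config
  paths <- list()

  for (cond in names(reads_by_condition)) {
    reads <- reads_by_condition[[cond]]
    sam <- file.path(out_dir, paste0(cond, ".sam"))
    header <- c("@HD\tVN:1.6\tSO:unknown",
                sprintf("@SQ\tSN:%s\tLN:%d", names(cfg$chrom_lengths),
                        as.integer(cfg$chrom_lengths)))
    body <- sprintf("r%07d\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*\tNH:i:%d",
                    seq_len(nrow(reads)),
                    ifelse(reads$strand == "-", 16L, 0L),
                    reads$chrom, reads$start + 1L,
                    ifelse(reads$unique, 42L, 1L),
                    reads$length,
                    strrep("N", reads$length),
                    ifelse(reads$unique, 1L, 2L))
    writeLines(c(header, body), sam)
    paths[[paste0("sam_", cond)]] <- sam

    bed <- file.path(out_dir, paste0(cond, ".bed"))
    fwrite(data.table(reads$chrom, reads$start, reads$start + reads$length,
                      sprintf("r%07d", seq_len(nrow(reads))), 0L, reads$strand),
           bed, sep = "\t", col.names = FALSE)
    paths[[paste0("bed_", cond)]] <- bed
  }

  gff <- file.path(out_dir, "mirna.gff3")
  lines <- "##gff-version 3"
  if (nrow(truth$mirna)) {
    m <- truth$mirna
    lines <- c(lines, sprintf("%s\tmcasr_sim\t%s\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                              m$chrom, m$type, m$start, m$end, m$strand,
                              m$name, m$name))
  }
  writeLines(lines, gff)
  paths$mirna_gff3 <- gff

  pirna <- file.path(out_dir, "pirna.bed")
  if (nrow(truth$pirna)) {
    fwrite(truth$pirna, pirna, sep = "\t", col.names = FALSE)
  } else writeLines(character(), pirna)
  paths$pirna_bed <- pirna

  tss <- file.path(out_dir, "tss.tsv")
  utils::write.table(truth$tss, tss, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$tss_tsv <- tss

  tt <- file.path(out_dir, "truth.tsv")
  utils::write.table(truth$loci, tt, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$truth_tsv <- tt

  invisible(paths)
}
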