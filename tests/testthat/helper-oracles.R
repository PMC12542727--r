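# Independent oracles and small fixture builders shared across tests.

# Build a read table from 5'-end positions (one strand, one chromosome).
make_reads <- function(five_prime, chrom = "chr1", strand = "+", length = 22L,
                       unique = TRUE) {
  n <- length(five_prime)
  chrom <- rep_len(chrom, n); strand <- rep_len(strand, n)
  length <- rep_len(as.integer(length), n); unique <- rep_len(unique, n)
  fp <- as.integer(five_prime)
  data.frame(chrom = chrom, strand = strand,
             start = ifelse(strand == "+", fp, fp - length + 1L),
             length = length, unique = unique, five_prime = fp,
             stringsAsFactors = FALSE)
}

# Brute-force union-find over ALL pairs at distance < gap (same chrom+strand),
# independent of the package's sorted-chaining implementation. Returns an
# integer group label per element.
uf_partition <- function(chrom, strand, pos, gap = 15L) {
  n <- length(pos)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unite <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <<- ri }
  key <- paste(chrom, strand)
  block <- 500L
  for (i0 in seq(1L, n, by = block)) {
    ii <- i0:min(n, i0 + block - 1L)
    hit <- abs(outer(pos[ii], pos, "-")) < gap &
      outer(key[ii], key, "==")
    w <- which(hit, arr.ind = TRUE)
    w <- w[ii[w[, 1]] < w[, 2], , drop = FALSE]
    for (r in seq_len(nrow(w))) unite(ii[w[r, 1]], w[r, 2])
  }
  vapply(seq_len(n), find, integer(1))
}

# Canonical signature of a partition of reads into clusters: one string per
# group over (chrom, strand, min, max, count), sorted.
partition_signature <- function(chrom, strand, pos, grp) {
  sig <- tapply(seq_along(pos), grp, function(i)
    sprintf("%s:%s:%d-%d:n%d", chrom[i][1], strand[i][1],
            min(pos[i]), max(pos[i]), length(i)))
  sort(unname(unlist(sig)))
}

# signature of a cluster_reads() result
cluster_table_signature <- function(cl) {
  sort(sprintf("%s:%s:%d-%d:n%d", cl$chrom, cl$strand, cl$min_pos, cl$max_pos,
               cl$read_count))
}

# Exact two-sided Mann-Whitney p-value by full enumeration of all
# choose(m+n, m) group assignments of the pooled sample (tie-free inputs).
exact_wilcox_p <- function(x, y) {
  pooled <- c(x, y)
  m <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  splits <- utils::combn(length(pooled), m)
  w_all <- colSums(matrix(r[splits], nrow = m)) - m * (m + 1) / 2
  mu <- m * (length(y)) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# condition_table straight from read counts (cluster ids c1, c2, ...)
make_table <- function(read_counts, condition = "BA",
                       total = max(sum(read_counts), 1)) {
  n <- length(read_counts)
  cl <- data.frame(cluster_id = sprintf("c%03d", seq_len(n)),
                   chrom = rep("chr1", n), strand = rep("+", n),
                   rep_pos = seq_len(n) * 1000L,
                   read_count = as.integer(read_counts),
                   length_5_95 = rep(0L, n), min_pos = seq_len(n) * 1000L,
                   max_pos = seq_len(n) * 1000L, stringsAsFactors = FALSE)
  compute_rpm(cl, total_mapped = total, condition = condition)
}

# hand-built matched_clusters object from an RPM matrix (columns = conditions)
fake_matched <- function(rpms) {
  n <- nrow(rpms)
  df <- data.frame(match_id = sprintf("m%03d", seq_len(n)),
                   chrom = rep("chr1", n), strand = rep("+", n),
                   anchor_pos = seq_len(n) * 1000L, stringsAsFactors = FALSE)
  for (cc in colnames(rpms)) {
    df[[paste0("rpm_", cc)]] <- rpms[, cc]
    df[[paste0("count_", cc)]] <- round(rpms[, cc])
  }
  members <- do.call(rbind, lapply(colnames(rpms), function(cc)
    data.frame(match_id = df$match_id, condition = rep(cc, n),
               cluster_id = paste0(cc, "_", df$match_id),
               stringsAsFactors = FALSE)))
  members <- members[as.vector(rpms) > 0, , drop = FALSE]
  structure(list(matched = df, members = members, conditions = colnames(rpms)),
            class = "matched_clusters")
}

# small fast simulation configuration for pipeline tests
small_sim_config <- function(seed = 1L, n_reads = 20000L, jitter_sd = 1, ...) {
  sim_config(seed = seed, n_reads = n_reads, jitter_sd = jitter_sd, ...)
}

# match recovered final clusters against planted loci; returns sensitivity
# and FDR with respect to the stable_high archetype
recovery_stats <- function(report, truth, tol = 15L) {
  final <- report$matched$matched[
    report$matched$matched$match_id %in% report$final_set, , drop = FALSE]
  stable <- truth$loci[truth$loci$archetype == "stable_high", , drop = FALSE]
  hit_stable <- vapply(seq_len(nrow(stable)), function(i)
    any(final$chrom == stable$chrom[i] & final$strand == stable$strand[i] &
          abs(final$anchor_pos - stable$pos5p[i]) < tol), logical(1))
  is_true_pos <- vapply(seq_len(nrow(final)), function(j)
    any(stable$chrom == final$chrom[j] & stable$strand == final$strand[j] &
          abs(stable$pos5p - final$anchor_pos[j]) < tol), logical(1))
  list(sensitivity = mean(hit_stable),
       fdr = if (nrow(final)) mean(!is_true_pos) else 0,
       final_size = nrow(final))
}

run_sim_pipeline <- function(cfg, n_perm = 200L) {
  truth <- generate_truth(cfg)
  reads <- lapply(stats::setNames(cfg$conditions, cfg$conditions),
                  function(cc) simulate_reads(truth, cc))
  pcfg <- pipeline_config(
    conditions = stats::setNames(rep("unused", length(cfg$conditions)),
                                 cfg$conditions),
    seed = cfg$seed, n_perm = n_perm)
  list(report = mcasr:::run_pipeline_frames(reads, pcfg, annots = NULL),
       truth = truth, reads = reads)
}
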