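two_cluster_tables <- function(pos_a, pos_b, strand_a = "+", strand_b = "+") {
  ta <- compute_rpm(cluster_reads(make_reads(pos_a, strand = strand_a)),
                    length(pos_a), condition = "BA")
  tb <- compute_rpm(cluster_reads(make_reads(pos_b, strand = strand_b)),
                    length(pos_b), condition = "LS")
  list(ta, tb)
}

test_that("clusters within the tolerance merge across conditions; strands never do", {
  m <- match_clusters(two_cluster_tables(rep(1000L, 5), rep(1004L, 3)))
  expect_equal(nrow(m$matched), 1L)
  expect_gt(m$matched$rpm_BA, 0)
  expect_gt(m$matched$rpm_LS, 0)

  m2 <- match_clusters(two_cluster_tables(rep(1000L, 5), rep(1004L, 3),
                                          strand_b = "-"))
  expect_equal(nrow(m2$matched), 2L)
  expect_error(match_clusters(list(two_cluster_tables(1L, 2L)[[1]])), "two")
})

test_that("cross-condition grouping equals brute-force transitive closure", {
  set.seed(31)
  for (i in 1:15) {
    conds <- c("BA", "LS", "HS")
    tabs <- lapply(conds, function(cc) {
      pos <- sample.int(3000, sample(20:80, 1))
      compute_rpm(cluster_reads(make_reads(pos)), length(pos), condition = cc)
    })
    m <- match_clusters(tabs)
    pooled <- do.call(rbind, lapply(tabs, function(t)
      data.frame(cond = t$condition, pos = t$clusters$rep_pos)))
    grp <- uf_partition(rep("chr1", nrow(pooled)), rep("+", nrow(pooled)),
                        pooled$pos)
    # same number of groups and same member partition by position signature
    expect_equal(nrow(m$matched), length(unique(grp)))
    memb <- merge(m$members,
                  do.call(rbind, lapply(tabs, function(t)
                    data.frame(condition = t$condition,
                               cluster_id = t$clusters$cluster_id,
                               pos = t$clusters$rep_pos))))
    sig_pkg <- sort(tapply(memb$pos, memb$match_id, function(p)
      paste(sort(p), collapse = ",")))
    sig_uf <- sort(tapply(pooled$pos, grp, function(p)
      paste(sort(p), collapse = ",")))
    expect_identical(unname(sig_pkg), unname(sig_uf))
    # symmetry: supplying the tables in reverse order changes nothing
    m_rev <- match_clusters(rev(tabs))
    expect_equal(nrow(m_rev$matched), nrow(m$matched))
    expect_identical(sort(m_rev$matched$anchor_pos), sort(m$matched$anchor_pos))
  }
})

test_that("stability bounds are strict and zero RPM fails the pair", {
  m <- fake_matched(cbind(BA = c(100, 100, 100), LS = c(60, 50, 0),
                          HS = c(80, 80, 80)))
  s <- stability_filter(m)
  expect_true("m001" %in% s[["BA-LS"]])   # ratio 1.667 inside (0.5, 2)
  expect_false("m002" %in% s[["BA-LS"]])  # ratio exactly 2 fails (open bound)
  expect_false("m003" %in% s[["BA-LS"]])  # absent in LS fails
  expect_false("m003" %in% s[["LS-HS"]])
})

test_that("passing all pairs is equivalent to max/min RPM ratio < 2", {
  set.seed(13)
  for (i in 1:300) {
    r <- stats::runif(3, 0, 10)
    if (i %% 7 == 0) r[sample(3, 1)] <- 0
    m <- fake_matched(matrix(r, 1, dimnames = list(NULL, c("BA", "LS", "HS"))))
    s <- stability_filter(m)
    passes <- all(vapply(s, function(x) "m001" %in% x, logical(1)))
    oracle <- all(r > 0) && max(r) / min(r) < 2
    expect_equal(passes, oracle)
  }
})

test_that("final set intersects pair sets with above-cut-off status", {
  rpms <- cbind(BA = c(100, 100, 100, 5), LS = c(90, 90, 90, 5),
                HS = c(80, 30, 80, 5))
  m <- fake_matched(rpms)
  s <- stability_filter(m)
  cutoffs <- lapply(c("BA", "LS", "HS"), function(cc) {
    sel <- m$members$cluster_id[m$members$condition == cc &
                                  m$matched[[paste0("rpm_", cc)]] >= 50]
    list(condition = cc, cutoff_rpm = 50, selected = sel, covered_fraction = 0.95)
  })
  names(cutoffs) <- c("BA", "LS", "HS")
  res <- high_stable_intersection(m, cutoffs, s)
  # m001/m003 pass everything; m002 fails both HS pairs (ratio > 2 and below
  # cut-off); m004 is below every cut-off
  expect_setequal(res$final, c("m001", "m003"))
  expect_true("m002" %in% res$pair_sets[["BA-LS"]])
  expect_false("m002" %in% res$pair_sets[["LS-HS"]])
  expect_true(all(res$final %in% res$pair_sets[["BA-LS"]]))

  # narrowing the ratio interval can only shrink the final set
  s_narrow <- stability_filter(m, lo = 0.8, hi = 1.25)
  res_narrow <- high_stable_intersection(m, cutoffs, s_narrow)
  expect_true(all(res_narrow$final %in% res$final))
  expect_error(high_stable_intersection(m, cutoffs["BA"], s), "cutoff")
})

test_that("overlap permutation p-value behaves at its extremes", {
  ids <- sprintf("m%03d", 1:148)
  res <- overlap_significance(list(ids, ids, ids), universe = 90000,
                              n_perm = 500, seed = 4)
  expect_equal(res$observed, 148L)
  expect_equal(res$p_value, 1 / 501)  # no random draw reaches 148

  expect_equal(overlap_significance(list(ids), universe = 1000)$p_value, 1)
  expect_error(overlap_significance(list(ids), universe = 10), "universe")

  # random sets are not significant
  set.seed(2)
  rnd <- lapply(1:3, function(i) sample(sprintf("m%03d", 1:200), 20))
  obs <- length(Reduce(intersect, rnd))
  p <- overlap_significance(rnd, universe = 200, n_perm = 400, seed = 9)$p_value
  expect_gt(p, 0.01)
})

test_that("planted condition-specific and labile loci are excluded from the final set", {
  out <- run_sim_pipeline(small_sim_config(seed = 19))
  final <- out$report$matched$matched[
    out$report$matched$matched$match_id %in% out$report$final_set, ]
  for (arch in c("hs_labile", "nc_specific")) {
    loci <- out$truth$loci[out$truth$loci$archetype == arch, ]
    hits <- vapply(seq_len(nrow(loci)), function(i)
      any(final$chrom == loci$chrom[i] & final$strand == loci$strand[i] &
            abs(final$anchor_pos - loci$pos5p[i]) < 15), logical(1))
    expect_false(any(hits))
  }
  # recovered stable clusters are strongly depleted in interphase nuclei
  expect_true(all(final$rpm_BA / pmax(final$rpm_NC, 1e-9) > 2))
})
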