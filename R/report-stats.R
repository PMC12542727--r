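#' Compare two RPM distributions (Wilcoxon rank-sum)
#'
#' Two-sided Mann-Whitney / Wilcoxon rank-sum test between the cluster RPM
#' distributions of two conditions. By default the exact null distribution
#' is used for small tie-free samples and the tie-corrected normal
#' approximation otherwise (the `stats::wilcox.test` rule); pass `exact` to
#' force either.
#'
#' @param rpms_a,rpms_b Numeric vectors (non-empty).
#' @param exact `NULL` (auto), `TRUE` or `FALSE`.
#' @return List with `statistic` (W), `p_value`, `method`.
#' @export
compare_rpm_distributions <- function(rpms_a, rpms_b, exact = NULL) {
  if (!length(rpms_a) || !length(rpms_b)) stopf("empty sample")
  ht <- suppressWarnings(
    stats::wilcox.test(rpms_a, rpms_b, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = "Wilcoxon rank-sum (two-sided)")
}

#' Compare group means (Welch t-test)
#'
#' Two-sided Welch t-test (unequal variances). Two identical zero-variance
#' groups are degenerate for the t statistic and return p = 1 with a
#' warning; zero-variance groups with different means return p = 0 with a
#' warning.
#'
#' @param group_a,group_b Numeric vectors of length >= 2.
#' @return List with `statistic`, `p_value`, `method`.
#' @export
compare_means_ttest <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stopf("each group needs >= 2 observations")
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    same <- isTRUE(all.equal(mean(group_a), mean(group_b)))
    warning("zero-variance groups; t statistic undefined")
    return(list(statistic = if (same) 0 else Inf,
                p_value = if (same) 1 else 0,
                method = "Welch two-sample t-test (degenerate)"))
  }
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = "Welch two-sample t-test (two-sided)")
}

#' PCA of conditions over matched-cluster RPMs
#'
#' Principal component analysis with conditions (samples) as observations
#' and matched clusters as variables. RPMs are log10(x + 1)-transformed by
#' default and each cluster is mean-centered across conditions before the
#' decomposition; set `log_transform = FALSE` for raw-RPM PCA. A matrix with
#' no variance yields all-zero coordinates and a warning.
#'
#' @param rpm_matrix Numeric matrix, clusters x conditions (column names =
#'   condition names); needs >= 2 of each.
#' @param log_transform Apply log10(x + 1) first (default `TRUE`).
#' @return List with `coordinates` (data.frame: condition, PC1, PC2) and
#'   `explained` (variance fractions for PC1, PC2).
#' @export
pca_conditions <- function(rpm_matrix, log_transform = TRUE) {
  if (ncol(rpm_matrix) < 2L || nrow(rpm_matrix) < 2L)
    stopf("need >= 2 conditions and >= 2 matched clusters")
  m <- if (log_transform) log10(rpm_matrix + 1) else rpm_matrix
  x <- t(m)  # samples in rows; prcomp centers each cluster
  if (all(abs(sweep(x, 2, colMeans(x))) < 1e-12)) {
    warning("constant RPM matrix; zero variance")
    coords <- data.frame(condition = colnames(rpm_matrix), PC1 = 0, PC2 = 0)
    return(list(coordinates = coords, explained = c(PC1 = 0, PC2 = 0)))
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- ncol(pc$x)
  pc1 <- pc$x[, 1]
  pc2 <- if (k >= 2) pc$x[, 2] else rep(0, nrow(x))
  vfrac <- pc$sdev^2 / sum(pc$sdev^2)
  list(
    coordinates = data.frame(condition = colnames(rpm_matrix),
                             PC1 = unname(pc1), PC2 = unname(pc2)),
    explained = c(PC1 = vfrac[1], PC2 = if (k >= 2) vfrac[2] else 0)
  )
}

#' Assemble a run report
#'
#' Collects the outputs of every pipeline stage into one structure whose
#' counts are taken directly from the stage results (nothing is recomputed
#' or cached independently, so the report cannot drift from the underlying
#' tables).
#'
#' @param condition_tables Named list of `condition_table` objects.
#' @param cutoffs Named list of [select_cutoff()] results.
#' @param intersection Result of [high_stable_intersection()].
#' @param classification Result of [classify_all()] (or `NULL`).
#' @param tests Named list of test results (or `NULL`).
#' @param pca Result of [pca_conditions()] (or `NULL`).
#' @param overlap Result of [overlap_significance()] (or `NULL`).
#' @param config Resolved pipeline configuration (stored for provenance).
#' @return A `run_report` list.
#' @export
build_report <- function(condition_tables, cutoffs, intersection,
                         classification = NULL, tests = NULL, pca = NULL,
                         overlap = NULL, config = NULL) {
  for (nm in c("condition_tables", "cutoffs", "intersection"))
    if (is.null(get(nm))) stopf("missing stage output: %s", nm)
  structure(list(
    n_clusters = vapply(condition_tables, function(t) nrow(t$clusters), integer(1)),
    total_mapped = vapply(condition_tables, function(t) t$total_mapped, numeric(1)),
    cutoffs = lapply(cutoffs, function(co)
      list(cutoff_rpm = co$cutoff_rpm, n_selected = length(co$selected),
           covered_fraction = co$covered_fraction)),
    pair_set_sizes = vapply(intersection$pair_sets, length, integer(1)),
    final_set_size = length(intersection$final),
    final_set = intersection$final,
    venn = intersection$venn[c("sizes", "pairwise", "common")],
    class_counts = classification$counts,
    unannotated_pct = classification$unannotated_pct,
    tests = tests,
    pca = pca,
    overlap = overlap,
    config = config,
    package_version = as.character(utils::packageVersion("mcasr"))
  ), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("mcasr run report\n")
  cat("  clusters per condition: ",
      paste(sprintf("%s=%d", names(x$n_clusters), x$n_clusters), collapse = ", "), "\n")
  for (nm in names(x$cutoffs))
    cat(sprintf("  cutoff %s: RPM >= %.3f (%d clusters, %.1f%% of reads)\n", nm,
                x$cutoffs[[nm]]$cutoff_rpm, x$cutoffs[[nm]]$n_selected,
                100 * x$cutoffs[[nm]]$covered_fraction))
  cat("  pair-set sizes: ",
      paste(sprintf("%s=%d", names(x$pair_set_sizes), x$pair_set_sizes),
            collapse = ", "), "\n")
  cat(sprintf("  final high/stable set: %d clusters\n", x$final_set_size))
  if (!is.null(x$class_counts)) {
    cat("  classes: ",
        paste(sprintf("%s=%d", names(x$class_counts), x$class_counts),
              collapse = ", "),
        sprintf(" (unannotated %.1f%%)\n", x$unannotated_pct))
  }
  invisible(x)
}

#' Serialise a run report to JSON
#'
#' @param report A `run_report`.
#' @param path Output path.
#' @export
write_report_json <- function(report, path) {
  out <- unclass(report)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(path)
}
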