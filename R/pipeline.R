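#' Pipeline configuration
#'
#' Bundles every tunable parameter of the analysis with defaults matching
#' the published workflow: read length cut at 30 nt, 5'-end clustering gap
#' 15 nt, cumulative-read cut-off fraction 0.90, top-148 ranking, and
#' stability bounds (0.5, 2). Condition roles are declared explicitly:
#' `wash_conditions` enter the cut-off/stability analysis, the optional
#' `control_condition` (interphase nuclei) is matched and reported but
#' never filtered on.
#'
#' @param conditions Named character vector or list: condition name ->
#'   alignment file path.
#' @param wash_conditions Conditions subject to cut-off + stability
#'   (default `c("BA", "LS", "HS")`).
#' @param control_condition Optional control condition name (default
#'   `"NC"` when present among `conditions`).
#' @param format Alignment format for all inputs (`"auto"`, `"sam"`,
#'   `"bam"`, `"bed"`).
#' @param max_read_length,unique_only Read filters ([filter_reads()]).
#' @param cluster_gap Clustering threshold nt ([cluster_reads()]).
#' @param cutoff_fraction Cut-off read fraction ([select_cutoff()]).
#' @param top_n Top-ranked set size ([top_n()]).
#' @param stability_lo,stability_hi Ratio bounds ([stability_filter()]).
#' @param match_tol Cross-condition matching radius nt ([match_clusters()]).
#' @param mirna_gff3,pirna_bed,tss_tsv Annotation paths (optional).
#' @param n_perm Permutations for the overlap test.
#' @param seed RNG seed for the permutation test.
#' @param out_dir Output directory for stage TSVs and the report
#'   (`NULL` = keep everything in memory only).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(conditions,
                            wash_conditions = c("BA", "LS", "HS"),
                            control_condition = if ("NC" %in% names(conditions)) "NC" else NULL,
                            format = "auto",
                            max_read_length = 30L,
                            unique_only = TRUE,
                            cluster_gap = 15L,
                            cutoff_fraction = 0.90,
                            top_n = 148L,
                            stability_lo = 0.5,
                            stability_hi = 2,
                            match_tol = 15L,
                            mirna_gff3 = NULL,
                            pirna_bed = NULL,
                            tss_tsv = NULL,
                            n_perm = 10000L,
                            seed = 1L,
                            out_dir = NULL) {
  conditions <- unlist(conditions)
  if (is.null(names(conditions)) || any(names(conditions) == ""))
    stopf("conditions must be a named vector: condition -> path")
  missing <- setdiff(wash_conditions, names(conditions))
  if (length(missing))
    stopf("missing input for wash condition(s): %s", paste(missing, collapse = ", "))
  if (length(wash_conditions) < 3L)
    stopf("the stability stage needs >= 3 wash conditions")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file is a flat mapping of [pipeline_config()] arguments, with
#' `conditions` itself a mapping of condition name to file path. `overrides`
#' (e.g. from command-line flags) take precedence over file keys.
#'
#' @param path YAML file.
#' @param overrides Named list overriding file keys.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  raw <- utils::modifyList(raw, overrides)
  do.call(pipeline_config, raw)
}

#' Run the full catalogue pipeline
#'
#' Executes filter -> cluster -> quantify -> cut-off -> match -> stability
#' -> intersection -> classification -> statistics -> report over the
#' configured condition libraries. Stage tables are written as TSV under
#' `out_dir` when set, so any stage can be inspected or re-run from its
#' persisted input.
#'
#' @param config A [pipeline_config()], or a path to a YAML config file.
#' @return A `run_report` (see [build_report()]).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  reads <- lapply(names(config$conditions), function(cond) {
    path <- config$conditions[[cond]]
    if (!file.exists(path))
      stopf("input for condition '%s' not found: %s", cond, path)
    read_alignments(path, format = config$format)
  })
  names(reads) <- names(config$conditions)
  annots <- annotation_set(mirna_gff3 = config$mirna_gff3,
                           pirna_bed = config$pirna_bed,
                           tss_tsv = config$tss_tsv)
  run_pipeline_frames(reads, config, annots)
}

# core pipeline over in-memory read tables; shared by run_pipeline() and the
# simulation-driven tests (no file round-trip needed there)
run_pipeline_frames <- function(reads_by_condition, config, annots = NULL) {
  conds <- names(reads_by_condition)
  wash <- config$wash_conditions
  out_dir <- config$out_dir
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  tables <- list()
  filter_stats <- list()
  for (cond in conds) {
    f <- filter_reads(reads_by_condition[[cond]],
                      max_len = config$max_read_length,
                      unique_only = config$unique_only)
    filter_stats[[cond]] <- f$stats
    cl <- cluster_reads(f$reads, max_gap = config$cluster_gap)
    tables[[cond]] <- compute_rpm(cl, total_mapped = f$stats$retained,
                                  condition = cond)
    if (!is.null(out_dir))
      utils::write.table(tables[[cond]]$clusters,
                         file.path(out_dir, paste0("clusters_", cond, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }

  cutoffs <- lapply(tables[wash], select_cutoff, fraction = config$cutoff_fraction)
  topns <- lapply(tables[wash], function(t)
    suppressWarnings(top_n(t, n = config$top_n)))

  matched <- match_clusters(tables, tol = config$match_tol)
  wash_pairs <- utils::combn(wash, 2, simplify = FALSE)
  pair_sets <- stability_filter(matched, pairs = wash_pairs,
                                lo = config$stability_lo,
                                hi = config$stability_hi)
  inter <- high_stable_intersection(matched, cutoffs, pair_sets,
                                    topn_sets = topns)
  overlap <- overlap_significance(inter$venn$sets,
                                  universe = nrow(matched$matched),
                                  n_perm = config$n_perm, seed = config$seed)

  final_df <- matched$matched[matched$matched$match_id %in% inter$final, ,
                              drop = FALSE]
  classification <- if (!is.null(annots)) classify_all(final_df, annots) else NULL

  # RPM distribution comparisons among wash conditions, above-cut-off clusters
  tests <- list()
  above_rpm <- lapply(wash, function(cond) {
    t <- tables[[cond]]
    t$clusters$rpm[t$clusters$cluster_id %in% cutoffs[[cond]]$selected]
  })
  names(above_rpm) <- wash
  for (p in wash_pairs) {
    key <- paste0("wilcoxon_", p[1], "_vs_", p[2])
    tests[[key]] <- compare_rpm_distributions(above_rpm[[p[1]]], above_rpm[[p[2]]])
  }
  if (!is.null(classification) && nrow(final_df) >= 4L) {
    is_mi <- classification$classified$assigned_class == "miRNA"
    counts_final <- rowSums(as.matrix(
      final_df[, paste0("count_", wash), drop = FALSE]))
    if (sum(is_mi) >= 2L && sum(!is_mi) >= 2L)
      tests$ttest_mirna_vs_rest <-
        compare_means_ttest(counts_final[is_mi], counts_final[!is_mi])
  }

  rpm_mat <- as.matrix(matched$matched[, paste0("rpm_", conds), drop = FALSE])
  colnames(rpm_mat) <- conds
  pca <- if (nrow(rpm_mat) >= 2L && ncol(rpm_mat) >= 2L)
    pca_conditions(rpm_mat) else NULL

  report <- build_report(tables, cutoffs, inter,
                         classification = classification, tests = tests,
                         pca = pca, overlap = overlap,
                         config = config_for_report(config))
  report$filter_stats <- filter_stats
  report$matched <- matched
  report$classification <- classification

  if (!is.null(out_dir)) {
    utils::write.table(matched$matched,
                       file.path(out_dir, "matched_clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(classification))
      utils::write.table(classification$classified,
                         file.path(out_dir, "classified_final_set.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    write_report_json(report_for_json(report),
                      file.path(out_dir, "report.json"))
  }
  report
}

config_for_report <- function(config) {
  keep <- setdiff(names(config), c("conditions"))
  c(list(conditions = as.list(config$conditions)),
    lapply(config[keep], function(x) if (is.null(x)) NA else x))
}

report_for_json <- function(report) {
  r <- unclass(report)
  r$matched <- NULL  # full matched table lives in matched_clusters.tsv
  r$final_set <- as.list(r$final_set)
  r
}
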