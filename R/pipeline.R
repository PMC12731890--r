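#' Pipeline configuration
#'
#' Collects every input and parameter of [run_full_pipeline()]. Inputs may
#' be given as file paths (read with the package's readers) or as
#' in-memory objects; each platform carries the samples of one cell group.
#'
#' @param platform_a,platform_b [beta_dataset()] objects, or paths to
#'   Beta CSVs.
#' @param pval_a,pval_b Optional detection p-value paths (used only when
#'   the corresponding platform is given as a path).
#' @param sheet A [sample_sheet()] or path.
#' @param manifest A [probe_manifest()], a path, or `NULL` (skips
#'   annotation).
#' @param out_dir Output directory (created if needed).
#' @param group_a,group_b Cell-group labels; defaults are the sorted
#'   unique groups of the sheet.
#' @param policy A [cleaning_policy()].
#' @param intragroup_cutoffs,intergroup_cutoffs [marginal_cutoffs()] for
#'   the within-group (default stringent 0.1/0.9) and between-group
#'   (default relaxed 0.2/0.8) stages.
#' @param aggregate_first Classify replicate means instead of requiring
#'   every replicate to be marginal (see [stable_marginal_profile()]).
#' @param norm_check Also run the quantile-normalization comparison
#'   ([compare_with_without_normalization()]) and write its report.
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(platform_a, platform_b, sheet, out_dir,
                            pval_a = NULL, pval_b = NULL, manifest = NULL,
                            group_a = NULL, group_b = NULL,
                            policy = cleaning_policy(),
                            intragroup_cutoffs = cutoffs_stringent(),
                            intergroup_cutoffs = cutoffs_relaxed(),
                            aggregate_first = FALSE, norm_check = FALSE) {
  structure(list(platform_a = platform_a, platform_b = platform_b,
                 pval_a = pval_a, pval_b = pval_b, sheet = sheet,
                 manifest = manifest, out_dir = out_dir,
                 group_a = group_a, group_b = group_b, policy = policy,
                 intragroup_cutoffs = intragroup_cutoffs,
                 intergroup_cutoffs = intergroup_cutoffs,
                 aggregate_first = isTRUE(aggregate_first),
                 norm_check = isTRUE(norm_check)),
            class = "pipeline_config")
}

.load_input <- function(x, reader, pval = NULL, platform = "") {
  if (is.character(x)) {
    if (identical(reader, "beta")) read_beta_dataset(x, pval, platform = platform)
    else if (identical(reader, "sheet")) read_sample_sheet(x)
    else read_manifest(x)
  } else x
}

#' Run the full marker-discovery pipeline
#'
#' Executes the end-to-end flow: detection cleaning of both platforms,
#' platform intersection, within-group polar comparisons on each
#' platform's full probe set (stringent cutoffs), between-group marker
#' discovery on the shared probes (relaxed cutoffs), manifest annotation
#' and genomic-context summaries, and optionally the
#' quantile-normalization comparison. All outputs are CSV plus a
#' plain-text run manifest logging every parameter, input checksum and
#' per-stage locus count; the run is fully deterministic, so identical
#' inputs give byte-identical outputs. On any stage failure the stage name
#' is reported and partial outputs are removed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `markers` (annotated marker table),
#'   `intragroup` (per-group [intragroup_distinctive_loci()] results),
#'   `pairwise` (per-group count matrices), `overlap`
#'   ([marginal_overlap_summary()]), `annotation_summary`, `norm_check`
#'   (or `NULL`) and `files` (paths written).
#' @export
run_full_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  stage <- "setup"
  result <- tryCatch({
    stage <- "read_inputs"
    ds_a <- .load_input(config$platform_a, "beta", config$pval_a, "platform_a")
    ds_b <- .load_input(config$platform_b, "beta", config$pval_b, "platform_b")
    sheet <- sample_sheet(.load_input(config$sheet, "sheet"))
    manifest <- if (is.null(config$manifest)) NULL
      else probe_manifest(.load_input(config$manifest, "manifest"))
    groups <- sort(unique(sheet$cell_group))
    group_a <- if (is.null(config$group_a)) groups[1] else config$group_a
    group_b <- if (is.null(config$group_b)) groups[2] else config$group_b
    policy <- config$policy

    stage <- "clean"
    clean_a <- apply_detection_filter(ds_a, policy)
    clean_b <- apply_detection_filter(ds_b, policy)

    stage <- "intersect_platforms"
    shared <- intersect_platforms(probe_ids(ds_a), probe_ids(ds_b))

    stage <- "intragroup"
    intra <- list(); pairwise <- list()
    for (g in c(group_a, group_b)) {
      ds_g <- if (g == group_a) clean_a else clean_b
      prof <- group_profiles(ds_g, sheet, g, config$intragroup_cutoffs,
                             policy, config$aggregate_first)
      intra[[g]] <- intragroup_distinctive_loci(prof)
      pairwise[[g]] <- pairwise_polar_counts(prof)
      f <- file.path(config$out_dir, sprintf("intragroup_categories_%s.csv", g))
      utils::write.csv(data.frame(probe_id = intra[[g]]$loci,
                                  intra[[g]]$categories,
                                  check.names = FALSE), f, row.names = FALSE,
                       quote = FALSE)
      written <- c(written, f)
      f <- file.path(config$out_dir, sprintf("pairwise_polar_counts_%s.csv", g))
      utils::write.csv(data.frame(cell_type = rownames(pairwise[[g]]),
                                  pairwise[[g]], check.names = FALSE), f,
                       row.names = FALSE, quote = FALSE)
      written <- c(written, f)
    }

    stage <- "intergroup"
    joint <- combine_platforms(clean_a, clean_b)
    prof_a <- group_profiles(joint, sheet, group_a, config$intergroup_cutoffs,
                             policy, config$aggregate_first)
    prof_b <- group_profiles(joint, sheet, group_b, config$intergroup_cutoffs,
                             policy, config$aggregate_first)
    means <- mean_beta_by_cell_type(joint, sheet, policy)
    markers <- intergroup_markers(prof_a, prof_b, mean_beta = means,
                                  group_labels = c(group_a, group_b))
    overlap <- marginal_overlap_summary(prof_a, prof_b,
                                        group_labels = c(group_a, group_b))
    f <- file.path(config$out_dir, "overlap_summary.csv")
    utils::write.csv(data.frame(
      group = c(group_a, group_b, "shared"),
      n_low = c(overlap[[group_a]]$n_low, overlap[[group_b]]$n_low,
                overlap$overlap$n_low),
      n_high = c(overlap[[group_a]]$n_high, overlap[[group_b]]$n_high,
                 overlap$overlap$n_high),
      n_marginal = c(overlap[[group_a]]$n_marginal,
                     overlap[[group_b]]$n_marginal, NA)),
      f, row.names = FALSE, quote = FALSE)
    written <- c(written, f)

    stage <- "annotate"
    summary_df <- NULL
    if (!is.null(manifest)) {
      markers <- annotate_markers(markers, manifest)
      summary_df <- summarize_annotations(markers)
      f <- file.path(config$out_dir, "annotation_summary.csv")
      utils::write.csv(summary_df, f, row.names = FALSE, quote = FALSE)
      written <- c(written, f)
    }
    f <- file.path(config$out_dir, "markers.csv")
    write_marker_table(markers, f)
    written <- c(written, f)

    stage <- "norm_check"
    norm <- NULL
    if (config$norm_check) {
      norm <- compare_with_without_normalization(
        ds_a, ds_b, sheet, config$intergroup_cutoffs, policy,
        group_a = group_a, group_b = group_b)
      all_loci <- sort(union(norm$raw, norm$normalized))
      f <- file.path(config$out_dir, "norm_check.csv")
      utils::write.csv(data.frame(probe_id = all_loci,
                                  in_raw = all_loci %in% norm$raw,
                                  in_normalized = all_loci %in% norm$normalized),
                       f, row.names = FALSE, quote = FALSE)
      written <- c(written, f)
    }

    stage <- "run_manifest"
    f <- file.path(config$out_dir, "run_manifest.txt")
    .write_run_manifest(f, config, ds_a, ds_b, sheet, shared, intra, markers,
                        group_a, group_b)
    written <- c(written, f)

    list(markers = markers, intragroup = intra, pairwise = pairwise,
         overlap = overlap, annotation_summary = summary_df,
         norm_check = norm, files = written)
  }, error = function(e) {
    unlink(written)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}

.write_run_manifest <- function(path, config, ds_a, ds_b, sheet, shared,
                                intra, markers, group_a, group_b) {
  checksum <- function(x) {
    if (is.character(x) && length(x) == 1 && file.exists(x))
      unname(tools::md5sum(x)) else "in-memory"
  }
  lines <- c(
    "polarmeth run manifest",
    sprintf("group_a: %s", group_a),
    sprintf("group_b: %s", group_b),
    sprintf("p_threshold: %g", config$policy$p_threshold),
    sprintf("min_passing_replicates: %d", config$policy$min_passing_replicates),
    sprintf("intragroup_cutoffs: %g/%g", config$intragroup_cutoffs$low,
            config$intragroup_cutoffs$high),
    sprintf("intergroup_cutoffs: %g/%g", config$intergroup_cutoffs$low,
            config$intergroup_cutoffs$high),
    sprintf("aggregate_first: %s", config$aggregate_first),
    sprintf("norm_check: %s", config$norm_check),
    sprintf("input_platform_a: %s", checksum(config$platform_a)),
    sprintf("input_platform_b: %s", checksum(config$platform_b)),
    sprintf("input_sheet: %s", checksum(config$sheet)),
    sprintf("input_manifest: %s",
            if (is.null(config$manifest)) "none" else checksum(config$manifest)),
    sprintf("n_loci_platform_a: %d", nrow(ds_a$beta)),
    sprintf("n_loci_platform_b: %d", nrow(ds_b$beta)),
    sprintf("n_samples: %d", ncol(ds_a$beta) + ncol(ds_b$beta)),
    sprintf("n_shared_loci: %d", length(shared)),
    sprintf("n_intragroup_%s: %d", group_a, length(intra[[group_a]]$loci)),
    sprintf("n_intragroup_%s: %d", group_b, length(intra[[group_b]]$loci)),
    sprintf("n_intergroup_markers: %d", nrow(markers)))
  writeLines(lines, path)
}
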