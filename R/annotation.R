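#' Attach manifest annotations to a marker table
#'
#' Joins each marker row to its [probe_manifest()] record (gene/element
#' pairs, island relation, enhancer flag, coordinates). Markers absent
#' from the manifest keep `NA` annotations and are flagged
#' `annotated = FALSE` with a warning. Reapplication is idempotent: any
#' existing annotation columns are replaced.
#'
#' @param markers A `marker_table` data.frame (see [intergroup_markers()]).
#' @param manifest A [probe_manifest()].
#' @return The marker table with columns `gene_elements`,
#'   `island_relation`, `enhancer`, `chromosome`, `position`, `annotated`.
#' @export
annotate_markers <- function(markers, manifest) {
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  manifest <- probe_manifest(manifest)
  ann_cols <- c("gene_elements", "island_relation", "enhancer",
                "chromosome", "position", "annotated")
  markers <- markers[, setdiff(names(markers), ann_cols), drop = FALSE]
  idx <- match(markers$probe_id, manifest$probe_id)
  markers$gene_elements <- manifest$gene_elements[idx]
  markers$island_relation <- manifest$island_relation[idx]
  markers$enhancer <- manifest$enhancer[idx]
  markers$chromosome <- manifest$chromosome[idx]
  markers$position <- manifest$position[idx]
  markers$annotated <- !is.na(idx)
  if (any(!markers$annotated))
    warning(sum(!markers$annotated),
            " marker(s) absent from manifest, left unannotated")
  class(markers) <- c("marker_table", "data.frame")
  markers
}

.has_element <- function(gene_elements, wanted) {
  vapply(gene_elements, function(s) {
    if (is.na(s) || !nzchar(s)) return(FALSE)
    any(parse_gene_elements(s)$element %in% wanted)
  }, logical(1), USE.NAMES = FALSE)
}

#' Genomic-context summary of annotated markers
#'
#' Per direction (or overall): the number of markers and how many have any
#' promoter annotation (`TSS200` or `TSS1500` on any associated gene), a
#' gene-body annotation with no promoter annotation (`body_only`), lie in
#' a CpG island, a shore (N or S), a shelf (N or S), or an enhancer; each
#' count also as a fraction of the direction's markers. A marker counts at
#' most once per category regardless of how many genes annotate it.
#'
#' @param markers An [annotate_markers()] result.
#' @param by_direction Summarize per direction (default) or as a single
#'   `"all"` row.
#' @return data.frame with one row per direction and columns `direction`,
#'   `n_markers`, `n_tss`, `n_body_only`, `n_island`, `n_shore`,
#'   `n_shelf`, `n_enhancer` plus matching `frac_*` columns.
#' @export
summarize_annotations <- function(markers, by_direction = TRUE) {
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  req <- c("probe_id", "direction", "gene_elements", "island_relation", "enhancer")
  if (!all(req %in% names(markers)))
    stop("markers must be annotated first (see annotate_markers)")
  groups <- if (by_direction && nrow(markers) > 0)
    sort(unique(markers$direction)) else "all"
  rows <- lapply(groups, function(d) {
    m <- if (identical(d, "all")) markers else markers[markers$direction == d, ]
    tss <- .has_element(m$gene_elements, c("TSS200", "TSS1500"))
    body <- .has_element(m$gene_elements, "Body")
    n <- nrow(m)
    counts <- c(
      n_tss = sum(tss),
      n_body_only = sum(body & !tss),
      n_island = sum(m$island_relation == "Island", na.rm = TRUE),
      n_shore = sum(m$island_relation %in% c("N_Shore", "S_Shore"), na.rm = TRUE),
      n_shelf = sum(m$island_relation %in% c("N_Shelf", "S_Shelf"), na.rm = TRUE),
      n_enhancer = sum(m$enhancer, na.rm = TRUE))
    fr <- if (n > 0) counts / n else rep(NA_real_, length(counts))
    names(fr) <- sub("^n_", "frac_", names(counts))
    cbind(data.frame(direction = d, n_markers = n, stringsAsFactors = FALSE),
          as.data.frame(as.list(counts)), as.data.frame(as.list(fr)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Packaged endothelial/leukocyte marker panel
#'
#' A curated 47-locus CpG panel that separates endothelial from leukocyte
#' DNA on Illumina methylation arrays: 34 loci stably methylated in
#' endothelial cells (`EC_HIGH`, i.e. demethylated in leukocytes) and 13
#' stably methylated in leukocytes (`LC_HIGH`), with per-probe gene and
#' genomic-element annotations, CpG island relation and enhancer flags.
#' Chromosome and position are not part of the panel and are `NA`. Ships
#' as reference/test data for the annotation summaries.
#'
#' @return A `marker_table` data.frame with 47 rows.
#' @export
ec_lc_marker_panel <- function() {
  path <- system.file("extdata", "ec_lc_marker_panel.csv",
                      package = "polarmeth", mustWork = TRUE)
  read_marker_table(path)
}
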