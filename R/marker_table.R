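#' Write a marker table CSV
#'
#' Serializes a [intergroup_markers()] result (optionally annotated by
#' [annotate_markers()]) with a deterministic column order (`probe_id`,
#' `direction`, mean-Beta columns, annotation columns) and rows sorted by
#' direction then probe ID, so repeated writes are byte-identical.
#'
#' @param markers A `marker_table` data.frame (empty allowed).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_marker_table <- function(markers, path) {
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  if (nrow(markers) > 0)
    markers <- markers[order(markers$direction, markers$probe_id), , drop = FALSE]
  lead <- c("probe_id", "direction")
  means <- sort(grep("^mean_", names(markers), value = TRUE))
  rest <- setdiff(names(markers), c(lead, means))
  ann <- intersect(c("gene_elements", "island_relation", "enhancer",
                     "chromosome", "position", "annotated"), rest)
  other <- setdiff(rest, ann)
  markers <- markers[, c(lead, means, ann, other), drop = FALSE]
  utils::write.csv(markers, path, row.names = FALSE, na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a marker table CSV
#'
#' @param path A file written by [write_marker_table()].
#' @return A data.frame of class `"marker_table"`.
#' @export
read_marker_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  out <- .read_table_auto(path)
  if (!all(c("probe_id", "direction") %in% names(out)))
    stop("marker table must have probe_id and direction columns")
  out$probe_id <- as.character(out$probe_id)
  out$direction <- as.character(out$direction)
  if ("enhancer" %in% names(out))
    out$enhancer <- .as_logical_strict(out$enhancer, "enhancer")
  if ("annotated" %in% names(out))
    out$annotated <- .as_logical_strict(out$annotated, "annotated")
  class(out) <- c("marker_table", "data.frame")
  out
}

#' @export
print.marker_table <- function(x, ...) {
  cat(sprintf("marker_table: %d loci\n", nrow(x)))
  if (nrow(x) > 0) {
    tab <- table(x$direction)
    for (d in names(tab)) cat(sprintf("  %s: %d\n", d, tab[[d]]))
  }
  NextMethod()
}
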