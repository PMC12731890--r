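#' Validate a sample sheet
#'
#' A sample sheet maps each sample column of a Beta dataset to a cell type
#' (e.g. HUVEC, neutrophils) and a cell group (e.g. ECs, LCs). Sample IDs
#' must be unique and every cell type must belong to exactly one group.
#'
#' @param sheet A data.frame with character columns `sample_id`,
#'   `cell_type`, `cell_group`.
#' @return The validated data.frame (class `"sample_sheet"` prepended).
#' @export
sample_sheet <- function(sheet) {
  req <- c("sample_id", "cell_type", "cell_group")
  if (!all(req %in% names(sheet)))
    stop("sample sheet must have columns: ", paste(req, collapse = ", "))
  sheet <- as.data.frame(sheet, stringsAsFactors = FALSE)
  for (col in req) sheet[[col]] <- as.character(sheet[[col]])
  if (anyDuplicated(sheet$sample_id))
    stop("duplicated sample_id in sample sheet: ",
         paste(unique(sheet$sample_id[duplicated(sheet$sample_id)]),
               collapse = ", "))
  bygroup <- unique(sheet[, c("cell_type", "cell_group")])
  dup <- bygroup$cell_type[duplicated(bygroup$cell_type)]
  if (length(dup) > 0)
    stop("cell type mapped to more than one cell group: ",
         paste(unique(dup), collapse = ", "))
  class(sheet) <- c("sample_sheet", "data.frame")
  sheet
}

#' Read a sample sheet CSV
#'
#' @param path CSV with columns `sample_id`, `cell_type`, `cell_group`.
#' @return A validated [sample_sheet()].
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sample_sheet(.read_table_auto(path))
}

#' Write a sample sheet CSV
#' @param sheet A [sample_sheet()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(as.data.frame(sheet)[, c("sample_id", "cell_type", "cell_group")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# sample IDs of one cell type, in sheet order
.samples_of_type <- function(sheet, cell_type) {
  sheet$sample_id[sheet$cell_type == cell_type]
}

# sorted cell types of one group
.types_of_group <- function(sheet, group) {
  sort(unique(sheet$cell_type[sheet$cell_group == group]))
}
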