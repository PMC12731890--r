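#' Allowed genomic-element and island-relation vocabularies
#'
#' Genomic elements follow the Illumina UCSC RefGene grouping: `TSS200`
#' and `TSS1500` (within 200 / 1500 bp of a transcription start site),
#' `Body`, `5'UTR`, `3'UTR` and `1stExon`. Island relations: `Island`,
#' `N_Shore` / `S_Shore` (up to 2 kb up-/downstream of an island),
#' `N_Shelf` / `S_Shelf` (2-4 kb) and `OpenSea`.
#'
#' @return Character vector of allowed tokens.
#' @export
genomic_element_vocabulary <- function() {
  c("TSS200", "TSS1500", "Body", "5'UTR", "3'UTR", "1stExon")
}

#' @rdname genomic_element_vocabulary
#' @export
island_relation_vocabulary <- function() {
  c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf", "OpenSea")
}

#' Parse a gene-annotation string into (gene, element) pairs
#'
#' Manifest cells hold semicolon-delimited `GENE:Element` pairs, e.g.
#' `"PSMB8:TSS1500;TAP1:3'UTR"` for a probe annotated to two genes.
#'
#' @param s A single annotation string ("" or `NA` = no gene annotation).
#' @return data.frame with character columns `gene` and `element` (0 rows
#'   when unannotated).
#' @export
parse_gene_elements <- function(s) {
  if (length(s) != 1) stop("parse_gene_elements expects a single string")
  if (is.na(s) || !nzchar(trimws(s)))
    return(data.frame(gene = character(), element = character(),
                      stringsAsFactors = FALSE))
  parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts)]
  gene <- sub(":.*$", "", parts)
  element <- sub("^[^:]*:", "", parts)
  bad <- setdiff(element, genomic_element_vocabulary())
  if (length(bad) > 0)
    stop("unknown genomic element token(s): ",
         paste(unique(bad), collapse = ", "),
         "; allowed: ", paste(genomic_element_vocabulary(), collapse = ", "))
  data.frame(gene = gene, element = element, stringsAsFactors = FALSE)
}

#' Validate a probe manifest table
#'
#' One record per probe: `probe_id`, `gene_elements` (semicolon-delimited
#' `GENE:Element` pairs, possibly empty), `island_relation`, logical
#' `enhancer`, `chromosome` and 1-based `position` (both may be `NA`).
#'
#' @param manifest data.frame with the columns above.
#' @return The validated data.frame (class `"probe_manifest"` prepended).
#' @export
probe_manifest <- function(manifest) {
  req <- c("probe_id", "gene_elements", "island_relation", "enhancer")
  if (!all(req %in% names(manifest)))
    stop("manifest must have columns: ", paste(req, collapse = ", "))
  manifest <- as.data.frame(manifest, stringsAsFactors = FALSE)
  manifest$probe_id <- as.character(manifest$probe_id)
  if (anyDuplicated(manifest$probe_id))
    stop("duplicated probe_id in manifest: ",
         paste(unique(manifest$probe_id[duplicated(manifest$probe_id)]),
               collapse = ", "))
  manifest$gene_elements <- as.character(manifest$gene_elements)
  manifest$gene_elements[is.na(manifest$gene_elements)] <- ""
  for (s in manifest$gene_elements) parse_gene_elements(s)  # vocabulary check
  manifest$island_relation <- as.character(manifest$island_relation)
  bad <- setdiff(stats::na.omit(manifest$island_relation),
                 island_relation_vocabulary())
  if (length(bad) > 0)
    stop("unknown island relation token(s): ",
         paste(unique(bad), collapse = ", "),
         "; allowed: ", paste(island_relation_vocabulary(), collapse = ", "))
  manifest$enhancer <- .as_logical_strict(manifest$enhancer, "enhancer")
  if (!"chromosome" %in% names(manifest)) manifest$chromosome <- NA_character_
  if (!"position" %in% names(manifest)) manifest$position <- NA_integer_
  manifest$chromosome <- as.character(manifest$chromosome)
  manifest$position <- as.integer(manifest$position)
  class(manifest) <- c("probe_manifest", "data.frame")
  manifest
}

.as_logical_strict <- function(x, what) {
  if (is.logical(x)) return(x)
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no")] <- FALSE
  if (anyNA(out) && !all(is.na(x[is.na(out)])))
    stop("column '", what, "' is not interpretable as logical")
  out
}

#' Read a probe manifest CSV
#'
#' @param path CSV with columns `probe_id`, `gene_elements`,
#'   `island_relation`, `enhancer`, and optionally `chromosome`, `position`.
#' @return A validated [probe_manifest()].
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  probe_manifest(.read_table_auto(path))
}

#' Write a probe manifest CSV
#' @param manifest A [probe_manifest()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(manifest, path) {
  cols <- c("probe_id", "gene_elements", "island_relation", "enhancer",
            "chromosome", "position")
  utils::write.csv(as.data.frame(manifest)[, cols], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
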