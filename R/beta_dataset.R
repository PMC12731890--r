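#' Construct a Beta-value dataset
#'
#' Bundles a loci-by-samples matrix of methylation Beta values (the
#' proportion of methylated cytosines at a CpG locus in a DNA sample, in
#' \[0, 1\]) with a same-shaped matrix of per-measurement detection
#' p-values and a free-text platform tag.
#'
#' @param beta Numeric matrix, probes in rows (unique rownames = probe
#'   IDs), samples in columns (unique colnames = sample IDs). Values in
#'   \[0, 1\]; `NA` marks a missing measurement.
#' @param detection_p Numeric matrix with identical dimensions and
#'   dimnames, values in \[0, 1\]. When `NULL`, filled with 0 so that every
#'   measurement passes any detection filter.
#' @param platform Free-text platform label, e.g. `"450K-like"`.
#'
#' @return An object of class `"beta_dataset"`: a list with elements
#'   `beta`, `detection_p` and `platform`.
#' @export
#' @examples
#' b <- matrix(c(0.05, 0.95, 0.5, 0.9), 2, 2,
#'             dimnames = list(c("cg01", "cg02"), c("s1", "s2")))
#' beta_dataset(b, platform = "450K-like")
beta_dataset <- function(beta, detection_p = NULL, platform = "") {
  beta <- as.matrix(beta)
  storage.mode(beta) <- "double"
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    stop("beta matrix must carry probe rownames and sample colnames")
  if (anyDuplicated(rownames(beta)))
    stop("duplicated probe IDs: ",
         paste(unique(rownames(beta)[duplicated(rownames(beta))]), collapse = ", "))
  if (anyDuplicated(colnames(beta)))
    stop("duplicated sample IDs: ",
         paste(unique(colnames(beta)[duplicated(colnames(beta))]), collapse = ", "))
  bad <- which(!is.na(beta) & (beta < 0 | beta > 1), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf(
      "beta value out of [0,1]: probe '%s', sample '%s' (value %g)",
      rownames(beta)[bad[1, 1]], colnames(beta)[bad[1, 2]],
      beta[bad[1, 1], bad[1, 2]]))
  if (is.null(detection_p)) {
    detection_p <- matrix(0, nrow(beta), ncol(beta), dimnames = dimnames(beta))
  } else {
    detection_p <- as.matrix(detection_p)
    storage.mode(detection_p) <- "double"
    if (!identical(dim(detection_p), dim(beta)))
      stop(sprintf(
        "alignment error: beta is %d x %d but detection_p is %d x %d",
        nrow(beta), ncol(beta), nrow(detection_p), ncol(detection_p)))
    if (!identical(rownames(detection_p), rownames(beta)) ||
        !identical(colnames(detection_p), colnames(beta)))
      stop("alignment error: beta and detection_p row/column labels differ")
    badp <- which(!is.na(detection_p) & (detection_p < 0 | detection_p > 1),
                  arr.ind = TRUE)
    if (nrow(badp) > 0)
      stop(sprintf(
        "detection p-value out of [0,1]: probe '%s', sample '%s'",
        rownames(beta)[badp[1, 1]], colnames(beta)[badp[1, 2]]))
  }
  structure(list(beta = beta, detection_p = detection_p,
                 platform = as.character(platform)[1]),
            class = "beta_dataset")
}

#' @export
print.beta_dataset <- function(x, ...) {
  cat(sprintf("beta_dataset: %d loci x %d samples%s\n",
              nrow(x$beta), ncol(x$beta),
              if (nzchar(x$platform)) paste0(" [", x$platform, "]") else ""))
  cat(sprintf("  missing betas: %d (%.1f%%)\n", sum(is.na(x$beta)),
              100 * mean(is.na(x$beta))))
  invisible(x)
}

#' @export
dim.beta_dataset <- function(x) dim(x$beta)

#' Probe IDs of a Beta dataset
#' @param ds A [beta_dataset()].
#' @return Character vector of probe IDs, in matrix row order.
#' @export
probe_ids <- function(ds) rownames(ds$beta)

#' Restrict a Beta dataset to a set of loci
#'
#' @param ds A [beta_dataset()].
#' @param loci Character vector of probe IDs; every ID must be present.
#' @return A [beta_dataset()] containing exactly `loci`, in the given order.
#' @export
restrict_loci <- function(ds, loci) {
  missing <- setdiff(loci, rownames(ds$beta))
  if (length(missing) > 0)
    stop("loci absent from dataset: ",
         paste(utils::head(missing, 5), collapse = ", "))
  beta_dataset(ds$beta[loci, , drop = FALSE],
               ds$detection_p[loci, , drop = FALSE],
               platform = ds$platform)
}

#' Column-bind two Beta datasets over their shared loci
#'
#' Used to build the joint cross-platform matrix for intergroup analysis
#' and for the quantile-normalization comparison: both datasets are
#' restricted to the (sorted) intersection of their probe sets and their
#' sample columns concatenated.
#'
#' @param a,b [beta_dataset()] objects with disjoint sample IDs.
#' @return A [beta_dataset()] over the shared loci.
#' @export
combine_platforms <- function(a, b) {
  shared <- intersect_platforms(probe_ids(a), probe_ids(b))
  if (length(shared) == 0) stop("platforms share no loci")
  if (length(intersect(colnames(a$beta), colnames(b$beta))) > 0)
    stop("sample IDs overlap between platforms")
  beta_dataset(
    cbind(a$beta[shared, , drop = FALSE], b$beta[shared, , drop = FALSE]),
    cbind(a$detection_p[shared, , drop = FALSE],
          b$detection_p[shared, , drop = FALSE]),
    platform = paste(a$platform, b$platform, sep = "+"))
}

.read_table_auto <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    na.strings = c("", "NA"), check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "")
}

.table_to_matrix <- function(df, path) {
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicated probe IDs in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Read a Beta-value dataset from delimited files
#'
#' Reads a GEO series-matrix-like table (probes in rows, first column =
#' probe ID, remaining columns = one numeric column per sample, header row
#' of sample IDs) and, optionally, a matching detection p-value table.
#' Comma- and tab-separated files are both accepted; empty cells and the
#' string `"NA"` are treated as missing.
#'
#' @param beta_path Path to the Beta-value table.
#' @param pval_path Optional path to the detection p-value table; must have
#'   identical shape and identical probe/sample labels. When absent, all
#'   detection p-values are set to 0 (every measurement passes).
#' @param platform Platform tag stored on the result.
#' @return A [beta_dataset()].
#' @export
read_beta_dataset <- function(beta_path, pval_path = NULL, platform = "") {
  if (!file.exists(beta_path)) stop("no such file: ", beta_path)
  beta <- .table_to_matrix(.read_table_auto(beta_path), beta_path)
  detp <- NULL
  if (!is.null(pval_path)) {
    if (!file.exists(pval_path)) stop("no such file: ", pval_path)
    detp <- .table_to_matrix(.read_table_auto(pval_path), pval_path)
    if (!identical(dim(detp), dim(beta)))
      stop(sprintf(
        "alignment error: %s has %d rows x %d samples, %s has %d rows x %d samples",
        beta_path, nrow(beta), ncol(beta), pval_path, nrow(detp), ncol(detp)))
    if (!identical(rownames(detp), rownames(beta)) ||
        !identical(colnames(detp), colnames(beta)))
      stop("alignment error: probe/sample labels differ between ",
           beta_path, " and ", pval_path)
  }
  beta_dataset(beta, detp, platform = platform)
}

#' Write a Beta-value dataset to CSV
#'
#' Inverse of [read_beta_dataset()]: writes the Beta matrix (and the
#' detection p-value matrix when `pval_path` is given) with a `probe_id`
#' first column.
#'
#' @param ds A [beta_dataset()].
#' @param beta_path Output path for the Beta table.
#' @param pval_path Optional output path for the detection p-value table.
#' @return Invisibly, `beta_path`.
#' @export
write_beta_dataset <- function(ds, beta_path, pval_path = NULL) {
  .write_matrix_csv(ds$beta, beta_path)
  if (!is.null(pval_path)) .write_matrix_csv(ds$detection_p, pval_path)
  invisible(beta_path)
}

.write_matrix_csv <- function(m, path) {
  df <- data.frame(probe_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "NA", quote = FALSE)
}
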