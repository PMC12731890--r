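#' Detection-filter cleaning policy
#'
#' @param p_threshold Detection p-value significance level; a measurement
#'   is kept only when its detection p is strictly below this (default
#'   0.05, the conventional array QC level).
#' @param min_passing_replicates Minimum number of a cell type's
#'   replicates in which a locus must pass the filter to remain evaluable
#'   for that cell type (default 1: a locus dropped in some replicates is
#'   rescued by the remaining ones).
#' @return An object of class `"cleaning_policy"`.
#' @export
cleaning_policy <- function(p_threshold = 0.05, min_passing_replicates = 1L) {
  if (!is.numeric(p_threshold) || length(p_threshold) != 1 ||
      p_threshold <= 0 || p_threshold > 1)
    stop("p_threshold must be in (0, 1]")
  min_passing_replicates <- as.integer(min_passing_replicates)
  if (is.na(min_passing_replicates) || min_passing_replicates < 1)
    stop("min_passing_replicates must be >= 1")
  structure(list(p_threshold = p_threshold,
                 min_passing_replicates = min_passing_replicates),
            class = "cleaning_policy")
}

#' Mask unreliable measurements by detection p-value
#'
#' Every Beta value whose paired detection p-value is not strictly below
#' `policy$p_threshold` (or is missing) is set to `NA`. The matrix shape
#' is unchanged and the operation is idempotent.
#'
#' @param ds A [beta_dataset()].
#' @param policy A [cleaning_policy()].
#' @return A [beta_dataset()] with failing measurements masked.
#' @export
apply_detection_filter <- function(ds, policy = cleaning_policy()) {
  fail <- !(ds$detection_p < policy$p_threshold)
  fail[is.na(fail)] <- TRUE
  beta <- ds$beta
  beta[fail] <- NA_real_
  beta_dataset(beta, ds$detection_p, platform = ds$platform)
}

#' Intersect two platforms' locus sets
#'
#' Harmonizes probe sets across array versions (e.g. a 450K-like and a
#' 27K-like platform) by exact set intersection.
#'
#' @param a,b Character vectors of probe IDs.
#' @return Sorted character vector, the intersection.
#' @export
intersect_platforms <- function(a, b) {
  sort(intersect(as.character(a), as.character(b)))
}

#' Per-cell-type mean Beta values
#'
#' Detection-filters the dataset, then averages each cell type's surviving
#' replicate values per locus. A mean is reported only where at least
#' `policy$min_passing_replicates` replicate values remain.
#'
#' @param ds A [beta_dataset()].
#' @param sheet A [sample_sheet()] covering every sample of `ds`.
#' @param policy A [cleaning_policy()].
#' @return Numeric matrix, loci x cell types (cell types sorted), `NA`
#'   where too few replicates pass.
#' @export
mean_beta_by_cell_type <- function(ds, sheet, policy = cleaning_policy()) {
  sheet <- sample_sheet(sheet)
  absent <- setdiff(colnames(ds$beta), sheet$sample_id)
  if (length(absent) > 0)
    stop("samples absent from sample sheet: ", paste(absent, collapse = ", "))
  clean <- apply_detection_filter(ds, policy)
  types <- sort(unique(sheet$cell_type[sheet$sample_id %in% colnames(ds$beta)]))
  out <- matrix(NA_real_, nrow(ds$beta), length(types),
                dimnames = list(rownames(ds$beta), types))
  for (ct in types) {
    cols <- intersect(.samples_of_type(sheet, ct), colnames(ds$beta))
    b <- clean$beta[, cols, drop = FALSE]
    n <- rowSums(!is.na(b))
    m <- rowMeans(b, na.rm = TRUE)
    m[n < policy$min_passing_replicates] <- NA_real_
    out[, ct] <- m
  }
  out
}
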