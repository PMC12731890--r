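#' Quantile-normalize a Beta dataset
#'
#' Forces every sample column onto the same empirical distribution: the
#' reference is the per-rank mean of the sorted columns, each value is
#' replaced by the reference value at its within-column quantile position,
#' and tied values receive the mean of the reference values at their tied
#' ranks. Missing values stay missing; columns with unequal numbers of
#' non-missing values are matched by linear interpolation of quantile
#' positions. Within-column rank order is preserved and the map is
#' idempotent.
#'
#' @param ds A [beta_dataset()] with at least 2 samples.
#' @return A [beta_dataset()] with normalized Beta values (detection
#'   p-values carried through unchanged).
#' @export
quantile_normalize <- function(ds) {
  x <- ds$beta
  if (ncol(x) < 2) stop("quantile normalization needs >= 2 samples")
  nobs <- colSums(!is.na(x))
  if (any(nobs == 0))
    stop("column with all-missing values: ",
         paste(colnames(x)[nobs == 0], collapse = ", "))
  nref <- max(nobs)
  grid <- seq(0, 1, length.out = nref)
  sorted <- matrix(vapply(seq_len(ncol(x)), function(j) {
    v <- unname(sort(x[, j]))
    if (length(v) == nref) v
    else if (length(v) == 1L) rep(v, nref)
    else stats::approx(seq(0, 1, length.out = length(v)), v, grid)$y
  }, numeric(nref)), nrow = nref)
  ref <- rowMeans(sorted)
  out <- x
  for (j in seq_len(ncol(x))) {
    ok <- !is.na(x[, j])
    n <- sum(ok)
    r <- rank(x[ok, j], ties.method = "average")
    pos <- if (n == 1L) 0.5 else (r - 1) / (n - 1)
    out[ok, j] <- if (nref == 1L) ref else stats::approx(grid, ref, pos)$y
  }
  beta_dataset(pmin(pmax(out, 0), 1), ds$detection_p, platform = ds$platform)
}

#' Compare marker discovery with and without quantile normalization
#'
#' Cross-platform batch-effect check: intergroup polar markers are
#' computed twice over the shared loci of two platforms' datasets — once
#' from the cleaned Beta values as measured, once after joint quantile
#' normalization of the platform-concatenated matrix — and the two locus
#' sets are reported side by side. No automatic choice is made between the
#' two; the comparison mirrors a manual batch-effect assessment in which
#' normalization typically expands the marker list.
#'
#' @param ds_a,ds_b [beta_dataset()] objects, one per platform; each
#'   platform carries the samples of one cell group.
#' @param sheet A [sample_sheet()] covering all samples, with exactly the
#'   two groups named in `group_a` / `group_b`.
#' @param cutoffs A [marginal_cutoffs()] pair (default relaxed, 0.2/0.8).
#' @param policy A [cleaning_policy()].
#' @param group_a,group_b Cell-group labels; defaults are the sorted
#'   unique groups of `sheet`.
#' @return List with sorted probe-ID vectors `raw` and `normalized`, plus
#'   `only_raw` and `only_normalized` set differences.
#' @export
compare_with_without_normalization <- function(ds_a, ds_b, sheet,
                                               cutoffs = marginal_cutoffs(0.2, 0.8),
                                               policy = cleaning_policy(),
                                               group_a = NULL, group_b = NULL) {
  sheet <- sample_sheet(sheet)
  groups <- sort(unique(sheet$cell_group))
  if (is.null(group_a)) group_a <- groups[1]
  if (is.null(group_b)) group_b <- groups[2]
  joint <- combine_platforms(ds_a, ds_b)
  marker_set <- function(ds) {
    pa <- group_profiles(ds, sheet, group_a, cutoffs, policy)
    pb <- group_profiles(ds, sheet, group_b, cutoffs, policy)
    intergroup_markers(pa, pb, group_labels = c(group_a, group_b))$probe_id
  }
  raw <- sort(marker_set(joint))
  normalized <- sort(marker_set(quantile_normalize(apply_detection_filter(joint, policy))))
  list(raw = raw, normalized = normalized,
       only_raw = setdiff(raw, normalized),
       only_normalized = setdiff(normalized, raw))
}
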