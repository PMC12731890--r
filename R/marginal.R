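#' Marginal Beta cutoffs
#'
#' The two boundaries defining the marginal (extreme) methylation
#' intervals: a Beta strictly below `low` is "marginally demethylated"
#' (LOW), strictly above `high` "marginally methylated" (HIGH). The
#' conventional relaxed pair is 0.2/0.8 (intergroup marker search) and the
#' stringent pair 0.1/0.9 (within-group comparisons).
#'
#' @param low Upper bound of the demethylated interval.
#' @param high Lower bound of the methylated interval.
#' @return An object of class `"marginal_cutoffs"`.
#' @export
marginal_cutoffs <- function(low = 0.2, high = 0.8) {
  if (!is.numeric(low) || !is.numeric(high) ||
      length(low) != 1 || length(high) != 1 ||
      !(0 < low && low < high && high < 1))
    stop("cutoffs must satisfy 0 < low < high < 1")
  structure(list(low = low, high = high), class = "marginal_cutoffs")
}

#' @rdname marginal_cutoffs
#' @export
cutoffs_stringent <- function() marginal_cutoffs(0.1, 0.9)

#' @rdname marginal_cutoffs
#' @export
cutoffs_relaxed <- function() marginal_cutoffs(0.2, 0.8)

.same_cutoffs <- function(a, b) {
  isTRUE(all.equal(c(a$low, a$high), c(b$low, b$high)))
}

#' Classify Beta values into marginal categories
#'
#' Strict inequalities on both sides: `LOW` when Beta < `low`, `HIGH` when
#' Beta > `high`, `INTERMEDIATE` otherwise (boundary values included),
#' `UNEVALUABLE` for missing values.
#'
#' @param beta Numeric vector (or matrix) of Beta values in \[0, 1\];
#'   `NA` allowed.
#' @param cutoffs A [marginal_cutoffs()].
#' @return Character vector (or matrix) of categories.
#' @export
classify_marginal <- function(beta, cutoffs = marginal_cutoffs()) {
  if (any(!is.na(beta) & (beta < 0 | beta > 1)))
    stop("beta value out of [0,1]")
  out <- ifelse(is.na(beta), "UNEVALUABLE",
                ifelse(beta < cutoffs$low, "LOW",
                       ifelse(beta > cutoffs$high, "HIGH", "INTERMEDIATE")))
  if (is.matrix(beta)) dim(out) <- dim(beta)
  if (is.matrix(beta)) dimnames(out) <- dimnames(beta)
  out
}

#' Stable marginal profile of one cell type
#'
#' Builds the cell type's stably demethylated (`low_set`) and stably
#' methylated (`high_set`) locus sets. A locus is evaluable for the cell
#' type when at least `policy$min_passing_replicates` replicates pass the
#' detection filter; it enters `low_set` when every passing replicate
#' value is strictly below `cutoffs$low` (analogously `high_set`). With
#' `aggregate_first = TRUE` the replicate mean, rather than each
#' replicate, is classified.
#'
#' @param ds A [beta_dataset()] (detection filtering is applied
#'   internally, so cleaned and raw datasets give identical results).
#' @param sheet A [sample_sheet()].
#' @param cell_type A cell type present in `sheet` with samples in `ds`.
#' @param cutoffs A [marginal_cutoffs()].
#' @param policy A [cleaning_policy()].
#' @param aggregate_first Classify the replicate-mean Beta instead of
#'   requiring every replicate to be marginal (default `FALSE`, the
#'   stricter per-replicate reading).
#' @return An object of class `"marginal_profile"`: list with `cell_type`,
#'   `cutoffs`, sorted `low_set`, `high_set` and `evaluable_set`, and
#'   `n_replicates`.
#' @export
stable_marginal_profile <- function(ds, sheet, cell_type,
                                    cutoffs = marginal_cutoffs(),
                                    policy = cleaning_policy(),
                                    aggregate_first = FALSE) {
  sheet <- sample_sheet(sheet)
  if (!cell_type %in% sheet$cell_type)
    stop("unknown cell type: ", cell_type)
  cols <- intersect(.samples_of_type(sheet, cell_type), colnames(ds$beta))
  if (length(cols) == 0)
    stop("cell type '", cell_type, "' has no samples in the dataset")
  b <- ds$beta[, cols, drop = FALSE]
  p <- ds$detection_p[, cols, drop = FALSE]
  fail <- !(p < policy$p_threshold)
  fail[is.na(fail)] <- TRUE
  b[fail] <- NA_real_
  npass <- rowSums(!is.na(b))
  evaluable <- npass >= policy$min_passing_replicates
  if (aggregate_first) {
    m <- rowMeans(b, na.rm = TRUE)
    low <- evaluable & !is.na(m) & m < cutoffs$low
    high <- evaluable & !is.na(m) & m > cutoffs$high
  } else {
    nlow <- rowSums(b < cutoffs$low, na.rm = TRUE)
    nhigh <- rowSums(b > cutoffs$high, na.rm = TRUE)
    low <- evaluable & nlow == npass
    high <- evaluable & nhigh == npass
  }
  ids <- rownames(ds$beta)
  structure(list(cell_type = cell_type, cutoffs = cutoffs,
                 low_set = sort(ids[low]), high_set = sort(ids[high]),
                 evaluable_set = sort(ids[evaluable]),
                 n_replicates = length(cols)),
            class = "marginal_profile")
}

#' @export
print.marginal_profile <- function(x, ...) {
  cat(sprintf(
    "marginal_profile '%s' (cutoffs %g/%g, %d replicates): %d LOW, %d HIGH, %d evaluable\n",
    x$cell_type, x$cutoffs$low, x$cutoffs$high, x$n_replicates,
    length(x$low_set), length(x$high_set), length(x$evaluable_set)))
  invisible(x)
}

#' Stable marginal profiles for every cell type of a group
#'
#' @inheritParams stable_marginal_profile
#' @param group A cell group present in `sheet`.
#' @return Named list of [stable_marginal_profile()] results, one per cell
#'   type of the group (sorted by cell type).
#' @export
group_profiles <- function(ds, sheet, group, cutoffs = marginal_cutoffs(),
                           policy = cleaning_policy(),
                           aggregate_first = FALSE) {
  sheet <- sample_sheet(sheet)
  types <- .types_of_group(sheet, group)
  if (length(types) == 0) stop("unknown or empty cell group: ", group)
  stats::setNames(lapply(types, function(ct)
    stable_marginal_profile(ds, sheet, ct, cutoffs, policy, aggregate_first)),
    types)
}

#' Polar marginal loci between two cell types
#'
#' A locus is polar marginal for a pair of cell types when it is stably
#' marginal in opposite directions: LOW in one type and HIGH in the other.
#'
#' @param profile_a,profile_b [stable_marginal_profile()] results built
#'   with identical cutoffs.
#' @return Sorted character vector:
#'   `(a.low v b.high) u (a.high v b.low)` where `v` is intersection and
#'   `u` union.
#' @export
polar_marginal_pair <- function(profile_a, profile_b) {
  if (!.same_cutoffs(profile_a$cutoffs, profile_b$cutoffs))
    stop(sprintf(
      "cutoff mismatch: profile '%s' uses %g/%g but profile '%s' uses %g/%g",
      profile_a$cell_type, profile_a$cutoffs$low, profile_a$cutoffs$high,
      profile_b$cell_type, profile_b$cutoffs$low, profile_b$cutoffs$high))
  sort(union(intersect(profile_a$low_set, profile_b$high_set),
             intersect(profile_a$high_set, profile_b$low_set)))
}

#' Pairwise polar-marginal counts within a group
#'
#' @param profiles List of [stable_marginal_profile()] results (>= 2),
#'   identical cutoffs.
#' @return Symmetric integer matrix (zero diagonal), rows/columns ordered
#'   by sorted cell type.
#' @export
pairwise_polar_counts <- function(profiles) {
  if (length(profiles) < 2) stop("need at least 2 profiles")
  types <- sort(vapply(profiles, `[[`, "", "cell_type"))
  profiles <- profiles[order(vapply(profiles, `[[`, "", "cell_type"))]
  k <- length(types)
  m <- matrix(0L, k, k, dimnames = list(types, types))
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    n <- length(polar_marginal_pair(profiles[[i]], profiles[[j]]))
    m[i, j] <- m[j, i] <- n
  }
  m
}

#' Intragroup distinctive loci
#'
#' Loci that are polar marginal for at least one pair of cell types within
#' a group; the remaining types may fall anywhere. Each selected locus is
#' annotated with every cell type's category (LOW / HIGH if in the type's
#' stable set, UNEVALUABLE if too few replicates pass, INTERMEDIATE
#' otherwise), ready for heatmap export.
#'
#' @param profiles List of [stable_marginal_profile()] results (>= 2),
#'   identical cutoffs.
#' @return List with sorted `loci` and a character `categories` matrix
#'   (loci x cell types).
#' @export
intragroup_distinctive_loci <- function(profiles) {
  if (length(profiles) < 2) stop("need at least 2 profiles")
  profiles <- profiles[order(vapply(profiles, `[[`, "", "cell_type"))]
  loci <- character()
  for (i in seq_len(length(profiles) - 1))
    for (j in seq(i + 1, length(profiles)))
      loci <- union(loci, polar_marginal_pair(profiles[[i]], profiles[[j]]))
  loci <- sort(loci)
  types <- vapply(profiles, `[[`, "", "cell_type")
  cats <- matrix("INTERMEDIATE", length(loci), length(types),
                 dimnames = list(loci, types))
  for (p in profiles) {
    cats[, p$cell_type][!loci %in% p$evaluable_set] <- "UNEVALUABLE"
    cats[, p$cell_type][loci %in% p$low_set] <- "LOW"
    cats[, p$cell_type][loci %in% p$high_set] <- "HIGH"
  }
  list(loci = loci, categories = cats)
}

# all-cell-type intersections of a group's stable sets
.group_stable_sets <- function(profiles) {
  list(low = sort(Reduce(intersect, lapply(profiles, `[[`, "low_set"))),
       high = sort(Reduce(intersect, lapply(profiles, `[[`, "high_set"))))
}

#' Intergroup polar marginal markers
#'
#' A marker is a locus marginal in the same direction for *every* cell
#' type of one group and in the opposite direction for every cell type of
#' the other: with `A_low` the intersection of all group-A `low_set`s
#' (similarly `A_high`, `B_low`, `B_high`), the markers are
#' `(A_high v B_low)` labeled `<A>_HIGH` plus `(A_low v B_high)` labeled
#' `<B>_HIGH`.
#'
#' @param profiles_a,profiles_b Non-empty lists of
#'   [stable_marginal_profile()] results, all with identical cutoffs.
#' @param mean_beta Optional loci x cell-type matrix (e.g. from
#'   [mean_beta_by_cell_type()]); when given, each marker row carries a
#'   `mean_<cell type>` column per cell type.
#' @param group_labels Length-2 character vector naming the groups; the
#'   direction labels are `paste0(group_labels, "_HIGH")`.
#' @return A data.frame of class `"marker_table"`: columns `probe_id`,
#'   `direction`, and optional mean-Beta columns; rows sorted by direction
#'   then probe ID.
#' @export
intergroup_markers <- function(profiles_a, profiles_b, mean_beta = NULL,
                               group_labels = c("GROUP_A", "GROUP_B")) {
  if (length(profiles_a) == 0 || length(profiles_b) == 0)
    stop("empty cell group: both groups need at least one profile")
  all_prof <- c(profiles_a, profiles_b)
  for (p in all_prof[-1])
    if (!.same_cutoffs(all_prof[[1]]$cutoffs, p$cutoffs))
      stop("cutoff mismatch across profiles")
  a <- .group_stable_sets(profiles_a)
  b <- .group_stable_sets(profiles_b)
  a_high <- intersect(a$high, b$low)
  b_high <- intersect(a$low, b$high)
  dir_a <- paste0(group_labels[1], "_HIGH")
  dir_b <- paste0(group_labels[2], "_HIGH")
  out <- data.frame(
    probe_id = c(sort(a_high), sort(b_high)),
    direction = c(rep(dir_a, length(a_high)), rep(dir_b, length(b_high))),
    stringsAsFactors = FALSE)
  out <- out[order(out$direction, out$probe_id), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(mean_beta) && nrow(out) > 0) {
    mb <- mean_beta[out$probe_id, , drop = FALSE]
    colnames(mb) <- paste0("mean_", colnames(mb))
    out <- cbind(out, as.data.frame(mb, stringsAsFactors = FALSE))
    rownames(out) <- NULL
  }
  class(out) <- c("marker_table", "data.frame")
  out
}

#' Marginal-set overlap summary between two groups
#'
#' For each group, the sizes of the all-cell-type stable LOW and HIGH sets
#' and of their union; across groups, the same-direction overlaps (the
#' usual Venn counts for comparing two groups' marginal methylomes).
#'
#' @param profiles_a,profiles_b Lists of [stable_marginal_profile()]
#'   results with identical cutoffs.
#' @param group_labels Length-2 character vector naming the groups.
#' @return List with per-group components (`n_low`, `n_high`,
#'   `n_marginal`) and `overlap` (`n_low`, `n_high` shared counts).
#' @export
marginal_overlap_summary <- function(profiles_a, profiles_b,
                                     group_labels = c("GROUP_A", "GROUP_B")) {
  a <- .group_stable_sets(profiles_a)
  b <- .group_stable_sets(profiles_b)
  per_group <- function(s) list(n_low = length(s$low), n_high = length(s$high),
                                n_marginal = length(union(s$low, s$high)))
  out <- list(per_group(a), per_group(b),
              overlap = list(n_low = length(intersect(a$low, b$low)),
                             n_high = length(intersect(a$high, b$high))))
  names(out)[1:2] <- group_labels
  out
}
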