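# shared fixtures and independent brute-force oracles

# small beta_dataset from a plain matrix, all detection p passing
bd <- function(m, detp = NULL, platform = "") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("cg%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  if (!is.null(detp)) dimnames(detp) <- dimnames(m)
  beta_dataset(m, detp, platform = platform)
}

# sample sheet for a named list group -> list(cell_type -> n replicates);
# sample ids follow <type>_rep<i>
make_sheet <- function(spec) {
  rows <- list()
  for (g in names(spec)) for (ct in names(spec[[g]])) {
    n <- spec[[g]][[ct]]
    rows[[paste(g, ct)]] <- data.frame(
      sample_id = sprintf("%s_rep%d", ct, seq_len(n)),
      cell_type = ct, cell_group = g, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  sample_sheet(out)
}

# random dataset + sheet with 2 groups: each (locus, cell type) gets an
# extreme-skewed base level shared by the type's replicates, plus replicate
# noise, occasional outlier replicates (to break stability) and detection
# failures — so stable sets, polar pairs and intergroup markers all occur
random_case <- function(n_loci = 100, seed = 1, p_fail = 0.1,
                        p_outlier = 0.05, types_per_group = 2:4,
                        reps_per_type = 2:4) {
  set.seed(seed)
  spec <- list(A = list(), B = list())
  for (g in names(spec)) {
    k <- sample(types_per_group, 1)
    for (i in seq_len(k))
      spec[[g]][[sprintf("%s_t%d", g, i)]] <- sample(reps_per_type, 1)
  }
  sheet <- make_sheet(spec)
  n_s <- nrow(sheet)
  types <- unique(sheet$cell_type)
  level <- matrix(sample(c(0.05, 0.5, 0.95), n_loci * length(types),
                         replace = TRUE, prob = c(0.4, 0.2, 0.4)),
                  n_loci, length(types), dimnames = list(NULL, types))
  base <- level[, sheet$cell_type, drop = FALSE]
  n <- n_loci * n_s
  vals <- pmin(pmax(base + rnorm(n, 0, 0.03), 0), 1)
  out <- runif(n) < p_outlier
  vals[out] <- runif(sum(out))
  beta <- matrix(vals, n_loci, n_s,
                 dimnames = list(sprintf("cg%05d", seq_len(n_loci)),
                                 sheet$sample_id))
  detp <- matrix(ifelse(runif(n) < p_fail, runif(n, 0.05, 1),
                        runif(n, 0, 0.05)),
                 n_loci, n_s, dimnames = dimnames(beta))
  list(ds = beta_dataset(beta, detp), sheet = sheet)
}

# --- independent oracles: direct per-locus, per-replicate scans ------------

# passing replicate values of one locus for one cell type
.oracle_vals <- function(ds, sheet, locus, cell_type, p_thr) {
  reps <- sheet$sample_id[sheet$cell_type == cell_type]
  out <- numeric()
  for (s in reps) {
    p <- ds$detection_p[locus, s]
    b <- ds$beta[locus, s]
    if (!is.na(p) && p < p_thr && !is.na(b)) out <- c(out, b)
  }
  out
}

oracle_profile <- function(ds, sheet, cell_type, low, high,
                           p_thr = 0.05, min_pass = 1) {
  low_set <- character(); high_set <- character()
  for (locus in rownames(ds$beta)) {
    v <- .oracle_vals(ds, sheet, locus, cell_type, p_thr)
    if (length(v) < min_pass) next
    if (all(v < low)) low_set <- c(low_set, locus)
    if (all(v > high)) high_set <- c(high_set, locus)
  }
  list(low_set = sort(low_set), high_set = sort(high_set))
}

oracle_intergroup <- function(ds, sheet, group_a, group_b, low, high,
                              p_thr = 0.05, min_pass = 1) {
  types_a <- unique(sheet$cell_type[sheet$cell_group == group_a])
  types_b <- unique(sheet$cell_type[sheet$cell_group == group_b])
  side <- function(locus, ct, what) {
    v <- .oracle_vals(ds, sheet, locus, ct, p_thr)
    length(v) >= min_pass &&
      if (what == "low") all(v < low) else all(v > high)
  }
  out <- data.frame(probe_id = character(), direction = character(),
                    stringsAsFactors = FALSE)
  for (locus in rownames(ds$beta)) {
    a_high <- all(vapply(types_a, side, TRUE, locus = locus, what = "high"))
    b_low <- all(vapply(types_b, side, TRUE, locus = locus, what = "low"))
    a_low <- all(vapply(types_a, side, TRUE, locus = locus, what = "low"))
    b_high <- all(vapply(types_b, side, TRUE, locus = locus, what = "high"))
    if (a_high && b_low)
      out <- rbind(out, data.frame(probe_id = locus, direction = "A_HIGH"))
    if (a_low && b_high)
      out <- rbind(out, data.frame(probe_id = locus, direction = "B_HIGH"))
  }
  out[order(out$direction, out$probe_id), , drop = FALSE]
}

# sort-average-unsort quantile normalization oracle (complete matrices,
# equal column lengths, no ties)
oracle_quantile_normalize <- function(x) {
  s <- apply(x, 2, sort)
  ref <- rowMeans(s)
  out <- x
  for (j in seq_len(ncol(x))) out[order(x[, j]), j] <- ref
  out
}

# intergroup marker probe ids for a generated synthetic bundle
recovered_markers <- function(sim, cutoffs = cutoffs_relaxed(),
                              policy = cleaning_policy()) {
  joint <- combine_platforms(sim$platform_a, sim$platform_b)
  grp <- sort(unique(sim$sheet$cell_group))
  pa <- group_profiles(joint, sim$sheet, grp[1], cutoffs, policy)
  pb <- group_profiles(joint, sim$sheet, grp[2], cutoffs, policy)
  intergroup_markers(pa, pb, group_labels = grp)
}
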