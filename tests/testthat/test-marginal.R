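test_that("marginal classification uses strict inequalities on both sides", {
  cut <- cutoffs_stringent()
  expect_equal(classify_marginal(0.05, cut), "LOW")
  expect_equal(classify_marginal(0.90, cut), "INTERMEDIATE")  # boundary
  expect_equal(classify_marginal(0.10, cut), "INTERMEDIATE")  # boundary
  expect_equal(classify_marginal(0.95, cut), "HIGH")
  expect_equal(classify_marginal(NA, cut), "UNEVALUABLE")
  expect_equal(classify_marginal(c(0, 1), cut), c("LOW", "HIGH"))
  expect_error(classify_marginal(1.7, cut), "out of")
  expect_error(marginal_cutoffs(0.9, 0.1), "0 < low < high < 1")
})

test_that("stable sets require every passing replicate to be marginal", {
  sheet <- make_sheet(list(G = list(t1 = 3, t2 = 2)))
  m <- matrix(c(0.03, 0.06, 0.09, 0.50, 0.50,
                0.03, 0.15, 0.05, 0.50, 0.50,
                0.95, 0.99, 0.91, 0.50, 0.50), 3, 5, byrow = TRUE,
              dimnames = list(c("cgA", "cgB", "cgC"), sheet$sample_id))
  prof <- stable_marginal_profile(bd(m), sheet, "t1", cutoffs_stringent())
  expect_equal(prof$low_set, "cgA")          # all replicates LOW
  expect_false("cgB" %in% prof$low_set)      # one replicate INTERMEDIATE
  expect_equal(prof$high_set, "cgC")
  expect_error(stable_marginal_profile(bd(m), sheet, "t9"), "unknown cell type")

  # p-filtered replicates are skipped, not stability-breaking
  p <- matrix(0, 3, 5, dimnames = dimnames(m))
  p["cgB", 2] <- 0.8                          # masks the 0.15 replicate
  prof2 <- stable_marginal_profile(beta_dataset(m, p), sheet, "t1",
                                   cutoffs_stringent())
  expect_true("cgB" %in% prof2$low_set)
  # ... unless too few replicates remain
  p["cgB", c(1, 3)] <- 0.8
  prof3 <- stable_marginal_profile(beta_dataset(m, p), sheet, "t1",
                                   cutoffs_stringent(),
                                   cleaning_policy(min_passing_replicates = 2))
  expect_false("cgB" %in% prof3$low_set)
  expect_false("cgB" %in% prof3$evaluable_set)
})

test_that("aggregate-first mode classifies the replicate mean instead", {
  sheet <- make_sheet(list(G = list(t1 = 2)))
  m <- matrix(c(0.05, 0.25), 1, 2, dimnames = list("cg1", sheet$sample_id))
  strict <- stable_marginal_profile(bd(m), sheet, "t1", cutoffs_relaxed())
  agg <- stable_marginal_profile(bd(m), sheet, "t1", cutoffs_relaxed(),
                                 aggregate_first = TRUE)
  expect_false("cg1" %in% strict$low_set)  # one replicate not marginal
  expect_true("cg1" %in% agg$low_set)      # mean 0.15 < 0.2
})

test_that("stable profiles match a brute-force per-locus scan", {
  for (seed in 1:8) {
    case <- random_case(n_loci = 200, seed = seed)
    types <- unique(case$sheet$cell_type)
    for (ct in types[1:2]) {
      prof <- stable_marginal_profile(case$ds, case$sheet, ct,
                                      cutoffs_relaxed())
      orc <- oracle_profile(case$ds, case$sheet, ct, 0.2, 0.8)
      expect_equal(prof$low_set, orc$low_set)
      expect_equal(prof$high_set, orc$high_set)
    }
  }
})

test_that("polar pairs are opposite-direction intersections, symmetric", {
  mkprof <- function(ct, low, high) structure(
    list(cell_type = ct, cutoffs = cutoffs_stringent(), low_set = low,
         high_set = high, evaluable_set = union(low, high),
         n_replicates = 3L), class = "marginal_profile")
  a <- mkprof("a", low = "cg1", high = character())
  b <- mkprof("b", low = character(), high = "cg1")
  expect_equal(polar_marginal_pair(a, b), "cg1")
  b2 <- mkprof("b", low = "cg1", high = character())
  expect_equal(polar_marginal_pair(a, b2), character(0))  # same direction
  # cutoff mismatch is a labeled error
  c2 <- mkprof("c", low = "cg1", high = character())
  c2$cutoffs <- cutoffs_relaxed()
  expect_error(polar_marginal_pair(a, c2), "cutoff mismatch")
  # symmetry on random profiles
  set.seed(9)
  ids <- sprintf("cg%02d", 1:40)
  for (i in 1:10) {
    p1 <- mkprof("x", sample(ids, 10), sample(setdiff(ids, ids[1:20]), 5))
    p2 <- mkprof("y", sample(ids, 10), sample(setdiff(ids, ids[1:20]), 5))
    expect_equal(polar_marginal_pair(p1, p2), polar_marginal_pair(p2, p1))
  }
})

test_that("pairwise polar counts form a symmetric zero-diagonal matrix", {
  sheet <- make_sheet(list(G = list(t1 = 2, t2 = 2)))
  m <- matrix(c(0.02, 0.03, 0.97, 0.96), 1, 4,
              dimnames = list("cg1", sheet$sample_id))
  prof <- group_profiles(bd(m), sheet, "G", cutoffs_stringent())
  expect_equal(unname(pairwise_polar_counts(prof)),
               matrix(c(0L, 1L, 1L, 0L), 2, 2))
  # identical profiles are never polar against each other
  m2 <- matrix(c(0.02, 0.03, 0.02, 0.03), 1, 4,
               dimnames = list("cg1", sheet$sample_id))
  prof2 <- group_profiles(bd(m2), sheet, "G", cutoffs_stringent())
  expect_true(all(pairwise_polar_counts(prof2) == 0))
})

test_that("intragroup distinctive loci report every cell type's category", {
  sheet <- make_sheet(list(G = list(t1 = 2, t2 = 2, t3 = 2)))
  m <- matrix(c(0.02, 0.04, 0.95, 0.97, 0.50, 0.50,   # cg7: t1/t2 polar
                0.50, 0.50, 0.50, 0.50, 0.50, 0.50),  # cg8: nothing
              2, 6, byrow = TRUE,
              dimnames = list(c("cg7", "cg8"), sheet$sample_id))
  prof <- group_profiles(bd(m), sheet, "G", cutoffs_stringent())
  res <- intragroup_distinctive_loci(prof)
  expect_equal(res$loci, "cg7")
  expect_equal(res$categories["cg7", ],
               c(t1 = "LOW", t2 = "HIGH", t3 = "INTERMEDIATE"))
  # no polar pair anywhere -> empty
  res2 <- intragroup_distinctive_loci(
    group_profiles(bd(m[2, , drop = FALSE]), sheet, "G", cutoffs_stringent()))
  expect_equal(res2$loci, character(0))
})

test_that("intergroup markers demand unanimity across every cell type", {
  sheet <- make_sheet(list(A = list(t1 = 2), B = list(u1 = 2)))
  m <- matrix(c(0.05, 0.08, 0.95, 0.92), 1, 4,
              dimnames = list("cg1", sheet$sample_id))
  pa <- group_profiles(bd(m), sheet, "A", cutoffs_relaxed())
  pb <- group_profiles(bd(m), sheet, "B", cutoffs_relaxed())
  mk <- intergroup_markers(pa, pb, group_labels = c("A", "B"))
  expect_equal(mk$probe_id, "cg1")
  expect_equal(mk$direction, "B_HIGH")
  expect_error(intergroup_markers(list(), pb), "empty cell group")

  # a locus INTERMEDIATE in one B type is excluded
  sheet2 <- make_sheet(list(A = list(t1 = 2), B = list(u1 = 1, u2 = 1)))
  m2 <- matrix(c(0.05, 0.08, 0.95, 0.50), 1, 4,
               dimnames = list("cg1", sheet2$sample_id))
  mk2 <- intergroup_markers(group_profiles(bd(m2), sheet2, "A", cutoffs_relaxed()),
                            group_profiles(bd(m2), sheet2, "B", cutoffs_relaxed()))
  expect_equal(nrow(mk2), 0L)
})

test_that("intergroup markers match the brute-force oracle on random data", {
  for (seed in 1:10) {
    case <- random_case(n_loci = 150, seed = 100 + seed)
    joint <- case$ds
    pa <- group_profiles(joint, case$sheet, "A", cutoffs_relaxed())
    pb <- group_profiles(joint, case$sheet, "B", cutoffs_relaxed())
    mk <- intergroup_markers(pa, pb, group_labels = c("A", "B"))
    orc <- oracle_intergroup(joint, case$sheet, "A", "B", 0.2, 0.8)
    expect_equal(mk$probe_id, orc$probe_id)
    expect_equal(mk$direction, orc$direction)
    # direction exclusivity
    expect_equal(anyDuplicated(mk$probe_id), 0L)
  }
})

test_that("marker mean Betas respect the cutoff intervals of their direction", {
  case <- random_case(n_loci = 300, seed = 77, p_fail = 0)
  pa <- group_profiles(case$ds, case$sheet, "A", cutoffs_relaxed())
  pb <- group_profiles(case$ds, case$sheet, "B", cutoffs_relaxed())
  means <- mean_beta_by_cell_type(case$ds, case$sheet)
  mk <- intergroup_markers(pa, pb, mean_beta = means,
                           group_labels = c("A", "B"))
  expect_gt(nrow(mk), 0)
  types_a <- unique(case$sheet$cell_type[case$sheet$cell_group == "A"])
  types_b <- unique(case$sheet$cell_type[case$sheet$cell_group == "B"])
  for (i in seq_len(nrow(mk))) {
    hi <- if (mk$direction[i] == "A_HIGH") types_a else types_b
    lo <- setdiff(c(types_a, types_b), hi)
    expect_true(all(mk[i, paste0("mean_", hi)] > 0.8))
    expect_true(all(mk[i, paste0("mean_", lo)] < 0.2))
  }
})

test_that("outputs are invariant to sample and cell-type enumeration order", {
  case <- random_case(n_loci = 120, seed = 55)
  perm_cols <- sample(colnames(case$ds$beta))
  ds_perm <- beta_dataset(case$ds$beta[, perm_cols],
                          case$ds$detection_p[, perm_cols])
  sheet_perm <- sample_sheet(case$sheet[sample(nrow(case$sheet)), ])
  for (ds2 in list(ds_perm)) {
    pa1 <- group_profiles(case$ds, case$sheet, "A", cutoffs_relaxed())
    pb1 <- group_profiles(case$ds, case$sheet, "B", cutoffs_relaxed())
    pa2 <- group_profiles(ds2, sheet_perm, "A", cutoffs_relaxed())
    pb2 <- group_profiles(ds2, sheet_perm, "B", cutoffs_relaxed())
    expect_identical(intergroup_markers(pa1, pb1), intergroup_markers(pa2, pb2))
    expect_identical(pairwise_polar_counts(pa1), pairwise_polar_counts(pa2))
    expect_identical(intragroup_distinctive_loci(pa1),
                     intragroup_distinctive_loci(pa2))
  }
})

test_that("stringent-cutoff sets are nested inside relaxed-cutoff sets", {
  for (seed in 1:5) {
    case <- random_case(n_loci = 150, seed = 200 + seed)
    for (ct in unique(case$sheet$cell_type)) {
      s <- stable_marginal_profile(case$ds, case$sheet, ct, cutoffs_stringent())
      r <- stable_marginal_profile(case$ds, case$sheet, ct, cutoffs_relaxed())
      expect_true(all(s$low_set %in% r$low_set))
      expect_true(all(s$high_set %in% r$high_set))
    }
    mk_s <- intergroup_markers(
      group_profiles(case$ds, case$sheet, "A", cutoffs_stringent()),
      group_profiles(case$ds, case$sheet, "B", cutoffs_stringent()))
    mk_r <- intergroup_markers(
      group_profiles(case$ds, case$sheet, "A", cutoffs_relaxed()),
      group_profiles(case$ds, case$sheet, "B", cutoffs_relaxed()))
    expect_true(all(mk_s$probe_id %in% mk_r$probe_id))
  }
})

test_that("overlap summaries count group sets and their intersections", {
  sheet <- make_sheet(list(A = list(t1 = 1), B = list(u1 = 1)))
  m <- matrix(c(0.05, 0.95,    # low in A, high in B
                0.04, 0.03,    # low in both
                0.96, 0.97),   # high in both
              3, 2, byrow = TRUE,
              dimnames = list(c("cg1", "cg2", "cg3"), sheet$sample_id))
  pa <- group_profiles(bd(m), sheet, "A", cutoffs_relaxed())
  pb <- group_profiles(bd(m), sheet, "B", cutoffs_relaxed())
  ov <- marginal_overlap_summary(pa, pb, group_labels = c("A", "B"))
  expect_equal(ov$A$n_low, 2L); expect_equal(ov$A$n_high, 1L)
  expect_equal(ov$B$n_low, 1L); expect_equal(ov$B$n_high, 2L)
  expect_equal(ov$overlap$n_low, 1L)   # cg2 shared LOW
  expect_equal(ov$overlap$n_high, 1L)  # cg3 shared HIGH
  expect_equal(ov$A$n_marginal, 3L)
})
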