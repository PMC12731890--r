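#' Design of a synthetic two-platform methylome
#'
#' Describes the study structure emulated by [generate_synthetic()]: a
#' large 450K-like platform carrying the first group's cell types and a
#' small 27K-like platform carrying the second group's, with a shared
#' probe subset; several cell types per group with 3-6 replicates each;
#' Beta-distributed measurement noise; planted intergroup markers and
#' intragroup polar pairs; background loci that are marginal in the same
#' direction in both groups (with a low:high imbalance of roughly 5:1, as
#' seen on real arrays); and detection-p dropout.
#'
#' @param n_loci_platform_a,n_loci_platform_b Probe counts of the two
#'   platforms.
#' @param n_shared_loci Number of probes present on both platforms;
#'   platform B = shared probes + private probes.
#' @param groups Named list, group -> character vector of cell types;
#'   exactly 2 groups; the first group's samples live on platform A, the
#'   second's on platform B.
#' @param replicates_per_type `NULL` (each type gets a uniform draw from
#'   3-6 replicates) or a single integer in \[3, 6\].
#' @param planted_intergroup Length-2 integer vector: number of planted
#'   intergroup markers HIGH in group A / HIGH in group B.
#' @param planted_intragroup Length-2 integer vector: number of planted
#'   within-group polar pairs for group A / group B.
#' @param dropout_rate Probability that a single measurement fails the
#'   detection filter.
#' @param noise_concentration Beta-distribution concentration (shape1 +
#'   shape2) of measurement noise around the intended mean; larger =
#'   tighter. The default 600 gives a replicate SD of about 0.009 at
#'   Beta = 0.05, typical technical precision at the extremes.
#' @param background_marginal_fraction Fraction of non-planted loci that
#'   are marginal (in the same direction for every cell type of a group).
#' @param background_low_fraction Of those, the fraction that are LOW
#'   (default 5/6, i.e. a 5:1 low:high imbalance).
#' @param background_shared_low_fraction,background_shared_high_fraction
#'   Fraction of a group's background LOW (resp. HIGH) loci that are
#'   marginal in the same direction in the *other* group too; the rest are
#'   marginal in one group only (INTERMEDIATE in the other). Defaults 0.9
#'   and 0.6 mirror the asymmetry seen on real arrays, where the two
#'   groups share most of their demethylated loci but fewer methylated
#'   ones.
#' @param seed Integer seed; the whole generation is reproducible from it.
#' @return An object of class `"synthetic_design"`.
#' @export
synthetic_design <- function(n_loci_platform_a = 5000L,
                             n_loci_platform_b = 1200L,
                             n_shared_loci = 1000L,
                             groups = list(
                               ECs = c("HUVEC", "HCMEC", "HPAEC", "HPMEC", "LSEC"),
                               LCs = c("Bcells", "CD4T", "CD8T", "panT",
                                       "NK_CD16pos", "NK_CD16neg", "panNK",
                                       "neutrophils", "granulocytes",
                                       "monocytes", "Tregs")),
                             replicates_per_type = NULL,
                             planted_intergroup = c(34L, 13L),
                             planted_intragroup = c(31L, 57L),
                             dropout_rate = 0.05,
                             noise_concentration = 600,
                             background_marginal_fraction = 0.70,
                             background_low_fraction = 5 / 6,
                             background_shared_low_fraction = 0.9,
                             background_shared_high_fraction = 0.6,
                             seed = 1L) {
  if (length(groups) != 2 || is.null(names(groups)))
    stop("groups must be a named list of exactly 2 groups")
  if (n_shared_loci > min(n_loci_platform_a, n_loci_platform_b))
    stop("n_shared_loci exceeds a platform's locus count")
  if (!is.null(replicates_per_type) &&
      (replicates_per_type < 3 || replicates_per_type > 6))
    stop("replicates_per_type must be in [3, 6]")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  n_planted <- sum(planted_intergroup)
  if (n_planted > n_shared_loci)
    stop("infeasible design: planted intergroup loci exceed shared loci")
  if (planted_intragroup[1] > n_loci_platform_a - n_shared_loci &&
      n_planted + sum(planted_intragroup) > n_shared_loci)
    stop("infeasible design: planted loci exceed available loci")
  if (any(vapply(groups, length, 0L) < 2))
    stop("each group needs at least 2 cell types")
  structure(list(
    n_loci_platform_a = as.integer(n_loci_platform_a),
    n_loci_platform_b = as.integer(n_loci_platform_b),
    n_shared_loci = as.integer(n_shared_loci),
    groups = groups,
    replicates_per_type = replicates_per_type,
    planted_intergroup = as.integer(planted_intergroup),
    planted_intragroup = as.integer(planted_intragroup),
    dropout_rate = dropout_rate,
    noise_concentration = noise_concentration,
    background_marginal_fraction = background_marginal_fraction,
    background_low_fraction = background_low_fraction,
    background_shared_low_fraction = background_shared_low_fraction,
    background_shared_high_fraction = background_shared_high_fraction,
    seed = as.integer(seed)), class = "synthetic_design")
}

# deterministic probe IDs: shared first, then A-private, then B-private
.design_loci <- function(design) {
  n_total <- design$n_loci_platform_a + design$n_loci_platform_b -
    design$n_shared_loci
  ids <- sprintf("cg%08d", seq_len(n_total))
  shared <- ids[seq_len(design$n_shared_loci)]
  a_priv <- setdiff(ids[seq_len(design$n_loci_platform_a)], shared)
  b_priv <- setdiff(ids, ids[seq_len(design$n_loci_platform_a)])
  list(all = ids, shared = shared,
       platform_a = c(shared, a_priv), platform_b = c(shared, b_priv))
}

.intended_means <- c(LOW = 0.05, INTERMEDIATE = 0.5, HIGH = 0.95)

#' Generate a synthetic two-platform Beta dataset with planted truth
#'
#' Draws Beta values from Beta distributions centered on the intended
#' category of each (locus, cell type) pair (LOW ~ 0.05, INTERMEDIATE
#' ~ 0.5, HIGH ~ 0.95, concentration `noise_concentration`), assigns
#' detection p-values (uniform on \[0, 0.05) for passing measurements,
#' uniform on \[0.05, 1\] for dropouts), and records the exact planted
#' truth in a ledger. Identical designs (including seed) give identical
#' output.
#'
#' @param design A [synthetic_design()].
#' @return List with elements `platform_a`, `platform_b` (each a
#'   [beta_dataset()]), `sheet` (a [sample_sheet()]), `manifest` (a
#'   [probe_manifest()]) and `ledger`. The ledger holds `intended` (loci x
#'   all-cell-types category matrix), `intergroup` (data.frame `probe_id`,
#'   `direction` with directions `<group>_HIGH`), and `intragroup`
#'   (data.frame `group`, `probe_id`, `type_low`, `type_high`).
#' @export
generate_synthetic <- function(design = synthetic_design()) {
  set.seed(design$seed)
  loci <- .design_loci(design)
  group_names <- names(design$groups)
  types_a <- design$groups[[1]]
  types_b <- design$groups[[2]]
  all_types <- c(types_a, types_b)

  # replicate structure and sample sheet
  nrep <- if (is.null(design$replicates_per_type))
    sample(3:6, length(all_types), replace = TRUE)
  else rep(as.integer(design$replicates_per_type), length(all_types))
  names(nrep) <- all_types
  sheet <- do.call(rbind, lapply(seq_along(all_types), function(i) {
    ct <- all_types[i]
    grp <- if (ct %in% types_a) group_names[1] else group_names[2]
    data.frame(sample_id = sprintf("%s_rep%d", ct, seq_len(nrep[i])),
               cell_type = ct, cell_group = grp, stringsAsFactors = FALSE)
  }))
  sheet <- sample_sheet(sheet)

  # intended category per (locus, cell type); default INTERMEDIATE
  intended <- matrix("INTERMEDIATE", length(loci$all), length(all_types),
                     dimnames = list(loci$all, all_types))

  # background marginal loci: every cell type of a group alike; a fraction
  # is shared by both groups, the rest marginal in one group only, chosen
  # so that shared/set-size equals the configured shared fraction
  n_bg <- round(design$background_marginal_fraction * length(loci$all))
  bg <- sample(loci$all, n_bg)
  bg_low <- bg[seq_len(round(design$background_low_fraction * length(bg)))]
  bg_high <- setdiff(bg, bg_low)
  assign_bg <- function(ids, category, shared_frac) {
    p_shared <- shared_frac / (2 - shared_frac)
    arm <- sample(c("both", "a", "b"), length(ids), replace = TRUE,
                  prob = c(p_shared, (1 - p_shared) / 2, (1 - p_shared) / 2))
    intended[ids[arm == "both"], ] <<- category
    intended[ids[arm == "a"], types_a] <<- category
    intended[ids[arm == "b"], types_b] <<- category
  }
  assign_bg(bg_low, "LOW", design$background_shared_low_fraction)
  assign_bg(bg_high, "HIGH", design$background_shared_high_fraction)

  # planted intergroup markers: polar between the groups, from shared loci
  n_ig <- sum(design$planted_intergroup)
  ig <- sample(loci$shared, n_ig)
  ig_a_high <- ig[seq_len(design$planted_intergroup[1])]
  ig_b_high <- setdiff(ig, ig_a_high)
  intended[ig_a_high, types_a] <- "HIGH"
  intended[ig_a_high, types_b] <- "LOW"
  intended[ig_b_high, types_a] <- "LOW"
  intended[ig_b_high, types_b] <- "HIGH"
  ledger_ig <- data.frame(
    probe_id = c(sort(ig_a_high), sort(ig_b_high)),
    direction = c(rep(paste0(group_names[1], "_HIGH"), length(ig_a_high)),
                  rep(paste0(group_names[2], "_HIGH"), length(ig_b_high))),
    stringsAsFactors = FALSE)

  # planted intragroup polar pairs: one LOW type, one HIGH type, the rest
  # of the group (and, for shared loci, the whole other group) INTERMEDIATE
  taken <- ig
  ledger_intra <- list()
  for (g in 1:2) {
    n_intra <- design$planted_intragroup[g]
    if (n_intra == 0) next
    platform_loci <- if (g == 1) loci$platform_a else loci$platform_b
    pool <- setdiff(platform_loci, taken)
    picks <- sample(pool, n_intra)
    taken <- c(taken, picks)
    g_types <- design$groups[[g]]
    pair_idx <- vapply(seq_len(n_intra), function(i)
      sample(length(g_types), 2), integer(2))
    intended[picks, ] <- "INTERMEDIATE"
    for (i in seq_len(n_intra)) {
      intended[picks[i], g_types[pair_idx[1, i]]] <- "LOW"
      intended[picks[i], g_types[pair_idx[2, i]]] <- "HIGH"
    }
    ledger_intra[[g]] <- data.frame(
      group = group_names[g], probe_id = picks,
      type_low = g_types[pair_idx[1, ]], type_high = g_types[pair_idx[2, ]],
      stringsAsFactors = FALSE)
  }
  ledger_intra <- do.call(rbind, ledger_intra)
  if (is.null(ledger_intra))
    ledger_intra <- data.frame(group = character(), probe_id = character(),
                               type_low = character(), type_high = character(),
                               stringsAsFactors = FALSE)
  ledger_intra <- ledger_intra[order(ledger_intra$group, ledger_intra$probe_id), ]
  rownames(ledger_intra) <- NULL

  draw_platform <- function(platform_loci, types, tag) {
    cols <- sheet$sample_id[sheet$cell_type %in% types]
    beta <- matrix(NA_real_, length(platform_loci), length(cols),
                   dimnames = list(platform_loci, cols))
    detp <- beta
    conc <- design$noise_concentration
    for (s in cols) {
      ct <- sheet$cell_type[sheet$sample_id == s]
      mu <- .intended_means[intended[platform_loci, ct]]
      beta[, s] <- stats::rbeta(length(mu), mu * conc, (1 - mu) * conc)
      fail <- stats::runif(length(mu)) < design$dropout_rate
      detp[, s] <- ifelse(fail, stats::runif(length(mu), 0.05, 1),
                          stats::runif(length(mu), 0, 0.05))
    }
    beta_dataset(beta, detp, platform = tag)
  }
  platform_a <- draw_platform(loci$platform_a, types_a, "450K-like")
  platform_b <- draw_platform(loci$platform_b, types_b, "27K-like")

  manifest <- make_manifest_for_design(design, planted = ledger_ig)

  list(platform_a = platform_a, platform_b = platform_b, sheet = sheet,
       manifest = manifest,
       ledger = list(intended = intended, intergroup = ledger_ig,
                     intragroup = ledger_intra))
}

#' Synthetic probe manifest for a design
#'
#' Assigns synthetic gene symbols and genomic elements (from the standard
#' element vocabulary), CpG-island relations and enhancer flags to every
#' locus of the design. Island membership is direction-dependent for
#' planted intergroup markers, echoing the island enrichment of
#' leukocyte-methylated versus endothelial-methylated marker panels.
#'
#' @param design A [synthetic_design()].
#' @param planted Optional data.frame (`probe_id`, `direction`) of planted
#'   intergroup markers, as in the generator ledger; when `NULL` the
#'   direction-dependent island probabilities are unused.
#' @param island_prob Named numeric vector with entries `a_high`,
#'   `b_high`, `background`: probability of an `Island` relation for loci
#'   planted HIGH in group A, HIGH in group B, and all other loci.
#' @param enhancer_prob Probability of the enhancer flag.
#' @param multi_gene_prob Probability that a probe is annotated to two
#'   genes.
#' @return A [probe_manifest()] covering every locus of the design.
#' @export
make_manifest_for_design <- function(design, planted = NULL,
                                     island_prob = c(a_high = 0.03,
                                                     b_high = 0.38,
                                                     background = 0.73),
                                     enhancer_prob = 0.03,
                                     multi_gene_prob = 0.05) {
  set.seed(design$seed + 131L)
  loci <- .design_loci(design)
  n <- length(loci$all)
  group_names <- names(design$groups)
  p_island <- rep(island_prob[["background"]], n)
  names(p_island) <- loci$all
  if (!is.null(planted)) {
    a_high <- planted$probe_id[planted$direction == paste0(group_names[1], "_HIGH")]
    b_high <- planted$probe_id[planted$direction == paste0(group_names[2], "_HIGH")]
    p_island[a_high] <- island_prob[["a_high"]]
    p_island[b_high] <- island_prob[["b_high"]]
  }
  is_island <- stats::runif(n) < p_island
  relation <- ifelse(is_island, "Island",
                     sample(c("N_Shore", "S_Shore", "N_Shelf", "S_Shelf",
                              "OpenSea"), n, replace = TRUE,
                            prob = c(0.1, 0.1, 0.05, 0.05, 0.7)))
  elements <- genomic_element_vocabulary()
  pick_annot <- function(gene_idx) {
    el <- sample(elements, 1, prob = c(0.15, 0.15, 0.35, 0.15, 0.05, 0.15))
    sprintf("GENE%05d:%s", gene_idx, el)
  }
  gene_idx <- sample(ceiling(n / 2), n, replace = TRUE)
  second <- stats::runif(n) < multi_gene_prob
  gene_elements <- vapply(seq_len(n), function(i) {
    g <- pick_annot(gene_idx[i])
    if (second[i]) paste(g, pick_annot(gene_idx[i] + 1L), sep = ";") else g
  }, character(1))
  probe_manifest(data.frame(
    probe_id = loci$all,
    gene_elements = gene_elements,
    island_relation = relation,
    enhancer = stats::runif(n) < enhancer_prob,
    chromosome = sample(as.character(1:22), n, replace = TRUE),
    position = sample.int(2.4e8, n, replace = TRUE),
    stringsAsFactors = FALSE))
}
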