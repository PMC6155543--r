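#' Configuration of a synthetic tumor cohort
#'
#' Defines the statistical conditions under which a complete synthetic
#' cohort is generated: true clone trees with cell fractions, read-level
#' mutation tables, candidate tree sets with a likelihood spread favoring
#' the true topology, copy-number segments hitting a target instability
#' class mix, and binary feature matrices with planted clonal/subclonal
#' effects. Defaults emulate an exome-sequenced cohort: 1-8 clones per
#' sample (95% of real tumors have fewer than 8), ~100x depth, a 1% VAF
#' detection floor, and a class mix dominated by low-instability samples.
#'
#' @param n_samples Number of samples (default 100).
#' @param tumor_type_labels Character vector of type labels; samples are
#'   assigned round-robin.
#' @param clones_min,clones_max Bounds of the per-sample clone count, drawn
#'   uniformly per class (see `class_clone_ranges`).
#' @param branching_tendency Probability in `[0, 1]` that a new clone
#'   attaches to the root rather than extending the most recent lineage
#'   (0 = always linear, 1 = star).
#' @param mutations_per_clone Mean of the per-clone Poisson mutation count.
#' @param depth_mean Mean sequencing depth (Poisson per site).
#' @param purity_shape1,purity_shape2 Beta law of sample purity (defaults
#'   give mean 0.7).
#' @param vaf_floor Observed-VAF detection floor (default 0.01: no mutation
#'   is reported below 1% VAF).
#' @param n_candidates Candidate trees harvested per sample (default 50, a
#'   scaled-down stand-in for a 500-tree harvest).
#' @param candidate_noise Mean number of topology-perturbation moves per
#'   candidate (prune-regraft, clone merge, clone split).
#' @param cdll_gap Mean log-likelihood penalty per perturbation move, so the
#'   true topology is top-ranked in expectation.
#' @param class_mix Named target proportions of the `Low`/`M`/`C`/`MC`
#'   instability classes.
#' @param class_clone_ranges Named list mapping each class to a
#'   `c(min, max)` clone-count range; defaults plant the gradient in which
#'   doubly-unstable (MC) tumors carry the most clones.
#' @param planted_features Tibble `feature_id`, `target` (`"clonal"` or
#'   `"subclonal"`), `effect_size` (multiplicative shift for carriers); may
#'   be empty.
#' @param n_null_features Number of additional unshifted features.
#' @param feature_prevalence Carrier probability per feature.
#' @param seed Master seed; the whole cohort is reproducible given it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 100,
                          tumor_type_labels = c("TT1", "TT2"),
                          clones_min = 1, clones_max = 8,
                          branching_tendency = 0.5,
                          mutations_per_clone = 50,
                          depth_mean = 100,
                          purity_shape1 = 7, purity_shape2 = 3,
                          vaf_floor = 0.01,
                          n_candidates = 50,
                          candidate_noise = 1,
                          cdll_gap = 5,
                          class_mix = c(Low = 0.55, M = 0.20, C = 0.15, MC = 0.10),
                          class_clone_ranges = list(
                            Low = c(1, 3), M = c(2, 5), C = c(2, 5), MC = c(4, 8)
                          ),
                          planted_features = NULL,
                          n_null_features = 10,
                          feature_prevalence = 0.3,
                          seed = 1L) {
  stopifnot(n_samples >= 1, clones_min >= 1, clones_max >= clones_min,
            branching_tendency >= 0, branching_tendency <= 1,
            mutations_per_clone > 0, depth_mean > 0,
            vaf_floor > 0, vaf_floor < 1,
            n_candidates >= 1, candidate_noise >= 0, cdll_gap >= 0,
            abs(sum(class_mix) - 1) < 1e-8,
            setequal(names(class_mix), c("Low", "M", "C", "MC")),
            feature_prevalence >= 0, feature_prevalence <= 1)
  if (is.null(planted_features)) {
    planted_features <- tibble::tibble(feature_id = character(),
                                       target = character(),
                                       effect_size = double())
  }
  structure(list(
    n_samples = as.integer(n_samples),
    tumor_type_labels = tumor_type_labels,
    clones_min = as.integer(clones_min), clones_max = as.integer(clones_max),
    branching_tendency = branching_tendency,
    mutations_per_clone = mutations_per_clone,
    depth_mean = depth_mean,
    purity_shape1 = purity_shape1, purity_shape2 = purity_shape2,
    vaf_floor = vaf_floor,
    n_candidates = as.integer(n_candidates),
    candidate_noise = candidate_noise, cdll_gap = cdll_gap,
    class_mix = class_mix, class_clone_ranges = class_clone_ranges,
    planted_features = tibble::as_tibble(planted_features),
    n_null_features = as.integer(n_null_features),
    feature_prevalence = feature_prevalence,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Generate a random true clone tree
#'
#' Sequential attachment: each new clone attaches to the root with
#' probability `branching_tendency`, otherwise it extends the most recently
#' added clone, so 0 yields the strictly linear chain and 1 the star. Cell
#' fractions follow a stick-breaking scheme down the tree, guaranteeing that
#' each clone's subtree fraction is consistent (children sum to at most the
#' parent) and the root's is 1.
#'
#' @param n_clones Number of clones.
#' @param branching_tendency Root-attachment probability in `[0, 1]`.
#' @param mutations_per_clone Mean per-clone Poisson mutation count (root
#'   and subclones alike; at least 1 mutation per clone so every clone is
#'   observable).
#' @param seed Integer seed.
#' @return A [clone_tree()] whose `cell_fraction` is the per-clone cancer
#'   cell fraction (clone convention; subtree sums are consistent).
#' @export
generate_true_tree <- function(n_clones, branching_tendency = 0.5,
                               mutations_per_clone = 50, seed = 1L) {
  stopifnot(n_clones >= 1)
  set.seed(seed)
  parent <- rep(NA_integer_, n_clones)
  if (n_clones > 1) {
    for (i in 2:n_clones) {
      parent[i] <- if (stats::runif(1) < branching_tendency) 1L else i - 1L
    }
  }
  # stick-breaking down the tree: each node keeps a Beta share of the mass
  # reaching it and splits the rest among its children
  subtree <- numeric(n_clones)
  own <- numeric(n_clones)
  subtree[1] <- 1
  for (i in seq_len(n_clones)) {
    kids <- which(parent == i)
    if (length(kids) == 0) {
      own[i] <- subtree[i]
    } else {
      keep <- stats::rbeta(1, 2, 2)
      own[i] <- subtree[i] * keep
      w <- stats::rgamma(length(kids), 1.5)
      subtree[kids] <- subtree[i] * (1 - keep) * w / sum(w)
    }
  }
  n_mut <- pmax(1, stats::rpois(n_clones, mutations_per_clone))
  clone_tree(tibble::tibble(
    clone_id = seq_len(n_clones), parent_id = parent,
    n_mutations = n_mut, cell_fraction = own
  ), fraction_convention = "clone")
}

# per-clone subtree cancer-cell fraction (clone + descendants)
subtree_fractions <- function(tree) {
  ccf <- tree$cell_fraction
  # rows are in topological order; accumulate bottom-up
  for (i in rev(seq_len(nrow(tree)))) {
    p <- tree$parent_id[i]
    if (!is.na(p)) {
      j <- match(p, tree$clone_id)
      ccf[j] <- ccf[j] + ccf[i]
    }
  }
  ccf
}

#' Generate a read-level mutation table from a true tree
#'
#' Each clone's mutations are observed at expected VAF
#' `purity * CCF / 2` (diploid convention, no copy-number-aware
#' multiplicity), where CCF is the clone's subtree cancer-cell fraction.
#' Read depth per site is Poisson, alternate reads binomial, and any record
#' whose observed VAF falls below `vaf_floor` is dropped, emulating the
#' detection limit of somatic variant calling.
#'
#' @param tree A [clone_tree()] with per-clone cell fractions.
#' @param sample_id Sample label for the emitted records.
#' @param purity Tumor purity in `(0, 1]`.
#' @param depth_mean Mean sequencing depth.
#' @param vaf_floor Observed-VAF floor (default 0.01).
#' @param seed Integer seed.
#' @return A MAF-like tibble: `sample_id`, `chromosome`, `position`,
#'   `ref_allele`, `alt_allele`, `t_ref_count`, `t_alt_count`, `clone_id`
#'   (truth column, not part of the interchange format).
#' @export
generate_mutation_table <- function(tree, sample_id = "S1", purity = 0.7,
                                    depth_mean = 100, vaf_floor = 0.01,
                                    seed = 1L) {
  stopifnot(is_clone_tree(tree), purity > 0, purity <= 1)
  set.seed(seed)
  ccf <- subtree_fractions(tree)
  n_mut <- round(tree$n_mutations)
  total <- sum(n_mut)
  if (total == 0) {
    return(tibble::tibble(
      sample_id = character(), chromosome = character(), position = integer(),
      ref_allele = character(), alt_allele = character(),
      t_ref_count = integer(), t_alt_count = integer(), clone_id = integer()
    ))
  }
  clone_of <- rep(seq_len(nrow(tree)), times = n_mut)
  exp_vaf <- pmin(0.5, purity * ccf[clone_of] / 2)
  depth <- stats::rpois(total, depth_mean)
  depth[depth == 0] <- 1L
  alt <- stats::rbinom(total, depth, exp_vaf)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, total, replace = TRUE)
  alt_allele <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
  out <- tibble::tibble(
    sample_id = sample_id,
    chromosome = as.character(sample(1:22, total, replace = TRUE)),
    position = sample.int(2e8, total, replace = TRUE),
    ref_allele = ref, alt_allele = alt_allele,
    t_ref_count = depth - alt, t_alt_count = alt,
    clone_id = tree$clone_id[clone_of]
  )
  out[alt / depth >= vaf_floor, ]
}

#' Generate a candidate tree set around a true tree
#'
#' Emulates the multi-tree harvest of probabilistic subclonal
#' reconstruction: candidates are the true tree perturbed by a Poisson
#' number of random moves (subtree prune-regraft, clone merge, clone
#' split), and each candidate's pseudo log-likelihood is
#' `-(moves) * cdll_gap` plus standard Gumbel noise, so the true topology
#' wins in expectation but rankings are occasionally scrambled, exercising
#' the min-max weighting nontrivially.
#'
#' @param true_tree The generating [clone_tree()].
#' @param sample_id Sample label.
#' @param n_candidates Number of candidates (the first is always the
#'   unperturbed truth).
#' @param candidate_noise Mean move count per candidate; 0 returns
#'   `n_candidates` copies of the truth.
#' @param cdll_gap Log-likelihood penalty per move.
#' @param seed Integer seed.
#' @return A [candidate_set()] tibble.
#' @export
generate_candidates <- function(true_tree, sample_id = "S1", n_candidates = 50,
                                candidate_noise = 1, cdll_gap = 5, seed = 1L) {
  stopifnot(is_clone_tree(true_tree), n_candidates >= 1)
  set.seed(seed)
  base_ll <- -1000
  trees <- vector("list", n_candidates)
  moves <- integer(n_candidates)
  trees[[1]] <- true_tree
  moves[1] <- 0L
  for (i in seq_len(n_candidates)[-1]) {
    k <- stats::rpois(1, candidate_noise)
    trees[[i]] <- perturb_tree(true_tree, k)
    moves[i] <- k
  }
  gumbel <- -log(-log(stats::runif(n_candidates)))
  candidate_set(sample_id, trees, base_ll - moves * cdll_gap + gumbel)
}

# Apply k random topology moves (regraft / merge / split) to a clone tree.
perturb_tree <- function(tree, k) {
  nodes <- as_tibble(tree)
  for (i in seq_len(k)) {
    n <- nrow(nodes)
    move <- sample(c("regraft", "merge", "split"), 1)
    if (move == "regraft" && n >= 3) {
      non_root <- which(!is.na(nodes$parent_id))
      v <- sample(non_root, 1)
      # descendants of v cannot host it (would create a cycle)
      desc <- v
      repeat {
        more <- which(nodes$parent_id %in% nodes$clone_id[desc] &
                        !(seq_len(n) %in% desc))
        if (length(more) == 0) break
        desc <- c(desc, more)
      }
      hosts <- setdiff(seq_len(n), desc)
      hosts <- setdiff(hosts, match(nodes$parent_id[v], nodes$clone_id))
      if (length(hosts) > 0) {
        nodes$parent_id[v] <- nodes$clone_id[hosts[sample.int(length(hosts), 1)]]
      }
    } else if (move == "merge" && n >= 2) {
      non_root <- which(!is.na(nodes$parent_id))
      v <- non_root[sample.int(length(non_root), 1)]
      p_id <- nodes$parent_id[v]
      p <- match(p_id, nodes$clone_id)
      # fold v into its parent: mutations and cell fraction move up,
      # children re-attach to the parent
      nodes$n_mutations[p] <- nodes$n_mutations[p] + nodes$n_mutations[v]
      if (!is.na(nodes$cell_fraction[v]) && !is.na(nodes$cell_fraction[p])) {
        # clamp: repeated merges can push the sum to 1 + eps in floating point
        nodes$cell_fraction[p] <- min(1, nodes$cell_fraction[p] +
                                        nodes$cell_fraction[v])
      }
      nodes$parent_id[nodes$parent_id %in% nodes$clone_id[v]] <- p_id
      nodes <- nodes[-v, ]
    } else if (move == "split") {
      v <- sample.int(n, 1)
      new_id <- max(nodes$clone_id) + 1L
      half <- floor(nodes$n_mutations[v] / 2)
      cf <- nodes$cell_fraction[v]
      nodes$n_mutations[v] <- nodes$n_mutations[v] - half
      if (!is.na(cf)) {
        nodes$cell_fraction[v] <- cf / 2
      }
      nodes <- dplyr::bind_rows(nodes, tibble::tibble(
        clone_id = new_id, parent_id = nodes$clone_id[v],
        n_mutations = half, cell_fraction = if (is.na(cf)) NA_real_ else cf / 2
      ))
    }
  }
  suppressMessages(clone_tree(nodes))
}

#' Draw per-sample burdens that realize a class mix
#'
#' Assigns each sample an instability class from the configured mix and
#' draws mutation and altered-segment counts inside that class's region of
#' the (mutations, CNA) plane (log-uniform within class bounds, away from
#' the 300/80 boundaries so classification is unambiguous).
#'
#' @param n_samples Number of samples.
#' @param class_mix Named proportions over `Low`, `M`, `C`, `MC`.
#' @param mut_thr,cna_thr Class thresholds (defaults 300 and 80).
#' @param seed Integer seed.
#' @return A tibble `sample_id`, `class_true`, `n_mutations_target`,
#'   `n_cna_target`.
#' @export
generate_burdens <- function(n_samples, class_mix = c(Low = 0.55, M = 0.20,
                                                      C = 0.15, MC = 0.10),
                             mut_thr = 300, cna_thr = 80, seed = 1L) {
  set.seed(seed)
  cls <- sample(names(class_mix), n_samples, replace = TRUE, prob = class_mix)
  rlog <- function(n, lo, hi) round(exp(stats::runif(n, log(lo), log(hi))))
  lo_m <- rlog(n_samples, 10, mut_thr * 0.9)
  hi_m <- rlog(n_samples, mut_thr * 1.2, mut_thr * 20)
  lo_c <- rlog(n_samples, 1, cna_thr * 0.9)
  hi_c <- rlog(n_samples, cna_thr * 1.2, cna_thr * 6)
  tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(n_samples)),
    class_true = factor(cls, levels = c("Low", "M", "C", "MC")),
    n_mutations_target = ifelse(cls %in% c("M", "MC"), hi_m, lo_m),
    n_cna_target = ifelse(cls %in% c("C", "MC"), hi_c, lo_c)
  )
}

#' Generate copy-number segments realizing target altered counts
#'
#' Emits, per sample, `n_cna_target` altered segments with mean log-ratio
#' drawn outside the `(-0.3, 0.3)` neutral band (uniform over
#' `[0.35, 1.5]` in absolute value, gains and losses equally likely) plus a
#' background of neutral segments strictly inside the band.
#'
#' @param burdens Tibble from [generate_burdens()] (needs `sample_id` and
#'   `n_cna_target`).
#' @param n_neutral Neutral background segments per sample.
#' @param seed Integer seed.
#' @return A SEG-like tibble: `sample_id`, `chromosome`, `start`, `end`,
#'   `n_probes`, `value`.
#' @export
generate_segments <- function(burdens, n_neutral = 20, seed = 1L) {
  set.seed(seed)
  purrr::pmap(list(burdens$sample_id, burdens$n_cna_target), function(sid, k) {
    n <- k + n_neutral
    val <- c(
      sample(c(-1, 1), k, replace = TRUE) * stats::runif(k, 0.35, 1.5),
      stats::runif(n_neutral, -0.25, 0.25)
    )
    start <- sort(sample.int(2e8, n))
    tibble::tibble(
      sample_id = sid,
      chromosome = as.character(sample(1:22, n, replace = TRUE)),
      start = start,
      end = start + sample.int(5e6, n),
      n_probes = sample(50:5000, n, replace = TRUE),
      value = val
    )
  }) |> purrr::list_rbind()
}

#' Plant feature effects on clonal/subclonal burdens
#'
#' Draws a binary carrier matrix at the configured prevalence and, for each
#' planted feature, resamples carriers' clonal or subclonal mutation counts
#' with a multiplicative shift (`count ~ Poisson(effect_size * count)`),
#' leaving null features unshifted. Planted effects are applied
#' sequentially to the shared per-sample counts, so planting several
#' features on the same target compounds.
#'
#' @param samples Tibble with `sample_id`, `n_clonal`, `n_subclonal`.
#' @param planted_features Tibble `feature_id`, `target`
#'   (`"clonal"`/`"subclonal"`), `effect_size`; zero rows allowed.
#' @param n_null_features Count of additional unshifted features.
#' @param prevalence Carrier probability.
#' @param seed Integer seed.
#' @return A list: `features` (wide binary tibble), `samples` (counts after
#'   planting), `truth` (per-feature carrier counts and planted effect).
#' @export
plant_feature_effects <- function(samples, planted_features,
                                  n_null_features = 10, prevalence = 0.3,
                                  seed = 1L) {
  stopifnot(all(c("sample_id", "n_clonal", "n_subclonal") %in% names(samples)))
  if (is.null(planted_features) || nrow(planted_features) == 0) {
    planted_features <- tibble::tibble(feature_id = character(),
                                       target = character(),
                                       effect_size = double())
  }
  planted_features <- tibble::as_tibble(planted_features)
  set.seed(seed)
  n <- nrow(samples)
  feat_ids <- c(planted_features$feature_id,
                sprintf("null_%02d", seq_len(n_null_features)))
  mat <- matrix(stats::rbinom(n * length(feat_ids), 1, prevalence), nrow = n,
                dimnames = list(NULL, feat_ids))
  out <- samples
  if (nrow(planted_features) > 0) {
    for (i in seq_len(nrow(planted_features))) {
      pf <- planted_features[i, ]
      carriers <- mat[, pf$feature_id] == 1
      col <- if (pf$target == "clonal") "n_clonal" else "n_subclonal"
      out[[col]][carriers] <- stats::rpois(
        sum(carriers), pf$effect_size * out[[col]][carriers]
      )
    }
  }
  truth <- tibble::tibble(
    feature_id = feat_ids,
    target = c(planted_features$target, rep(NA_character_, n_null_features)),
    effect_size = c(planted_features$effect_size, rep(1, n_null_features)),
    n_carriers = unname(colSums(mat))
  )
  list(
    features = dplyr::bind_cols(tibble::tibble(sample_id = samples$sample_id),
                                tibble::as_tibble(mat)),
    samples = out,
    truth = truth
  )
}

#' Generate a complete synthetic cohort
#'
#' Runs the full generator under one master seed: burdens and classes, true
#' trees (clone counts drawn per class so doubly-unstable samples carry the
#' most clones), mutation tables with read counts, candidate tree sets,
#' segments, purity, and feature matrices with planted effects. The result
#' bundles every interchange table plus a truth table for every planted
#' quantity; [write_cohort()] serializes it to disk.
#'
#' @param config A [cohort_config()].
#' @return A list of class `cohort_bundle` with elements `truth`,
#'   `trees` (named list of true [clone_tree()]s), `candidates` (tibble),
#'   `maf`, `seg`, `features`, `feature_truth`, `purity`, `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  burdens <- generate_burdens(cfg$n_samples, cfg$class_mix,
                              seed = derive_seed(cfg$seed, 1))
  set.seed(derive_seed(cfg$seed, 2))
  rng <- cfg$class_clone_ranges
  n_clones <- vapply(as.character(burdens$class_true), function(cl) {
    r <- rng[[cl]]
    lo <- max(cfg$clones_min, r[1])
    hi <- max(lo, min(cfg$clones_max, r[2]))
    lo + sample.int(hi - lo + 1L, 1) - 1L   # safe for lo == hi
  }, double(1), USE.NAMES = FALSE)
  purity <- stats::rbeta(cfg$n_samples, cfg$purity_shape1, cfg$purity_shape2)
  tumor_type <- rep_len(cfg$tumor_type_labels, cfg$n_samples)

  trees <- vector("list", cfg$n_samples)
  names(trees) <- burdens$sample_id
  maf <- vector("list", cfg$n_samples)
  cands <- vector("list", cfg$n_samples)
  truth_rows <- vector("list", cfg$n_samples)
  for (i in seq_len(cfg$n_samples)) {
    sid <- burdens$sample_id[i]
    mpc <- burdens$n_mutations_target[i] / n_clones[i]
    tr <- generate_true_tree(n_clones[i], cfg$branching_tendency, mpc,
                             seed = derive_seed(cfg$seed, 3, i))
    trees[[i]] <- tr
    maf[[i]] <- generate_mutation_table(tr, sid, purity[i], cfg$depth_mean,
                                        cfg$vaf_floor,
                                        seed = derive_seed(cfg$seed, 4, i))
    cands[[i]] <- generate_candidates(tr, sid, cfg$n_candidates,
                                      cfg$candidate_noise, cfg$cdll_gap,
                                      seed = derive_seed(cfg$seed, 5, i))
    cs <- clonal_subclonal_counts(tr)
    truth_rows[[i]] <- tibble::tibble(
      sample_id = sid, tumor_type = tumor_type[i],
      class_true = burdens$class_true[i],
      n_clones_true = n_clones[i], tree_score_true = tree_score(tr),
      n_clonal = cs$clonal, n_subclonal = cs$subclonal,
      purity = purity[i],
      n_mutations_target = burdens$n_mutations_target[i],
      n_cna_target = burdens$n_cna_target[i]
    )
  }
  truth <- purrr::list_rbind(truth_rows)
  seg <- generate_segments(burdens, seed = derive_seed(cfg$seed, 6))
  planted <- plant_feature_effects(
    truth[, c("sample_id", "n_clonal", "n_subclonal")],
    cfg$planted_features, cfg$n_null_features, cfg$feature_prevalence,
    seed = derive_seed(cfg$seed, 7)
  )
  truth$n_clonal <- planted$samples$n_clonal
  truth$n_subclonal <- planted$samples$n_subclonal
  structure(list(
    truth = truth, trees = trees,
    candidates = purrr::list_rbind(cands),
    maf = purrr::list_rbind(maf), seg = seg,
    features = planted$features, feature_truth = planted$truth,
    purity = tibble::tibble(sample_id = truth$sample_id, purity = purity,
                            ploidy = 2),
    config = cfg
  ), class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf(
    "<cohort_bundle> %d sample(s), %d candidate tree(s), %d mutation record(s), %d segment(s), %d feature(s)\n",
    nrow(x$truth), nrow(x$candidates), nrow(x$maf), nrow(x$seg),
    ncol(x$features) - 1L
  ))
  invisible(x)
}
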