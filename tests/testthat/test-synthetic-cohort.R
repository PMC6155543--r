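test_that("true-tree generator spans chain to star and keeps fractions consistent", {
  expect_equal(tree_score(generate_true_tree(6, branching_tendency = 0, seed = 1)), 0)
  star <- generate_true_tree(5, branching_tendency = 1, seed = 1)
  expect_equal(tree_score(star), 0.75)
  for (seed in 1:10) {
    tr <- generate_true_tree(7, branching_tendency = 0.5, seed = seed)
    expect_lte(sum(tr$cell_fraction), 1 + 1e-12)
    expect_true(all(tr$cell_fraction >= 0))
    # root subtree fraction is the whole tumor
    expect_equal(max(clonearch:::subtree_fractions(tr)), 1, tolerance = 1e-12)
  }
})

test_that("mutation tables respect the VAF floor and binomial sampling moments", {
  tr <- generate_true_tree(1, seed = 2, mutations_per_clone = 400)
  maf <- generate_mutation_table(tr, purity = 1, depth_mean = 200,
                                 vaf_floor = 0.01, seed = 3)
  vaf <- maf$t_alt_count / (maf$t_alt_count + maf$t_ref_count)
  # root clone at CCF 1, purity 1: expected VAF 0.5
  se <- stats::sd(vaf) / sqrt(length(vaf))
  expect_lt(abs(mean(vaf) - 0.5) / se, 3)
  expect_true(all(vaf >= 0.01))

  # at very high depth the observed VAF converges to the expectation
  deep <- generate_mutation_table(tr, purity = 0.6, depth_mean = 1e5, seed = 4)
  dvaf <- deep$t_alt_count / (deep$t_alt_count + deep$t_ref_count)
  expect_lt(max(abs(dvaf - 0.3)), 0.02)
})

test_that("noise-free candidate sets collapse the consensus onto the truth", {
  tr <- generate_true_tree(5, seed = 6, mutations_per_clone = 20)
  cands <- generate_candidates(tr, "s1", n_candidates = 20,
                               candidate_noise = 0, seed = 7)
  out <- consensus_summary(cands, fraction = 0.5)
  expect_equal(out$mean_n_clones, 5)
  expect_equal(out$mean_tree_score, tree_score(tr))
  cs <- clonal_subclonal_counts(tr)
  expect_equal(out$mean_clonal, cs$clonal)
  expect_equal(out$mean_subclonal, cs$subclonal)
})

test_that("perturbed candidates parse, vary, and keep mutation totals on merges/regrafts", {
  tr <- generate_true_tree(6, seed = 8, mutations_per_clone = 30)
  total <- sum(tr$n_mutations)
  cands <- generate_candidates(tr, "s1", n_candidates = 30,
                               candidate_noise = 2, seed = 9)
  expect_equal(nrow(cands), 30)
  for (t2 in cands$tree) {
    expect_true(is_clone_tree(t2))
    # moves redistribute mutations but never create or destroy them
    expect_equal(sum(t2$n_mutations), total)
  }
  # the unperturbed truth is the top-likelihood candidate in expectation:
  # it must be among the best-ranked candidates here
  best <- cands$tree[[which.max(cands$cdll)]]
  expect_lte(abs(count_clones(best) - 6), 1)
})

test_that("burden generator hits the requested class mix exactly by construction", {
  b <- generate_burdens(300, c(Low = 0.25, M = 0.25, C = 0.25, MC = 0.25), seed = 3)
  expect_equal(as.character(classify_instability(b$n_mutations_target, b$n_cna_target)),
               as.character(b$class_true))
  # empirical proportions within multinomial error of the targets
  expect_true(all(abs(table(b$class_true) / 300 - 0.25) < 3 * sqrt(0.25 * 0.75 / 300)))

  seg <- generate_segments(b[1:20, ], seed = 4)
  counted <- count_cna_segments(seg)
  expect_equal(counted$n_cna_segments[match(b$sample_id[1:20], counted$sample_id)],
               b$n_cna_target[1:20])
})

test_that("cohort bundles are deterministic per seed and internally consistent", {
  cfg <- cohort_config(n_samples = 12, seed = 21)
  b1 <- suppressMessages(generate_cohort(cfg))
  b2 <- suppressMessages(generate_cohort(cfg))
  expect_identical(b1$truth, b2$truth)
  expect_identical(b1$maf, b2$maf)
  expect_equal(nrow(b1$truth), 12)
  # truth clone counts match the stored trees
  expect_equal(b1$truth$n_clones_true,
               vapply(b1$trees[b1$truth$sample_id], count_clones, integer(1),
                      USE.NAMES = FALSE))
  # planted class gradient: MC samples carry at least as many clones as Low
  mc <- b1$truth$n_clones_true[b1$truth$class_true == "MC"]
  lo <- b1$truth$n_clones_true[b1$truth$class_true == "Low"]
  if (length(mc) > 0 && length(lo) > 0) expect_gte(min(mc), max(lo) - 2)
})

test_that("planted feature effects shift only their target burden", {
  base <- null_burdens(500, seed = 31)[, c("sample_id", "n_clonal", "n_subclonal")]
  pf <- tibble::tibble(feature_id = "sub2", target = "subclonal", effect_size = 2)
  planted <- plant_feature_effects(base, pf, n_null_features = 2,
                                   prevalence = 0.4, seed = 32)
  carriers <- planted$features$sub2 == 1
  expect_gt(mean(planted$samples$n_subclonal[carriers]),
            1.7 * mean(planted$samples$n_subclonal[!carriers]))
  expect_lt(abs(mean(planted$samples$n_clonal[carriers]) -
                  mean(planted$samples$n_clonal[!carriers])), 10)
  expect_equal(planted$truth$n_carriers[1], sum(carriers))
})
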