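test_that("score binarization sets any positive score to 1", {
  scores <- tibble::tibble(sample_id = c("a", "b", "c"),
                           s1 = c(0.31, 0, 0.002), s2 = c(0, 0, 0))
  expect_message(out <- binarize_scores(scores), "no carriers")
  expect_equal(out$s1, c(1L, 0L, 1L))
  expect_equal(out$s2, c(0L, 0L, 0L))
  expect_error(binarize_scores(tibble::tibble(sample_id = "a", s1 = -0.1)),
               "non-negative")
})

test_that("one-tailed rank-sum p-values match exact enumeration", {
  # all carrier ranks above all non-carrier ranks: p = 1 / choose(6, 3)
  expect_equal(wilcoxon_one_tailed(c(10, 12, 14), c(1, 2, 3)), 1 / 20)
  # the opposite extreme arrangement has exact p = 1
  expect_equal(wilcoxon_one_tailed(c(1, 2, 3), c(10, 12, 14)), 1)
  expect_error(wilcoxon_one_tailed(numeric(0), 1:3), "non-empty")

  # exact vs normal-approximation branches agree on tie-free 8 x 8 samples
  # away from the extreme tails (where a normal tail is known to thin out)
  set.seed(21)
  checked <- 0
  for (i in 1:40) {
    v <- sample.int(10000, 16)  # distinct values: tie-free by construction
    x <- v[1:8]
    y <- v[9:16]
    p_exact <- wilcoxon_one_tailed(x, y, exact = TRUE)
    if (p_exact < 0.05 || p_exact > 0.95) next
    p_approx <- wilcoxon_one_tailed(x, y, exact = FALSE)
    expect_lt(abs(p_approx - p_exact) / p_exact, 0.1)
    checked <- checked + 1
  }
  expect_gte(checked, 10)
})

test_that("null rank-sum p-values are approximately uniform", {
  set.seed(33)
  ps <- replicate(400, wilcoxon_one_tailed(stats::rnorm(12), stats::rnorm(12)))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("BH adjustment reproduces the hand-applied step-up", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(0.05, 4)), rep(0.05, 4))
  p <- c(0.001, 0.9, 0.03, 0.2)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  # order invariance of the input-position mapping
  perm <- c(3, 1, 4, 2)
  expect_equal(bh_fdr(p[perm]), q[perm])
})

test_that("enrichment scan recovers a planted subclonal effect as class S", {
  set.seed(8)
  dat <- null_burdens(40, seed = 80)
  planted <- plant_feature_effects(
    dat[, c("sample_id", "n_clonal", "n_subclonal")],
    tibble::tibble(feature_id = "hit", target = "subclonal", effect_size = 2),
    n_null_features = 3, prevalence = 0.5, seed = 81
  )
  dat$n_clonal <- planted$samples$n_clonal
  dat$n_subclonal <- planted$samples$n_subclonal
  res <- enrichment_scan(dat, planted$features, "signature")
  hit <- res[res$feature_id == "hit", ]
  expect_equal(as.character(hit$enrichment_class), "S")
  expect_gt(hit$score_subclonal, 2.5)
  expect_lt(hit$score_clonal, 2.5)
  expect_equal(hit$score_subclonal, -log10(hit$p_subclonal))
})

test_that("features with too few carriers are skipped with a reason", {
  dat <- null_burdens(10, seed = 5)
  feats <- tibble::tibble(sample_id = dat$sample_id,
                          rare = c(1, rep(0, 9)), common = rep(c(0, 1), 5))
  expect_message(res <- enrichment_scan(dat, feats), "skipped")
  expect_true(res$skipped[res$feature_id == "rare"])
  expect_true(is.na(res$p_clonal[res$feature_id == "rare"]))
  expect_false(res$skipped[res$feature_id == "common"])
})

test_that("tumor types are tested and FDR-adjusted independently", {
  dat <- dplyr::bind_rows(null_burdens(30, "T1", seed = 1),
                          null_burdens(30, "T2", seed = 2))
  set.seed(3)
  feats <- tibble::tibble(sample_id = dat$sample_id)
  for (f in sprintf("f%d", 1:4)) feats[[f]] <- stats::rbinom(60, 1, 0.5)
  res <- enrichment_scan(dat, feats)
  expect_equal(nrow(res), 8)  # 4 features x 2 types
  for (tt in c("T1", "T2")) {
    sub <- res[res$tumor_type == tt, ]
    expect_equal(sub$q_clonal, bh_fdr(sub$p_clonal))
  }
})
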