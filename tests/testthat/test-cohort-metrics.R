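tiny_maf <- function() {
  tibble::tibble(
    sample_id = c("a", "a", "a", "b"),
    chromosome = "1", position = 1:4,
    ref_allele = "A", alt_allele = "T",
    t_ref_count = c(30, 50, 10, 20),
    t_alt_count = c(10, 10, 5, 5)
  )
}

test_that("mutation counting includes every variant row", {
  expect_equal(count_mutations(tiny_maf())$n_mutations, c(3L, 1L))
  empty <- tiny_maf()[0, ]
  expect_equal(nrow(count_mutations(empty)), 0)
})

test_that("CNA segments are counted by strict value thresholds only", {
  seg <- tibble::tibble(
    sample_id = "a", chromosome = "1",
    start = c(1, 100, 200, 300), end = c(50, 150, 250, 350),
    value = c(0.4, -0.5, 0.1, 0.3)   # 0.3 exactly is NOT a gain
  )
  expect_equal(count_cna_segments(seg)$n_cna_segments, 2L)
  expect_equal(count_cna_segments(seg[seg$value == 0.3, ])$n_cna_segments, 0L)
  # order/coordinate invariance: shuffling rows changes nothing
  expect_equal(count_cna_segments(seg[c(3, 1, 4, 2), ]),
               count_cna_segments(seg))
  expect_equal(nrow(count_cna_segments(seg[0, ])), 0)
})

test_that("mean RMS averages total depth over mutated sites", {
  out <- mean_rms(tiny_maf())
  expect_equal(out$mean_rms[out$sample_id == "a"], mean(c(40, 60, 15)))
  expect_equal(out$mean_rms[out$sample_id == "b"], 25)
})

test_that("purity/ploidy solution selection minimizes squared distance", {
  sols <- tibble::tibble(purity = c(0.6, 0.9), ploidy = c(2.1, 3.0))
  ref <- list(purity = 0.62, ploidy = 2.0)
  expect_equal(select_absolute_solution(sols, ref)$purity, 0.6)
  # exact match wins with distance 0
  hit <- select_absolute_solution(sols, list(purity = 0.9, ploidy = 3.0))
  expect_equal(hit$distance2, 0)
  # equidistant candidates: first listed wins
  eq <- tibble::tibble(purity = c(0.5, 0.7), ploidy = c(2, 2))
  expect_equal(select_absolute_solution(eq, list(purity = 0.6, ploidy = 2))$purity,
               0.5)
  expect_error(select_absolute_solution(eq[0, ], ref))
})

test_that("instability classes partition the burden plane with strict cuts", {
  expect_equal(as.character(classify_instability(500, 100)), "MC")
  expect_equal(as.character(classify_instability(150, 20)), "Low")
  expect_equal(as.character(classify_instability(301, 79)), "M")
  expect_equal(as.character(classify_instability(299, 81)), "C")
  # boundary equality falls in the lower category
  expect_equal(as.character(classify_instability(300, 80)), "Low")
  expect_equal(as.character(classify_instability(300, 81)), "C")
  expect_equal(as.character(classify_instability(301, 80)), "M")
  # exhaustive and mutually exclusive on a grid spanning all regions
  grid <- expand.grid(m = c(0, 299, 300, 301, 1000), c = c(0, 79, 80, 81, 500))
  cls <- classify_instability(grid$m, grid$c)
  expect_false(anyNA(cls))
  expect_setequal(levels(cls), c("Low", "M", "C", "MC"))
})

test_that("sample_metrics joins burdens, depth, purity and class", {
  seg <- tibble::tibble(sample_id = c("a", "b"), chromosome = "1",
                        start = 1, end = 10, value = c(0.5, 0.0))
  pur <- tibble::tibble(sample_id = c("a", "b"), purity = c(0.7, 0.8),
                        ploidy = c(2, 3.1))
  sm <- sample_metrics(tiny_maf(), seg, pur)
  expect_equal(sm$sample_id, c("a", "b"))
  expect_equal(sm$n_mutations, c(3L, 1L))
  expect_equal(sm$n_cna_segments, c(1L, 0L))
  expect_equal(sm$purity, c(0.7, 0.8))
  expect_equal(as.character(sm$instability_class), c("Low", "Low"))
})

test_that("clone heatmap bins the normalized log-burden plane", {
  # identical samples collapse into one occupied cell holding their value
  same <- tibble::tibble(n_mutations = 100, n_cna = 50, mean_n_clones = c(3, 3, 3))
  hm <- clone_heatmap(same, n_bins = 10)
  expect_equal(nrow(hm), 1)
  expect_equal(hm$mean_clones, 3)
  expect_equal(hm$n_samples, 3L)

  # opposite corners occupy two distinct cells
  corners <- tibble::tibble(n_mutations = c(0, 5000), n_cna = c(0, 400),
                            mean_n_clones = c(1, 6))
  hm2 <- clone_heatmap(corners, n_bins = 5)
  expect_equal(nrow(hm2), 2)
  expect_equal(hm2$x_bin[which.max(hm2$mean_clones)], 5L)

  # planted gradient: clones grow with both burdens; top-right beats bottom-left
  set.seed(1)
  n <- 300
  mut <- round(exp(stats::runif(n, 0, 8)))
  cna <- round(exp(stats::runif(n, 0, 6)))
  clones <- 1 + 4 * (log1p(mut) / max(log1p(mut)) + log1p(cna) / max(log1p(cna))) / 2
  hm3 <- clone_heatmap(tibble::tibble(n_mutations = mut, n_cna = cna,
                                      mean_n_clones = clones), n_bins = 4)
  top_right <- hm3$mean_clones[hm3$x_bin == 4 & hm3$y_bin == 4]
  bottom_left <- hm3$mean_clones[hm3$x_bin == 1 & hm3$y_bin == 1]
  expect_gt(top_right, bottom_left)
})
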