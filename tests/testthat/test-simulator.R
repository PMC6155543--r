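test_that("death probability follows (1/2)(1-s)^k and is monotone", {
  expect_equal(death_probability(0, 0.3), 0.5)
  expect_equal(death_probability(5, 0), 0.5)
  expect_equal(death_probability(2, 0.1), 0.405)
  k <- 0:10
  expect_true(all(diff(death_probability(k, 0.2)) < 0))
  expect_true(all(diff(vapply(c(0.01, 0.1, 0.3), function(s)
    death_probability(3, s), double(1))) < 0))
  expect_error(death_probability(-1, 0.1), "k")
  expect_error(death_probability(1, 1), "s")
})

test_that("mu = 0 keeps a single clone with zero mutations forever", {
  p <- sim_params(mu = 0, s = 0.2, n_initial = 50, g_max = 30, seed = 3,
                  condition_on_survival = FALSE)
  sim <- simulate_tumor(p)
  expect_equal(nrow(sim$clones), 1)
  expect_equal(sim$clones$n_private_mutations, 0L)
  expect_equal(sim$n_mutation_events, 0)
  expect_equal(sim$final_population, sum(sim$clones$cell_count))
})

test_that("mu = 1 with no drivers creates one clone per replication event", {
  p <- sim_params(mu = 1, K = 0, s = 0, n_initial = 4, g_max = 12, seed = 11,
                  condition_on_survival = FALSE)
  sim <- simulate_tumor(p)
  expect_equal(nrow(sim$clones), 1 + sim$n_replications)
  expect_equal(sim$n_mutation_events, sim$n_replications)
  expect_equal(sim$n_driver_events, 0)
  expect_true(all(sim$clones$k_drivers == 0))
})

test_that("population bookkeeping is conserved and runs are seed-reproducible", {
  p <- sim_params(mu = 0.05, s = 0.1, n_initial = 20, g_max = 40, seed = 99,
                  condition_on_survival = FALSE)
  a <- simulate_tumor(p)
  b <- simulate_tumor(p)
  expect_identical(a$clones, b$clones)
  expect_equal(a$final_population, sum(a$clones$cell_count))
  # drivers never decrease along lineages
  kids <- !is.na(a$clones$parent_id)
  pk <- a$clones$k_drivers[match(a$clones$parent_id[kids], a$clones$clone_id)]
  expect_true(all(a$clones$k_drivers[kids] >= pk))
})

test_that("critical process (k = 0) keeps its mean population", {
  # expected offspring per cell is exactly 1; Monte-Carlo mean at a fixed
  # generation must match n_initial within 3 standard errors
  n0 <- 100
  reps <- 400
  pops <- vapply(seq_len(reps), function(i) {
    p <- sim_params(mu = 0, s = 0, n_initial = n0, g_max = 25,
                    condition_on_survival = FALSE, seed = 1000 + i)
    simulate_tumor(p)$final_population
  }, double(1))
  se <- stats::sd(pops) / sqrt(reps)
  expect_lt(abs(mean(pops) - n0), 3 * se)
})

test_that("survival conditioning reports attempts and can exhaust its budget", {
  # from a single cell the critical process almost surely dies quickly;
  # a tiny attempt budget must raise the documented failure
  p <- sim_params(mu = 0, s = 0, n_initial = 1, g_max = 500, seed = 5,
                  condition_on_survival = TRUE, max_attempts = 3)
  expect_error(simulate_tumor(p), "extinct in all 3 attempts")
})

test_that("phylogeny extraction applies the 1% floor and collapses ancestors", {
  fake <- function(clones, pop) {
    structure(list(clones = clones, final_population = pop, extinct = FALSE),
              class = "tumor_sim")
  }
  # A at 5/1095 = 0.46% is dropped; B stays
  sim <- fake(tibble::tibble(
    clone_id = 1:3, parent_id = c(NA, 1L, 1L), k_drivers = 0L,
    n_private_mutations = c(0L, 4L, 7L), cell_count = c(990, 5, 100)
  ), 1095)
  phy <- suppressMessages(extract_phylogeny(sim))
  expect_equal(sort(phy$clone_id), c(1L, 3L))
  expect_equal(phy$n_mutations[phy$clone_id == 3], 7)

  # dropped intermediate: B re-attaches to root and inherits A's mutations
  sim2 <- fake(tibble::tibble(
    clone_id = 1:3, parent_id = c(NA, 1L, 2L), k_drivers = 0L,
    n_private_mutations = c(0L, 4L, 7L), cell_count = c(2000, 5, 300)
  ), 2305)
  phy2 <- suppressMessages(extract_phylogeny(sim2))
  expect_equal(sort(phy2$clone_id), c(1L, 3L))
  expect_equal(phy2$parent_id[phy2$clone_id == 3], 1L)
  expect_equal(phy2$n_mutations[phy2$clone_id == 3], 11)

  # single surviving clone: N = 1, Tree score 0
  sim3 <- fake(tibble::tibble(
    clone_id = 1:2, parent_id = c(NA, 1L), k_drivers = 0L,
    n_private_mutations = c(0L, 2L), cell_count = c(0, 500)
  ), 500)
  phy3 <- suppressMessages(extract_phylogeny(sim3))
  expect_equal(count_clones(phy3), 1)
  expect_equal(tree_score(phy3), 0)
  # the extinct root's (zero) mutations collapsed into the survivor
  expect_equal(phy3$n_mutations, 2)

  # dropped root with two surviving lineages: root restored for rootedness
  sim4 <- fake(tibble::tibble(
    clone_id = 1:3, parent_id = c(NA, 1L, 1L), k_drivers = 0L,
    n_private_mutations = c(3L, 1L, 1L), cell_count = c(0, 600, 400)
  ), 1000)
  phy4 <- suppressMessages(extract_phylogeny(sim4))
  expect_equal(count_clones(phy4), 3)
  expect_equal(phy4$n_mutations[is.na(phy4$parent_id)], 3)
  expect_error(extract_phylogeny(fake(tibble::tibble(
    clone_id = 1L, parent_id = NA_integer_, k_drivers = 0L,
    n_private_mutations = 0L, cell_count = 0
  ), 0)), "extinct")
})

test_that("parameter sweep emits one tidy row per grid cell and replicate", {
  base <- sim_params(n_initial = 30, g_max = 15, condition_on_survival = FALSE)
  sw <- suppressMessages(parameter_sweep(c(0, 0.2), c(0, 0.1), replicates = 3,
                                         base_params = base, seed = 2))
  expect_equal(nrow(sw), 2 * 2 * 3)
  # extinct replicates are recorded, not dropped
  expect_true(all(!is.na(sw$extinct)))
  # mu = 0 column: every surviving tumor has exactly one clone, score 0
  mu0 <- sw[sw$mu == 0 & !sw$extinct, ]
  expect_true(all(mu0$n_clones == 1))
  expect_true(all(mu0$tree_score == 0))
  # deterministic given the master seed
  sw2 <- suppressMessages(parameter_sweep(c(0, 0.2), c(0, 0.1), replicates = 3,
                                          base_params = base, seed = 2))
  expect_identical(sw, sw2)
})
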