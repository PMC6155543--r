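test_that("leaf depths follow the unique root-to-leaf paths", {
  # chain r -> a -> b -> c: single leaf at depth 3
  ld <- leaf_depths(chain_tree(4))
  expect_equal(ld$clone_id, 4L)
  expect_equal(ld$depth, 3L)

  # star: all four children are leaves at depth 1
  ld <- leaf_depths(star_tree(5))
  expect_equal(sort(ld$clone_id), 2:5)
  expect_equal(ld$depth, rep(1L, 4))

  # mixed topology 1 -> 2, 1 -> 3, 3 -> 4, 3 -> 5: leaves at depths 1, 2, 2
  tr <- tree_from_parents(c(NA, 1, 1, 3, 3))
  ld <- leaf_depths(tr)
  expect_equal(ld$depth[match(c(2, 4, 5), ld$clone_id)], c(1L, 2L, 2L))

  # single-node tree: the root is its own leaf at depth 0
  ld <- leaf_depths(chain_tree(1))
  expect_equal(ld$depth, 0L)
})

test_that("malformed trees are rejected", {
  expect_error(clone_tree(data.frame(clone_id = 1:2, parent_id = c(NA, NA),
                                     n_mutations = 0)),
               "exactly one root")
  expect_error(clone_tree(data.frame(clone_id = 1:2, parent_id = c(NA, 9),
                                     n_mutations = 0)),
               "unknown clone")
  # 2 <-> 3 cycle hanging off a root
  expect_error(clone_tree(data.frame(clone_id = 1:3, parent_id = c(NA, 3, 2),
                                     n_mutations = 0)),
               "cycle")
  expect_error(clone_tree(data.frame(clone_id = c(1, 1), parent_id = c(NA, 1),
                                     n_mutations = 0)),
               "duplicate")
  expect_error(clone_tree(data.frame(clone_id = 1, parent_id = NA,
                                     n_mutations = -1)),
               "n_mutations")
})

test_that("tree score matches hand-computed reference topologies", {
  expect_identical(tree_score(chain_tree(1)), 0)
  expect_identical(tree_score(star_tree(5)), 0.75)
  # leaves at depths 1, 2, 2 with N = 5: 1 - mean(1,2,2)/4 = 7/12
  expect_equal(tree_score(tree_from_parents(c(NA, 1, 1, 3, 3))), 7 / 12)
})

test_that("every strictly linear phylogeny scores exactly 0", {
  for (n in 1:50) {
    expect_identical(tree_score(chain_tree(n)), 0)
  }
})

test_that("tree score equals the path-enumeration oracle on all shapes up to N = 6", {
  for (n in 1:6) {
    for (parent in enumerate_rooted_trees(n)) {
      expect_equal(tree_score(tree_from_parents(parent)),
                   oracle_tree_score(parent), tolerance = 1e-12)
    }
  }
})

test_that("score bounds hold and the star attains the maximum", {
  for (n in 2:6) {
    scores <- vapply(enumerate_rooted_trees(n), function(p) {
      tree_score(tree_from_parents(p))
    }, double(1))
    expect_true(all(scores >= 0))
    expect_true(all(scores <= 1 - 1 / (n - 1) + 1e-12))
    expect_equal(max(scores), 1 - 1 / (n - 1))
    star <- c(NA_integer_, rep(1L, n - 1))
    expect_equal(tree_score(tree_from_parents(star)), 1 - 1 / (n - 1))
  }
})

test_that("clonal/subclonal counts split at the root and conserve the total", {
  tr <- tree_from_parents(c(NA, 1, 2), n_mutations = c(10, 5, 2))
  cs <- clonal_subclonal_counts(tr)
  expect_equal(cs$clonal, 10)
  expect_equal(cs$subclonal, 7)

  cs1 <- clonal_subclonal_counts(tree_from_parents(NA_integer_, 8))
  expect_equal(c(cs1$clonal, cs1$subclonal), c(8, 0))

  # conservation on random shapes
  set.seed(42)
  for (i in 1:20) {
    n <- sample(2:9, 1)
    parent <- c(NA_integer_, vapply(2:n, function(j) sample.int(j - 1, 1), integer(1)))
    muts <- sample(0:30, n, replace = TRUE)
    tr <- tree_from_parents(parent, muts)
    cs <- clonal_subclonal_counts(tr)
    expect_equal(cs$clonal + cs$subclonal, sum(muts))
  }
})

test_that("count_clones is the node count", {
  expect_equal(count_clones(chain_tree(1)), 1L)
  expect_equal(count_clones(chain_tree(4)), 4L)
  expect_equal(count_clones(star_tree(5)), 5L)
})

test_that("newick serialization round-trips through ape", {
  skip_if_not_installed("ape")
  tr <- tree_from_parents(c(NA, 1, 1, 3, 3))
  phy <- ape::read.tree(text = as_newick(tr))
  expect_equal(ape::Ntip(phy), nrow(leaf_depths(tr)))
  expect_equal(ape::Nnode(phy), 5 - ape::Ntip(phy))
  # depths agree (unit branch lengths)
  dd <- ape::node.depth.edgelength(phy)[seq_len(ape::Ntip(phy))]
  expect_equal(sort(dd), sort(leaf_depths(tr)$depth))
})
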