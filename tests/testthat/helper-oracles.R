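# Independent brute-force oracles and tree builders used across tests.
# The oracles never call the package's own scoring path.

# Build a clone_tree from a parent vector (parent[1] must be NA, parents
# precede children).
tree_from_parents <- function(parent, n_mutations = 1) {
  suppressMessages(clone_tree(tibble::tibble(
    clone_id = seq_along(parent),
    parent_id = as.integer(parent),
    n_mutations = rep_len(n_mutations, length(parent))
  )))
}

# Oracle: Tree score by explicit enumeration of every root-to-leaf path,
# walking parent pointers one node at a time.
oracle_tree_score <- function(parent) {
  n <- length(parent)
  if (n == 1) return(0)
  depth_of <- function(i) {
    d <- 0
    while (!is.na(parent[i])) {
      i <- parent[i]
      d <- d + 1
    }
    d
  }
  leaves <- setdiff(seq_len(n), parent[!is.na(parent)])
  1 - mean(vapply(leaves, depth_of, double(1))) / (n - 1)
}

# Exhaustively enumerate rooted trees on n nodes as parent vectors with
# parent[i] < i. Every rooted tree shape occurs under some such increasing
# labeling, so shape-only statistics (depths, Tree score) are covered.
enumerate_rooted_trees <- function(n) {
  if (n == 1) return(list(NA_integer_))
  choices <- lapply(2:n, function(i) seq_len(i - 1))
  grid <- expand.grid(choices, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(r) {
    c(NA_integer_, as.integer(unlist(grid[r, ])))
  })
}

# Deterministic VAFs lying exactly on the neutral 1/f line:
# M(f_i) = i  for  f_i = 1 / (i/c + 1/f_max).
exact_neutral_vafs <- function(n = 60, f_min = 0.12, f_max = 0.24) {
  c_scale <- n / (1 / f_min - 1 / f_max)
  1 / (seq_len(n) / c_scale + 1 / f_max)
}

# Bimodal two-clone VAFs with binomial read noise: half the mutations near
# each mode, mimicking two subclones inside the fit window.
bimodal_vafs <- function(n = 200, modes = c(0.13, 0.23), depth = 150,
                         seed = 1) {
  set.seed(seed)
  expected <- rep(modes, length.out = n)
  stats::rbinom(n, depth, expected) / depth
}

# Null per-sample burden table for enrichment simulations. Dispersion is
# chosen so that a x2 multiplicative shift equals roughly +5 standard
# deviations of the null law (negative binomial size 30: sd(90) ~ 19).
null_burdens <- function(n_samples, tumor_type = "TT1", seed = 1) {
  set.seed(seed)
  tibble::tibble(
    sample_id = sprintf("%s_%04d", tumor_type, seq_len(n_samples)),
    tumor_type = tumor_type,
    n_clonal = stats::rnbinom(n_samples, mu = 60, size = 30),
    n_subclonal = stats::rnbinom(n_samples, mu = 90, size = 30)
  )
}
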