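#' Construct a clonal phylogeny
#'
#' A `clone_tree` is a rooted tree of tumor clones: the root holds the clonal
#' (truncal) mutations present in every cancer cell, and each non-root clone
#' holds the subclonal mutations private to its lineage. Internally it is a
#' tibble of nodes, one row per clone, so it composes naturally with dplyr.
#'
#' @param nodes A data frame with columns `clone_id` (integer, unique),
#'   `parent_id` (integer, `NA` for the root), `n_mutations` (non-negative
#'   count of somatic variants assigned to the clone) and optionally
#'   `cell_fraction` (fraction in `[0, 1]` of tumor cells; see
#'   `fraction_convention`).
#' @param fraction_convention How `cell_fraction` is to be read: `"subtree"`
#'   (the clone and all its descendants, PhyloWGS-style cancer-cell fraction)
#'   or `"clone"` (the clone alone). Recorded as an attribute; both are
#'   accepted since upstream tools differ.
#'
#' @return A tibble of class `clone_tree` with one row per clone, ordered so
#'   that every parent precedes its children (topological order).
#'
#' @details Validation enforces the rooted-tree invariants: exactly one
#'   parentless node, every `parent_id` present among the `clone_id`s, no
#'   cycles, and a connected graph. A root carrying zero mutations is legal
#'   (some reconstructions emit a non-cancerous root) but is flagged with a
#'   message so the clonal/subclonal split is interpreted knowingly.
#'
#' @examples
#' tr <- clone_tree(data.frame(
#'   clone_id = 1:3, parent_id = c(NA, 1, 1), n_mutations = c(10, 4, 2)
#' ))
#' tree_score(tr)
#' @export
clone_tree <- function(nodes, fraction_convention = c("subtree", "clone")) {
  fraction_convention <- match.arg(fraction_convention)
  stopifnot(is.data.frame(nodes))
  required <- c("clone_id", "parent_id", "n_mutations")
  missing_cols <- setdiff(required, names(nodes))
  if (length(missing_cols) > 0) {
    stop("clone_tree nodes lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  nodes <- tibble::as_tibble(nodes)
  nodes$clone_id <- as.integer(nodes$clone_id)
  nodes$parent_id <- as.integer(nodes$parent_id)
  nodes$n_mutations <- as.double(nodes$n_mutations)
  if (!"cell_fraction" %in% names(nodes)) nodes$cell_fraction <- NA_real_
  nodes <- nodes[, c("clone_id", "parent_id", "n_mutations", "cell_fraction")]
  validate_clone_nodes(nodes)
  nodes <- nodes[order(node_depths(nodes), nodes$clone_id), ]
  out <- tibble::new_tibble(nodes, class = "clone_tree",
                            fraction_convention = fraction_convention)
  root_mut <- out$n_mutations[is.na(out$parent_id)]
  if (nrow(out) > 1 && root_mut == 0) {
    message("clone_tree: root carries 0 mutations (non-cancerous root?)")
  }
  out
}

#' @export
#' @rdname clone_tree
is_clone_tree <- function(x) inherits(x, "clone_tree")

# Structural validation shared by the constructor and the JSON reader.
validate_clone_nodes <- function(nodes) {
  if (nrow(nodes) < 1) stop("clone tree must contain at least one clone", call. = FALSE)
  if (anyDuplicated(nodes$clone_id)) stop("duplicate clone_id", call. = FALSE)
  if (any(is.na(nodes$clone_id))) stop("missing clone_id", call. = FALSE)
  root <- which(is.na(nodes$parent_id))
  if (length(root) != 1) {
    stop("clone tree must have exactly one root (found ", length(root), ")",
         call. = FALSE)
  }
  known <- nodes$parent_id %in% nodes$clone_id | is.na(nodes$parent_id)
  if (!all(known)) {
    stop("parent_id refers to unknown clone(s): ",
         paste(nodes$parent_id[!known], collapse = ", "), call. = FALSE)
  }
  if (any(nodes$n_mutations < 0)) stop("n_mutations must be >= 0", call. = FALSE)
  cf <- nodes$cell_fraction
  if (any(!is.na(cf) & (cf < 0 | cf > 1))) {
    stop("cell_fraction must lie in [0, 1]", call. = FALSE)
  }
  # depth assignment doubles as the cycle/connectivity check
  node_depths(nodes)
  invisible(nodes)
}

# Edge-count depth of every node from the root; errors on cycles since a
# cycle leaves nodes unreachable from the root.
node_depths <- function(nodes) {
  n <- nrow(nodes)
  idx <- match(nodes$parent_id, nodes$clone_id)
  depth <- rep(NA_integer_, n)
  depth[is.na(nodes$parent_id)] <- 0L
  frontier <- which(depth == 0L)
  d <- 0L
  while (length(frontier) > 0) {
    d <- d + 1L
    frontier <- which(idx %in% frontier & is.na(depth))
    depth[frontier] <- d
  }
  if (anyNA(depth)) {
    stop("clone tree is disconnected or contains a cycle", call. = FALSE)
  }
  depth
}

root_id <- function(tree) tree$clone_id[is.na(tree$parent_id)]

#' Leaf depths of a clonal phylogeny
#'
#' Returns every leaf (clone without descendants) together with its depth,
#' counted in edges along the unique path to the root. A single-clone tree
#' returns its root at depth 0.
#'
#' @param tree A [clone_tree()].
#' @return A tibble with columns `clone_id` and `depth`.
#' @export
leaf_depths <- function(tree) {
  stopifnot(is_clone_tree(tree))
  depth <- node_depths(tree)
  is_leaf <- !(tree$clone_id %in% tree$parent_id)
  tibble::tibble(clone_id = tree$clone_id[is_leaf], depth = depth[is_leaf])
}

#' Tree score: the branching statistic of a clonal phylogeny
#'
#' Quantifies how branching a phylogeny is as
#' \deqn{1 - \frac{1}{L} \sum_l \frac{d(l, \mathrm{root})}{N - 1}}
#' where \eqn{L} is the number of leaves, \eqn{N} the number of clones and
#' \eqn{d(l, \mathrm{root})} the edge count from leaf \eqn{l} to the root.
#' Every strictly linear phylogeny scores exactly 0; the score grows with the
#' degree of branching, and for a fixed \eqn{N \ge 2} the star topology
#' attains the maximum \eqn{1 - 1/(N-1)}. A nonzero score first becomes
#' attainable at \eqn{N = 3}.
#'
#' @param tree A [clone_tree()].
#' @return A number in `[0, 1]`. A single-clone tree returns 0 by convention:
#'   the formula's \eqn{N - 1} denominator vanishes and no branching is
#'   expressible, which keeps the score continuous with the linear case.
#' @export
tree_score <- function(tree) {
  stopifnot(is_clone_tree(tree))
  n <- nrow(tree)
  if (n == 1) return(0)
  ld <- leaf_depths(tree)
  1 - mean(ld$depth) / (n - 1)
}

#' Number of clones in a phylogeny
#'
#' @param tree A [clone_tree()].
#' @return Positive integer node count.
#' @export
count_clones <- function(tree) {
  stopifnot(is_clone_tree(tree))
  nrow(tree)
}

#' Clonal and subclonal mutation counts
#'
#' Clonal mutations are those grouped in the root clone (present in all
#' cancer cells, the early events); subclonal mutations are everything
#' assigned to non-root clones (late events). Their sum is the tree's total
#' mutation count.
#'
#' @param tree A [clone_tree()].
#' @return A one-row tibble with columns `clonal` and `subclonal`.
#' @export
clonal_subclonal_counts <- function(tree) {
  stopifnot(is_clone_tree(tree))
  is_root <- is.na(tree$parent_id)
  tibble::tibble(
    clonal = sum(tree$n_mutations[is_root]),
    subclonal = sum(tree$n_mutations[!is_root])
  )
}

#' Convenience constructors for reference topologies
#'
#' `chain_tree()` builds the strictly linear phylogeny (each clone has one
#' child; Tree score 0). `star_tree()` builds the maximally branching one
#' (root plus `n - 1` leaves; Tree score `1 - 1/(n-1)` for `n >= 2`).
#'
#' @param n Number of clones (>= 1).
#' @param n_mutations Mutation counts, recycled to length `n` (default 1).
#' @return A [clone_tree()].
#' @export
chain_tree <- function(n, n_mutations = 1) {
  stopifnot(n >= 1)
  clone_tree(tibble::tibble(
    clone_id = seq_len(n),
    parent_id = c(NA_integer_, seq_len(n - 1L)),
    n_mutations = rep_len(n_mutations, n)
  ))
}

#' @rdname chain_tree
#' @export
star_tree <- function(n, n_mutations = 1) {
  stopifnot(n >= 1)
  clone_tree(tibble::tibble(
    clone_id = seq_len(n),
    parent_id = c(NA_integer_, rep(1L, n - 1L)),
    n_mutations = rep_len(n_mutations, n)
  ))
}

#' @export
print.clone_tree <- function(x, ...) {
  cat(sprintf(
    "<clone_tree> %d clone(s), root %d, Tree score %.4f, %g clonal / %g subclonal mutations\n",
    nrow(x), root_id(x), tree_score(x),
    clonal_subclonal_counts(x)$clonal, clonal_subclonal_counts(x)$subclonal
  ))
  NextMethod()
}

# dplyr verbs strip our subclass; keep the bare-tibble behaviour but provide
# an explicit down-cast for code that wants the plain node table.
#' @method as_tibble clone_tree
#' @export
as_tibble.clone_tree <- function(x, ...) {
  tibble::new_tibble(unclass(x)[c("clone_id", "parent_id", "n_mutations", "cell_fraction")],
                     nrow = length(unclass(x)$clone_id))
}

#' Serialize a clonal phylogeny to Newick
#'
#' Writes the tree with `clone_id`s as labels and unit branch lengths, the
#' interchange form understood by standard phylogenetics tools (e.g.
#' `ape::read.tree()`).
#'
#' @param tree A [clone_tree()].
#' @return A single Newick string, terminated by `;`.
#' @export
as_newick <- function(tree) {
  stopifnot(is_clone_tree(tree))
  kids <- split(tree$clone_id, factor(tree$parent_id, levels = tree$clone_id))
  rec <- function(id) {
    ch <- kids[[as.character(id)]]
    if (is.null(ch) || length(ch) == 0) return(sprintf("%d:1", id))
    sprintf("(%s)%d:1", paste(vapply(ch, rec, character(1)), collapse = ","), id)
  }
  sub("(:1);$", ";", paste0(rec(root_id(tree)), ";"))
}
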