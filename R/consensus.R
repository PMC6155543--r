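#' Assemble a candidate tree set
#'
#' Subclonal-reconstruction tools such as PhyloWGS do not return one tree but
#' many, each scored by its complete-data log-likelihood (CDLL). A candidate
#' set is a tibble with one row per candidate phylogeny, carrying the sample
#' it belongs to, the CDLL, and the tree itself in a list-column.
#'
#' @param sample_id Single sample identifier.
#' @param trees List of [clone_tree()] objects.
#' @param cdll Numeric vector of complete-data log-likelihoods (natural log),
#'   one per tree, all finite.
#' @return A tibble with columns `sample_id`, `cdll`, `tree` (list-column).
#' @export
candidate_set <- function(sample_id, trees, cdll) {
  stopifnot(length(trees) >= 1, length(trees) == length(cdll))
  if (any(!is.finite(cdll))) stop("cdll must be finite", call. = FALSE)
  if (!all(vapply(trees, is_clone_tree, logical(1)))) {
    stop("all candidates must be clone_tree objects", call. = FALSE)
  }
  tibble::tibble(sample_id = as.character(sample_id), cdll = as.double(cdll),
                 tree = trees)
}

#' Keep the top-likelihood fraction of candidate trees
#'
#' Reproduces the harvesting step in which all candidate phylogenies of a
#' sample are sorted by log-likelihood and only the best fraction (by default
#' the top 10%, e.g. 50 out of 500) is carried into the weighted consensus.
#'
#' @param candidates A candidate-set tibble (see [candidate_set()]); may hold
#'   several samples, which are cut independently.
#' @param fraction Fraction in `(0, 1]` to retain. The retained count is
#'   `ceiling(fraction * n)`, never less than 1; ties in `cdll` are broken by
#'   input order.
#' @return The retained rows, sorted by decreasing `cdll` within sample.
#' @export
select_top_fraction <- function(candidates, fraction = 0.1) {
  stopifnot(is.data.frame(candidates), nrow(candidates) >= 1)
  if (!(fraction > 0 && fraction <= 1)) {
    stop("fraction must lie in (0, 1]", call. = FALSE)
  }
  candidates |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::arrange(dplyr::desc(.data$cdll), .by_group = TRUE) |>
    dplyr::filter(dplyr::row_number() <= max(1L, ceiling(fraction * dplyr::n()))) |>
    dplyr::ungroup()
}

#' Min-max likelihood weights for candidate trees
#'
#' Each retained tree i is weighted by
#' `(cdll_i - min(cdll)) / (max(cdll) - min(cdll))`, so the best tree gets
#' weight 1 and the worst weight 0. When all CDLLs are equal the formula is
#' 0/0; the degenerate range falls back to uniform weight 1, which preserves
#' the plain mean.
#'
#' @param cdll Numeric vector of finite log-likelihoods, length >= 1.
#' @return Numeric vector of weights in `[0, 1]`, same length.
#' @export
s50_weights <- function(cdll) {
  if (length(cdll) == 0) stop("empty cdll vector", call. = FALSE)
  if (any(!is.finite(cdll))) stop("cdll must be finite", call. = FALSE)
  rng <- range(cdll)
  if (rng[1] == rng[2]) return(rep(1, length(cdll)))
  (cdll - rng[1]) / (rng[2] - rng[1])
}

#' Likelihood-weighted consensus over candidate phylogenies
#'
#' Summarizes a sample's candidate trees into a single description of its
#' clonal architecture: keep the top-likelihood fraction, weight each
#' retained tree by its min-max likelihood score ([s50_weights()]), and
#' report the weighted means of the clone count, the Tree score, and the
#' clonal and subclonal mutation counts.
#'
#' @param candidates A candidate-set tibble; may hold several samples.
#' @param fraction Top fraction retained before weighting (default 0.1).
#' @return A tibble with one row per sample: `sample_id`, `mean_n_clones`,
#'   `mean_tree_score`, `mean_clonal`, `mean_subclonal`, `n_candidates_used`.
#'   Each mean lies in the convex hull of the retained candidates' values.
#' @examples
#' cs <- candidate_set("s1", list(star_tree(4), chain_tree(4)), c(-10, -20))
#' consensus_summary(cs, fraction = 1)
#' @export
consensus_summary <- function(candidates, fraction = 0.1) {
  kept <- select_top_fraction(candidates, fraction)
  kept |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      mean_n_clones = weighted_mean_by_s50(
        vapply(.data$tree, count_clones, double(1)), .data$cdll),
      mean_tree_score = weighted_mean_by_s50(
        vapply(.data$tree, tree_score, double(1)), .data$cdll),
      mean_clonal = weighted_mean_by_s50(
        vapply(.data$tree, function(t) clonal_subclonal_counts(t)$clonal, double(1)),
        .data$cdll),
      mean_subclonal = weighted_mean_by_s50(
        vapply(.data$tree, function(t) clonal_subclonal_counts(t)$subclonal, double(1)),
        .data$cdll),
      n_candidates_used = dplyr::n(),
      .groups = "drop"
    )
}

weighted_mean_by_s50 <- function(x, cdll) {
  w <- s50_weights(cdll)
  sum(w * x) / sum(w)
}
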