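#' Per-sample mutation count
#'
#' Counts all variant rows per sample, with no variant-class filtering:
#' every row of the mutation table (SNV or indel, any consequence) is one
#' variant. Multiple alternate alleles at one site count as separate
#' variants; no deduplication is performed.
#'
#' @param maf A MAF-like tibble with at least `sample_id` (see [read_maf()]).
#' @return A tibble `sample_id`, `n_mutations`.
#' @export
count_mutations <- function(maf) {
  stopifnot(is.data.frame(maf), "sample_id" %in% names(maf))
  maf |>
    dplyr::count(.data$sample_id, name = "n_mutations")
}

#' Per-sample count of copy-number-altered segments
#'
#' A segment counts as altered when its mean log-ratio exceeds the gain
#' threshold or falls below the loss threshold, both strict inequalities
#' (a value of exactly 0.3 is not a gain). Only segment values matter;
#' coordinates and segment lengths do not enter the count.
#'
#' @param seg A SEG-like tibble with `sample_id` and `value` columns
#'   (see [read_seg()]).
#' @param gain_thr,loss_thr Strict thresholds, defaults `0.3` and `-0.3`.
#' @return A tibble `sample_id`, `n_cna_segments` (samples present in `seg`
#'   but with no altered segment report 0).
#' @export
count_cna_segments <- function(seg, gain_thr = 0.3, loss_thr = -0.3) {
  stopifnot(is.data.frame(seg), all(c("sample_id", "value") %in% names(seg)))
  seg |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      n_cna_segments = sum(.data$value > gain_thr | .data$value < loss_thr),
      .groups = "drop"
    )
}

#' Mean reads per mutated site (mean RMS)
#'
#' The mean, over a sample's mutated sites, of the total read depth
#' `t_ref_count + t_alt_count`. Sequencing depth bounds the detectability of
#' rare subclones, so this covariate is reported alongside clone counts.
#'
#' @param maf A MAF-like tibble with `sample_id`, `t_ref_count`,
#'   `t_alt_count`.
#' @return A tibble `sample_id`, `mean_rms`; a sample with zero mutations
#'   has no row (undefined mean, reported as missing downstream).
#' @export
mean_rms <- function(maf) {
  stopifnot(is.data.frame(maf),
            all(c("sample_id", "t_ref_count", "t_alt_count") %in% names(maf)))
  maf |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      mean_rms = mean(.data$t_ref_count + .data$t_alt_count),
      .groups = "drop"
    )
}

#' Select the purity/ploidy solution closest to a reference
#'
#' Purity/ploidy callers return several candidate solutions; absent manual
#' curation, the one minimizing the unweighted squared Euclidean distance
#' `(purity - ref_purity)^2 + (ploidy - ref_ploidy)^2` to a previously
#' curated reference solution is kept. Ties go to the first listed solution.
#'
#' @param solutions Tibble of candidate solutions with `purity` in `[0, 1]`
#'   and `ploidy > 0`.
#' @param reference One-row tibble (or list) with `purity` and `ploidy`.
#' @return The selected row of `solutions`, with a `distance2` column.
#' @export
select_absolute_solution <- function(solutions, reference) {
  stopifnot(is.data.frame(solutions), nrow(solutions) >= 1,
            all(c("purity", "ploidy") %in% names(solutions)))
  stopifnot(all(solutions$purity >= 0 & solutions$purity <= 1),
            all(solutions$ploidy > 0))
  d2 <- (solutions$purity - reference$purity)^2 +
    (solutions$ploidy - reference$ploidy)^2
  out <- solutions[which.min(d2), , drop = FALSE]
  out$distance2 <- min(d2)
  tibble::as_tibble(out)
}

#' Genomic-instability class from mutation and CNA burdens
#'
#' Stratifies samples by whether they carry many mutations (`> mut_thr`),
#' many copy-number-altered segments (`> cna_thr`), both, or neither:
#' `M` (mutation-driven instability), `C` (chromosomal instability),
#' `MC` (both high), `Low` otherwise. All comparisons are strict, so
#' boundary values (exactly 300 mutations or 80 segments) fall in the lower
#' category and are absorbed by `Low` (or the single-sided class).
#'
#' @param n_mutations,n_cna Non-negative counts (vectorized).
#' @param mut_thr,cna_thr Strict thresholds, defaults 300 and 80.
#' @return A factor with levels `Low`, `M`, `C`, `MC`.
#' @export
classify_instability <- function(n_mutations, n_cna, mut_thr = 300, cna_thr = 80) {
  stopifnot(length(n_mutations) == length(n_cna))
  hi_m <- n_mutations > mut_thr
  hi_c <- n_cna > cna_thr
  cls <- dplyr::case_when(
    hi_m & hi_c ~ "MC",
    hi_m & !hi_c ~ "M",
    !hi_m & hi_c ~ "C",
    .default = "Low"
  )
  factor(cls, levels = c("Low", "M", "C", "MC"))
}

#' Assemble per-sample burden metrics
#'
#' Joins the per-sample mutation count, altered-segment count, mean RMS and
#' (optionally) purity/ploidy into one table and attaches the instability
#' class. Samples present in either input are kept; absent counts are 0 and
#' an absent mean RMS stays missing.
#'
#' @param maf MAF-like mutation tibble (see [read_maf()]).
#' @param seg SEG-like segment tibble (see [read_seg()]).
#' @param purity Optional tibble `sample_id`, `purity`, `ploidy`.
#' @param mut_thr,cna_thr,gain_thr,loss_thr Thresholds passed through to
#'   [classify_instability()] and [count_cna_segments()].
#' @return A tibble `sample_id`, `n_mutations`, `n_cna_segments`,
#'   `mean_rms`, (`purity`, `ploidy`,) `instability_class`.
#' @export
sample_metrics <- function(maf, seg, purity = NULL,
                           mut_thr = 300, cna_thr = 80,
                           gain_thr = 0.3, loss_thr = -0.3) {
  m <- dplyr::full_join(count_mutations(maf), mean_rms(maf), by = "sample_id")
  out <- dplyr::full_join(m, count_cna_segments(seg, gain_thr, loss_thr),
                          by = "sample_id") |>
    dplyr::mutate(
      n_mutations = dplyr::coalesce(.data$n_mutations, 0L),
      n_cna_segments = dplyr::coalesce(.data$n_cna_segments, 0L)
    )
  if (!is.null(purity)) {
    out <- dplyr::left_join(out, tibble::as_tibble(purity), by = "sample_id")
  }
  out |>
    dplyr::mutate(instability_class = classify_instability(
      .data$n_mutations, .data$n_cna_segments, mut_thr, cna_thr
    )) |>
    dplyr::arrange(.data$sample_id)
}

#' Mean clone count over the (CNA, mutation) burden plane
#'
#' Bins samples on normalized log-burden axes -- `x = log1p(n_cna) / max`,
#' `y = log1p(n_mutations) / max`, both maxima taken over the cohort -- into
#' an `n_bins` x `n_bins` grid on the unit square, and reports the mean of
#' `mean_n_clones` within each occupied cell. `log1p` (natural log) admits
#' zero counts; empty cells are absent from the output (missing).
#'
#' @param samples Tibble with `n_mutations`, `n_cna`, `mean_n_clones`.
#' @param n_bins Number of equal-width bins per axis (default 20).
#' @return A tibble `x_bin`, `y_bin` (1-based bin indices), `x_mid`, `y_mid`
#'   (bin midpoints on the normalized axes), `n_samples`, `mean_clones`.
#' @export
clone_heatmap <- function(samples, n_bins = 20) {
  stopifnot(is.data.frame(samples),
            all(c("n_mutations", "n_cna", "mean_n_clones") %in% names(samples)),
            n_bins >= 1)
  x <- log1p(samples$n_cna)
  y <- log1p(samples$n_mutations)
  xm <- max(x); ym <- max(y)
  x <- if (xm > 0) x / xm else x * 0
  y <- if (ym > 0) y / ym else y * 0
  bin <- function(v) pmin(n_bins, floor(v * n_bins) + 1L)
  tibble::tibble(
    x_bin = bin(x), y_bin = bin(y),
    mean_n_clones = samples$mean_n_clones
  ) |>
    dplyr::group_by(.data$x_bin, .data$y_bin) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      mean_clones = mean(.data$mean_n_clones),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      x_mid = (.data$x_bin - 0.5) / n_bins,
      y_mid = (.data$y_bin - 0.5) / n_bins
    ) |>
    dplyr::relocate("x_bin", "y_bin", "x_mid", "y_mid")
}
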