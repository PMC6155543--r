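#' Cumulative 1/f mutation curve
#'
#' Under neutral evolution the cumulative number of subclonal mutations at
#' allele frequency at least f, M(f), grows linearly in 1/f. This computes
#' the empirical curve: at each observed VAF within the window
#' `[f_min, f_max]`, pairs `1/f` with `M(f) =` the number of mutations whose
#' VAF is `>= f`. The curve is non-increasing in f by construction.
#'
#' @param vafs Numeric vector of variant allele frequencies in `(0, 1]`.
#' @param f_min,f_max The frequency window; defaults 0.12-0.24, the range in
#'   which subclonal mutations are reliably detected by exome sequencing yet
#'   clonal (VAF ~ 0.5) mutations are excluded.
#' @return A tibble `f`, `inv_f`, `m` with one row per distinct in-window
#'   VAF, ordered by increasing `f`.
#' @export
cumulative_vaf_curve <- function(vafs, f_min = 0.12, f_max = 0.24) {
  stopifnot(f_min > 0, f_min < f_max, f_max <= 1)
  vafs <- vafs[!is.na(vafs)]
  f <- sort(unique(vafs[vafs >= f_min & vafs <= f_max]))
  m <- vapply(f, function(x) sum(vafs >= x), double(1))
  tibble::tibble(f = f, inv_f = 1 / f, m = m)
}

#' Fit the neutral-evolution 1/f model
#'
#' Ordinary least squares of M(f) against 1/f over the in-window curve
#' points. A high coefficient of determination (R-squared) means the VAF
#' spectrum is consistent with neutral accumulation of subclonal mutations;
#' samples with `R^2 > 0.98` are classified as exhibiting features of
#' neutral evolution.
#'
#' @param vafs Numeric vector of VAFs.
#' @param f_min,f_max The frequency window (see [cumulative_vaf_curve()]).
#' @param min_mutations Minimum number of in-window mutations required to
#'   attempt the fit (default 10); below it the sample is unevaluable, not
#'   non-neutral.
#' @param intercept Fit through an intercept (default `TRUE`, the cited
#'   model's practice).
#' @return An object of class `neutral_fit`: list with `r_squared`,
#'   `n_in_range`, `curve` (the fitted points), `fit` (the `lm`, or `NULL`),
#'   and the window. `r_squared` is `NA` when unevaluable (too few
#'   mutations, or fewer than 3 distinct support points, where a line fits
#'   vacuously). Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @export
neutral_fit <- function(vafs, f_min = 0.12, f_max = 0.24,
                        min_mutations = 10, intercept = TRUE) {
  curve <- cumulative_vaf_curve(vafs, f_min, f_max)
  n_in <- sum(vafs >= f_min & vafs <= f_max, na.rm = TRUE)
  out <- structure(
    list(r_squared = NA_real_, n_in_range = n_in, curve = curve, fit = NULL,
         f_min = f_min, f_max = f_max, intercept = intercept),
    class = "neutral_fit"
  )
  if (n_in < min_mutations || nrow(curve) < 3) return(out)
  fm <- if (intercept) stats::lm(m ~ inv_f, data = curve)
        else stats::lm(m ~ inv_f - 1, data = curve)
  out$fit <- fm
  # R^2 computed directly (avoids summary.lm's perfect-fit warning)
  ss_res <- sum(stats::residuals(fm)^2)
  ss_tot <- if (intercept) sum((curve$m - mean(curve$m))^2) else sum(curve$m^2)
  out$r_squared <- 1 - ss_res / ss_tot
  out
}

#' @rdname neutral_fit
#' @export
neutral_fit_r2 <- function(vafs, f_min = 0.12, f_max = 0.24,
                           min_mutations = 10, intercept = TRUE) {
  neutral_fit(vafs, f_min, f_max, min_mutations, intercept)$r_squared
}

#' Classify a sample as neutral from its model fit
#'
#' Strict comparison: `r_squared > threshold` is neutral, a fit exactly at
#' the threshold is not, and a missing fit stays missing.
#'
#' @param r_squared R-squared value(s) from [neutral_fit()].
#' @param threshold Classification cut, default 0.98.
#' @return Logical (with `NA` propagated).
#' @export
classify_neutral <- function(r_squared, threshold = 0.98) {
  r_squared > threshold
}

#' Neutrality scan over a mutation table
#'
#' Computes per-sample VAFs as `t_alt_count / (t_alt_count + t_ref_count)`
#' (no purity or copy-number correction) and fits the 1/f model for each
#' sample.
#'
#' @param maf MAF-like tibble with read counts (see [read_maf()]).
#' @inheritParams neutral_fit
#' @param threshold Neutrality cut on R-squared (default 0.98).
#' @return A tibble `sample_id`, `r_squared`, `n_in_range`, `neutral`,
#'   `f_min`, `f_max`.
#' @export
neutrality_scan <- function(maf, f_min = 0.12, f_max = 0.24,
                            min_mutations = 10, intercept = TRUE,
                            threshold = 0.98) {
  stopifnot(all(c("sample_id", "t_ref_count", "t_alt_count") %in% names(maf)))
  maf |>
    dplyr::mutate(vaf = .data$t_alt_count /
                    (.data$t_alt_count + .data$t_ref_count)) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      {
        ft <- neutral_fit(.data$vaf, f_min, f_max, min_mutations, intercept)
        tibble::tibble(r_squared = ft$r_squared, n_in_range = ft$n_in_range)
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(neutral = classify_neutral(.data$r_squared, threshold),
                  f_min = f_min, f_max = f_max)
}

#' @export
print.neutral_fit <- function(x, ...) {
  cat(sprintf(
    "<neutral_fit> window [%.3g, %.3g], %d mutation(s) in range, R^2 = %s\n",
    x$f_min, x$f_max, x$n_in_range,
    if (is.na(x$r_squared)) "NA (unevaluable)" else sprintf("%.4f", x$r_squared)
  ))
  invisible(x)
}

#' @method tidy neutral_fit
#' @export
tidy.neutral_fit <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble::tibble(term = character(), estimate = double(),
                          std.error = double()))
  }
  cf <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(term = rownames(cf), estimate = cf[, 1], std.error = cf[, 2])
}

#' @method glance neutral_fit
#' @export
glance.neutral_fit <- function(x, ...) {
  tibble::tibble(
    r_squared = x$r_squared, n_in_range = x$n_in_range,
    n_support_points = nrow(x$curve),
    neutral = classify_neutral(x$r_squared),
    f_min = x$f_min, f_max = x$f_max
  )
}

#' @method autoplot neutral_fit
#' @export
autoplot.neutral_fit <- function(object, ...) {
  p <- ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$inv_f, y = .data$m)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "1 / f", y = "M(f): mutations with VAF >= f",
                  title = sprintf("1/f model fit, R^2 = %s",
                                  ifelse(is.na(object$r_squared), "NA",
                                         sprintf("%.3f", object$r_squared))))
  if (!is.null(object$fit)) {
    p <- p + ggplot2::geom_line(
      ggplot2::aes(y = stats::predict(object$fit)), color = "red")
  }
  p
}
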