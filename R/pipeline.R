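#' Pipeline configuration
#'
#' Collects the input paths and every analysis threshold into a validated
#' list. Unknown keys are rejected so a typo cannot silently fall back to a
#' default. Can be populated from a YAML file via `pipeline_config_from_yaml()`.
#'
#' @param tree_json,maf,seg,features,tumor_types,purity Input file paths
#'   (`purity` and `features`/`tumor_types` optional; enrichment is skipped
#'   without features).
#' @param out_dir Output directory.
#' @param top_fraction Candidate-tree top fraction (default 0.1).
#' @param mut_thr,cna_thr Instability class thresholds (defaults 300, 80).
#' @param gain_thr,loss_thr CNA segment value cuts (defaults 0.3, -0.3).
#' @param neutral_threshold Neutrality R-squared cut (default 0.98).
#' @param f_min,f_max Neutrality VAF window (defaults 0.12, 0.24).
#' @param signature_score_threshold,alteration_score_threshold Enrichment
#'   score cuts (defaults 2.5, 3.0).
#' @param feature_kind How to treat the feature matrix (default
#'   `"signature"`).
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(tree_json, maf, seg, features = NULL,
                            tumor_types = NULL, purity = NULL,
                            out_dir = "clonearch-out",
                            top_fraction = 0.1,
                            mut_thr = 300, cna_thr = 80,
                            gain_thr = 0.3, loss_thr = -0.3,
                            neutral_threshold = 0.98,
                            f_min = 0.12, f_max = 0.24,
                            signature_score_threshold = 2.5,
                            alteration_score_threshold = 3.0,
                            feature_kind = "signature",
                            seed = 1L) {
  stopifnot(top_fraction > 0, top_fraction <= 1,
            mut_thr > 0, cna_thr > 0, gain_thr > 0, loss_thr < 0,
            neutral_threshold > 0, neutral_threshold <= 1,
            f_min > 0, f_min < f_max, f_max <= 1,
            signature_score_threshold > 0, alteration_score_threshold > 0,
            feature_kind %in% c("signature", "alteration"))
  structure(as.list(environment()), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file whose keys are `pipeline_config()` arguments;
#'   unknown keys are an error.
#' @export
pipeline_config_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(pipeline_config)))
  if (length(unknown) > 0) {
    stop("unknown pipeline config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, vals)
}

#' Run the end-to-end cohort analysis
#'
#' Chains the full analysis: candidate trees to likelihood-weighted
#' consensus summaries; mutation and segment tables to burden metrics and
#' instability classes; VAFs to the neutrality fit; and, when a feature
#' matrix is supplied, the clonal/subclonal enrichment scan with
#' per-tumor-type FDR. Writes one TSV per stage plus a run manifest
#' (seed, thresholds, package version) into `out_dir`. Fully deterministic
#' given its inputs.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `cohort_report`: `consensus`, `metrics`,
#'   `neutrality`, `enrichment` (or `NULL`), `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (f in c("tree_json", "maf", "seg")) {
    if (!file.exists(config[[f]])) {
      stop("input file not found: ", f, " = ", config[[f]], call. = FALSE)
    }
  }
  candidates <- read_tree_json(config$tree_json)
  maf <- read_maf(config$maf)
  seg <- read_seg(config$seg)
  purity <- if (!is.null(config$purity)) {
    readr::read_tsv(config$purity, show_col_types = FALSE)
  }
  consensus <- consensus_summary(candidates, config$top_fraction)
  metrics <- sample_metrics(maf, seg, purity, config$mut_thr, config$cna_thr,
                            config$gain_thr, config$loss_thr)
  neutrality <- neutrality_scan(maf, config$f_min, config$f_max,
                                threshold = config$neutral_threshold)
  enrichment <- NULL
  if (!is.null(config$features) && !is.null(config$tumor_types)) {
    features <- read_feature_matrix(config$features)
    types <- readr::read_tsv(config$tumor_types, show_col_types = FALSE)
    dat <- consensus |>
      dplyr::inner_join(types, by = "sample_id") |>
      dplyr::transmute(.data$sample_id, .data$tumor_type,
                       n_clonal = .data$mean_clonal,
                       n_subclonal = .data$mean_subclonal)
    thr <- if (config$feature_kind == "signature") {
      config$signature_score_threshold
    } else {
      config$alteration_score_threshold
    }
    enrichment <- enrichment_scan(dat, features, config$feature_kind,
                                  score_threshold = thr)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_consensus(consensus, file.path(config$out_dir, "consensus.tsv"))
  readr::write_tsv(metrics, file.path(config$out_dir, "sample_metrics.tsv"))
  readr::write_tsv(neutrality, file.path(config$out_dir, "neutrality.tsv"))
  if (!is.null(enrichment)) {
    readr::write_tsv(enrichment, file.path(config$out_dir, "enrichment.tsv"))
  }
  manifest <- list(
    package = "clonearch",
    version = as.character(utils::packageVersion("clonearch")),
    seed = config$seed,
    thresholds = config[c("top_fraction", "mut_thr", "cna_thr", "gain_thr",
                          "loss_thr", "neutral_threshold", "f_min", "f_max",
                          "signature_score_threshold",
                          "alteration_score_threshold")]
  )
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  structure(list(consensus = consensus, metrics = metrics,
                 neutrality = neutrality, enrichment = enrichment,
                 manifest = manifest), class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf(
    "<cohort_report> %d sample(s); enrichment: %s\n",
    nrow(x$consensus),
    if (is.null(x$enrichment)) "not run" else
      sprintf("%d test(s)", nrow(x$enrichment))
  ))
  invisible(x)
}

#' Flag samples whose clone count may be overestimated
#'
#' Subclonal-reconstruction accuracy depends on read depth and on the
#' number of mutations available per clone. Given user-supplied threshold
#' curves -- one per clone count, each a two-column table
#' (`mutations_per_clone`, `min_mean_rms`) interpolated linearly -- a
#' sample falling below its curve is flagged `possibly_overestimated`.
#' No default curves ship with the package (published ones are
#' figure-derived, not printed); with no curve configured every sample is
#' `ok` and a notice is logged once.
#'
#' @param mean_rms Mean reads per mutated site (vectorized).
#' @param mutations_per_clone Mutations divided by inferred clone count.
#' @param n_clones Inferred clone count.
#' @param curves Named list: names are clone counts (as characters), values
#'   two-column data frames `mutations_per_clone`, `min_mean_rms`. A clone
#'   count without a curve uses the largest available count's curve below
#'   it, or none.
#' @return Factor with levels `ok`, `possibly_overestimated`.
#' @export
accuracy_flag <- function(mean_rms, mutations_per_clone, n_clones,
                          curves = NULL) {
  n <- length(mean_rms)
  stopifnot(length(mutations_per_clone) == n, length(n_clones) == n)
  if (is.null(curves) || length(curves) == 0) {
    message("accuracy_flag: no threshold curves configured; all samples ok")
    return(factor(rep("ok", n), levels = c("ok", "possibly_overestimated")))
  }
  avail <- sort(as.integer(names(curves)))
  flag <- vapply(seq_len(n), function(i) {
    usable <- avail[avail <= n_clones[i]]
    if (length(usable) == 0) return("ok")
    cv <- curves[[as.character(max(usable))]]
    thr <- stats::approx(cv$mutations_per_clone, cv$min_mean_rms,
                         xout = mutations_per_clone[i], rule = 2)$y
    if (is.na(mean_rms[i]) || mean_rms[i] >= thr) "ok"
    else "possibly_overestimated"
  }, character(1))
  factor(flag, levels = c("ok", "possibly_overestimated"))
}
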