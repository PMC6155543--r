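#' Read and write candidate tree sets as JSON
#'
#' One JSON document per sample:
#' `{sample_id, candidates: [{cdll, nodes: [{clone_id, parent_id|null,
#' n_mutations, cell_fraction|null}]}]}`. The reader validates every tree
#' against the rooted-tree invariants (unique root, known parents, no
#' cycles) and fails with the offending candidate's position.
#'
#' @param path File path. For `read_tree_json()`, a file holding either one
#'   document or an array of documents.
#' @return `read_tree_json()`: a candidate-set tibble (`sample_id`, `cdll`,
#'   `tree`) covering all samples in the file.
#' @export
read_tree_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.null(doc$sample_id)) doc <- list(doc)
  purrr::map(doc, function(d) {
    if (is.null(d$sample_id) || is.null(d$candidates) ||
        length(d$candidates) == 0) {
      stop("tree JSON document needs sample_id and non-empty candidates",
           call. = FALSE)
    }
    trees <- purrr::imap(d$candidates, function(cand, i) {
      nodes <- purrr::map(cand$nodes, function(nd) {
        tibble::tibble(
          clone_id = as.integer(nd$clone_id),
          parent_id = if (is.null(nd$parent_id)) NA_integer_
                      else as.integer(nd$parent_id),
          n_mutations = as.double(nd$n_mutations),
          cell_fraction = if (is.null(nd$cell_fraction)) NA_real_
                          else as.double(nd$cell_fraction)
        )
      }) |> purrr::list_rbind()
      tryCatch(suppressMessages(clone_tree(nodes)),
               error = function(e) stop(
                 sprintf("sample %s, candidate %d: %s",
                         d$sample_id, i, conditionMessage(e)), call. = FALSE))
    })
    cdll <- purrr::map_dbl(d$candidates, function(cand) {
      if (is.null(cand$cdll) || !is.finite(as.double(cand$cdll))) {
        stop("candidate without finite cdll in sample ", d$sample_id,
             call. = FALSE)
      }
      as.double(cand$cdll)
    })
    candidate_set(d$sample_id, trees, cdll)
  }) |> purrr::list_rbind()
}

#' @rdname read_tree_json
#' @param candidates A candidate-set tibble (possibly several samples).
#' @export
write_tree_json <- function(candidates, path) {
  docs <- candidates |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_map(function(g, key) {
      list(
        sample_id = key$sample_id,
        candidates = purrr::map2(g$tree, g$cdll, function(tr, ll) {
          list(cdll = ll, nodes = purrr::pmap(
            as_tibble(tr),
            function(clone_id, parent_id, n_mutations, cell_fraction) {
              list(clone_id = clone_id,
                   parent_id = if (is.na(parent_id)) NULL else parent_id,
                   n_mutations = n_mutations,
                   cell_fraction = if (is.na(cell_fraction)) NULL
                                   else cell_fraction)
            }))
        })
      )
    })
  jsonlite::write_json(docs, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

maf_col_map <- c(
  sample_id = "Tumor_Sample_Barcode", chromosome = "Chromosome",
  position = "Start_Position", ref_allele = "Reference_Allele",
  alt_allele = "Tumor_Seq_Allele2",
  t_ref_count = "t_ref_count", t_alt_count = "t_alt_count"
)

#' Read and write MAF-like mutation tables
#'
#' Tab-delimited mutation annotation tables with at least the columns
#' `Tumor_Sample_Barcode`, `Chromosome`, `Start_Position` (1-based),
#' `Reference_Allele`, `Tumor_Seq_Allele2`, `t_ref_count`, `t_alt_count`.
#' The reader renames them to the package's tidy names (`sample_id`,
#' `chromosome`, `position`, `ref_allele`, `alt_allele`, `t_ref_count`,
#' `t_alt_count`), validates non-negative read counts and positive
#' positions, and reports offending row numbers.
#'
#' @param path File path.
#' @return A tibble in the tidy column layout above.
#' @export
read_maf <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  missing_cols <- setdiff(unname(maf_col_map), names(raw))
  if (length(missing_cols) > 0) {
    stop("MAF file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- raw[unname(maf_col_map)]
  names(out) <- names(maf_col_map)
  out$position <- as.integer(out$position)
  bad <- which(out$t_ref_count < 0 | out$t_alt_count < 0 | out$position < 1)
  if (length(bad) > 0) {
    stop("MAF file ", path, ": invalid counts/position at data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(out)
}

#' @rdname read_maf
#' @param maf A tidy mutation tibble (see above).
#' @export
write_maf <- function(maf, path) {
  out <- maf[names(maf_col_map)]
  names(out) <- unname(maf_col_map)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read and write SEG copy-number segmentation files
#'
#' Standard segmentation layout: `Sample`, `Chromosome`, `Start`, `End`
#' (1-based inclusive), optional `Num_Probes`, `Segment_Mean`. The reader
#' renames to `sample_id`, `chromosome`, `start`, `end`, `n_probes`,
#' `value` and rejects segments with `start > end`, naming the row.
#'
#' @param path File path.
#' @return A tidy segment tibble.
#' @export
read_seg <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("Sample", "Chromosome", "Start", "End", "Segment_Mean")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop("SEG file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    sample_id = as.character(raw$Sample),
    chromosome = as.character(raw$Chromosome),
    start = as.integer(raw$Start), end = as.integer(raw$End),
    n_probes = if ("Num_Probes" %in% names(raw)) as.integer(raw$Num_Probes)
               else NA_integer_,
    value = as.double(raw$Segment_Mean)
  )
  bad <- which(out$start > out$end | out$start < 1)
  if (length(bad) > 0) {
    stop("SEG file ", path, ": start > end (or start < 1) at data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  out
}

#' @rdname read_seg
#' @param seg A tidy segment tibble.
#' @export
write_seg <- function(seg, path) {
  out <- tibble::tibble(
    Sample = seg$sample_id, Chromosome = seg$chromosome,
    Start = seg$start, End = seg$end,
    Num_Probes = if ("n_probes" %in% names(seg)) seg$n_probes else NA_integer_,
    Segment_Mean = seg$value
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read and write binary feature matrices
#'
#' Samples-by-features TSV: a `sample_id` column plus one column per
#' feature, entries `{0, 1}` (or non-negative scores, which the caller can
#' pass through [binarize_scores()]). Sample and feature labels must be
#' unique.
#'
#' @param path File path.
#' @return A wide tibble.
#' @export
read_feature_matrix <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"sample_id" %in% names(out)) {
    stop("feature matrix ", path, " lacks a sample_id column", call. = FALSE)
  }
  if (anyDuplicated(out$sample_id)) {
    stop("feature matrix ", path, ": duplicate sample_id", call. = FALSE)
  }
  if (anyDuplicated(names(out))) {
    stop("feature matrix ", path, ": duplicate feature names", call. = FALSE)
  }
  vals <- as.matrix(out[setdiff(names(out), "sample_id")])
  if (any(vals < 0, na.rm = TRUE)) {
    stop("feature matrix ", path, ": negative entries", call. = FALSE)
  }
  out
}

#' @rdname read_feature_matrix
#' @param features A wide feature tibble.
#' @export
write_feature_matrix <- function(features, path) {
  readr::write_tsv(features, path)
  invisible(path)
}

#' Read and write per-sample consensus summaries
#'
#' TSV with the columns of [consensus_summary()]: `sample_id`,
#' `mean_n_clones`, `mean_tree_score`, `mean_clonal`, `mean_subclonal`,
#' `n_candidates_used`.
#'
#' @param path File path.
#' @export
read_consensus <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("sample_id", "mean_n_clones", "mean_tree_score", "mean_clonal",
            "mean_subclonal", "n_candidates_used")
  missing_cols <- setdiff(need, names(out))
  if (length(missing_cols) > 0) {
    stop("consensus file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out
}

#' @rdname read_consensus
#' @param consensus A consensus tibble.
#' @export
write_consensus <- function(consensus, path) {
  readr::write_tsv(consensus, path)
  invisible(path)
}

#' Serialize a synthetic cohort bundle to disk
#'
#' Writes every interchange file of a [generate_cohort()] bundle into a
#' directory: `trees.json` (candidate sets), `mutations.maf.tsv`,
#' `segments.seg.tsv`, `features.tsv`, `purity.tsv`, `truth.tsv` and
#' `config.yaml`. All files are plain text and re-read bit-compatibly by
#' the package's strict readers.
#'
#' @param bundle A `cohort_bundle`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tree_json(bundle$candidates, file.path(dir, "trees.json"))
  write_maf(bundle$maf, file.path(dir, "mutations.maf.tsv"))
  write_seg(bundle$seg, file.path(dir, "segments.seg.tsv"))
  write_feature_matrix(bundle$features, file.path(dir, "features.tsv"))
  readr::write_tsv(bundle$purity, file.path(dir, "purity.tsv"))
  readr::write_tsv(bundle$truth, file.path(dir, "truth.tsv"))
  readr::write_tsv(bundle$truth[, c("sample_id", "tumor_type")],
                   file.path(dir, "tumor_types.tsv"))
  cfg <- bundle$config
  cfg$planted_features <- as.list(cfg$planted_features)
  cfg$class_mix <- as.list(cfg$class_mix)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}
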