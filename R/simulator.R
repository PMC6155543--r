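#' Parameters of the branching-process tumor model
#'
#' The simulator is a discrete-time Galton-Watson branching process. At every
#' generation each cell either dies, with probability [death_probability()]
#' `= (1/2) (1 - s)^k` where `k` is its accumulated driver count, or
#' replicates. On replication one of the two daughters acquires a new
#' somatic alteration with probability `mu`; the mutated daughter founds a
#' new clone whether the alteration is a driver or a passenger. Drivers lower
#' the lineage's death probability and so confer a selective advantage;
#' passengers are neutral.
#'
#' @param mu Per-replication mutation probability in `[0, 1]`. Exome-derived
#'   tumor estimates span roughly `1e-7` to `1e-3` per nucleotide-equivalent
#'   replication.
#' @param s Fitness advantage per driver, in `[0, 1)`; literature values
#'   range over `1e-4` to `0.5`.
#' @param K Driver-fraction constant (default 0.025, i.e. roughly 500 driver
#'   genes out of 20,000).
#' @param driver_mode How `K` enters the per-mutation driver probability:
#'   `"conditional_K"` (default) reads `K` as the fraction of new mutations
#'   that are drivers, `P(driver | mutation) = K`; `"conditional_K_mu"` is
#'   the literal product form `P(driver | mutation) = K * mu`, under which
#'   drivers are vanishingly rare at realistic `mu`.
#' @param n_initial Founding cell count (default 1).
#' @param n_max Population size at which growth stops (default `1e5` cells).
#' @param g_max Generation cap (default 2000).
#' @param prevalence_threshold Clone retention floor used downstream by
#'   [extract_phylogeny()] (default 0.01: a clone must hold at least 1% of
#'   cells to be detectable, mirroring the variant-allele-frequency floor of
#'   exome studies).
#' @param condition_on_survival If `TRUE` (default), an extinct run is
#'   restarted with a fresh seed stream, up to `max_attempts` times;
#'   the attempt count is reported so survivorship conditioning is auditable.
#' @param max_attempts Restart budget under `condition_on_survival`.
#' @param seed Integer seed; the full simulation is reproducible given it.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(mu = 1e-4, s = 0.01, K = 0.025,
                       driver_mode = c("conditional_K", "conditional_K_mu"),
                       n_initial = 1L, n_max = 1e5, g_max = 2000L,
                       prevalence_threshold = 0.01,
                       condition_on_survival = TRUE, max_attempts = 100L,
                       seed = 1L) {
  driver_mode <- match.arg(driver_mode)
  stopifnot(mu >= 0, mu <= 1, s >= 0, s < 1, K >= 0,
            n_initial >= 1, n_max >= 1, g_max >= 1,
            prevalence_threshold > 0, prevalence_threshold < 1,
            max_attempts >= 1)
  structure(list(
    mu = mu, s = s, K = K, driver_mode = driver_mode,
    n_initial = as.integer(n_initial), n_max = n_max,
    g_max = as.integer(g_max), prevalence_threshold = prevalence_threshold,
    condition_on_survival = isTRUE(condition_on_survival),
    max_attempts = as.integer(max_attempts), seed = as.integer(seed)
  ), class = "sim_params")
}

#' Death probability of a cell with k drivers
#'
#' `d(k, s) = (1/2) (1 - s)^k`: a driver-free cell dies or replicates with
#' equal probability (a critical process); every accumulated driver lowers
#' the death probability by the factor `(1 - s)`, making the lineage
#' supercritical. The replication probability is the complement.
#'
#' @param k Non-negative driver count (vectorized).
#' @param s Fitness parameter in `[0, 1)`.
#' @return Death probabilities in `(0, 0.5]`.
#' @export
death_probability <- function(k, s) {
  if (any(k < 0)) stop("k must be >= 0", call. = FALSE)
  if (any(s < 0 | s >= 1)) stop("s must lie in [0, 1)", call. = FALSE)
  0.5 * (1 - s)^k
}

#' Simulate tumor growth as a branching process
#'
#' Runs the Galton-Watson model of [sim_params()] with synchronous
#' generations and clone-level bookkeeping: clones (not individual cells)
#' are tracked, with binomial draws for deaths, replications and mutated
#' daughters within each clone, which is exact for the cell-level model
#' because cells of a clone are exchangeable. The run stops when the
#' population reaches `n_max`, at generation `g_max`, or at extinction.
#'
#' @param params A [sim_params()] object.
#' @return An object of class `tumor_sim`: a list with `clones` (tibble of
#'   `clone_id`, `parent_id`, `k_drivers`, `n_private_mutations`,
#'   `cell_count`, including extinct clones at count 0), `generations_run`,
#'   `final_population`, `extinct`, `attempts`, event totals
#'   (`n_replications`, `n_mutation_events`, `n_driver_events`) and the
#'   `params` used. [generics::tidy()] returns the clone table,
#'   [generics::glance()] a one-row summary.
#' @export
simulate_tumor <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  for (attempt in seq_len(if (params$condition_on_survival) params$max_attempts else 1L)) {
    res <- run_gw_once(params, derive_seed(params$seed, attempt))
    res$attempts <- attempt
    if (!res$extinct || !params$condition_on_survival) {
      res$params <- params
      return(structure(res, class = "tumor_sim"))
    }
  }
  stop("tumor went extinct in all ", params$max_attempts,
       " attempts (condition_on_survival)", call. = FALSE)
}

# Deterministic child-seed derivation; keeps values in 32-bit integer range.
derive_seed <- function(seed, ...) {
  ix <- c(seed, ...)
  as.integer(Reduce(function(a, b) (a * 69069 + b * 1234567 + 97) %% 2147483647,
                    as.double(ix), accumulate = FALSE))
}

run_gw_once <- function(p, seed) {
  set.seed(seed)
  p_driver <- switch(p$driver_mode,
                     conditional_K = p$K,
                     conditional_K_mu = p$K * p$mu)
  p_driver <- min(p_driver, 1)
  cap <- 64L
  parent <- rep(NA_integer_, cap)
  kdrv <- integer(cap)
  priv <- integer(cap)
  cells <- numeric(cap)
  n_clones <- 1L
  cells[1] <- p$n_initial
  total <- p$n_initial
  n_repl_total <- 0; n_mut_total <- 0; n_drv_total <- 0
  gen <- 0L
  while (gen < p$g_max && total > 0 && total < p$n_max) {
    gen <- gen + 1L
    ai <- which(cells[seq_len(n_clones)] > 0)
    d <- death_probability(kdrv[ai], p$s)
    deaths <- stats::rbinom(length(ai), cells[ai], d)
    repl <- cells[ai] - deaths
    mut <- if (p$mu > 0) stats::rbinom(length(ai), repl, p$mu) else integer(length(ai))
    cells[ai] <- 2 * repl - mut
    n_repl_total <- n_repl_total + sum(repl)
    n_new <- sum(mut)
    if (n_new > 0) {
      drv <- stats::rbinom(length(ai), mut, p_driver)
      n_drv_total <- n_drv_total + sum(drv)
      n_mut_total <- n_mut_total + n_new
      new_parent <- rep(ai, times = mut)
      new_driver <- rep(rep(c(TRUE, FALSE), length(ai)),
                        times = as.vector(rbind(drv, mut - drv)))
      while (n_clones + n_new > cap) {
        cap <- cap * 2L
        parent <- c(parent, rep(NA_integer_, cap - length(parent)))
        kdrv <- c(kdrv, integer(cap - length(kdrv)))
        priv <- c(priv, integer(cap - length(priv)))
        cells <- c(cells, numeric(cap - length(cells)))
      }
      new_ix <- n_clones + seq_len(n_new)
      parent[new_ix] <- new_parent
      kdrv[new_ix] <- kdrv[new_parent] + new_driver
      priv[new_ix] <- 1L
      cells[new_ix] <- 1
      n_clones <- n_clones + n_new
    }
    total <- sum(cells[seq_len(n_clones)])
  }
  ix <- seq_len(n_clones)
  list(
    clones = tibble::tibble(
      clone_id = ix, parent_id = parent[ix], k_drivers = kdrv[ix],
      n_private_mutations = priv[ix], cell_count = cells[ix]
    ),
    generations_run = gen, final_population = total,
    extinct = total == 0, attempts = 1L,
    n_replications = n_repl_total, n_mutation_events = n_mut_total,
    n_driver_events = n_drv_total
  )
}

#' @export
print.tumor_sim <- function(x, ...) {
  cat(sprintf(
    "<tumor_sim> %d clone(s), %g cells after %d generation(s)%s; attempts: %d\n",
    nrow(x$clones), x$final_population, x$generations_run,
    if (x$extinct) " (extinct)" else "", x$attempts
  ))
  invisible(x)
}

#' @method tidy tumor_sim
#' @export
tidy.tumor_sim <- function(x, ...) x$clones

#' @method glance tumor_sim
#' @export
glance.tumor_sim <- function(x, ...) {
  tibble::tibble(
    n_clones_total = nrow(x$clones),
    final_population = x$final_population,
    generations_run = x$generations_run,
    extinct = x$extinct,
    attempts = x$attempts,
    n_replications = x$n_replications,
    n_mutation_events = x$n_mutation_events,
    n_driver_events = x$n_driver_events
  )
}

#' Extract the detectable clonal phylogeny from a simulation
#'
#' Applies the detection floor of bulk sequencing: only clones holding at
#' least `threshold` (default 1%) of the final population are retained.
#' Each retained non-root clone is re-attached to its nearest retained
#' ancestor, and the private mutations of dropped intermediate ancestors are
#' collapsed into the nearest retained descendant on their path (mutations of
#' dropped terminal lineages are lost, as they would be to the sequencer).
#' If the founding clone itself falls below the floor while several retained
#' lineages survive, the minimal dropped ancestors needed for a single root
#' (the retained set's most recent common ancestor) are kept so the result
#' is a rooted tree.
#'
#' @param result A `tumor_sim` from [simulate_tumor()].
#' @param threshold Retention floor on `cell_count / final_population`.
#' @return A [clone_tree()]; `cell_fraction` holds each clone's share of the
#'   final population (per-clone convention).
#' @export
extract_phylogeny <- function(result, threshold = 0.01) {
  stopifnot(inherits(result, "tumor_sim"))
  if (result$final_population <= 0) {
    stop("cannot extract a phylogeny from an extinct tumor", call. = FALSE)
  }
  cl <- result$clones
  frac <- cl$cell_count / result$final_population
  keep <- frac >= threshold & cl$cell_count > 0
  if (!any(keep)) stop("no clone reaches the prevalence threshold", call. = FALSE)
  keep_ids <- cl$clone_id[keep]
  parent_of <- function(id) cl$parent_id[match(id, cl$clone_id)]
  # orphans = retained clones with no retained ancestor; with > 1 orphan the
  # induced tree would be a forest, so the orphans' MRCA is added back
  find_orphans <- function(ids) {
    ids[vapply(ids, function(id) {
      p <- parent_of(id)
      while (!is.na(p) && !(p %in% ids)) p <- parent_of(p)
      is.na(p)
    }, logical(1))]
  }
  repeat {
    orphan <- find_orphans(keep_ids)
    if (length(orphan) <= 1) break
    anc_paths <- lapply(orphan, function(id) {
      path <- integer(0)
      while (!is.na(id)) { path <- c(path, id); id <- parent_of(id) }
      path
    })
    common <- Reduce(intersect, anc_paths)  # node-to-root order: [1] is the MRCA
    if (length(common) == 0) stop("simulated clones form a forest", call. = FALSE)
    keep_ids <- c(keep_ids, common[1])
  }
  # re-attach and collapse dropped intermediates' private mutations downward
  nearest_kept_anc <- function(id) {
    p <- parent_of(id)
    while (!is.na(p) && !(p %in% keep_ids)) p <- parent_of(p)
    p
  }
  collapsed_mut <- function(id) {
    m <- cl$n_private_mutations[match(id, cl$clone_id)]
    p <- parent_of(id)
    while (!is.na(p) && !(p %in% keep_ids)) {
      m <- m + cl$n_private_mutations[match(p, cl$clone_id)]
      p <- parent_of(p)
    }
    m
  }
  keep_ids <- sort(keep_ids)
  nodes <- tibble::tibble(
    clone_id = keep_ids,
    parent_id = vapply(keep_ids, nearest_kept_anc, integer(1)),
    n_mutations = vapply(keep_ids, collapsed_mut, double(1)),
    cell_fraction = cl$cell_count[match(keep_ids, cl$clone_id)] /
      result$final_population
  )
  clone_tree(nodes, fraction_convention = "clone")
}

#' Sweep the (mu, s) parameter plane
#'
#' Runs [simulate_tumor()] plus [extract_phylogeny()] over a grid of
#' mutation rates and fitness values, with several replicates per grid cell.
#' Replicate seeds are derived deterministically from `(seed, mu index,
#' s index, replicate)`, so any cell can be reproduced in isolation. Grid
#' cells whose restart budget is exhausted by extinction (the near-critical
#' corner of the plane) are recorded as extinct rows with `NA` metrics
#' rather than aborting the sweep.
#'
#' @param mu_grid,s_grid Numeric grids of mutation rates and fitness values.
#' @param replicates Replicates per grid cell.
#' @param base_params A [sim_params()] supplying all other settings.
#' @param seed Master seed for the sweep.
#' @return A tibble with one row per (mu, s, replicate): `n_clones`,
#'   `tree_score`, `clonal`, `subclonal`, `generations`, `final_population`,
#'   `attempts`, `extinct`.
#' @export
parameter_sweep <- function(mu_grid, s_grid, replicates = 10,
                            base_params = sim_params(), seed = 1L) {
  stopifnot(all(mu_grid >= 0 & mu_grid <= 1), all(s_grid >= 0 & s_grid < 1),
            replicates >= 1)
  grid <- tidyr::expand_grid(
    mu_ix = seq_along(mu_grid), s_ix = seq_along(s_grid),
    replicate = seq_len(replicates)
  )
  purrr::pmap(grid, function(mu_ix, s_ix, replicate) {
    p <- base_params
    p$mu <- mu_grid[mu_ix]
    p$s <- s_grid[s_ix]
    p$seed <- derive_seed(seed, mu_ix, s_ix, replicate)
    row <- tibble::tibble(
      mu = p$mu, s = p$s, replicate = replicate,
      n_clones = NA_integer_, tree_score = NA_real_,
      clonal = NA_real_, subclonal = NA_real_,
      generations = NA_integer_, final_population = NA_real_,
      attempts = NA_integer_, extinct = TRUE
    )
    sim <- tryCatch(simulate_tumor(p), error = function(e) NULL)
    if (is.null(sim)) return(row)
    if (sim$extinct) {
      row$generations <- sim$generations_run
      row$final_population <- 0
      row$attempts <- sim$attempts
      return(row)
    }
    phy <- extract_phylogeny(sim, p$prevalence_threshold)
    cs <- clonal_subclonal_counts(phy)
    row$n_clones <- count_clones(phy)
    row$tree_score <- tree_score(phy)
    row$clonal <- cs$clonal
    row$subclonal <- cs$subclonal
    row$generations <- sim$generations_run
    row$final_population <- sim$final_population
    row$attempts <- sim$attempts
    row$extinct <- FALSE
    row
  }) |> purrr::list_rbind()
}
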