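#' Establishment probability across insertion biases
#'
#' For each bias, simulates replicate invasions started from `n0`
#' single-copy insertions (default 10) and records whether at least one TE
#' copy is still present at generation `generations` (default 500) — the
#' operational definition of establishment. The branching-process
#' reference for neutral TEs is `1 - (1 - 2u)^n0`, since a single copy
#' escapes stochastic loss with probability approximately `2u`.
#'
#' @param biases Integer vector of insertion biases to test.
#' @param replicates Replicates per bias.
#' @param params A [sim_params()]; `n0` and `generations` default to the
#'   establishment setup (10 insertions, 500 generations).
#' @param genome A [te_genome()].
#' @param seed Base seed.
#' @return An object of class `te_establishment` with `replicates` (one
#'   row per run) and `summary` (per-bias establishment frequency and the
#'   theoretical reference).
#' @examples
#' \donttest{
#' est <- establishment_experiment(biases = c(-50, 50), replicates = 5,
#'   params = sim_params(N = 100, n0 = 10, generations = 100), seed = 1)
#' est$summary
#' }
#' @export
establishment_experiment <- function(biases = seq(-100, 100, by = 10),
                                     replicates = 100,
                                     params = sim_params(n0 = 10, generations = 500),
                                     genome = te_genome(),
                                     seed = NULL) {
  stopifnot(replicates >= 1)
  seeds <- replicate_seeds(seed, replicates * length(biases))
  grid <- tidyr::expand_grid(bias = as.integer(biases),
                             replicate = seq_len(replicates))
  grid$seed <- seeds

  per_rep <- purrr::pmap(grid, function(bias, replicate, seed) {
    p <- params
    p$bias0 <- bias
    run <- run_invasion(p, genome, seed = seed, stop_at = "generations")
    tibble::tibble(bias = bias, replicate = replicate, seed = seed,
                   status = run$status,
                   generations = run$last_generation,
                   established = run$status != "fail-0",
                   final_mean_n = utils::tail(run$trajectory$mean_n, 1))
  })
  per_rep <- dplyr::bind_rows(per_rep)

  theory <- 1 - (1 - 2 * params$u)^params$n0
  summary <- per_rep |>
    dplyr::group_by(.data$bias) |>
    dplyr::summarise(replicates = dplyr::n(),
                     frequency = mean(.data$established),
                     n_established = sum(.data$established),
                     .groups = "drop") |>
    dplyr::mutate(expected = theory)

  structure(list(replicates = per_rep, summary = summary,
                 expected = theory, params = params, genome = genome),
            class = "te_establishment")
}

#' @export
print.te_establishment <- function(x, ...) {
  cat("<te_establishment> ", nrow(x$summary), " bias value(s), ",
      max(x$summary$replicates), " replicate(s) each; theory = ",
      round(x$expected, 3), "\n", sep = "")
  print(x$summary, n = Inf)
  invisible(x)
}

#' @rdname establishment_experiment
#' @param x A `te_establishment`.
#' @param ... Unused.
#' @export
tidy.te_establishment <- function(x, ...) x$replicates

#' @rdname establishment_experiment
#' @export
glance.te_establishment <- function(x, ...) x$summary

#' Invasion phase summaries across insertion biases
#'
#' Simulates replicate invasions per bias (neutral defaults) and reports,
#' per replicate, the lengths of the rapid and shotgun phases and the mean
#' insertions and cluster insertions per individual at the end of each
#' phase. The rapid phase ends at the first cluster insertion in the
#' population; the shotgun phase ends once every individual carries at
#' least one cluster insertion. Replicates that never complete a phase
#' within the generation cap are flagged `censored`.
#'
#' @param biases Integer vector of insertion biases.
#' @param replicates Replicates per bias.
#' @param params A [sim_params()].
#' @param genome A [te_genome()].
#' @param seed Base seed.
#' @return An object of class `te_invasion_phases` with `replicates` and
#'   per-bias `summary` tibbles.
#' @export
invasion_summary <- function(biases = c(-50, 0, 50), replicates = 100,
                             params = sim_params(), genome = te_genome(),
                             seed = NULL) {
  seeds <- replicate_seeds(seed, replicates * length(biases))
  grid <- tidyr::expand_grid(bias = as.integer(biases),
                             replicate = seq_len(replicates))
  grid$seed <- seeds

  per_rep <- purrr::pmap(grid, function(bias, replicate, seed) {
    p <- params
    p$bias0 <- bias
    run <- run_invasion(p, genome, seed = seed, stop_at = "regulated")
    traj <- run$trajectory
    at <- function(gen, col) {
      if (is.na(gen)) NA_real_ else traj[[col]][match(gen, traj$generation)]
    }
    tibble::tibble(
      bias = bias, replicate = replicate, seed = seed, status = run$status,
      censored = is.na(run$gen_all_regulated),
      rapid_length = run$gen_first_cluster,
      shotgun_length = run$gen_all_regulated - run$gen_first_cluster,
      n_end_rapid = at(run$gen_first_cluster, "mean_n"),
      n_end_shotgun = at(run$gen_all_regulated, "mean_n"),
      cluster_n_end_rapid = at(run$gen_first_cluster, "mean_cluster_n"),
      cluster_n_end_shotgun = at(run$gen_all_regulated, "mean_cluster_n")
    )
  })
  per_rep <- dplyr::bind_rows(per_rep)

  summary <- per_rep |>
    dplyr::filter(!.data$censored) |>
    dplyr::group_by(.data$bias) |>
    dplyr::summarise(dplyr::across(
      c("rapid_length", "shotgun_length", "n_end_rapid", "n_end_shotgun",
        "cluster_n_end_rapid", "cluster_n_end_shotgun"),
      \(v) mean(v, na.rm = TRUE)), .groups = "drop")

  structure(list(replicates = per_rep, summary = summary,
                 params = params, genome = genome),
            class = "te_invasion_phases")
}

#' @export
print.te_invasion_phases <- function(x, ...) {
  cat("<te_invasion_phases> per-bias phase summaries (",
      nrow(x$replicates), " run(s))\n", sep = "")
  print(x$summary, n = Inf)
  invisible(x)
}

#' @rdname invasion_summary
#' @param x A `te_invasion_phases`.
#' @param ... Unused.
#' @export
tidy.te_invasion_phases <- function(x, ...) x$replicates

#' @rdname invasion_summary
#' @export
glance.te_invasion_phases <- function(x, ...) x$summary

#' Fitness burden across a cluster-size by insertion-bias grid
#'
#' Simulates deleterious invasions (`x > 0`) over a grid of per-chromosome
#' piRNA cluster sizes and insertion biases and records, per cell, the
#' minimum over generations of the population mean fitness (`min_w`, the
#' maximum fitness burden of the invasion). Cells are categorised on the
#' fitness palette: `dark-red` (`min_w < 0.01`), `red` (`< 0.1`), `yellow`
#' (`< 0.33`), `green` (recovered/high fitness) — plus `fail-0`
#' (TE lost from the population) and `fail-w` (population extinct).
#'
#' @param clusters_kb Numeric vector of per-chromosome cluster sizes (kb).
#' @param biases Integer vector of insertion biases.
#' @param x Fitness cost per insertion (must be > 0 for a meaningful
#'   sweep).
#' @param replicates Replicates per grid cell.
#' @param params Base [sim_params()]; its `x` is replaced by the `x`
#'   argument and `generations` caps each run.
#' @param chromosomes_mbp,recombination_cm_mb Genome geometry (passed to
#'   [te_genome()] for each cluster size).
#' @param seed Base seed.
#' @return An object of class `te_sweep` with `replicates` (per run) and
#'   `grid` (per cell: mean `min_w`, category, status counts).
#' @export
fitness_sweep <- function(clusters_kb = c(10, 30, 100, 300, 1000),
                          biases = seq(-100, 100, by = 25),
                          x = 0.01, replicates = 10,
                          params = sim_params(generations = 1000),
                          chromosomes_mbp = rep(10, 5),
                          recombination_cm_mb = 4,
                          seed = NULL) {
  if (x <= 0) stop("x: the fitness sweep needs a positive fitness cost", call. = FALSE)
  params$x <- x
  seeds <- replicate_seeds(seed, replicates * length(clusters_kb) * length(biases))
  grid <- tidyr::expand_grid(clusters_kb = clusters_kb,
                             bias = as.integer(biases),
                             replicate = seq_len(replicates))
  grid$seed <- seeds

  per_rep <- purrr::pmap(grid, function(clusters_kb, bias, replicate, seed) {
    genome <- te_genome(chromosomes_mbp, clusters_kb, recombination_cm_mb)
    p <- params
    p$bias0 <- bias
    run <- run_invasion(p, genome, seed = seed, stop_at = "generations")
    tibble::tibble(clusters_kb = clusters_kb, cluster_fraction = genome$f,
                   bias = bias, replicate = replicate, seed = seed,
                   status = run$status, min_w = run$min_mean_w)
  })
  per_rep <- dplyr::bind_rows(per_rep)

  grid_sum <- per_rep |>
    dplyr::group_by(.data$clusters_kb, .data$cluster_fraction, .data$bias) |>
    dplyr::summarise(
      replicates = dplyr::n(),
      n_fail0 = sum(.data$status == "fail-0"),
      n_failw = sum(.data$status == "fail-w"),
      min_w = mean(.data$min_w),
      .groups = "drop") |>
    dplyr::mutate(category = sweep_category(.data$min_w, .data$n_fail0,
                                            .data$n_failw, .data$replicates))

  structure(list(replicates = per_rep, grid = grid_sum,
                 params = params, x = x),
            class = "te_sweep")
}

#' Fitness-palette category for a sweep cell
#'
#' @param min_w Minimum mean population fitness of the cell.
#' @param n_fail0,n_failw Counts of `fail-0` / `fail-w` replicates.
#' @param replicates Total replicates in the cell.
#' @return Factor with levels `fail-w`, `fail-0`, `dark-red`, `red`,
#'   `yellow`, `green`.
#' @export
sweep_category <- function(min_w, n_fail0 = 0, n_failw = 0, replicates = 1) {
  cat <- dplyr::case_when(
    n_failw > replicates / 2 ~ "fail-w",
    n_fail0 > replicates / 2 ~ "fail-0",
    min_w < 0.01 ~ "dark-red",
    min_w < 0.1 ~ "red",
    min_w < 0.33 ~ "yellow",
    TRUE ~ "green"
  )
  factor(cat, levels = c("fail-w", "fail-0", "dark-red", "red", "yellow", "green"))
}

#' @export
print.te_sweep <- function(x, ...) {
  cat("<te_sweep> ", nrow(x$grid), " grid cell(s), x = ", x$x, "\n", sep = "")
  print(table(category = x$grid$category))
  invisible(x)
}

#' @rdname fitness_sweep
#' @param object,x A `te_sweep`.
#' @param ... Unused.
#' @export
tidy.te_sweep <- function(x, ...) x$replicates

#' @rdname fitness_sweep
#' @export
glance.te_sweep <- function(x, ...) x$grid
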