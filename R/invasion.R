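STATUS_LEVELS <- c("ongoing", "inactive", "fail-0", "fail-w")

#' Simulate one TE invasion
#'
#' Runs an individual-based forward simulation of a TE invasion under the
#' trap model. Each generation: individual fitness `w = 1 - x n` (floored
#' at 0, optionally excluding cluster insertions and/or adding `beta` per
#' cluster copy) determines mating probability (fecundity selection,
#' hermaphrodites, selfing allowed); each offspring receives one gamete
#' from each of two independently drawn parents; a gamete is formed by
#' random assortment and Poisson crossovers per chromosome, followed by
#' transposition: `Poisson(u n / 2)` new copies, each inheriting the bias
#' of a donor copy drawn uniformly from the parent's `n` insertions and
#' placed by the biased site sampler. Individuals carrying at least one
#' cluster insertion transpose at rate 0 (silencing in trans). New
#' insertions landing on an occupied gamete site are discarded.
#'
#' The run records, per generation, mean diploid copy number, mean cluster
#' insertions, mean and minimum individual fitness, the fraction of
#' regulated individuals (carrying >= 1 cluster insertion), and whether a
#' cluster insertion is fixed (present on >= 1 haplotype of every
#' individual at the same position).
#'
#' Terminal states: `fail-0` (no TE copies left), `fail-w` (no individual
#' with positive fitness; population extinct), `inactive` (a cluster
#' insertion reached fixation, when `stop_at = "fixation"`), otherwise
#' `ongoing` at the generation cap.
#'
#' @param params A [sim_params()].
#' @param genome A [te_genome()].
#' @param seed Optional integer seed (calls `set.seed()`).
#' @param base_population Optional tibble with columns `haplotype`
#'   (1..2N), `position`, `bias`, e.g. from [read_base_population()]. When
#'   `NULL`, `n0` insertions with bias `bias0` are placed at random.
#' @param track_bias Optional integer vector of bias values whose
#'   per-individual copy numbers are reported as extra trajectory columns
#'   (used by the competition experiment).
#' @param stop_at When to stop: `"fixation"` (default; first fixation of a
#'   cluster insertion ends the run as `inactive`), `"regulated"` (stop
#'   once every individual is regulated; an efficiency device for phase
#'   summaries) or `"generations"` (always run to the generation cap
#'   unless a fail state occurs).
#' @return An object of class `te_invasion` with elements `trajectory`
#'   (tibble, one row per generation with a `phase` column), `status`,
#'   `gen_first_cluster`, `gen_all_regulated`, `gen_fixation` (NA if not
#'   reached), `min_mean_w`, `params`, `genome`.
#' @examples
#' inv <- run_invasion(sim_params(N = 100, generations = 50), te_genome(), seed = 1)
#' glance(inv)
#' @export
run_invasion <- function(params, genome = te_genome(), seed = NULL,
                         base_population = NULL, track_bias = NULL,
                         stop_at = c("fixation", "regulated", "generations")) {
  stopifnot(inherits(params, "te_params"), inherits(genome, "te_genome"))
  stop_at <- match.arg(stop_at)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(base_population)) {
    base_population <- random_base_population(params, genome)
  }
  bp <- check_base_population(base_population, params$N, genome)
  if (genome$cluster_bp == 0 &&
      (length(params$bias0) > 0 && any(params$bias0 == 100)) && nrow(bp) > 0) {
    stop("bias = 100 requires a genome with at least one piRNA cluster", call. = FALSE)
  }
  track_bias <- unique(as.integer(track_bias %||% integer()))
  stop_mode <- switch(stop_at, generations = 0L, regulated = 1L, fixation = 2L)

  res <- run_invasion_cpp(
    as.integer(genome$chrom_bounds),
    as.integer(genome$clusters$start), as.integer(genome$clusters$end),
    as.numeric(genome$xover_lambda),
    params$N, params$u, params$x, params$cluster_neutral, params$beta,
    params$generations, stop_mode,
    as.integer(bp$haplotype) - 1L, as.integer(bp$position), as.integer(bp$bias),
    track_bias
  )

  cols <- c("generation", "mean_n", "mean_cluster_n", "total_cluster_n",
            "mean_w", "min_w", "frac_regulated", "fixed")
  if (length(track_bias) > 0) cols <- c(cols, paste0("n_bias_", track_bias))
  traj <- tibble::as_tibble(setNames(as.data.frame(res$trajectory), cols))
  traj$generation <- as.integer(traj$generation)
  traj$fixed <- traj$fixed > 0

  gen_first_cluster <- if (res$first_cluster_gen < 0) NA_integer_ else res$first_cluster_gen
  gen_all_regulated <- if (res$all_regulated_gen < 0) NA_integer_ else res$all_regulated_gen
  gen_fixation <- if (res$fixation_gen < 0) NA_integer_ else res$fixation_gen

  traj$phase <- classify_phase(traj$generation, gen_first_cluster, gen_all_regulated)

  structure(
    list(
      trajectory = traj,
      status = STATUS_LEVELS[res$status + 1L],
      gen_first_cluster = gen_first_cluster,
      gen_all_regulated = gen_all_regulated,
      gen_fixation = gen_fixation,
      last_generation = as.integer(res$last_gen),
      min_mean_w = min(traj$mean_w),
      params = params,
      genome = genome
    ),
    class = "te_invasion"
  )
}

#' Classify invasion phases from first-passage generations
#'
#' An invasion is in the `rapid` phase while the population carries no
#' cluster insertion, in the `shotgun` phase from the first cluster
#' insertion until TE regulation is established in every individual
#' (everyone carries >= 1 cluster insertion), and `inactive` thereafter.
#'
#' @param generation Integer vector of generations to classify.
#' @param gen_first_cluster Generation of the first cluster insertion
#'   (NA if none yet).
#' @param gen_all_regulated First generation at which every individual is
#'   regulated (NA if not reached).
#' @return Factor with levels `rapid`, `shotgun`, `inactive`.
#' @export
classify_phase <- function(generation, gen_first_cluster, gen_all_regulated) {
  phase <- rep("rapid", length(generation))
  if (!is.na(gen_first_cluster)) phase[generation >= gen_first_cluster] <- "shotgun"
  if (!is.na(gen_all_regulated)) phase[generation >= gen_all_regulated] <- "inactive"
  factor(phase, levels = c("rapid", "shotgun", "inactive"))
}

#' @export
print.te_invasion <- function(x, ...) {
  cat("<te_invasion> status: ", x$status, ", ", x$last_generation,
      " generation(s)\n", sep = "")
  cat("  first cluster insertion: ", x$gen_first_cluster,
      "; all regulated: ", x$gen_all_regulated,
      "; fixation: ", x$gen_fixation, "\n", sep = "")
  cat("  final mean copies/individual: ",
      round(utils::tail(x$trajectory$mean_n, 1), 2),
      "; min mean fitness: ", round(x$min_mean_w, 4), "\n", sep = "")
  invisible(x)
}

#' @rdname run_invasion
#' @param x A `te_invasion` object.
#' @param ... Unused.
#' @export
tidy.te_invasion <- function(x, ...) x$trajectory

#' @rdname run_invasion
#' @export
glance.te_invasion <- function(x, ...) {
  traj <- x$trajectory
  last <- traj[nrow(traj), ]
  tibble::tibble(
    status = x$status,
    generations = x$last_generation,
    gen_first_cluster = x$gen_first_cluster,
    gen_all_regulated = x$gen_all_regulated,
    gen_fixation = x$gen_fixation,
    rapid_length = x$gen_first_cluster,
    shotgun_length = x$gen_all_regulated - x$gen_first_cluster,
    min_mean_w = x$min_mean_w,
    final_mean_n = last$mean_n,
    final_mean_cluster_n = last$mean_cluster_n
  )
}

#' Simulate replicate TE invasions
#'
#' Runs [run_invasion()] `replicates` times. Per-replicate seeds are drawn
#' once from `seed` (via `sample.int()` after `set.seed(seed)`), so any
#' replicate can be re-run individually and the whole set is reproducible.
#'
#' @inheritParams run_invasion
#' @param replicates Number of replicate invasions.
#' @param seed Integer base seed for the replicate set.
#' @return An object of class `te_invasion_set`: list of `te_invasion`
#'   runs plus a `summary` tibble (one row per replicate).
#' @examples
#' set <- simulate_invasions(sim_params(N = 100, generations = 30),
#'                           replicates = 2, seed = 7)
#' glance(set)
#' @export
simulate_invasions <- function(params, genome = te_genome(), replicates = 100,
                               seed = NULL, base_population = NULL,
                               track_bias = NULL,
                               stop_at = c("fixation", "regulated", "generations")) {
  stop_at <- match.arg(stop_at)
  seeds <- replicate_seeds(seed, replicates)
  runs <- purrr::map(seq_len(replicates), function(r) {
    run_invasion(params, genome, seed = seeds[r],
                 base_population = base_population, track_bias = track_bias,
                 stop_at = stop_at)
  })
  summary <- dplyr::bind_rows(purrr::map(runs, glance))
  summary <- dplyr::mutate(summary, replicate = dplyr::row_number(),
                           seed = seeds, .before = 1)
  structure(list(runs = runs, summary = summary, params = params, genome = genome),
            class = "te_invasion_set")
}

replicate_seeds <- function(seed, replicates) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(.Machine$integer.max, replicates)
}

#' @export
print.te_invasion_set <- function(x, ...) {
  cat("<te_invasion_set> ", length(x$runs), " replicate invasion(s)\n", sep = "")
  print(table(status = x$summary$status))
  invisible(x)
}

#' @rdname simulate_invasions
#' @param x A `te_invasion_set`.
#' @param ... Unused.
#' @export
tidy.te_invasion_set <- function(x, ...) {
  dplyr::bind_rows(
    purrr::imap(x$runs, function(run, r) {
      dplyr::mutate(run$trajectory, replicate = r, .before = 1)
    })
  )
}

#' @rdname simulate_invasions
#' @export
glance.te_invasion_set <- function(x, ...) x$summary

`%||%` <- function(a, b) if (is.null(a)) b else a
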