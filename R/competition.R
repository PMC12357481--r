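#' Scaled competition statistic
#'
#' Compares the mean copy numbers of two co-invading TEs:
#' \deqn{S = 2 Y / (X + Y) - 1}
#' where `X` is the mean total copy number of the more cluster-biased TE
#' and `Y` that of the less biased TE. `S = 1` means only the less biased
#' TE persists, `S = -1` only the more biased TE, `S = 0` equal copy
#' numbers. When both are extinct (`X + Y = 0`) the outcome is `NA`
#' (absent), not 0.
#'
#' @param X Mean copy number of the more biased TE.
#' @param Y Mean copy number of the less biased TE.
#' @return Numeric in \[-1, 1\], or `NA` if `X + Y == 0`.
#' @examples
#' competition_statistic(0, 5)   #  1
#' competition_statistic(3, 1)   # -0.5
#' @export
competition_statistic <- function(X, Y) {
  ifelse(X + Y > 0, 2 * Y / (X + Y) - 1, NA_real_)
}

competition_scenarios <- list(
  A = list(selection = 0,    chromosomes_mbp = rep(10, 5), clusters_kb = 300, rr = 4),
  B = list(selection = 0,    chromosomes_mbp = 10,         clusters_kb = 300, rr = 0),
  C = list(selection = 0.01, chromosomes_mbp = rep(10, 5), clusters_kb = 300, rr = 4),
  D = list(selection = 0.01, chromosomes_mbp = 10,         clusters_kb = 300, rr = 0)
)

#' Pairwise competition between TEs of different insertion biases
#'
#' Two TE types that differ only in insertion bias jointly invade one
#' population: `copies_per_te` copies of each are placed at random
#' positions on random haplotypes, and an insertion of either TE into a
#' piRNA cluster silences both (shared piRNA-mediated silencing). After
#' `generations` (default 500) the mean per-individual copy number of each
#' type is recorded and scaled into [competition_statistic()].
#'
#' Four standard scenarios cover the selection-by-recombination design:
#' * `A`: neutral, 5 recombining chromosomes (4 cM/Mbp), 5 clusters;
#' * `B`: neutral, 1 chromosome, 1 cluster, no recombination;
#' * `C`: selection (x = 0.01), 5 recombining chromosomes;
#' * `D`: selection (x = 0.01), 1 chromosome, no recombination.
#'
#' All scenarios use N = 1000, u = 0.1 and one 300 kb cluster per
#' chromosome.
#'
#' @param bias_pairs Two-column data frame (or matrix) of bias pairs; the
#'   first column is the more cluster-biased TE, the second the less
#'   biased one. Defaults to all ordered pairs over a step-20 grid.
#' @param scenario One of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param replicates Replicates per pair.
#' @param copies_per_te Starting copies of each TE type.
#' @param params Base [sim_params()] (N, u, generation cap); selection and
#'   geometry come from the scenario.
#' @param seed Base seed.
#' @return An object of class `te_competition` with `replicates` (per-run
#'   X, Y) and `pairs` (per-pair means and `S`, with an `absent` flag).
#' @examples
#' \donttest{
#' comp <- competition_experiment(data.frame(bias_high = 50, bias_low = 0),
#'   scenario = "A", replicates = 3,
#'   params = sim_params(N = 100, generations = 100), seed = 1)
#' comp$pairs
#' }
#' @export
competition_experiment <- function(bias_pairs = NULL,
                                   scenario = c("A", "B", "C", "D"),
                                   replicates = 100,
                                   copies_per_te = 100,
                                   params = sim_params(generations = 500),
                                   seed = NULL) {
  scenario <- match.arg(scenario)
  sc <- competition_scenarios[[scenario]]
  genome <- te_genome(sc$chromosomes_mbp, sc$clusters_kb, sc$rr)
  params$x <- sc$selection

  if (is.null(bias_pairs)) {
    b <- seq(-100, 100, by = 20)
    bias_pairs <- tidyr::expand_grid(bias_high = b, bias_low = b) |>
      dplyr::filter(.data$bias_high >= .data$bias_low)
  }
  bias_pairs <- tibble::as_tibble(as.data.frame(bias_pairs))
  names(bias_pairs)[1:2] <- c("bias_high", "bias_low")
  if (any(bias_pairs$bias_high < bias_pairs$bias_low)) {
    stop("bias_pairs: first column must be the more cluster-biased TE", call. = FALSE)
  }

  seeds <- replicate_seeds(seed, nrow(bias_pairs) * replicates)
  grid <- tidyr::expand_grid(pair = seq_len(nrow(bias_pairs)),
                             replicate = seq_len(replicates))
  grid$seed <- seeds

  per_rep <- purrr::pmap(grid, function(pair, replicate, seed) {
    bh <- bias_pairs$bias_high[pair]
    bl <- bias_pairs$bias_low[pair]
    set.seed(seed)
    base <- competition_base_population(copies_per_te, c(bh, bl), params$N, genome)
    run <- run_invasion(params, genome, seed = NULL, base_population = base,
                        track_bias = c(bh, bl), stop_at = "generations")
    traj <- run$trajectory
    last <- traj[nrow(traj), ]
    if (bh == bl) {
      # indistinguishable types: the tracked class holds both; split evenly
      X <- last[[paste0("n_bias_", bh)]] / 2
      Y <- X
    } else {
      X <- last[[paste0("n_bias_", bh)]]
      Y <- last[[paste0("n_bias_", bl)]]
    }
    tibble::tibble(bias_high = bh, bias_low = bl, replicate = replicate,
                   seed = seed, status = run$status,
                   generations = run$last_generation, X = X, Y = Y)
  })
  per_rep <- dplyr::bind_rows(per_rep)

  pairs <- per_rep |>
    dplyr::group_by(.data$bias_high, .data$bias_low) |>
    dplyr::summarise(replicates = dplyr::n(),
                     X = mean(.data$X), Y = mean(.data$Y), .groups = "drop") |>
    dplyr::mutate(S = competition_statistic(.data$X, .data$Y),
                  absent = .data$X + .data$Y == 0)

  structure(list(replicates = per_rep, pairs = pairs, scenario = scenario,
                 params = params, genome = genome),
            class = "te_competition")
}

# copies_per_te insertions of each bias class on random haplotypes at
# random positions; collisions resampled
competition_base_population <- function(copies_per_te, biases, N, genome) {
  n <- copies_per_te * length(biases)
  hap <- sample.int(2L * N, n, replace = TRUE)
  pos <- as.integer(floor(stats::runif(n) * genome$g))
  repeat {
    dup <- duplicated(paste(hap, pos))
    if (!any(dup)) break
    pos[dup] <- as.integer(floor(stats::runif(sum(dup)) * genome$g))
  }
  tibble::tibble(haplotype = hap, position = pos,
                 bias = rep(as.integer(biases), each = copies_per_te))
}

#' @export
print.te_competition <- function(x, ...) {
  cat("<te_competition> scenario ", x$scenario, ", ",
      nrow(x$pairs), " bias pair(s)\n", sep = "")
  print(x$pairs, n = min(nrow(x$pairs), 20))
  invisible(x)
}

#' @rdname competition_experiment
#' @param x A `te_competition`.
#' @param ... Unused.
#' @export
tidy.te_competition <- function(x, ...) x$replicates

#' @rdname competition_experiment
#' @export
glance.te_competition <- function(x, ...) x$pairs
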