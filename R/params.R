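#' Simulation parameters for one TE invasion scenario
#'
#' Bundles the population-genetic parameters of a single scenario. Defaults
#' follow the standard invasion setup: N = 1000 diploids, transposition rate
#' u = 0.1 per copy per generation, neutral insertions (x = 0), a base
#' population of 100 randomly placed unbiased insertions, and up to 5000
#' generations.
#'
#' @param N Diploid population size (constant across generations).
#' @param u Transposition rate: probability per TE copy per generation of
#'   producing a new insertion. Set to 0 in individuals carrying a cluster
#'   insertion (trap model silencing).
#' @param x Fitness cost per insertion; individual fitness is
#'   `w = 1 - x * n` (floored at 0). `x = 0` gives neutral runs.
#' @param cluster_neutral If `TRUE`, cluster insertions are excluded from
#'   the fitness cost (they still silence).
#' @param beta Optional additive fitness benefit per cluster insertion
#'   (default 0, i.e. disabled).
#' @param generations Maximum number of generations to simulate.
#' @param n0 Number of TE insertions in the base population (each on one
#'   random haplotype, i.e. starting frequency 1/(2N)).
#' @param bias0 Insertion bias of the starting insertions (single value or
#'   length `n0`).
#' @return An object of class `te_params`.
#' @examples
#' sim_params()               # default neutral invasion scenario
#' sim_params(x = 0.01)       # deleterious insertions
#' @export
sim_params <- function(N = 1000, u = 0.1, x = 0, cluster_neutral = FALSE,
                       beta = 0, generations = 5000, n0 = 100, bias0 = 0) {
  if (length(N) != 1 || N < 1 || N != round(N)) {
    stop("N: population size must be a positive integer", call. = FALSE)
  }
  if (length(u) != 1 || u < 0) stop("u: transposition rate must be >= 0", call. = FALSE)
  if (length(x) != 1 || x < 0) stop("x: fitness cost must be >= 0", call. = FALSE)
  if (length(generations) != 1 || generations < 1) {
    stop("generations: must be >= 1", call. = FALSE)
  }
  if (length(n0) != 1 || n0 < 0 || n0 != round(n0)) {
    stop("n0: number of starting insertions must be a non-negative integer", call. = FALSE)
  }
  if (any(bias0 < -100 | bias0 > 100)) {
    stop("bias0: insertion bias must lie in [-100, 100]", call. = FALSE)
  }
  if (!(length(bias0) == 1 || length(bias0) == n0)) {
    stop("bias0: give one bias or one per starting insertion", call. = FALSE)
  }
  structure(
    list(N = as.integer(N), u = u, x = x,
         cluster_neutral = isTRUE(cluster_neutral), beta = beta,
         generations = as.integer(generations),
         n0 = as.integer(n0), bias0 = as.integer(round(bias0))),
    class = "te_params"
  )
}

#' @export
print.te_params <- function(x, ...) {
  cat("<te_params> N = ", x$N, ", u = ", x$u, ", x = ", x$x,
      if (x$cluster_neutral) ", cluster insertions neutral" else "",
      if (x$beta != 0) paste0(", beta = ", x$beta) else "",
      "\n  generations <= ", x$generations,
      ", n0 = ", x$n0, ", bias0 = ",
      if (length(x$bias0) == 1) x$bias0 else "(per insertion)", "\n", sep = "")
  invisible(x)
}
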