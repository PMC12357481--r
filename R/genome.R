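#' Genome architecture for TE invasion simulations
#'
#' Defines the coordinate system of the simulated genome: chromosomes tile
#' the half-open interval `[0, g)` contiguously, and each chromosome may
#' carry one piRNA cluster anchored at its left end. The genomic cluster
#' fraction `f` (total cluster bp / genome size) is always derived from this
#' geometry, never supplied directly, so configurations cannot be
#' inconsistent.
#'
#' The default genome mirrors a typical simulation setup for a
#' Drosophila-like genome: five chromosome arms of 10 Mbp each, one 300 kb
#' piRNA cluster per arm (f = 0.03) and a recombination rate of 4 cM/Mbp.
#'
#' @param chromosomes_mbp Numeric vector of chromosome lengths in Mbp.
#' @param clusters_kb Numeric vector of piRNA cluster sizes in kb, one per
#'   chromosome (recycled if length 1). Use 0 for chromosomes without a
#'   cluster.
#' @param recombination_cm_mb Recombination rate in cM/Mbp per chromosome
#'   (recycled if length 1). 0 disables crossovers; chromosomes still
#'   assort independently.
#'
#' @return An object of class `te_genome`: a list with chromosome bounds
#'   (bp), a tibble of cluster intervals, per-chromosome crossover
#'   expectations, genome size `g`, total cluster bp and cluster fraction
#'   `f`.
#'
#' @examples
#' gen <- te_genome()
#' gen$f # 0.03
#' te_genome(chromosomes_mbp = 10, clusters_kb = 300, recombination_cm_mb = 0)
#' @export
te_genome <- function(chromosomes_mbp = rep(10, 5),
                      clusters_kb = 300,
                      recombination_cm_mb = 4) {
  if (length(chromosomes_mbp) < 1 || any(chromosomes_mbp <= 0)) {
    stop("chromosomes_mbp: need at least one chromosome of positive length", call. = FALSE)
  }
  nchrom <- length(chromosomes_mbp)
  clusters_kb <- rep_len(clusters_kb, nchrom)
  recombination_cm_mb <- rep_len(recombination_cm_mb, nchrom)
  if (any(clusters_kb < 0)) stop("clusters_kb: cluster sizes must be >= 0", call. = FALSE)
  if (any(recombination_cm_mb < 0)) stop("recombination_cm_mb: rates must be >= 0", call. = FALSE)

  chrom_bp <- as.integer(round(chromosomes_mbp * 1e6))
  cluster_bp <- as.integer(round(clusters_kb * 1e3))
  if (any(cluster_bp > chrom_bp)) {
    stop("clusters_kb: a piRNA cluster cannot be larger than its chromosome", call. = FALSE)
  }
  bounds <- c(0L, cumsum(chrom_bp))
  g <- bounds[nchrom + 1]

  # one cluster anchored at the left end of each chromosome
  keep <- cluster_bp > 0L
  clusters <- tibble::tibble(
    chromosome = seq_len(nchrom)[keep],
    start = bounds[seq_len(nchrom)][keep],
    end = bounds[seq_len(nchrom)][keep] + cluster_bp[keep]
  )
  total_cluster <- sum(as.numeric(cluster_bp))
  if (total_cluster >= as.numeric(g)) {
    stop("clusters_kb: clusters must cover less than the whole genome (f < 1)", call. = FALSE)
  }

  structure(
    list(
      chromosomes_mbp = chromosomes_mbp,
      clusters_kb = clusters_kb,
      recombination_cm_mb = recombination_cm_mb,
      chrom_bounds = bounds,
      clusters = clusters,
      xover_lambda = recombination_cm_mb * chromosomes_mbp / 100,
      g = g,
      cluster_bp = as.integer(total_cluster),
      f = total_cluster / as.numeric(g)
    ),
    class = "te_genome"
  )
}

#' @export
print.te_genome <- function(x, ...) {
  cat("<te_genome> ", length(x$chromosomes_mbp), " chromosome(s), g = ",
      format(x$g, big.mark = ","), " bp\n", sep = "")
  cat("  clusters: ", nrow(x$clusters), " interval(s), ",
      format(x$cluster_bp, big.mark = ","), " bp (f = ",
      signif(x$f, 4), ")\n", sep = "")
  cat("  recombination: ", paste(x$recombination_cm_mb, collapse = ", "),
      " cM/Mbp\n", sep = "")
  invisible(x)
}

#' Probability that a biased TE insertion lands in a piRNA cluster
#'
#' Transforms an insertion bias `b` in \[-100, 100\] and a genomic cluster
#' fraction `f` into the probability `p_c` that a new insertion falls inside
#' a piRNA cluster:
#' \deqn{a = (b/100 + 1)/2, \quad s = a f + (1 - a)(1 - f), \quad p_c = a f / s}
#' At `b = 0` this reduces to `p_c = f` (insertion proportional to cluster
#' size); `b = -100` gives 0 (complete avoidance) and `b = +100` gives 1
#' (cluster-only insertion). `p_c` is strictly increasing in `b` for
#' `0 < f < 1`.
#'
#' @param bias Integer insertion bias (vectorised), in \[-100, 100\].
#' @param f Genomic cluster fraction in `[0, 1)`.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @examples
#' cluster_probability(0, 0.03)    # 0.03
#' cluster_probability(100, 0.035) # 1
#' cluster_probability(c(-50, 50), 0.03)
#' @export
cluster_probability <- function(bias, f) {
  if (length(f) != 1 || !is.finite(f) || f < 0 || f >= 1) {
    stop("f: cluster fraction must be a single value in [0, 1)", call. = FALSE)
  }
  if (any(!is.finite(bias)) || any(bias < -100) || any(bias > 100)) {
    stop("bias: insertion bias must lie in [-100, 100]", call. = FALSE)
  }
  a <- (bias / 100 + 1) / 2
  s <- a * f + (1 - a) * (1 - f)
  if (any(s == 0)) {
    # only reachable at b = 100 with f = 0: all insertions targeted at
    # clusters but no cluster bp exists
    stop("bias = 100 with f = 0: cluster-only insertion into a genome without clusters", call. = FALSE)
  }
  a * f / s
}

#' Does a genomic position fall inside a piRNA cluster?
#'
#' @param position Integer vector of 0-based genomic positions in `[0, g)`.
#' @param genome A [te_genome()].
#' @return Logical vector.
#' @examples
#' gen <- te_genome()
#' is_cluster(c(0, 300000), gen) # TRUE, FALSE (half-open intervals)
#' @export
is_cluster <- function(position, genome) {
  stopifnot(inherits(genome, "te_genome"))
  if (any(position < 0 | position >= genome$g)) {
    stop("position: outside the genome interval [0, g)", call. = FALSE)
  }
  is_cluster_cpp(as.integer(position), as.integer(genome$chrom_bounds),
                 as.integer(genome$clusters$start), as.integer(genome$clusters$end))
}

#' Map positions to chromosomes
#'
#' @inheritParams is_cluster
#' @return Integer vector of 1-based chromosome indices.
#' @export
position_chromosome <- function(position, genome) {
  stopifnot(inherits(genome, "te_genome"))
  if (any(position < 0 | position >= genome$g)) {
    stop("position: outside the genome interval [0, g)", call. = FALSE)
  }
  findInterval(position, genome$chrom_bounds, rightmost.closed = FALSE, left.open = FALSE)
}

#' Sample insertion sites for a TE with a given insertion bias
#'
#' With probability `p_c(bias, f)` a site is drawn uniformly from cluster
#' bp, otherwise uniformly from non-cluster bp (see
#' [cluster_probability()]).
#'
#' @param n Number of sites to draw.
#' @param bias Insertion bias in \[-100, 100\] (single value).
#' @param genome A [te_genome()].
#' @return Integer vector of `n` positions in `[0, g)`.
#' @examples
#' set.seed(1)
#' mean(is_cluster(sample_insertion_sites(1e4, 0, te_genome()), te_genome())) # ~0.03
#' @export
sample_insertion_sites <- function(n, bias, genome) {
  stopifnot(inherits(genome, "te_genome"))
  if (length(bias) != 1 || bias < -100 || bias > 100) {
    stop("bias: insertion bias must be a single value in [-100, 100]", call. = FALSE)
  }
  if (genome$cluster_bp == 0 && bias == 100) {
    stop("bias = 100 requires a genome with at least one piRNA cluster", call. = FALSE)
  }
  sample_sites_cpp(as.integer(n), as.integer(bias),
                   as.integer(genome$chrom_bounds),
                   as.integer(genome$clusters$start), as.integer(genome$clusters$end))
}
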