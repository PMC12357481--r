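#' Random base population of TE insertions
#'
#' Places `n0` insertions on haplotypes drawn uniformly from the 2N
#' haplotypes of the population, at positions drawn uniformly from
#' `[0, g)`. Each insertion therefore starts at population frequency
#' 1/(2N). Collisions (same haplotype, same position) are resampled.
#'
#' @param params A [sim_params()] (supplies `N`, `n0`, `bias0`).
#' @param genome A [te_genome()].
#' @return A tibble with columns `haplotype` (1..2N), `position`, `bias`.
#' @examples
#' set.seed(1)
#' random_base_population(sim_params(n0 = 5), te_genome())
#' @export
random_base_population <- function(params, genome) {
  stopifnot(inherits(params, "te_params"), inherits(genome, "te_genome"))
  n0 <- params$n0
  if (n0 == 0) {
    return(tibble::tibble(haplotype = integer(), position = integer(), bias = integer()))
  }
  hap <- sample.int(2L * params$N, n0, replace = TRUE)
  pos <- as.integer(floor(stats::runif(n0) * genome$g))
  repeat {
    dup <- duplicated(paste(hap, pos))
    if (!any(dup)) break
    pos[dup] <- as.integer(floor(stats::runif(sum(dup)) * genome$g))
  }
  tibble::tibble(haplotype = hap, position = pos,
                 bias = as.integer(rep_len(params$bias0, n0)))
}

#' Read a base population from a TSV file
#'
#' The file gives the position and bias of each starting TE insertion, one
#' row per insertion: a headered TSV with columns `position`, `bias` and
#' optionally `haplotype` (1..2N). When the haplotype column is omitted,
#' insertions are assigned to haplotypes uniformly at random, so each
#' single-copy row starts at frequency 1/(2N).
#'
#' @param path Path to the TSV file.
#' @param N Diploid population size the insertions are placed into.
#' @param genome A [te_genome()] (for position validation).
#' @return A tibble with columns `haplotype`, `position`, `bias`.
#' @export
read_base_population <- function(path, N, genome) {
  stopifnot(inherits(genome, "te_genome"))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = NA, check.names = TRUE)
  if (!all(c("position", "bias") %in% names(df))) {
    stop("base population file: need columns 'position' and 'bias'", call. = FALSE)
  }
  pos <- as.integer(df$position)
  bias <- as.integer(df$bias)
  if (any(is.na(pos)) || any(pos < 0 | pos >= genome$g)) {
    stop("base population file: position outside [0, g)", call. = FALSE)
  }
  if (any(is.na(bias)) || any(bias < -100 | bias > 100)) {
    stop("base population file: bias outside [-100, 100]", call. = FALSE)
  }
  if ("haplotype" %in% names(df)) {
    hap <- as.integer(df$haplotype)
    if (any(is.na(hap)) || any(hap < 1 | hap > 2L * N)) {
      stop("base population file: haplotype index outside 1..2N", call. = FALSE)
    }
  } else {
    hap <- sample.int(2L * N, length(pos), replace = TRUE)
  }
  if (anyDuplicated(paste(hap, pos))) {
    stop("base population file: duplicate (haplotype, position)", call. = FALSE)
  }
  tibble::tibble(haplotype = hap, position = pos, bias = bias)
}

check_base_population <- function(base_population, N, genome) {
  bp <- tibble::as_tibble(base_population)
  if (!all(c("haplotype", "position", "bias") %in% names(bp))) {
    stop("base_population: need columns haplotype, position, bias", call. = FALSE)
  }
  if (nrow(bp) > 0) {
    if (any(bp$haplotype < 1 | bp$haplotype > 2L * N)) {
      stop("base_population: haplotype index outside 1..2N", call. = FALSE)
    }
    if (any(bp$position < 0 | bp$position >= genome$g)) {
      stop("base_population: position outside [0, g)", call. = FALSE)
    }
    if (any(bp$bias < -100 | bp$bias > 100)) {
      stop("base_population: bias outside [-100, 100]", call. = FALSE)
    }
    if (anyDuplicated(paste(bp$haplotype, bp$position))) {
      stop("base_population: duplicate (haplotype, position)", call. = FALSE)
    }
    if (genome$cluster_bp == 0 && any(bp$bias == 100)) {
      stop("base_population: bias = 100 requires a genome with clusters", call. = FALSE)
    }
  }
  bp
}
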