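#' Read a simulation configuration file
#'
#' Configurations are flat `key: value` text (YAML syntax). Recognised
#' keys and their defaults:
#'
#' ```
#' N: 1000            # diploid population size
#' u: 0.1             # transposition rate / copy / generation
#' x: 0               # fitness cost per insertion (0 = neutral)
#' cluster_neutral: false
#' beta: 0            # fitness benefit per cluster insertion
#' generations: 5000
#' n0: 100            # starting insertions (ignored with base_population)
#' bias0: 0
#' replicates: 100
#' seed: 1
#' chromosomes: [10, 10, 10, 10, 10]   # Mbp
#' clusters: [300, 300, 300, 300, 300] # kb, one per chromosome
#' rr: [4, 4, 4, 4, 4]                 # cM/Mbp, one per chromosome
#' base_population: path/to/insertions.tsv   # optional
#' ```
#'
#' Missing keys take the defaults above; an empty file reproduces the
#' standard invasion scenario. Validation errors name the offending field.
#'
#' @param path Path to the config file, or `NULL` for pure defaults.
#' @return A list with elements `params` ([sim_params()]), `genome`
#'   ([te_genome()]), `replicates`, `seed`, `base_population` (path or
#'   `NULL`).
#' @export
read_sim_config <- function(path = NULL) {
  cfg <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config: file not found: ", path, call. = FALSE)
    # keep booleans as strings so YAML 1.1 does not turn the key "N" (or a
    # value like "y") into a logical; flags are coerced explicitly below
    cfg <- yaml::read_yaml(path, handlers = list(
      "bool#yes" = function(x) x, "bool#no" = function(x) x))
    if (is.null(cfg)) cfg <- list()
  }
  # "package"/"version" let a run manifest be re-read as a config
  known <- c("N", "u", "x", "cluster_neutral", "beta", "generations", "n0",
             "bias0", "replicates", "seed", "chromosomes", "clusters", "rr",
             "base_population", "package", "version")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    stop("config: unknown field(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  get <- function(key, default) cfg[[key]] %||% default
  as_flag <- function(v) {
    if (is.logical(v)) return(isTRUE(v))
    tolower(as.character(v)) %in% c("true", "yes", "on", "y")
  }
  params <- sim_params(
    N = get("N", 1000), u = get("u", 0.1), x = get("x", 0),
    cluster_neutral = as_flag(get("cluster_neutral", FALSE)), beta = get("beta", 0),
    generations = get("generations", 5000),
    n0 = get("n0", 100), bias0 = get("bias0", 0)
  )
  chromosomes <- get("chromosomes", rep(10, 5))
  genome <- te_genome(
    chromosomes_mbp = chromosomes,
    clusters_kb = get("clusters", 300),
    recombination_cm_mb = get("rr", 4)
  )
  replicates <- get("replicates", 100)
  if (replicates < 1) stop("config: replicates must be >= 1", call. = FALSE)
  list(params = params, genome = genome,
       replicates = as.integer(replicates),
       seed = cfg$seed, base_population = cfg$base_population)
}

#' Write replicate trajectories and a run manifest
#'
#' Writes one TSV per replicate (`trajectory_<r>.tsv`, the per-generation
#' summary), a run-level `status.tsv` (replicate, seed, status, stop
#' generation, phase lengths, min mean fitness) and a `manifest.yml` with
#' the fully resolved configuration, seed and package version, so a run
#' can be re-launched from its manifest.
#'
#' @param set A `te_invasion_set` from [simulate_invasions()].
#' @param dir Output directory (created if missing).
#' @param seed The base seed used for the set (recorded in the manifest).
#' @return Invisibly, the paths written.
#' @export
write_invasion_set <- function(set, dir, seed = NULL) {
  stopifnot(inherits(set, "te_invasion_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (r in seq_along(set$runs)) {
    p <- file.path(dir, sprintf("trajectory_%03d.tsv", r))
    readr::write_tsv(set$runs[[r]]$trajectory, p)
    paths <- c(paths, p)
  }
  status_path <- file.path(dir, "status.tsv")
  readr::write_tsv(set$summary, status_path)
  manifest_path <- file.path(dir, "manifest.yml")
  write_run_manifest(manifest_path, set$params, set$genome,
                     replicates = length(set$runs), seed = seed)
  invisible(c(paths, status_path, manifest_path))
}

write_run_manifest <- function(path, params, genome, replicates, seed = NULL) {
  manifest <- list(
    package = "trapsim",
    version = as.character(utils::packageVersion("trapsim")),
    N = params$N, u = params$u, x = params$x,
    cluster_neutral = params$cluster_neutral, beta = params$beta,
    generations = params$generations, n0 = params$n0,
    bias0 = params$bias0,
    chromosomes = genome$chromosomes_mbp,
    clusters = genome$clusters_kb,
    rr = genome$recombination_cm_mb,
    replicates = replicates,
    seed = seed
  )
  yaml::write_yaml(manifest, path)
  invisible(path)
}
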