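# Small fixtures shared across tests; everything is built in code.

# 1 chromosome of 1 Mbp with a 30 kb cluster (f = 0.03); cheap to simulate
tiny_genome <- function(rr = 4) {
  te_genome(chromosomes_mbp = 1, clusters_kb = 30, recombination_cm_mb = rr)
}

# cluster-free genome (f = 0): transposition is never silenced
free_genome <- function(mbp = 10, rr = 4) {
  te_genome(chromosomes_mbp = mbp, clusters_kb = 0, recombination_cm_mb = rr)
}

# base population with every insertion placed explicitly
base_pop <- function(haplotype, position, bias = 0) {
  tibble::tibble(haplotype = as.integer(haplotype),
                 position = as.integer(position),
                 bias = as.integer(rep_len(bias, length(position))))
}

# 3 binomial standard errors around p for n draws
binom_3se <- function(p, n) 3 * sqrt(p * (1 - p) / n)
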