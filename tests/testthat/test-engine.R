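test_that("fitness is linear in copy number and respects the neutral-cluster flag", {
  gen <- tiny_genome()
  # individual 1: 10 non-cluster insertions on haplotype 1; individual 2 empty
  pos10 <- seq(500000L, 509000L, by = 1000L)
  bp <- base_pop(haplotype = rep(1L, 10), position = pos10)
  p <- sim_params(N = 2, u = 0, x = 0.01, n0 = 0, generations = 1)
  run <- run_invasion(p, gen, seed = 1, base_population = bp,
                      stop_at = "generations")
  g0 <- run$trajectory[1, ]
  expect_equal(g0$min_w, 0.9)          # w = 1 - 0.01 * 10
  expect_equal(g0$mean_w, (0.9 + 1) / 2)
  # neutral runs: x = 0 gives w = 1 regardless of copy number
  p0 <- sim_params(N = 2, u = 0, x = 0, n0 = 0, generations = 1)
  run0 <- run_invasion(p0, gen, seed = 1, base_population = bp,
                       stop_at = "generations")
  expect_equal(run0$trajectory$mean_w[1], 1)
  expect_equal(run0$min_mean_w, 1)
  # cluster insertions excluded from the cost when flagged neutral
  bp_cl <- base_pop(haplotype = c(1L, 1L), position = c(100L, 500000L))
  pn <- sim_params(N = 2, u = 0, x = 0.1, cluster_neutral = TRUE,
                   n0 = 0, generations = 1)
  runn <- run_invasion(pn, gen, seed = 1, base_population = bp_cl,
                       stop_at = "generations")
  expect_equal(runn$trajectory$min_w[1], 0.9) # only the non-cluster copy costs
  # per-cluster-copy benefit adds beta
  pb <- sim_params(N = 2, u = 0, x = 0, beta = 0.05, n0 = 0, generations = 1)
  runb <- run_invasion(pb, gen, seed = 1, base_population = bp_cl,
                       stop_at = "generations")
  expect_equal(runb$trajectory$mean_w[1], (1.05 + 1) / 2)
})

test_that("parents are drawn proportionally to fitness, with degenerate cases", {
  # two individuals, w = 0.9 and 0.3: first parent chosen ~75% of the time
  set.seed(501)
  draws <- trapsim:::sample_parents_cpp(c(0.9, 0.3), 1e5)
  expect_lt(abs(mean(draws == 1) - 0.75), binom_3se(0.75, 1e5))
  # equal fitness: uniform choice
  draws <- trapsim:::sample_parents_cpp(rep(1, 4), 4e4)
  expect_true(all(abs(tabulate(draws, 4) / 4e4 - 0.25) < binom_3se(0.25, 4e4)))
  # single survivor: all offspring descend from it (selfing)
  draws <- trapsim:::sample_parents_cpp(c(0, 0.5, 0), 1000)
  expect_true(all(draws == 2))
  # nobody viable: fail-w
  expect_error(trapsim:::sample_parents_cpp(c(0, 0), 10), "fail-w")
})

test_that("gametes inherit one haplotype per chromosome when recombination is off", {
  gen <- tiny_genome(rr = 0)
  posA <- c(1000L, 2000L, 3000L)
  posB <- c(500000L, 600000L)
  set.seed(502)
  sawA <- FALSE; sawB <- FALSE
  for (i in 1:50) {
    gam <- trapsim:::make_gamete_cpp(posA, rep(0L, 3), posB, rep(0L, 2),
                                     gen$chrom_bounds, gen$clusters$start,
                                     gen$clusters$end, gen$xover_lambda, 0)
    expect_true(identical(gam$position, posA) || identical(gam$position, posB))
    if (identical(gam$position, posA)) sawA <- TRUE else sawB <- TRUE
  }
  expect_true(sawA && sawB)
})

test_that("recombined gametes only carry parental insertions, in order", {
  gen <- te_genome(chromosomes_mbp = c(1, 1), clusters_kb = 0,
                   recombination_cm_mb = 100) # ~1 crossover per Mbp
  set.seed(503)
  posA <- sort(sample.int(2e6, 30) - 1L)
  posB <- sort(sample.int(2e6, 30) - 1L)
  for (i in 1:30) {
    gam <- trapsim:::make_gamete_cpp(posA, rep(0L, 30), posB, rep(0L, 30),
                                     gen$chrom_bounds, gen$clusters$start,
                                     gen$clusters$end, gen$xover_lambda, 0)
    expect_true(all(gam$position %in% c(posA, posB)))
    expect_true(!is.unsorted(gam$position, strictly = TRUE))
  }
})

test_that("transposition adds Poisson(u n / 2) copies and respects the trap", {
  gen <- tiny_genome(rr = 0)
  # parent with n = 10 identical haplotypes: inherited part is always the
  # same 5 positions, so new copies are countable
  pos5 <- c(600000L, 650000L, 700000L, 750000L, 800000L)
  set.seed(504)
  extra <- replicate(2e4, {
    gam <- trapsim:::make_gamete_cpp(pos5, rep(0L, 5), pos5, rep(0L, 5),
                                     gen$chrom_bounds, gen$clusters$start,
                                     gen$clusters$end, gen$xover_lambda, 0.1)
    length(gam$position) - 5L
  })
  lambda <- 0.1 * 10 / 2
  expect_lt(abs(mean(extra) - lambda), 3 * sqrt(lambda / 2e4))
  # empty parent makes an empty gamete
  gam0 <- trapsim:::make_gamete_cpp(integer(), integer(), integer(), integer(),
                                    gen$chrom_bounds, gen$clusters$start,
                                    gen$clusters$end, gen$xover_lambda, 0.5)
  expect_length(gam0$position, 0)
  # trap property: a parent carrying a cluster insertion never transposes,
  # even at an extreme transposition rate
  pos_cl <- c(100L, pos5) # 100 is inside the cluster [0, 30000)
  for (i in 1:200) {
    gam <- trapsim:::make_gamete_cpp(pos_cl, rep(0L, 6), pos5, rep(0L, 5),
                                     gen$chrom_bounds, gen$clusters$start,
                                     gen$clusters$end, gen$xover_lambda, 10)
    expect_true(all(gam$position %in% c(pos_cl, pos5)))
  }
})

test_that("gamete sites are unique (occupied sites discard new insertions)", {
  gen <- te_genome(chromosomes_mbp = 0.001, clusters_kb = 0,
                   recombination_cm_mb = 0) # 1000 bp genome forces collisions
  pos <- seq(0L, 999L, by = 10L) # 100 copies on each haplotype
  set.seed(505)
  for (i in 1:50) {
    gam <- trapsim:::make_gamete_cpp(pos, rep(0L, 100), pos, rep(0L, 100),
                                     gen$chrom_bounds, gen$clusters$start,
                                     gen$clusters$end, gen$xover_lambda, 1)
    expect_false(any(duplicated(gam$position)))
    expect_true(all(gam$position >= 0 & gam$position < 1000))
  }
})

test_that("a single neutral insertion is a martingale across one generation", {
  gen <- free_genome(mbp = 1)
  p <- sim_params(N = 50, u = 0, x = 0, n0 = 1, generations = 1)
  set.seed(506)
  seeds <- sample.int(.Machine$integer.max, 3000)
  counts <- vapply(seeds, function(s) {
    run <- run_invasion(p, gen, seed = s, stop_at = "generations")
    utils::tail(run$trajectory$mean_n, 1) * 50
  }, numeric(1))
  # copy count after one generation has mean 1 (WF binomial sampling)
  expect_lt(abs(mean(counts) - 1), 3 * sd(counts) / sqrt(3000))
})

test_that("early copy-number growth approximates the (1 + u) rate without clusters", {
  gen <- free_genome()
  p <- sim_params(N = 1000, u = 0.1, x = 0, n0 = 200, generations = 10)
  set.seed(507)
  rates <- replicate(5, {
    run <- run_invasion(p, gen, stop_at = "generations")
    traj <- run$trajectory
    mean(diff(log(traj$mean_n)))
  })
  expect_lt(abs(mean(rates) - log(1 + 0.1)), 0.03)
})

test_that("terminal states: fail-0 without insertions, fail-w without viable parents", {
  gen <- tiny_genome()
  r0 <- run_invasion(sim_params(N = 10, n0 = 0, generations = 100), gen, seed = 1)
  expect_equal(r0$status, "fail-0")
  expect_equal(nrow(r0$trajectory), 1)
  # every individual overloaded with deleterious copies: w = 0 for all
  bp <- base_pop(haplotype = rep(1:4, each = 50),
                 position = rep(seq(40000L, 89000L, by = 1000L), 4))
  pw <- sim_params(N = 2, u = 0, x = 0.02, n0 = 0, generations = 100)
  rw <- run_invasion(pw, gen, seed = 1, base_population = bp,
                     stop_at = "generations")
  expect_equal(rw$status, "fail-w")
})

test_that("phase classification follows first cluster insertion and full regulation", {
  expect_equal(as.character(classify_phase(0:5, NA_integer_, NA_integer_)),
               rep("rapid", 6))
  expect_equal(as.character(classify_phase(0:5, 2L, 4L)),
               c("rapid", "rapid", "shotgun", "shotgun", "inactive", "inactive"))
  # one segregating cluster insertion: shotgun from generation 0
  gen <- tiny_genome()
  bp <- base_pop(haplotype = 1L, position = 100L) # inside the cluster
  p <- sim_params(N = 20, u = 0, x = 0, n0 = 0, generations = 2)
  run <- run_invasion(p, gen, seed = 3, base_population = bp,
                      stop_at = "generations")
  expect_equal(run$gen_first_cluster, 0L)
  expect_equal(as.character(run$trajectory$phase[1]), "shotgun")
})

test_that("an invasion stops as inactive when a cluster insertion fixes", {
  gen <- tiny_genome()
  # cluster insertion on one haplotype of every individual: fixed at entry
  bp <- base_pop(haplotype = seq(1L, 39L, by = 2L), position = 100L)
  p <- sim_params(N = 20, u = 0.1, x = 0, n0 = 0, generations = 50)
  run <- run_invasion(p, gen, seed = 4, base_population = bp,
                      stop_at = "fixation")
  expect_equal(run$status, "inactive")
  expect_equal(run$gen_fixation, 0L)
  expect_equal(run$gen_all_regulated, 0L)
  expect_true(run$trajectory$fixed[1])
  # homozygous fixation cannot be lost: run to the cap, silent throughout
  bp2 <- base_pop(haplotype = 1:40, position = 100L)
  run2 <- run_invasion(p, gen, seed = 4, base_population = bp2,
                       stop_at = "generations")
  expect_equal(nrow(run2$trajectory), 51)
  expect_true(all(run2$trajectory$fixed))
  expect_true(all(run2$trajectory$mean_n == 2)) # trap: no transposition ever
})

test_that("seeded runs are exactly reproducible and seeds matter", {
  gen <- tiny_genome()
  p <- sim_params(N = 50, u = 0.1, x = 0, n0 = 20, generations = 40)
  r1 <- run_invasion(p, gen, seed = 99, stop_at = "generations")
  r2 <- run_invasion(p, gen, seed = 99, stop_at = "generations")
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(glance(r1), glance(r2))
  r3 <- run_invasion(p, gen, seed = 100, stop_at = "generations")
  expect_false(identical(r1$trajectory, r3$trajectory))
  # replicate sets reproduce too
  s1 <- simulate_invasions(p, gen, replicates = 3, seed = 7, stop_at = "generations")
  s2 <- simulate_invasions(p, gen, replicates = 3, seed = 7, stop_at = "generations")
  expect_identical(tidy(s1), tidy(s2))
})

test_that("competition-mode tracking splits copy numbers by bias class", {
  gen <- tiny_genome()
  bp <- base_pop(haplotype = c(1L, 2L, 3L), position = c(500000L, 600000L, 700000L),
                 bias = c(-50L, -50L, 50L))
  p <- sim_params(N = 10, u = 0, x = 0, n0 = 0, generations = 1)
  run <- run_invasion(p, gen, seed = 5, base_population = bp,
                      track_bias = c(-50L, 50L), stop_at = "generations")
  g0 <- run$trajectory[1, ]
  expect_equal(g0[["n_bias_-50"]], 2 / 10)
  expect_equal(g0[["n_bias_50"]], 1 / 10)
  expect_equal(g0$mean_n, 3 / 10)
})
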