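# ga_optimizer: operators, loop, reproducibility

test_that("initialization: determinism, flat individual, genome lengths", {
  g <- pupil_grid(36)
  spec <- genome_spec("segment", segment_layout(3, g), grid = g)
  cfg <- ga_config(population_size = 6, rng_seed = 7)
  set.seed(1); p1 <- initialize_population(cfg, spec)
  set.seed(1); p2 <- initialize_population(cfg, spec)
  expect_identical(p1, p2)
  expect_equal(length(p1), 6)
  # 9x9 layout -> genome length 81
  expect_equal(length(p1[[2]]$segment_levels), 81)
  expect_true(all(vapply(p1, function(x)
    all(x$segment_levels >= 0 & x$segment_levels <= 255), logical(1))))
  # flat individual is always seeded
  expect_true(all(p1[[1]]$segment_levels == 0))
  # mixed mode carries both parts
  spec_m <- genome_spec("mixed", segment_layout(1, g), 4:9, g)
  pm <- initialize_population(cfg, spec_m)
  expect_equal(length(pm[[2]]$segment_levels), 9)
  expect_equal(length(pm[[2]]$zernike_coeffs), 6)
  expect_error(genome_spec("zernike", zernike_modes = 1:5, grid = g),
               "piston")
})

test_that("rank-weighted selection matches the multinomial oracle", {
  cfg <- ga_config(population_size = 6, n_parents = 4, rng_seed = 1)
  fit <- c(0.1, 0.9, 0.4, 0.7, 0.2, 0.05)   # ranks: 2 6 4 5 3 1
  set.seed(99)
  n_draw <- 20000
  pairs <- select_parents(fit, cfg, n_draw)
  expect_true(all(pairs[, 1] != pairs[, 2]))
  # only the top-4 individuals (2,4,3,5) can be parents
  expect_true(all(pairs %in% c(2, 3, 4, 5)))
  # first-slot marginal is rank-proportional over the pool
  w <- c(6, 5, 4, 3); w <- w / sum(w)         # ranks of 2,4,3,5
  counts <- table(factor(pairs[, 1], levels = c(2, 4, 3, 5)))
  p_hat <- as.numeric(counts) / n_draw
  se <- sqrt(w * (1 - w) / n_draw)
  expect_true(all(abs(p_hat - w) < 3.5 * se))
  # best individual is the most frequent parent overall
  expect_equal(as.integer(names(which.max(table(pairs)))), 2L)
  # population of 2: the single possible distinct pair
  cfg2 <- ga_config(population_size = 2, n_parents = 2, elitism = 1)
  pr <- select_parents(c(0.2, 0.8), cfg2, 5)
  expect_true(all(apply(pr, 1, sort) == c(1, 2)))
  expect_error(select_parents(c(0.1, NA, 0.3), cfg, 1), "non-finite")
})

test_that("uniform crossover: identity, gene provenance, inheritance fraction", {
  g <- pupil_grid(36)
  spec <- genome_spec("segment", segment_layout(3, g), grid = g)
  set.seed(5)
  cfg <- ga_config(population_size = 4)
  pop <- initialize_population(cfg, spec)
  a <- pop[[2]]; b <- pop[[3]]
  expect_identical(crossover(a, a), a)
  off <- crossover(a, b)
  expect_true(all(off$segment_levels == a$segment_levels |
                    off$segment_levels == b$segment_levels))
  # inheritance fraction over ~10^4 genes: binomial oracle
  set.seed(6)
  tot <- 0; from_a <- 0
  for (k in 1:124) {     # 124 * 81 = 10044 genes
    o <- crossover(a, b)
    diffgene <- a$segment_levels != b$segment_levels
    tot <- tot + sum(diffgene)
    from_a <- from_a + sum(o$segment_levels[diffgene] ==
                             a$segment_levels[diffgene])
  }
  expect_lt(abs(from_a / tot - 0.5), 0.015)
  expect_error(crossover(a, pop[[1]][c("mode", "zernike_coeffs")]), "structure")
})

test_that("mutation: schedule endpoints, bounds, empirical rate", {
  g <- pupil_grid(36)
  spec <- genome_spec("segment", segment_layout(3, g), grid = g)
  genome <- initialize_population(ga_config(population_size = 4), spec)[[2]]
  cfg0 <- ga_config(mutation_rate_initial = 0, mutation_rate_final = 0)
  expect_identical(mutate(genome, 0, cfg0), genome)
  cfg1 <- ga_config(mutation_rate_initial = 1, mutation_rate_final = 1)
  set.seed(2)
  m1 <- mutate(genome, 0, cfg1)
  expect_true(all(m1$segment_levels >= 0 & m1$segment_levels <= 255))
  # empirical mutation fraction at g=0 ~ R_initial (binomial oracle)
  cfg <- ga_config(mutation_rate_initial = 0.1, mutation_rate_final = 0.013)
  set.seed(3)
  hits <- 0; tot <- 0
  for (k in 1:1235) {    # ~10^5 genes
    m <- mutate(genome, 0, cfg)
    ch <- m$segment_levels != genome$segment_levels
    hits <- hits + sum(ch); tot <- tot + length(ch)
  }
  # a uniform resample leaves the gene unchanged with prob 1/256
  p_eff <- 0.1 * 255 / 256
  se <- sqrt(p_eff * (1 - p_eff) / tot)
  expect_lt(abs(hits / tot - p_eff), 3 * se)
  expect_error(mutate(genome, -1, cfg), "generation")
})

test_that("run_ga finds the optimum of a separable toy fitness", {
  g <- pupil_grid(36)
  spec <- genome_spec("segment", segment_layout(1, g), grid = g)  # 9 genes
  toy <- function(genome) -sum((genome$segment_levels - 100)^2)
  cfg <- ga_config(population_size = 20, n_generations = 300, n_parents = 10,
                   rng_seed = 4, stop_patience = 300)
  res <- run_ga(toy, cfg, spec)
  # unique optimum at all-100; GA should come within a few levels per gene
  expect_lt(mean(abs(res$best$segment_levels - 100)), 8)
  expect_gt(res$best_fitness, -9 * 15^2)
  # noise-free elitist monotonicity
  expect_true(all(diff(res$trace$best) >= 0))
  # trace bookkeeping
  expect_equal(res$trace$evaluations[nrow(res$trace)], res$n_evaluations)
})

test_that("seeded runs are bit-identical", {
  g <- pupil_grid(36)
  spec <- genome_spec("zernike", zernike_modes = 4:9, grid = g)
  scr <- make_screen(screen_recipe("zernike_random", 1.0, 4:9, rng_seed = 3), g)
  fit <- ga_fitness(spec, scr)
  cfg <- ga_config(population_size = 10, n_generations = 15, n_parents = 5,
                   rng_seed = 123)
  r1 <- run_ga(fit, cfg, spec)
  r2 <- run_ga(fit, cfg, spec)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$best, r2$best)
})

test_that("run_ga aborts with a diagnostic on non-finite fitness", {
  g <- pupil_grid(36)
  spec <- genome_spec("segment", segment_layout(1, g), grid = g)
  bad <- function(genome) if (genome$segment_levels[1] > 200) NaN else 1
  cfg <- ga_config(population_size = 10, n_generations = 5, rng_seed = 1)
  expect_error(run_ga(bad, cfg, spec), "non-finite fitness")
})

test_that("correction_from_genome: zero, pure-Zernike, mixed composition", {
  g <- pupil_grid(36)
  lay <- segment_layout(1, g)
  spec <- genome_spec("mixed", lay, 4:9, g)
  z <- correction_from_genome(
    structure(list(mode = "mixed", segment_levels = rep(0L, 9),
                   zernike_coeffs = rep(0, 6)), class = "genome"), spec)
  expect_equal(z, matrix(0, 36, 36))
  cf <- c(0.5, 0, -0.2, 0, 0, 0.1)
  gz <- structure(list(mode = "mixed", segment_levels = rep(0L, 9),
                       zernike_coeffs = cf), class = "genome")
  expect_equal(correction_from_genome(gz, spec),
               zernike_phase(setNames(cf, 4:9), g), tolerance = 1e-12)
  gm <- structure(list(mode = "mixed",
                       segment_levels = sample(0:255, 9),
                       zernike_coeffs = cf), class = "genome")
  expect_equal(correction_from_genome(gm, spec),
               segment_phase(gm$segment_levels, lay, g) +
                 zernike_phase(setNames(cf, 4:9), g), tolerance = 1e-12)
})

test_that("convergence-vs-segments: coarser layout converges at least as well on a fixed budget", {
  g <- pupil_grid(72)
  scr <- make_screen(screen_recipe("zernike_random", 1.0, 4:11, rng_seed = 8), g)
  run_seg <- function(n_seg) {
    spec <- genome_spec("segment", segment_layout(n_seg, g), grid = g)
    cfg <- ga_config(population_size = 20, n_generations = 40,
                     n_parents = 10, rng_seed = 17, stop_patience = 40)
    run_ga(ga_fitness(spec, scr), cfg, spec)$best_fitness
  }
  f36 <- run_seg(2)    # 36 segments
  f144 <- run_seg(4)   # 144 segments
  expect_gte(f36, f144)
})
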