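#' Genome specification
#'
#' Declares the search encoding: piecewise-constant SLM segments
#' ("segment"), Zernike coefficients ("zernike"), or their sum ("mixed") —
#' the three encodings used for system vs full (sample) aberration
#' correction. The decode of any genome is deterministic: segment levels map
#' to 2*pi*L/256 block phases, Zernike coefficients to an RMS-normalized
#' modal sum; mixed genomes add both.
#'
#' @param mode "segment", "zernike" or "mixed".
#' @param layout a [segment_layout()] (segment/mixed modes).
#' @param zernike_modes integer vector of Noll indices (zernike/mixed modes);
#'   default 4:15 — piston, tip and tilt are excluded because they do not
#'   change the focal intensity pattern.
#' @param grid a [pupil_grid()].
#' @return object of class `genome_spec` with a precomputed Zernike basis for
#'   fast decoding.
#' @export
genome_spec <- function(mode = c("segment", "zernike", "mixed"),
                        layout = NULL, zernike_modes = 4:15,
                        grid = pupil_grid()) {
  mode <- match.arg(mode)
  if (mode %in% c("segment", "mixed")) {
    if (is.null(layout)) layout <- segment_layout(3L, grid)
    if (layout$n_pixels != grid$n_pixels)
      stop("segment layout does not match grid")
  } else layout <- NULL
  if (mode %in% c("zernike", "mixed")) {
    if (any(zernike_modes < 2)) stop("piston (j=1) is excluded from genomes")
    basis <- zernike_basis(zernike_modes, grid)
  } else { zernike_modes <- integer(0); basis <- NULL }
  structure(list(mode = mode, layout = layout,
                 zernike_modes = as.integer(zernike_modes),
                 basis = basis, grid = grid),
            class = "genome_spec")
}

genome_lengths <- function(spec) {
  c(segment = if (is.null(spec$layout)) 0L else spec$layout$n_segments,
    zernike = length(spec$zernike_modes))
}

new_genome <- function(spec, segment_levels = NULL, zernike_coeffs = NULL) {
  len <- genome_lengths(spec)
  if (len["segment"] > 0) {
    if (is.null(segment_levels)) segment_levels <- rep(0L, len["segment"])
    if (length(segment_levels) != len["segment"])
      stop("segment_levels must have length ", len["segment"])
    if (any(segment_levels < 0 | segment_levels > 255))
      stop("segment levels must be in [0, 255]")
  } else segment_levels <- integer(0)
  if (len["zernike"] > 0) {
    if (is.null(zernike_coeffs)) zernike_coeffs <- rep(0, len["zernike"])
    if (length(zernike_coeffs) != len["zernike"])
      stop("zernike_coeffs must have length ", len["zernike"])
  } else zernike_coeffs <- numeric(0)
  structure(list(mode = spec$mode,
                 segment_levels = as.integer(round(segment_levels)),
                 zernike_coeffs = as.numeric(zernike_coeffs)),
            class = "genome")
}

#' Decode a genome into its correction phase mask
#'
#' Segment part: level L -> 2*pi*L/256 over the segment's pixel block.
#' Zernike part: RMS-normalized modal sum. Mixed genomes compose both.
#' The result is ready to compose with the spiral and blazed-grating masks,
#' and exportable as an 8-bit image via [quantize_mask()] +
#' [write_mask_bmp()].
#'
#' @param genome a genome (from [run_ga()] or [initialize_population()]).
#' @param spec the matching [genome_spec()].
#' @return phase matrix in radians (unwrapped Zernike part; wrap at use).
#' @export
correction_from_genome <- function(genome, spec) {
  stopifnot(inherits(genome, "genome"), inherits(spec, "genome_spec"))
  grid <- spec$grid
  out <- matrix(0, grid$n_pixels, grid$n_pixels)
  if (length(genome$segment_levels) > 0)
    out <- out + segment_phase(genome$segment_levels, spec$layout, grid)
  if (length(genome$zernike_coeffs) > 0) {
    zp <- matrix(0, grid$n_pixels, grid$n_pixels)
    zp[grid$aperture] <- as.vector(spec$basis %*% genome$zernike_coeffs)
    out <- out + zp
  }
  out
}

# correction phase restricted to aperture pixels (fast path for engines)
decode_aperture <- function(genome, spec) {
  ap <- spec$grid$aperture
  out <- numeric(sum(ap))
  if (length(genome$segment_levels) > 0)
    out <- out + (2 * pi / 256) * genome$segment_levels[spec$layout$index[ap]]
  if (length(genome$zernike_coeffs) > 0)
    out <- out + as.vector(spec$basis %*% genome$zernike_coeffs)
  out
}

#' GA hyperparameters
#'
#' The source method reports no hyperparameters; these defaults follow the
#' wavefront-shaping GA literature it builds on: population 30, 15 parents,
#' rank-weighted selection, uniform crossover, per-gene mutation rate
#' decaying 0.1 -> 0.013 exponentially, elitism 2. The Zernike mutation step
#' (sd, radians) anneals on the same schedule so late generations refine
#' rather than explore. All exposed here.
#'
#' @param population_size individuals per generation (>= 2*elitism).
#' @param n_generations generation cap.
#' @param n_parents size of the mating pool (top-ranked individuals);
#'   default: half the population (at least 2).
#' @param mutation_rate_initial,mutation_rate_final per-gene mutation
#'   probability at generation 0 / asymptotically.
#' @param mutation_decay e-folding time of the schedule, generations.
#' @param mutation_scale_initial,mutation_scale_final sd (radians) of the
#'   Gaussian perturbation applied to mutated Zernike genes at generation 0 /
#'   asymptotically. Segment genes are resampled uniformly on [0, 255].
#' @param elitism number of top individuals copied unchanged (>= 1
#'   guarantees non-decreasing best fitness in the noise-free case).
#' @param rng_seed integer seed; the whole run is reproducible from it.
#' @param stop_patience stop after this many generations without improvement
#'   of the best fitness.
#' @return object of class `ga_config`.
#' @export
ga_config <- function(population_size = 30L, n_generations = 300L,
                      n_parents = NULL,
                      mutation_rate_initial = 0.1,
                      mutation_rate_final = 0.013,
                      mutation_decay = 40,
                      mutation_scale_initial = 0.5,
                      mutation_scale_final = 0.05,
                      elitism = 2L, rng_seed = 1L,
                      stop_patience = 30L) {
  if (is.null(n_parents)) n_parents <- max(2L, population_size %/% 2L)
  cfg <- list(population_size = as.integer(population_size),
              n_generations = as.integer(n_generations),
              n_parents = as.integer(n_parents),
              mutation_rate_initial = mutation_rate_initial,
              mutation_rate_final = mutation_rate_final,
              mutation_decay = mutation_decay,
              mutation_scale_initial = mutation_scale_initial,
              mutation_scale_final = mutation_scale_final,
              elitism = as.integer(elitism),
              rng_seed = as.integer(rng_seed),
              stop_patience = as.integer(stop_patience))
  if (cfg$population_size < 2L * cfg$elitism)
    stop("population_size must be >= 2*elitism")
  if (cfg$n_parents < 2L || cfg$n_parents > cfg$population_size)
    stop("n_parents must be in [2, population_size]")
  for (r in c(cfg$mutation_rate_initial, cfg$mutation_rate_final))
    if (r < 0 || r > 1) stop("mutation rates must be in [0, 1]")
  if (cfg$mutation_decay <= 0) stop("mutation_decay must be positive")
  if (cfg$elitism < 1L) stop("elitism must be >= 1")
  structure(cfg, class = "ga_config")
}

mutation_rate_at <- function(config, generation)
  config$mutation_rate_final + (config$mutation_rate_initial -
    config$mutation_rate_final) * exp(-generation / config$mutation_decay)

mutation_scale_at <- function(config, generation)
  config$mutation_scale_final + (config$mutation_scale_initial -
    config$mutation_scale_final) * exp(-generation / config$mutation_decay)

#' Initialize a GA population
#'
#' Segment levels uniform on [0, 255]; Zernike coefficients Normal(0,
#' `init_sd`). One all-zero (flat) individual is always seeded, so the
#' optimizer can never end worse than the uncorrected system.
#'
#' @param config a [ga_config()]. Call `set.seed` beforehand or use
#'   [run_ga()], which seeds for you.
#' @param spec a [genome_spec()].
#' @param init_sd sd of initial Zernike coefficients (radians).
#' @return list of genomes, length `config$population_size`.
#' @export
initialize_population <- function(config, spec, init_sd = 0.5) {
  len <- genome_lengths(spec)
  pop <- vector("list", config$population_size)
  pop[[1]] <- new_genome(spec)  # flat individual
  for (i in seq_len(config$population_size - 1L) + 1L) {
    sl <- if (len["segment"] > 0) sample.int(256L, len["segment"],
                                             replace = TRUE) - 1L else NULL
    zc <- if (len["zernike"] > 0) stats::rnorm(len["zernike"], 0, init_sd)
          else NULL
    pop[[i]] <- new_genome(spec, sl, zc)
  }
  pop
}

#' Select parent pairs by rank weighting
#'
#' Probability proportional to rank (best = population_size) among the top
#' `n_parents` individuals; the two parents of a pair are distinct. All-equal
#' fitnesses degrade gracefully to uniform sampling.
#'
#' @param fitnesses numeric vector (finite).
#' @param config a [ga_config()].
#' @param n_pairs number of pairs to draw.
#' @return integer matrix, n_pairs x 2, of population indices.
#' @export
select_parents <- function(fitnesses, config, n_pairs) {
  if (any(!is.finite(fitnesses))) stop("non-finite fitness in selection")
  rk <- rank(fitnesses, ties.method = "average")  # best gets highest rank
  pool <- order(fitnesses, decreasing = TRUE)[seq_len(config$n_parents)]
  w <- rk[pool]
  out <- matrix(0L, n_pairs, 2)
  for (i in seq_len(n_pairs)) {
    a <- pool[sample.int(length(pool), 1, prob = w)]
    repeat {
      b <- pool[sample.int(length(pool), 1, prob = w)]
      if (b != a) break
    }
    out[i, ] <- c(a, b)
  }
  out
}

#' Uniform crossover
#'
#' Each gene is inherited from either parent with probability 1/2; segment
#' and Zernike parts of mixed genomes cross independently (which is what
#' per-gene inheritance gives).
#'
#' @param parent_a,parent_b genomes with identical structure.
#' @return offspring genome.
#' @export
crossover <- function(parent_a, parent_b) {
  if (!identical(parent_a$mode, parent_b$mode) ||
      length(parent_a$segment_levels) != length(parent_b$segment_levels) ||
      length(parent_a$zernike_coeffs) != length(parent_b$zernike_coeffs))
    stop("parents have mismatched genome structure")
  sl <- parent_a$segment_levels
  if (length(sl) > 0) {
    from_b <- stats::runif(length(sl)) < 0.5
    sl[from_b] <- parent_b$segment_levels[from_b]
  }
  zc <- parent_a$zernike_coeffs
  if (length(zc) > 0) {
    from_b <- stats::runif(length(zc)) < 0.5
    zc[from_b] <- parent_b$zernike_coeffs[from_b]
  }
  structure(list(mode = parent_a$mode, segment_levels = sl,
                 zernike_coeffs = zc), class = "genome")
}

#' Mutate a genome
#'
#' Per-gene mutation probability follows the exponential schedule
#' R(g) = R_final + (R_initial - R_final) exp(-g / decay). Mutated segment
#' genes are resampled uniformly on [0, 255]; mutated Zernike genes receive a
#' Gaussian perturbation whose sd follows the analogous schedule.
#'
#' @param genome a genome.
#' @param generation current generation (>= 0).
#' @param config a [ga_config()].
#' @return mutated genome (always valid).
#' @export
mutate <- function(genome, generation, config) {
  if (generation < 0) stop("generation must be >= 0")
  r <- mutation_rate_at(config, generation)
  sl <- genome$segment_levels
  if (length(sl) > 0) {
    hit <- stats::runif(length(sl)) < r
    if (any(hit)) sl[hit] <- sample.int(256L, sum(hit), replace = TRUE) - 1L
  }
  zc <- genome$zernike_coeffs
  if (length(zc) > 0) {
    hit <- stats::runif(length(zc)) < r
    if (any(hit))
      zc[hit] <- zc[hit] + stats::rnorm(sum(hit), 0,
                                        mutation_scale_at(config, generation))
  }
  structure(list(mode = genome$mode, segment_levels = sl,
                 zernike_coeffs = zc), class = "genome")
}

#' Run the genetic algorithm
#'
#' Elitist generational GA: evaluate, copy the top `elitism` individuals
#' unchanged, fill the rest with mutated uniform-crossover offspring of
#' rank-selected parents. Stops at the generation cap or after
#' `stop_patience` generations without best-fitness improvement. The whole
#' run (including any noise drawn by the fitness function from the R RNG) is
#' reproducible from `config$rng_seed`.
#'
#' @param fitness_fn function(genome) -> finite scalar to maximize. For
#'   phase-correction runs build it with [ga_fitness()] or pass a
#'   [guide_star_engine()]-backed closure.
#' @param config a [ga_config()].
#' @param spec a [genome_spec()].
#' @param init_sd initial Zernike coefficient sd (radians).
#' @return list with `best` (genome, highest fitness ever observed),
#'   `best_fitness`, `trace` (data.frame: generation, best, mean, sd,
#'   evaluations), `converged` (stopped on patience), `n_evaluations`.
#' @export
run_ga <- function(fitness_fn, config, spec, init_sd = 0.5) {
  set.seed(config$rng_seed)
  pop <- initialize_population(config, spec, init_sd)
  n <- config$population_size
  evals <- 0L
  eval_pop <- function(p) {
    f <- vapply(p, fitness_fn, numeric(1))
    if (any(!is.finite(f))) {
      bad <- which(!is.finite(f))[1]
      stop("non-finite fitness for genome #", bad, " (mode ", p[[bad]]$mode,
           ", first genes: ",
           paste(utils::head(c(p[[bad]]$segment_levels,
                               signif(p[[bad]]$zernike_coeffs, 3)), 5),
                 collapse = ", "), ")")
    }
    evals <<- evals + length(f)
    f
  }
  fit <- eval_pop(pop)
  best_i <- which.max(fit)
  best <- pop[[best_i]]; best_fit <- fit[best_i]
  trace <- data.frame(generation = 0L, best = max(fit), mean = mean(fit),
                      sd = stats::sd(fit), evaluations = evals)
  stall <- 0L; converged <- FALSE
  for (g in seq_len(config$n_generations)) {
    ord <- order(fit, decreasing = TRUE)
    elite <- pop[ord[seq_len(config$elitism)]]
    n_off <- n - config$elitism
    pairs <- select_parents(fit, config, n_off)
    offspring <- vector("list", n_off)
    for (k in seq_len(n_off))
      offspring[[k]] <- mutate(crossover(pop[[pairs[k, 1]]],
                                         pop[[pairs[k, 2]]]),
                               g, config)
    pop <- c(elite, offspring)
    fit <- c(fit[ord[seq_len(config$elitism)]],   # elites keep their scores
             eval_pop(offspring))
    gen_best_i <- which.max(fit)
    if (fit[gen_best_i] > best_fit) {
      best_fit <- fit[gen_best_i]; best <- pop[[gen_best_i]]; stall <- 0L
    } else stall <- stall + 1L
    trace <- rbind(trace, data.frame(generation = g, best = max(fit),
                                     mean = mean(fit), sd = stats::sd(fit),
                                     evaluations = evals))
    if (stall >= config$stop_patience) { converged <- TRUE; break }
  }
  list(best = best, best_fitness = best_fit, trace = trace,
       converged = converged, n_evaluations = evals)
}

#' Guide-star fitness closure for genomes
#'
#' Binds a [guide_star_engine()] to a [genome_spec()] so [run_ga()] can
#' evaluate genomes directly.
#'
#' @param spec a [genome_spec()].
#' @param screen an [aberration_screen()] or phase matrix.
#' @param star a [guide_star()].
#' @param noise_sd fitness noise sd (fraction of the unaberrated ceiling).
#' @return function(genome) -> fitness.
#' @export
ga_fitness <- function(spec, screen, star = guide_star(), noise_sd = 0) {
  engine <- guide_star_engine(spec$grid, screen, star, noise_sd)
  function(genome) engine(decode_aperture(genome, spec))
}

#' Random-search baseline
#'
#' Best fitness among `n_evals` genomes drawn from the GA's initial
#' distribution (flat individual included) — the equal-budget straw man the
#' GA must beat on the 256^81-sized segment space.
#'
#' @param fitness_fn function(genome) -> scalar.
#' @param n_evals evaluation budget.
#' @param spec a [genome_spec()].
#' @param rng_seed integer seed.
#' @param init_sd initial Zernike sd.
#' @return list with `best`, `best_fitness`, `n_evaluations`.
#' @export
random_search <- function(fitness_fn, n_evals, spec, rng_seed = 1L,
                          init_sd = 0.5) {
  set.seed(rng_seed)
  cfg_like <- list(population_size = as.integer(n_evals))
  pop <- initialize_population(structure(cfg_like, class = "ga_config"),
                               spec, init_sd)
  fit <- vapply(pop, fitness_fn, numeric(1))
  i <- which.max(fit)
  list(best = pop[[i]], best_fitness = fit[i], n_evaluations = n_evals)
}
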