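# Binary-encoded genetic algorithm over feature masks.
#
# Each generation keeps the best half of the population (which always
# contains the top elites), and refills the other half with offspring bred by
# roulette-wheel parent selection over the full previous population,
# one-point crossover and bit-flip mutation. The mutation rate is either
# fixed or follows the decreasing linear schedule.

#' Genetic algorithm parameters
#'
#' @param population_size number of masks kept per generation (default 30);
#'   must be even and at least `2 * elite_count`.
#' @param mutation_rate fixed per-bit flip probability (default 0.01);
#'   ignored when a schedule is supplied to [ga_run()].
#' @param parent_selection_rate fraction of the population replaced by
#'   offspring each generation (default 0.5).
#' @param generations number of generations (default 100).
#' @param elite_count solutions that persist unconditionally (default 3).
#' @param seed integer RNG seed.
#' @export
ga_params <- function(population_size = 30, mutation_rate = 0.01,
                      parent_selection_rate = 0.5, generations = 100,
                      elite_count = 3, seed = 1L) {
  if (population_size %% 2 != 0 || population_size < 2 * elite_count) {
    stop_invalid("population_size must be even and >= 2 * elite_count")
  }
  if (mutation_rate < 0 || mutation_rate > 1 ||
      parent_selection_rate < 0 || parent_selection_rate > 1) {
    stop_invalid("rates must be in [0, 1]")
  }
  if (generations < 1) stop_invalid("generations must be >= 1")
  structure(list(population_size = population_size,
                 mutation_rate = mutation_rate,
                 parent_selection_rate = parent_selection_rate,
                 generations = generations, elite_count = elite_count,
                 seed = seed),
            class = "ga_params")
}

#' Random initial population
#'
#' Each bit is i.i.d. Bernoulli(0.5), so initial masks carry a free (not
#' fixed) number of selected features. Consumes the current RNG stream.
#'
#' @param n_features mask length
#' @param size number of masks
#' @return list of `feature_mask`s
#' @export
init_population <- function(n_features, size) {
  if (size < 2 || n_features < 1) stop_invalid("need size >= 2, n_features >= 1")
  lapply(seq_len(size), function(i) {
    feature_mask(stats::rbinom(n_features, 1L, 0.5))
  })
}

#' Fitness-proportional (roulette-wheel) selection
#'
#' Draws one index with probability `fitness_i / sum(fitness)`; when every
#' fitness is zero the draw is uniform. Consumes the current RNG stream.
#'
#' @param fitness non-negative fitness values
#' @return a single index
#' @export
roulette_select <- function(fitness) {
  if (any(fitness < 0)) stop_invalid("fitness values must be non-negative")
  if (sum(fitness) == 0) return(sample.int(length(fitness), 1L))
  sample.int(length(fitness), 1L, prob = fitness)
}

#' One-point crossover
#'
#' Cuts both parents at the same uniformly chosen interior point and swaps
#' tails. Consumes the current RNG stream.
#'
#' @param a,b parent masks of equal length >= 2
#' @return list of two child masks
#' @export
one_point_crossover <- function(a, b) {
  L <- length(a)
  if (length(b) != L) stop_invalid("parents differ in length")
  if (L < 2) stop_invalid("masks must have length >= 2")
  cut <- sample.int(L - 1L, 1L)
  list(feature_mask(c(a[seq_len(cut)], b[(cut + 1L):L])),
       feature_mask(c(b[seq_len(cut)], a[(cut + 1L):L])))
}

#' Bit-flip mutation
#'
#' Flips each bit independently with probability `rate`. Consumes the current
#' RNG stream.
#'
#' @param m a mask
#' @param rate per-bit flip probability in \[0, 1\]
#' @export
bit_flip_mutation <- function(m, rate) {
  if (rate < 0 || rate > 1) stop_invalid("rate must be in [0, 1]")
  flip <- stats::runif(length(m)) < rate
  feature_mask(ifelse(flip, 1L - as.integer(m), as.integer(m)))
}

# One generation: keep the best half, breed the rest.
# population: list of masks; fitness: numeric; returns list(population,
# fitness, n_new). `g` is the 0-based generation index used by the schedule.
ga_generation_step <- function(population, fitness, params, g, evaluator,
                               schedule = NULL) {
  size <- params$population_size
  stopifnot(length(population) == size, length(fitness) == size)
  n_new <- floor(size * params$parent_selection_rate)
  n_keep <- size - n_new
  rate <- if (is.null(schedule)) params$mutation_rate else
    mutation_at(g, params$generations, schedule)
  keep <- order(fitness, decreasing = TRUE)[seq_len(n_keep)]
  offspring <- vector("list", n_new)
  made <- 0L
  while (made < n_new) {
    i <- roulette_select(fitness)
    j <- roulette_select(fitness)
    kids <- one_point_crossover(population[[i]], population[[j]])
    for (kid in kids) {
      if (made >= n_new) break            # odd surplus discarded
      made <- made + 1L
      offspring[[made]] <- bit_flip_mutation(kid, rate)
    }
  }
  off_fit <- vapply(offspring, evaluator, numeric(1))
  list(population = c(population[keep], offspring),
       fitness = c(fitness[keep], off_fit),
       n_new = n_new)
}

#' Run the genetic algorithm
#'
#' Seeds the RNG from `params$seed` (restoring the caller's RNG state
#' afterwards), evaluates the initial population, then iterates
#' [ga_generation_step()] for `params$generations` generations. Returns the
#' highest-fitness mask ever evaluated together with the per-generation
#' history.
#'
#' @param ds labelled `survey_dataset`; ignored when `evaluator` is given.
#' @param params a [ga_params()]
#' @param schedule optional [schedule_params()] switching the mutation rate to
#'   the decreasing linear schedule; `NULL` keeps the fixed rate.
#' @param evaluator function mask -> fitness; defaults to a cached 5-fold CV
#'   naive Bayes evaluator built from `ds` under `params$seed`.
#' @return list of class `metaheuristic_run`: `best_mask`, `best_fitness`,
#'   `history` (data.frame generation/best/mean), `best_mask_per_gen`,
#'   `n_evaluated` (offspring evaluations, excluding the initial population).
#' @export
ga_run <- function(ds = NULL, params = ga_params(), schedule = NULL,
                   evaluator = NULL) {
  if (is.null(evaluator)) {
    if (is.null(ds) || is.null(ds$labels)) {
      stop_invalid("need a labelled dataset or an explicit evaluator")
    }
    evaluator <- make_cv_evaluator(ds, k = 5, seed = params$seed)
  }
  n_feat <- if (!is.null(ds)) n_features(ds) else NULL
  with_local_seed(params$seed, {
    if (is.null(n_feat)) stop_invalid("`ds` required to size the masks")
    population <- init_population(n_feat, params$population_size)
    fitness <- vapply(population, evaluator, numeric(1))
    G <- params$generations
    hist_best <- numeric(G + 1L); hist_mean <- numeric(G + 1L)
    best_per_gen <- vector("list", G + 1L)
    record <- function(slot) {
      b <- which.max(fitness)
      hist_best[slot] <<- fitness[b]
      hist_mean[slot] <<- mean(fitness)
      best_per_gen[[slot]] <<- population[[b]]
    }
    record(1L)
    best_mask <- best_per_gen[[1L]]
    best_fitness <- hist_best[1L]
    n_evaluated <- 0L
    for (g in seq_len(G)) {
      step <- ga_generation_step(population, fitness, params, g - 1L,
                                 evaluator, schedule)
      population <- step$population
      fitness <- step$fitness
      n_evaluated <- n_evaluated + step$n_new
      record(g + 1L)
      if (hist_best[g + 1L] > best_fitness) {
        best_fitness <- hist_best[g + 1L]
        best_mask <- best_per_gen[[g + 1L]]
      }
    }
    structure(list(best_mask = best_mask, best_fitness = best_fitness,
                   history = data.frame(generation = 0:G, best = hist_best,
                                        mean = hist_mean),
                   best_mask_per_gen = best_per_gen,
                   n_evaluated = n_evaluated),
              class = "metaheuristic_run")
  })
}

#' @export
print.metaheuristic_run <- function(x, ...) {
  cat(sprintf("<metaheuristic_run> best fitness %.4f with %d features (%d evaluations)\n",
              x$best_fitness, sum(x$best_mask), x$n_evaluated))
  invisible(x)
}
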