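# Binary harmony search over feature masks.
#
# The harmony memory holds `hms` masks. Each iteration improvises one
# candidate: every bit is either copied from a uniformly chosen memory
# harmony (with probability HMCR, source harmony drawn independently per
# bit) or drawn Bernoulli(0.5); pitch adjustment then perturbs the
# candidate. The candidate replaces the current worst memory entry only on a
# strict fitness improvement.

#' Harmony search parameters
#'
#' @param hms harmony memory size (default 30)
#' @param hmcr harmony memory consideration rate (default 0.85); ignored when
#'   a schedule is supplied to [hs_run()].
#' @param par pitch adjustment rate (default 0.7)
#' @param iterations improvisation count (default 1000)
#' @param par_mode `"per_harmony"` (default): with probability `par`, flip
#'   exactly one uniformly chosen bit of the candidate — the binary analogue
#'   of a single pitch step. `"per_bit"`: flip each memory-derived bit
#'   independently with probability `par`.
#' @param seed integer RNG seed
#' @export
hs_params <- function(hms = 30, hmcr = 0.85, par = 0.7, iterations = 1000,
                      par_mode = c("per_harmony", "per_bit"), seed = 1L) {
  par_mode <- match.arg(par_mode)
  if (hms < 2) stop_invalid("hms must be >= 2")
  if (hmcr < 0 || hmcr > 1 || par < 0 || par > 1) {
    stop_invalid("hmcr and par must be in [0, 1]")
  }
  if (iterations < 1) stop_invalid("iterations must be >= 1")
  structure(list(hms = hms, hmcr = hmcr, par = par, iterations = iterations,
                 par_mode = par_mode, seed = seed),
            class = "hs_params")
}

#' Improvise one candidate mask from harmony memory
#'
#' Consumes the current RNG stream.
#'
#' @param memory integer matrix, `hms` rows x mask-length columns of 0/1
#' @param hmcr,par rates in \[0, 1\]
#' @param par_mode see [hs_params()]
#' @return a `feature_mask`
#' @export
improvise <- function(memory, hmcr, par, par_mode = "per_harmony") {
  hms <- nrow(memory)
  L <- ncol(memory)
  from_mem <- stats::runif(L) < hmcr
  src <- sample.int(hms, L, replace = TRUE)
  bits <- integer(L)
  bits[from_mem] <- memory[cbind(src[from_mem], which(from_mem))]
  n_rand <- sum(!from_mem)
  if (n_rand > 0L) bits[!from_mem] <- stats::rbinom(n_rand, 1L, 0.5)
  if (par_mode == "per_harmony") {
    if (stats::runif(1L) < par) {
      at <- sample.int(L, 1L)
      bits[at] <- 1L - bits[at]
    }
  } else {
    flip <- from_mem & (stats::runif(L) < par)
    bits[flip] <- 1L - bits[flip]
  }
  feature_mask(bits)
}

#' Replace the worst harmony on strict improvement
#'
#' @param memory list with `masks` (matrix) and `fitness` (numeric)
#' @param candidate a mask
#' @param fitness the candidate's fitness
#' @return list with updated `memory` and logical `accepted`
#' @export
hs_replace <- function(memory, candidate, fitness) {
  worst <- which.min(memory$fitness)
  if (fitness > memory$fitness[worst]) {
    memory$masks[worst, ] <- as.integer(candidate)
    memory$fitness[worst] <- fitness
    list(memory = memory, accepted = TRUE)
  } else {
    list(memory = memory, accepted = FALSE)
  }
}

#' Run harmony search
#'
#' Seeds the RNG from `params$seed` (restoring the caller's state), fills the
#' memory with Bernoulli(0.5) masks, then improvises exactly one candidate
#' per iteration, evaluating each with the wrapper fitness and replacing the
#' worst memory entry on strict improvement. With a schedule, HMCR follows
#' the increasing linear ramp over the iteration index.
#'
#' @param ds labelled `survey_dataset`; ignored when `evaluator` is given.
#' @param params an [hs_params()]
#' @param schedule optional [schedule_params()] enabling dynamic HMCR
#' @param evaluator function mask -> fitness; defaults to a cached 5-fold CV
#'   naive Bayes evaluator built from `ds` under `params$seed`.
#' @return list of class `metaheuristic_run`: `best_mask`, `best_fitness`,
#'   `history` (data.frame iteration/best/mean over memory), `n_evaluated`
#'   (post-initialization candidate evaluations, equal to `iterations`).
#' @export
hs_run <- function(ds = NULL, params = hs_params(), schedule = NULL,
                   evaluator = NULL) {
  if (is.null(evaluator)) {
    if (is.null(ds) || is.null(ds$labels)) {
      stop_invalid("need a labelled dataset or an explicit evaluator")
    }
    evaluator <- make_cv_evaluator(ds, k = 5, seed = params$seed)
  }
  if (is.null(ds)) stop_invalid("`ds` required to size the masks")
  L <- n_features(ds)
  with_local_seed(params$seed, {
    masks <- matrix(stats::rbinom(params$hms * L, 1L, 0.5),
                    nrow = params$hms, ncol = L)
    fit <- vapply(seq_len(params$hms),
                  function(i) evaluator(masks[i, ]), numeric(1))
    memory <- list(masks = masks, fitness = fit)
    best_i <- which.max(fit)
    best_mask <- feature_mask(masks[best_i, ])
    best_fitness <- fit[best_i]
    T <- params$iterations
    hist_best <- numeric(T + 1L); hist_mean <- numeric(T + 1L)
    hist_best[1L] <- best_fitness; hist_mean[1L] <- mean(fit)
    for (t in seq_len(T)) {
      hmcr <- if (is.null(schedule)) params$hmcr else
        hmcr_at(t - 1L, T, schedule)
      cand <- improvise(memory$masks, hmcr, params$par, params$par_mode)
      f <- evaluator(cand)
      memory <- hs_replace(memory, cand, f)$memory
      if (f > best_fitness) {
        best_fitness <- f
        best_mask <- cand
      }
      hist_best[t + 1L] <- best_fitness
      hist_mean[t + 1L] <- mean(memory$fitness)
    }
    structure(list(best_mask = best_mask, best_fitness = best_fitness,
                   history = data.frame(iteration = 0:T, best = hist_best,
                                        mean = hist_mean),
                   n_evaluated = T),
              class = "metaheuristic_run")
  })
}
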