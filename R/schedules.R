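# Linear dynamic-parameter schedules shared by both optimizers.
#
# Early iterations should explore (low memory-consideration rate, high
# mutation rate); late iterations should refine (the reverse). Both schedules
# interpolate linearly over index/(total - 1) so that the endpoints are
# attained exactly, and the mutation rate never falls below its floor.

#' Dynamic-parameter schedule endpoints
#'
#' Holds the interpolation ranges: the harmony memory consideration rate
#' (HMCR) rises from `hmcr_min` to `hmcr_max` over the run; the genetic
#' algorithm's mutation rate falls from `mut_max` to `mut_min`, floored at
#' `mut_min` to avoid premature convergence.
#'
#' @param hmcr_min,hmcr_max HMCR range (defaults 0.7 to 1.0)
#' @param mut_min,mut_max mutation-rate range (defaults 0.001 to 0.1)
#' @export
schedule_params <- function(hmcr_min = 0.7, hmcr_max = 1.0,
                            mut_min = 0.001, mut_max = 0.1) {
  vals <- c(hmcr_min, hmcr_max, mut_min, mut_max)
  if (any(vals < 0 | vals > 1)) stop_invalid("schedule rates must be in [0, 1]")
  if (hmcr_min > hmcr_max) stop_invalid("hmcr_min must not exceed hmcr_max")
  if (mut_min > mut_max) stop_invalid("mut_min must not exceed mut_max")
  structure(list(hmcr_min = hmcr_min, hmcr_max = hmcr_max,
                 mut_min = mut_min, mut_max = mut_max),
            class = "schedule_params")
}

#' HMCR at iteration t of T (linearly increasing)
#'
#' `hmcr_min + (hmcr_max - hmcr_min) * t / (T - 1)`; for `T = 1` the value is
#' `hmcr_min`. Iteration indices are 0-based.
#'
#' @param t 0-based iteration index, `0 <= t < T`
#' @param T total iterations, `T >= 1`
#' @param p a [schedule_params()]
#' @export
hmcr_at <- function(t, T, p = schedule_params()) {
  if (T < 1) stop_invalid("T must be >= 1")
  if (any(t < 0 | t >= T)) stop_invalid("t must satisfy 0 <= t < T")
  if (T == 1) return(rep(p$hmcr_min, length(t)))
  p$hmcr_min + (p$hmcr_max - p$hmcr_min) * t / (T - 1)
}

#' Mutation rate at generation g of G (linearly decreasing, floored)
#'
#' `max(mut_min, mut_max - (mut_max - mut_min) * g / (G - 1))`. Generation
#' indices are 0-based; for `G = 1` the value is `mut_max`.
#'
#' @param g 0-based generation index, `0 <= g < G`
#' @param G total generations, `G >= 1`
#' @param p a [schedule_params()]
#' @export
mutation_at <- function(g, G, p = schedule_params()) {
  if (G < 1) stop_invalid("G must be >= 1")
  if (any(g < 0 | g >= G)) stop_invalid("g must satisfy 0 <= g < G")
  if (G == 1) return(rep(p$mut_max, length(g)))
  pmax(p$mut_min, p$mut_max - (p$mut_max - p$mut_min) * g / (G - 1))
}
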