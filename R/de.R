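#' Seeded bound-constrained differential evolution
#'
#' A compact DE/rand/1/bin optimiser: derivative-free, bound-constrained,
#' population-based, fully deterministic for a fixed seed. The first
#' population member is the supplied initial guess, so a budget of a
#' single evaluation returns that guess with its cost.
#'
#' @param fn objective taking a numeric vector, returning a scalar cost.
#' @param lower,upper bound vectors.
#' @param init optional initial guess (defaults to the bound midpoint).
#' @param budget maximal number of objective evaluations.
#' @param pop population size (default `10 * length(lower)`, capped by
#'   the budget).
#' @param f,cr differential weight and crossover rate.
#' @param seed RNG seed.
#' @return list: `par`, `value`, `n_eval`, `trace` (tibble of best cost
#'   per generation).
#' @export
de_optimize <- function(fn, lower, upper, init = NULL, budget = 2000,
                        pop = NULL, f = 0.7, cr = 0.9, seed = 1) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper >= lower), budget >= 1)
  if (is.null(init)) init <- (lower + upper) / 2
  set.seed(seed)
  np <- min(if (is.null(pop)) max(10 * d, 15) else pop, budget)
  X <- matrix(runif(np * d, lower, upper), nrow = np, byrow = TRUE)
  X[1, ] <- pmin(pmax(init, lower), upper)
  cost <- rep(Inf, np)
  n_eval <- 0
  for (i in seq_len(np)) {
    if (n_eval >= budget) break
    cost[i] <- fn(X[i, ])
    n_eval <- n_eval + 1
  }
  trace <- list(tibble::tibble(generation = 0L, best_cost = min(cost),
                               n_eval = n_eval))
  gen <- 0L
  while (n_eval < budget) {
    gen <- gen + 1L
    for (i in seq_len(np)) {
      if (n_eval >= budget) break
      idx <- sample(setdiff(seq_len(np), i), 3)
      trial <- X[idx[1], ] + f * (X[idx[2], ] - X[idx[3], ])
      # reflect into the bounds
      below <- trial < lower; trial[below] <- pmin(2 * lower - trial, upper)[below]
      above <- trial > upper; trial[above] <- pmax(2 * upper - trial, lower)[above]
      trial <- pmin(pmax(trial, lower), upper)
      mask <- runif(d) < cr
      mask[sample.int(d, 1)] <- TRUE
      cand <- ifelse(mask, trial, X[i, ])
      cc <- fn(cand)
      n_eval <- n_eval + 1
      if (cc <= cost[i]) { X[i, ] <- cand; cost[i] <- cc }
    }
    trace[[length(trace) + 1]] <- tibble::tibble(
      generation = gen, best_cost = min(cost), n_eval = n_eval)
    if (n_eval >= budget) break
  }
  best <- which.min(cost)
  list(par = X[best, ], value = cost[best], n_eval = n_eval,
       trace = dplyr::bind_rows(trace))
}
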