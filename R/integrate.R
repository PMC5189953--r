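#' Simulate the clock network (method of steps)
#'
#' Integrates the delay-differential system with a fixed-step classical
#' Runge-Kutta scheme; delayed terms are read from a cubic Hermite
#' interpolant of the already-computed solution (method of steps). The
#' default history is constant at the cached clamp means, which starts the
#' system near its limit cycle.
#'
#' @param model a `clock_model` (possibly with node/edge clamps).
#' @param t_end simulation horizon in hours (default 500, at least eight
#'   cycles of a circadian rhythm after the transient).
#' @param step integration step in hours (default 0.05). The step must not
#'   exceed the smallest positive delay actually used by an active
#'   (unclamped) regulation, otherwise the interpolation contract of the
#'   method of steps is broken and the call aborts.
#' @param history initial function on `[-max(tau), 0]`: `NULL` (constant
#'   at clamp means, falling back to the reference means), a named or
#'   positional numeric of length 5 (constant), or a data frame with a
#'   `time_h` column (values at nonpositive times, interpolated linearly).
#' @return a `clock_trajectory` tibble with columns `time_h` and one
#'   column per gene.
#' @examples
#' \donttest{
#' m <- default_clock_model()
#' traj <- simulate_clock(m, t_end = 500)
#' classify_oscillation(traj)
#' }
#' @export
simulate_clock <- function(model, t_end = 500, step = 0.05, history = NULL) {
  stopifnot(is.numeric(t_end), t_end > 0, is.numeric(step), step > 0)
  validate_model(model)
  cpp <- model_to_cpp(model)
  min_tau <- min_active_delay(model)
  if (is.finite(min_tau) && min_tau > 0 && step > min_tau + 1e-12)
    abort(sprintf(
      "step (%g h) exceeds the smallest active delay (%g h); reduce the step",
      step, min_tau), class = "clockloops_argument_error")
  h <- build_history(model, history)
  max_tau <- suppressWarnings(max(model$genes$delay[active_sources(model)], 0))
  if (nrow(h$values) > 1 && h$times[1] > -max_tau + 1e-9)
    abort(sprintf("history must span [-%g, 0] h", max_tau),
          class = "clockloops_argument_error")
  res <- cpp_integrate_clock(cpp, t_end, step, h$times, h$values)
  out <- tibble::as_tibble(
    c(list(time_h = res$time),
      setNames(lapply(seq_len(5), function(g) res$y[, g]), clock_gene_names)))
  structure(out, class = c("clock_trajectory", class(out)),
            step = step, gene_names = clock_gene_names)
}

# genes whose delayed value is actually read: sources of unclamped edges
# out of unclamped nodes
active_sources <- function(model) {
  e <- model$regulations
  keep <- !e$clamped & !(e$source %in% model$node_clamps) &
    !(e$target %in% model$node_clamps)
  sort(unique(e$source_index[keep]))
}

min_active_delay <- function(model) {
  idx <- active_sources(model)
  tau <- model$genes$delay[idx]
  tau <- tau[tau > 0]
  if (!length(tau)) Inf else min(tau)
}

build_history <- function(model, history) {
  if (is.null(history)) {
    const <- model$clamp_means %||% model$ref_means
    return(list(times = 0, values = matrix(as.numeric(const), nrow = 1)))
  }
  if (is.numeric(history) && is.null(dim(history))) {
    if (length(history) != 5)
      abort("constant history must have 5 values",
            class = "clockloops_argument_error")
    if (!is.null(names(history))) history <- history[clock_gene_names]
    return(list(times = 0, values = matrix(as.numeric(history), nrow = 1)))
  }
  if (is.data.frame(history)) {
    if (!"time_h" %in% names(history))
      abort("history data frame needs a time_h column",
            class = "clockloops_argument_error")
    hh <- history[order(history$time_h), , drop = FALSE]
    if (any(hh$time_h > 1e-9))
      abort("history times must be <= 0", class = "clockloops_argument_error")
    return(list(times = hh$time_h,
                values = as.matrix(hh[, clock_gene_names])))
  }
  abort("unsupported history specification",
        class = "clockloops_argument_error")
}

#' Write a trajectory to CSV
#'
#' @param traj a `clock_trajectory`.
#' @param path output file.
#' @export
write_trajectory <- function(traj, path) {
  write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' Time-averaged gene levels over whole cycles
#'
#' Simulates the model and returns each gene's time average over an
#' integer number of cycles after the transient (the steady-state level
#' if the model does not oscillate). These are the constants used by all
#' clamping operations.
#'
#' @inheritParams simulate_clock
#' @param transient initial stretch to discard, in hours (must be
#'   < `t_end`).
#' @param settings classifier settings, see [oscillation_settings()].
#' @return named numeric vector of per-gene means.
#' @export
limit_cycle_means <- function(model, t_end = 500, transient = 300,
                              step = 0.05, settings = oscillation_settings()) {
  if (transient >= t_end)
    abort("transient must be smaller than t_end",
          class = "clockloops_argument_error")
  traj <- simulate_clock(model, t_end = t_end, step = step)
  rep <- classify_oscillation(traj, transient = transient, settings = settings)
  if (rep$oscillating) {
    vapply(clock_gene_names, function(g)
      cycle_average(traj$time_h, traj[[g]], rep$period, transient), 0)
  } else {
    idx <- traj$time_h >= transient
    vapply(clock_gene_names, function(g) mean(traj[[g]][idx]), 0)
  }
}

#' Attach computed clamp means to a model
#'
#' Convenience wrapper: computes [limit_cycle_means()] of the (fully
#' unclamped) model and stores them in `model$clamp_means`, where every
#' clamping operation reads them. Per design the means are computed once
#' from the complete default network and reused unchanged for every
#' clamped configuration.
#'
#' @inheritParams limit_cycle_means
#' @return the model with `clamp_means` set.
#' @export
with_clamp_means <- function(model, t_end = 500, transient = 300,
                             step = 0.05) {
  base <- model
  base$node_clamps <- character(0)
  base$regulations$clamped <- FALSE
  model$clamp_means <- limit_cycle_means(base, t_end, transient, step)
  model
}

# mean over the largest whole number of cycles starting at `from`
cycle_average <- function(time, x, period, from) {
  idx <- which(time >= from)
  t0 <- time[idx[1]]
  span <- time[length(time)] - t0
  k <- floor(span / period)
  if (k < 1) return(mean(x[idx]))
  keep <- idx[time[idx] < t0 + k * period - 1e-9]
  mean(x[keep])
}

#' Integrate the scalar linear delayed-feedback test equation
#'
#' Integrates \eqn{x'(t) = -k\, x(t-\tau)} with constant history, using the
#' same fixed-step Runge-Kutta / cubic-Hermite machinery as
#' [simulate_clock()]. The equation has a closed-form oscillation
#' criterion (Hopf at \eqn{k\tau = \pi/2}, frequency \eqn{\omega}
#' solving \eqn{\omega = k\cos(\omega\tau)} at onset), which makes it the
#' validation oracle for the integrator.
#'
#' @param k feedback gain (> 0).
#' @param tau delay.
#' @param t_end,step horizon and step.
#' @param history constant history value.
#' @return tibble with `time_h` and `x`.
#' @export
integrate_linear_dde <- function(k, tau, t_end = 200, step = 0.05,
                                 history = 1) {
  stopifnot(k > 0, tau >= step)
  res <- cpp_integrate_linear_dde(k, tau, t_end, step, history)
  tibble::tibble(time_h = res$time, x = res$x)
}
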