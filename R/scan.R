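#' One-parameter bifurcation sweep with state inheritance
#'
#' Steps one kinetic parameter through a log-spaced grid of multipliers of
#' its default value, in the given direction, inheriting the final stretch
#' of each simulation as the initial history of the next (numerical
#' continuation). Classifies every point and records the period. The
#' inheritance is what exposes direction-dependent branches near period
#' jumps (hysteresis / birhythmicity).
#'
#' @param model a `clock_model` with clamp means set.
#' @param param one of the 34 parameter names (see [clock_params()]).
#' @param lo_mult,hi_mult multiplier range (defaults 0.01 and 100: two
#'   orders of magnitude around the default).
#' @param n_points grid size per direction (default 200).
#' @param direction `"up"` or `"down"`.
#' @param inherit inherit state between grid points (default TRUE); with
#'   FALSE every point starts from the clamp-mean history.
#' @param t_end,step,transient,settings simulation/classifier settings.
#'   When a delay parameter is swept below the step, the step is reduced
#'   to keep the method-of-steps contract.
#' @return a `clock_sweep` tibble: `param`, `multiplier`, `value`,
#'   `direction`, `oscillating`, `period`, `rel_amp`, `cv`, `torus`.
#' @export
sweep_parameter <- function(model, param, lo_mult = 0.01, hi_mult = 100,
                            n_points = 200, direction = c("up", "down"),
                            inherit = TRUE, t_end = 500, step = 0.05,
                            transient = 300,
                            settings = oscillation_settings()) {
  direction <- match.arg(direction)
  stopifnot(lo_mult > 0, hi_mult > lo_mult, n_points >= 2)
  default <- get_clock_param(model, param)
  grid <- 10^seq(log10(lo_mult), log10(hi_mult), length.out = n_points)
  if (direction == "down") grid <- rev(grid)
  hist <- NULL
  prev_traj <- NULL
  rows <- vector("list", n_points)
  for (i in seq_len(n_points)) {
    mm <- set_clock_param(model, param, default * grid[i])
    st <- min(step, max(min_active_delay(mm), step / 20))
    max_tau <- max(mm$genes$delay)
    if (!is.null(prev_traj) && inherit) {
      tt <- prev_traj$time_h
      prev_step <- attr(prev_traj, "step") %||% step
      # one extra grid point so the tail covers [-max_tau, 0] exactly
      keep <- tt >= max(tt) - max_tau - prev_step - 1e-9
      hist <- as.data.frame(prev_traj[keep, ])
      hist$time_h <- hist$time_h - max(tt)
    }
    traj <- simulate_clock(mm, t_end = t_end, step = st, history = hist)
    cls <- cpp_classify_series(traj$time_h, traj[[settings$ref_gene]],
                               transient, settings$eps_amp, settings$eps_cv,
                               settings$decay_tol, settings$min_peaks,
                               settings$prominence)
    rows[[i]] <- tibble::tibble(
      param = param, multiplier = grid[i], value = default * grid[i],
      direction = direction, oscillating = isTRUE(cls$oscillating),
      period = if (isTRUE(cls$oscillating)) cls$period else NA_real_,
      rel_amp = cls$rel_amp, cv = cls$cv, torus = isTRUE(cls$torus))
    prev_traj <- traj
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("clock_sweep", class(out)))
}

#' Detect period jumps and oscillation boundaries in a sweep
#'
#' Flags adjacent oscillating grid pairs whose period differs by more
#' than `threshold_h` (period jumps), and grid pairs where oscillation
#' appears or dies (candidate Hopf bifurcations).
#'
#' @param sweep a `clock_sweep` (single direction, or a direction subset
#'   is taken per group).
#' @param threshold_h period-difference threshold in hours (default 4).
#' @return tibble: `direction`, `index`, `multiplier_left`,
#'   `multiplier_right`, `period_left`, `period_right`, `delta_period`,
#'   `type` in `jump`, `onset`, `death`.
#' @export
detect_jumps <- function(sweep, threshold_h = 4) {
  purrr::map_dfr(split(sweep, sweep$direction), function(sw) {
    if (sum(sw$oscillating) < 2 && !any(sw$oscillating)) return(NULL)
    n <- nrow(sw)
    left <- seq_len(n - 1)
    right <- left + 1
    type <- rep(NA_character_, n - 1)
    both <- sw$oscillating[left] & sw$oscillating[right]
    delta <- sw$period[right] - sw$period[left]
    type[both & abs(delta) > threshold_h] <- "jump"
    type[!sw$oscillating[left] & sw$oscillating[right]] <- "onset"
    type[sw$oscillating[left] & !sw$oscillating[right]] <- "death"
    keep <- !is.na(type)
    tibble::tibble(
      direction = sw$direction[1], index = left[keep],
      multiplier_left = sw$multiplier[left][keep],
      multiplier_right = sw$multiplier[right][keep],
      period_left = sw$period[left][keep],
      period_right = sw$period[right][keep],
      delta_period = delta[keep], type = type[keep])
  })
}

#' Paired up/down sweeps and their hysteresis overlap
#'
#' Runs an upward and a downward sweep with state inheritance and reports
#' grid points where the two directions disagree: different periods
#' beyond `threshold_h` (coexisting limit cycles, birhythmicity),
#' different verdicts, or torus-flagged interval variance.
#'
#' @inheritParams sweep_parameter
#' @param threshold_h period-difference threshold for the overlap report.
#' @return list with `sweeps` (both directions bound together) and
#'   `overlap` (tibble of disagreeing grid points), class
#'   `clock_hysteresis`.
#' @export
hysteresis_scan <- function(model, param, lo_mult = 0.01, hi_mult = 100,
                            n_points = 200, threshold_h = 4, t_end = 500,
                            step = 0.05, transient = 300,
                            settings = oscillation_settings()) {
  up <- sweep_parameter(model, param, lo_mult, hi_mult, n_points, "up",
                        TRUE, t_end, step, transient, settings)
  down <- sweep_parameter(model, param, lo_mult, hi_mult, n_points, "down",
                          TRUE, t_end, step, transient, settings)
  key_up <- up[order(up$multiplier), ]
  key_dn <- down[order(down$multiplier), ]
  overlap <- tibble::tibble(
    param = param,
    multiplier = key_up$multiplier,
    oscillating_up = key_up$oscillating,
    oscillating_down = key_dn$oscillating,
    period_up = key_up$period, period_down = key_dn$period,
    torus = key_up$torus | key_dn$torus)
  overlap$delta_period <- abs(overlap$period_up - overlap$period_down)
  overlap$disagree <- (overlap$oscillating_up != overlap$oscillating_down) |
    (!is.na(overlap$delta_period) & overlap$delta_period > threshold_h)
  structure(list(sweeps = dplyr::bind_rows(up, down),
                 overlap = overlap[overlap$disagree | overlap$torus, ]),
            class = "clock_hysteresis")
}

#' @export
print.clock_hysteresis <- function(x, ...) {
  cat(sprintf("<clock_hysteresis> %s: %d grid point(s) with coexisting or torus dynamics\n",
              x$sweeps$param[1], nrow(x$overlap)))
  if (nrow(x$overlap)) print(x$overlap)
  invisible(x)
}

#' Write a sweep to CSV
#' @param sweep a `clock_sweep`.
#' @param path output file.
#' @export
write_sweep <- function(sweep, path) {
  write.csv(as.data.frame(sweep), path, row.names = FALSE)
  invisible(path)
}
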