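#' Generate synthetic qPCR-style expression profiles
#'
#' Emulates mean-normalised circadian mRNA time courses: cosine-shaped
#' 24 h profiles with gene-specific peak phase and relative amplitude,
#' multiplied by log-normal measurement noise with unit mean. The default
#' phases encode the canonical liver phase ordering (Rev-erb-alpha early,
#' Dbp, then Per2, then Cry1 late, Bmal1 in antiphase to Dbp). These are
#' emulation defaults, not measurements.
#'
#' @param phases named per-gene peak times in h, within `[0, 24)`.
#' @param amplitudes named per-gene relative amplitudes
#'   ((max - min)/mean of the noise-free profile).
#' @param noise_sd standard deviation of the log-normal noise on the log
#'   scale (0 = noise-free).
#' @param n_days days covered (samples at `seq(0, n_days*24 - dt, dt)`,
#'   i.e. whole cycles).
#' @param dt sampling interval in h; must divide 24.
#' @param replicates replicate count per time point.
#' @param condition condition label carried through (cosmetic, e.g.
#'   `"LD"` or `"DD"`).
#' @param seed RNG seed; output is reproducible per seed.
#' @return tibble: `gene`, `time_h`, `replicate`, `value`, `condition`.
#' @export
generate_profiles <- function(phases = c(Bmal1 = 23, Rev_erba = 5, Per2 = 15,
                                         Cry1 = 19, Dbp = 11),
                              amplitudes = c(Bmal1 = 1.2, Rev_erba = 1.6,
                                             Per2 = 1.2, Cry1 = 0.8,
                                             Dbp = 1.6),
                              noise_sd = 0.15, n_days = 2, dt = 2,
                              replicates = 3, condition = "LD", seed = 1) {
  if (abs(24 / dt - round(24 / dt)) > 1e-9)
    abort("dt must divide 24", class = "clockloops_argument_error")
  if (noise_sd < 0)
    abort("noise_sd must be >= 0", class = "clockloops_argument_error")
  phases <- phases[clock_gene_names]
  amplitudes <- amplitudes[clock_gene_names]
  if (any(is.na(phases)) || any(phases < 0) || any(phases >= 24))
    abort("phases must be given for all 5 genes, within [0, 24)",
          class = "clockloops_argument_error")
  if (any(is.na(amplitudes)) || any(amplitudes < 0) || any(amplitudes >= 2))
    abort("relative amplitudes must be in [0, 2) to keep values positive",
          class = "clockloops_argument_error")
  times <- seq(0, n_days * 24 - dt, by = dt)
  set.seed(seed)
  out <- tidyr::expand_grid(gene = clock_gene_names, time_h = times,
                            replicate = seq_len(replicates))
  base <- 1 + (amplitudes[out$gene] / 2) *
    cos(2 * pi * (out$time_h - phases[out$gene]) / 24)
  noise <- if (noise_sd > 0)
    exp(rnorm(nrow(out), -noise_sd^2 / 2, noise_sd)) else 1
  out$value <- as.numeric(base * noise)
  out$condition <- condition
  out
}

#' Normalise profiles to unit mean over whole cycles
#'
#' Each gene is rescaled so that its mean over the largest whole number
#' of 24 h cycles (per replicate-pooled series) equals 1, matching the
#' model's relative-expression convention. Scale-invariant: multiplying
#' the input by any constant leaves the output unchanged.
#'
#' @param profiles tibble as from [generate_profiles()].
#' @return the normalised tibble.
#' @export
normalize_profiles <- function(profiles) {
  if (any(profiles$value <= 0))
    abort("profiles must be strictly positive",
          class = "clockloops_domain_error")
  dplyr::mutate(
    dplyr::group_by(profiles, .data$gene),
    value = .data$value / whole_cycle_mean(.data$time_h, .data$value)) |>
    dplyr::ungroup()
}

whole_cycle_mean <- function(time, value, period = 24) {
  ut <- sort(unique(time))
  dt <- if (length(ut) > 1) min(diff(ut)) else 0
  t0 <- min(time)
  span <- max(time) - t0 + dt # a grid 0..(T-dt) covers T hours of phase
  k <- max(floor(span / period + 1e-9), 0)
  if (k < 1) return(mean(value))
  keep <- time < t0 + k * period - 1e-9
  mean(value[keep])
}

#' Sample simulated trajectories like a qPCR experiment
#'
#' Extracts post-transient model output on the same grid a profile set
#' uses; used for self-generated parameter-recovery experiments.
#'
#' @param traj a `clock_trajectory`.
#' @param t_start first sampled time (after transients).
#' @param dt,n_days sampling grid.
#' @param condition condition label.
#' @return tibble like [generate_profiles()] output (one replicate).
#' @export
profiles_from_trajectory <- function(traj, t_start = 400, dt = 2, n_days = 2,
                                     condition = "synthetic") {
  times <- seq(0, n_days * 24 - dt, by = dt)
  purrr::map_dfr(clock_gene_names, function(g) {
    v <- approx(traj$time_h, traj[[g]], xout = t_start + times)$y
    tibble::tibble(gene = g, time_h = times, replicate = 1L, value = v,
                   condition = condition)
  })
}

#' Fit clock parameters to expression profiles
#'
#' Global, derivative-free fit of selected kinetic parameters by
#' differential evolution: each candidate model is simulated, its
#' post-transient limit cycle sampled at the profile time grid, both
#' sides normalised to unit mean over whole cycles, and the cost is the
#' root-mean-square deviation minimised over a circular phase shift. A
#' candidate that does not oscillate is scored by its flat steady state,
#' which upper-bounds the cost against rhythmic data.
#'
#' @param model template `clock_model`; non-free parameters stay fixed.
#' @param profiles tibble of profiles (replicates are averaged).
#' @param free_params character vector of parameter names to fit
#'   (subset of the 34).
#' @param lower,upper optional named bounds; default `0.25x` to `4x` the
#'   template values.
#' @param budget maximal objective evaluations (default 3000).
#' @param pop DE population size.
#' @param seed RNG seed.
#' @param t_end,transient,step simulation settings per evaluation.
#' @return a `clock_fit`: fitted parameters, cost, updated model, trace.
#' @export
fit_clock <- function(model, profiles, free_params, lower = NULL,
                      upper = NULL, budget = 3000, pop = NULL, seed = 1,
                      t_end = 360, transient = 260, step = 0.1) {
  bad <- setdiff(free_params, names(clock_params(model)))
  if (length(bad))
    abort(paste0("unknown parameter(s): ", paste(bad, collapse = ", ")),
          class = "clockloops_argument_error")
  start <- clock_params(model)[free_params]
  if (is.null(lower)) lower <- start * 0.25
  if (is.null(upper)) upper <- start * 4
  obs <- dplyr::summarise(
    dplyr::group_by(normalize_profiles(profiles), .data$gene, .data$time_h),
    value = mean(.data$value), .groups = "drop")
  obs_mat <- tidyr::pivot_wider(obs, names_from = "gene",
                                values_from = "value")
  obs_mat <- obs_mat[order(obs_mat$time_h), ]
  cost_fn <- make_profile_cost(model, free_params, obs_mat, t_end, transient,
                               step)
  res <- de_optimize(cost_fn, lower, upper, init = start, budget = budget,
                     pop = pop, seed = seed)
  fitted <- model
  for (i in seq_along(free_params))
    fitted <- set_clock_param(fitted, free_params[i], res$par[i])
  structure(list(par = setNames(res$par, free_params), cost = res$value,
                 model = fitted, trace = res$trace, n_eval = res$n_eval,
                 seed = seed, free_params = free_params,
                 oscillating = is.finite(res$value) &&
                   attr(cost_fn(res$par), "oscillating")),
            class = "clock_fit")
}

make_profile_cost <- function(model, free_params, obs_mat, t_end, transient,
                              step) {
  times <- obs_mat$time_h
  genes <- intersect(clock_gene_names, names(obs_mat))
  obs <- as.matrix(obs_mat[, genes])
  shift_grid <- seq(0, 30, by = 0.5)
  function(par) {
    mm <- model
    for (i in seq_along(free_params))
      mm <- set_clock_param(mm, free_params[i], par[i])
    traj <- tryCatch(simulate_clock(mm, t_end = t_end, step = step),
                     error = function(e) NULL)
    if (is.null(traj))
      return(structure(1e3, oscillating = FALSE))
    cls <- cpp_classify_series(traj$time_h, traj$Per2, transient, 1e-3, 0.01,
                               0.01, 4, 0.05)
    sim <- as.matrix(traj[, genes])
    tt <- traj$time_h
    if (!isTRUE(cls$oscillating)) {
      flat <- colMeans(sim[tt >= transient, , drop = FALSE])
      flat <- flat / pmax(flat, 1e-12) # unit-mean normalised flat line = 1
      pred <- matrix(rep(flat, each = length(times)), ncol = length(genes))
      return(structure(sqrt(mean((pred - obs)^2)), oscillating = FALSE))
    }
    rmse_at <- function(s) {
      qt <- transient + s + times
      idx <- round(qt / step) + 1
      pred <- if (max(abs(idx * step - step - qt)) < 1e-9) {
        sim[idx, , drop = FALSE] # query times sit on the simulation grid
      } else {
        vapply(seq_along(genes), function(g)
          approx(tt, sim[, g], xout = qt)$y, numeric(length(times)))
      }
      pred <- sweep(pred, 2, pmax(colMeans(pred), 1e-12), "/")
      sqrt(mean((pred - obs)^2))
    }
    coarse <- vapply(shift_grid, rmse_at, 0)
    s0 <- shift_grid[which.min(coarse)]
    # refine the circular alignment around the best coarse shift
    fine <- seq(max(0, s0 - 0.5), s0 + 0.5, by = 0.05)
    best <- min(vapply(fine, rmse_at, 0))
    structure(best, oscillating = TRUE)
  }
}

#' @export
print.clock_fit <- function(x, ...) {
  cat(sprintf("<clock_fit> %d free parameter(s), cost %.4g after %d evaluations\n",
              length(x$par), x$cost, x$n_eval))
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.clock_fit <- function(x, ...) {
  tibble::tibble(param = names(x$par), estimate = unname(x$par))
}

#' @export
glance.clock_fit <- function(x, ...) {
  tibble::tibble(cost = x$cost, n_eval = x$n_eval,
                 n_free = length(x$par), seed = x$seed,
                 oscillating = x$oscillating)
}
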