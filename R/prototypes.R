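#' Three-stage prototype oscillators
#'
#' Two minimal single-loop negative-feedback systems used to compare the
#' robustness of oscillation mechanisms:
#'
#' * `goodwin` -- the classical chain: stage 1 is produced under Hill-type
#'   repression by stage 3, stages 2 and 3 are driven linearly, all three
#'   degrade linearly. One inhibition carries the whole nonlinearity, so
#'   with equal degradation rates the loop needs a Hill coefficient above
#'   the secant bound of 8 to oscillate.
#' * `repressilator` -- each stage is produced under Hill-type repression
#'   by its predecessor (a ring of three inhibitions), linear degradation.
#'   The required nonlinearity is shared over the ring, which lowers the
#'   minimal Hill coefficient to about 2.
#'
#' Both are plain ODE systems,
#' \deqn{x_1' = v_1/(1 + x_3^h) - d_1 x_1, \quad \dots}
#'
#' @param family `"goodwin"` or `"repressilator"`.
#' @param hill Hill exponent (> 0).
#' @param production per-stage maximal production rates `v` (length 3).
#'   For `goodwin`, stages 2 and 3 use them as linear drive coefficients.
#' @param degradation per-stage linear degradation rates `d` (length 3).
#' @return a `prototype_model`.
#' @export
prototype_model <- function(family = c("goodwin", "repressilator"), hill = 2,
                            production = c(1000, 1, 1),
                            degradation = c(1, 1, 1)) {
  family <- match.arg(family)
  if (!is.numeric(hill) || hill <= 0)
    abort("Hill exponent must be > 0", class = "clockloops_argument_error")
  stopifnot(length(production) == 3, all(production > 0),
            length(degradation) == 3, all(degradation > 0))
  structure(list(family = family, hill = hill,
                 production = as.numeric(production),
                 degradation = as.numeric(degradation)),
            class = "prototype_model")
}

proto_pars <- function(proto) {
  c(proto$production, proto$degradation, proto$hill)
}

#' @export
print.prototype_model <- function(x, ...) {
  cat(sprintf("<prototype_model> %s, h = %g, v = (%s), d = (%s)\n", x$family,
              x$hill, paste(signif(x$production, 4), collapse = ", "),
              paste(signif(x$degradation, 4), collapse = ", ")))
  invisible(x)
}

#' Simulate a prototype oscillator
#'
#' Fixed-step RK4 from a perturbed fixed point.
#'
#' @param proto a `prototype_model`.
#' @param t_end,step horizon and step (dimensionless time).
#' @return tibble `time`, `x1`, `x2`, `x3` with class
#'   `prototype_trajectory`.
#' @export
simulate_prototype <- function(proto, t_end = 600, step = 0.02) {
  res <- cpp_prototype_sim(match(proto$family,
                                 c("goodwin", "repressilator")) - 1L,
                           proto_pars(proto), t_end, step)
  out <- tibble::tibble(time = res$time, x1 = res$y[, 1], x2 = res$y[, 2],
                        x3 = res$y[, 3])
  structure(out, class = c("prototype_trajectory", class(out)))
}

#' Fixed point and linear stability of a prototype
#'
#' Computes the unique positive fixed point (both families have a
#' monotone-decreasing composed return map, so it exists and is unique),
#' the Jacobian there, and its eigenvalues. An unstable fixed point of
#' these monotone cyclic negative-feedback systems implies a stable limit
#' cycle, so the sign of the leading real part is an oscillation oracle.
#'
#' @param proto a `prototype_model`.
#' @return list: `fixed_point`, `jacobian`, `eigenvalues`, `max_re`,
#'   `unstable`.
#' @export
prototype_stability <- function(proto) {
  fam <- match(proto$family, c("goodwin", "repressilator")) - 1L
  xs <- cpp_prototype_fixed_point(fam, proto_pars(proto))
  v <- proto$production; d <- proto$degradation; h <- proto$hill
  hillslope <- function(vmax, x) {
    u <- x^h
    -vmax * h * x^(h - 1) / (1 + u)^2
  }
  J <- diag(-d)
  if (proto$family == "goodwin") {
    J[1, 3] <- hillslope(v[1], xs[3])
    J[2, 1] <- v[2]
    J[3, 2] <- v[3]
  } else {
    J[1, 3] <- hillslope(v[1], xs[3])
    J[2, 1] <- hillslope(v[2], xs[1])
    J[3, 2] <- hillslope(v[3], xs[2])
  }
  ev <- eigen(J, only.values = TRUE)$values
  mre <- max(Re(ev))
  list(fixed_point = xs, jacobian = J, eigenvalues = ev, max_re = mre,
       unstable = mre > 0)
}

#' Does a prototype oscillate (by simulation)?
#'
#' @param proto a `prototype_model`.
#' @param t_end,step,transient simulation settings; long horizons resolve
#'   the slow growth near onset.
#' @param settings classifier settings.
#' @return logical.
#' @export
prototype_oscillates <- function(proto, t_end = 1500, step = 0.02,
                                 transient = 750,
                                 settings = oscillation_settings()) {
  fam <- match(proto$family, c("goodwin", "repressilator")) - 1L
  res <- cpp_prototype_batch(fam, matrix(proto_pars(proto), nrow = 1),
                             t_end, step, transient, settings$eps_amp,
                             settings$eps_cv, settings$decay_tol,
                             settings$min_peaks, settings$prominence)
  unname(res[1, "oscillating"] == 1)
}

#' Minimal Hill coefficient for self-sustained oscillation
#'
#' Bisects the Hill exponent for the smallest value at which the
#' prototype oscillates. With `method = "stability"` the criterion is the
#' sign change of the leading eigenvalue's real part at the fixed point
#' (the Hopf condition); with `method = "simulation"` each candidate is
#' integrated and classified by the limit-cycle detector.
#'
#' @param family `"goodwin"` or `"repressilator"`.
#' @param h_range search interval; the oscillation status must differ at
#'   its ends, otherwise a search error is raised.
#' @param resolution bisection tolerance on h.
#' @param method `"stability"` (default) or `"simulation"`.
#' @param production,degradation passed to [prototype_model()].
#' @param ... simulation settings for `method = "simulation"`.
#' @return the threshold Hill coefficient.
#' @export
minimal_hill <- function(family = c("goodwin", "repressilator"),
                         h_range = c(1, 16), resolution = 1e-3,
                         method = c("stability", "simulation"),
                         production = c(1000, 1, 1),
                         degradation = c(1, 1, 1), ...) {
  family <- match.arg(family)
  method <- match.arg(method)
  osc <- function(h) {
    p <- prototype_model(family, h, production, degradation)
    if (method == "stability") prototype_stability(p)$unstable
    else prototype_oscillates(p, ...)
  }
  lo <- h_range[1]; hi <- h_range[2]
  if (osc(lo) || !osc(hi))
    abort("oscillation status does not change over h_range",
          class = "clockloops_search_error")
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    if (osc(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Robustness comparison of the two prototype families
#'
#' Draws `n_samples` random parameter sets per family (production and
#' degradation rates log-uniform over `ranges$rate`, Hill exponent
#' log-uniform over `ranges$hill`), simulates and classifies each, and
#' reports the oscillating fraction and the smallest Hill exponent among
#' the oscillating samples. Fully reproducible for a given seed.
#'
#' @param n_samples samples per family (>= 100).
#' @param seed RNG seed.
#' @param ranges list with `rate` and `hill` ranges.
#' @param t_end,step,transient simulation settings per sample.
#' @param settings classifier settings.
#' @return a `robustness_result` tibble, one row per family: `family`,
#'   `n_samples`, `fraction_oscillating`, `minimal_hill`,
#'   `median_period`; seed and ranges kept as attributes.
#' @export
robustness_compare <- function(n_samples = 10000, seed = 1,
                               ranges = list(rate = c(0.1, 10),
                                             hill = c(1, 12)),
                               t_end = 600, step = 0.02, transient = 300,
                               settings = oscillation_settings()) {
  if (n_samples < 100)
    abort("n_samples must be >= 100", class = "clockloops_argument_error")
  run_family <- function(family, fam_seed) {
    set.seed(fam_seed)
    lu <- function(n, r) exp(runif(n, log(r[1]), log(r[2])))
    pars <- cbind(lu(n_samples, ranges$rate), lu(n_samples, ranges$rate),
                  lu(n_samples, ranges$rate), lu(n_samples, ranges$rate),
                  lu(n_samples, ranges$rate), lu(n_samples, ranges$rate),
                  lu(n_samples, ranges$hill))
    fam <- match(family, c("goodwin", "repressilator")) - 1L
    res <- cpp_prototype_batch(fam, pars, t_end, step, transient,
                               settings$eps_amp, settings$eps_cv,
                               settings$decay_tol, settings$min_peaks,
                               settings$prominence)
    osc <- res[, "oscillating"] == 1
    tibble::tibble(
      family = family, n_samples = n_samples,
      fraction_oscillating = mean(osc),
      minimal_hill = if (any(osc)) min(pars[osc, 7]) else NA_real_,
      median_period = if (any(osc)) median(res[osc, "period"]) else NA_real_)
  }
  out <- dplyr::bind_rows(run_family("goodwin", seed),
                          run_family("repressilator", seed + 1))
  structure(out, class = c("robustness_result", class(out)),
            seed = seed, ranges = ranges)
}
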