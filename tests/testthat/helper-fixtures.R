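# shared fixtures: memoised default model (clamp means cached in the shipped
# config) and synthetic trajectory builders

.fixture_env <- new.env(parent = emptyenv())

test_model <- function() {
  if (is.null(.fixture_env$model))
    .fixture_env$model <- default_clock_model()
  .fixture_env$model
}

# default-model trajectory reused across tests (500 h, step 0.05)
test_trajectory <- function() {
  if (is.null(.fixture_env$traj))
    .fixture_env$traj <- simulate_clock(test_model(), t_end = 500)
  .fixture_env$traj
}

test_report <- function() {
  if (is.null(.fixture_env$report))
    .fixture_env$report <- classify_oscillation(test_trajectory())
  .fixture_env$report
}

# synthetic multi-gene trajectory: per-gene sinusoids
# x_g(t) = mean_g + amp_g/2 * cos(2*pi*(t - phase_g)/period)
sinusoid_trajectory <- function(period = 24, t_end = 500, step = 0.05,
                                phases = setNames(rep(0, 5), clockloops:::clock_gene_names),
                                amps = setNames(rep(1, 5), clockloops:::clock_gene_names),
                                means = setNames(rep(2, 5), clockloops:::clock_gene_names)) {
  gn <- clockloops:::clock_gene_names
  tt <- seq(0, t_end, by = step)
  cols <- lapply(gn, function(g)
    means[[g]] + amps[[g]] / 2 * cos(2 * pi * (tt - phases[[g]]) / period))
  out <- tibble::as_tibble(c(list(time_h = tt), setNames(cols, gn)))
  structure(out, class = c("clock_trajectory", class(out)),
            step = step, gene_names = gn)
}

# quick classifier call on a bare numeric series
classify_series <- function(time, x, transient = 0,
                            settings = oscillation_settings()) {
  clockloops:::cpp_classify_series(time, x, transient, settings$eps_amp,
                                   settings$eps_cv, settings$decay_tol,
                                   settings$min_peaks, settings$prominence)
}

# all permutations of a character vector (tiny n only)
combinat_perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  do.call(c, lapply(seq_along(x), function(i)
    lapply(combinat_perms(x[-i]), function(p) c(x[i], p))))
}
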