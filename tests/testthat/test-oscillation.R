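test_that("peak detection matches analytic maxima and a brute-force oracle", {
  traj <- sinusoid_trajectory(period = 24, phases = c(Bmal1 = 0, Rev_erba = 0,
    Per2 = 0, Cry1 = 0, Dbp = 0))
  pk <- detect_peaks(traj, "Per2", window = c(300, 500))
  expect_true(all(abs(pk$peak_time %% 24) < 0.05 |
                  abs(pk$peak_time %% 24 - 24) < 0.05))
  expect_equal(diff(pk$peak_time), rep(24, length(pk$peak_time) - 1),
               tolerance = 1e-3)

  # monotone series has no strict maxima
  mono <- sinusoid_trajectory()
  mono$Per2 <- seq_along(mono$time_h) * 0.01
  expect_equal(nrow(detect_peaks(mono, "Per2")), 0)

  # 24 h fundamental plus a small 12 h harmonic: spacing stays 24 h,
  # verified against dense per-cycle argmax
  tt <- seq(0, 500, by = 0.05)
  x <- cos(2 * pi * tt / 24) + 0.2 * cos(2 * pi * tt / 12)
  tr <- sinusoid_trajectory()
  tr$Per2 <- x
  pk <- detect_peaks(tr, "Per2", window = c(90, 480))
  brute <- vapply(4:19, function(cyc) {
    idx <- tt >= cyc * 24 - 12 & tt < cyc * 24 + 12
    tt[idx][which.max(x[idx])]
  }, 0)
  expect_equal(length(pk$peak_time), length(brute))
  expect_equal(pk$peak_time, brute, tolerance = 0.05)

  expect_error(detect_peaks(traj, "Per2", window = c(600, 700)),
               class = "clockloops_argument_error")
  expect_error(detect_peaks(traj, "nope"),
               class = "clockloops_argument_error")
})

test_that("classifier separates limit cycles from damped and flat dynamics", {
  tt <- seq(0, 500, by = 0.05)
  base <- sinusoid_trajectory()
  # 5% amplitude decay per cycle: transient, not a limit cycle
  damped <- base
  damped$Per2 <- 2 + 0.95^(tt / 24) * cos(2 * pi * tt / 24)
  expect_false(classify_oscillation(damped, transient = 100)$oscillating)
  # constant trajectory
  flat <- base
  for (g in clockloops:::clock_gene_names) flat[[g]] <- rep(1.3, length(tt))
  repf <- classify_oscillation(flat, transient = 100)
  expect_false(repf$oscillating)
  expect_equal(repf$rel_amplitude, 0)
  # clean sinusoids across the circadian range: period within one step
  for (p in c(6, 12, 24, 40)) {
    tr <- sinusoid_trajectory(period = p)
    rep <- classify_oscillation(tr, transient = 100)
    expect_true(rep$oscillating)
    expect_equal(rep$period, p, tolerance = 0.05 / p)
  }
})

test_that("supercritical Hopf normal form classifies with its analytic period", {
  # r' = mu r - r^3, theta' = omega: limit cycle r = sqrt(mu), period 2pi/omega
  mu <- 0.25; omega <- 2 * pi / 24
  f <- function(t, y, parms) {
    r2 <- y[1]^2 + y[2]^2
    list(c(mu * y[1] - omega * y[2] - y[1] * r2,
           omega * y[1] + mu * y[2] - y[2] * r2))
  }
  out <- deSolve::ode(c(0.05, 0), seq(0, 500, by = 0.05), f, NULL)
  tr <- sinusoid_trajectory()
  tr$Per2 <- 2 + out[, 2]
  rep <- classify_oscillation(tr, transient = 200)
  expect_true(rep$oscillating)
  expect_equal(rep$period, 24, tolerance = 1e-3)
  amp <- rep$genes$rel_amplitude[rep$genes$gene == "Per2"]
  expect_equal(amp, 2 * sqrt(mu) / 2, tolerance = 0.02)
})

test_that("classification is invariant under rescaling and time translation", {
  m <- test_model()
  traj <- test_trajectory()
  rep <- test_report()
  scaled <- traj
  for (g in clockloops:::clock_gene_names) scaled[[g]] <- traj[[g]] * 7
  rep_s <- classify_oscillation(scaled)
  expect_equal(rep_s$oscillating, rep$oscillating)
  expect_equal(rep_s$period, rep$period, tolerance = 1e-12)
  expect_equal(rep_s$genes$rel_amplitude, rep$genes$rel_amplitude,
               tolerance = 1e-9)
  # translation by an integer number of steps (drop the first 10 h)
  shifted <- traj[traj$time_h >= 10, ]
  shifted$time_h <- shifted$time_h - 10
  attr(shifted, "gene_names") <- clockloops:::clock_gene_names
  rep_t <- classify_oscillation(shifted)
  expect_equal(rep_t$period, rep$period, tolerance = 1e-6)
})

test_that("periods agree with a discrete-Fourier dominant-frequency oracle", {
  traj <- test_trajectory()
  rep <- test_report()
  x <- traj$Per2[traj$time_h >= 300]
  x <- x - mean(x)
  n <- length(x)
  spec <- Mod(stats::fft(x))[2:floor(n / 2)]
  freq <- (seq_along(spec)) / (n * 0.05)
  p_fft <- 1 / freq[which.max(spec)]
  # grid resolution of the DFT at ~24 h over a 200 h window is coarse
  expect_equal(rep$period, p_fft, tolerance = 24 / (200 / 24) / 24)
})

test_that("phase differences are circular and ordered as published", {
  tr <- sinusoid_trajectory(phases = c(Bmal1 = 0, Rev_erba = 6, Per2 = 0,
                                       Cry1 = 0, Dbp = 0))
  rep <- classify_oscillation(tr, transient = 100)
  expect_equal(unname(phase_of(rep, "Per2", "Per2")), 0)
  expect_equal(unname(phase_of(rep, "Rev_erba", "Bmal1")), 6, tolerance = 0.02)
  expect_equal(unname(phase_of(rep, "Bmal1", "Rev_erba")), 18, tolerance = 0.02)
  flat <- sinusoid_trajectory()
  for (g in clockloops:::clock_gene_names) flat[[g]] <- 1
  expect_error(phase_of(classify_oscillation(flat), "Per2", "Cry1"),
               class = "clockloops_state_error")
})

test_that("report writer emits one row with per-gene columns", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_report(test_report(), f)
  row <- read.csv(f)
  expect_equal(nrow(row), 1)
  expect_true(all(c("oscillating", "period_h", "amp_Per2", "phase_Cry1",
                    "mean_Bmal1") %in% names(row)))
})
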