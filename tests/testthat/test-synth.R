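test_that("noise-free profiles are exact cosines with the requested phases", {
  prof <- generate_profiles(noise_sd = 0, replicates = 1, seed = 3)
  for (g in clockloops:::clock_gene_names) {
    pg <- prof[prof$gene == g, ]
    peak <- pg$time_h[which.max(pg$value)] %% 24
    expect_equal(peak,
                 c(Bmal1 = 23, Rev_erba = 5, Per2 = 15, Cry1 = 19,
                   Dbp = 11)[[g]], tolerance = 1)
    expect_equal(mean(pg$value), 1, tolerance = 1e-12) # whole-cycle grid
  }
  expect_true(all(prof$value > 0))
})

test_that("profile generation is reproducible per seed and validates input", {
  a <- generate_profiles(seed = 11)
  b <- generate_profiles(seed = 11)
  expect_identical(a, b)
  c <- generate_profiles(seed = 12)
  expect_false(identical(a$value, c$value))
  expect_error(generate_profiles(dt = 5), class = "clockloops_argument_error")
  expect_error(generate_profiles(noise_sd = -1),
               class = "clockloops_argument_error")
  expect_error(generate_profiles(phases = c(Bmal1 = 25, Rev_erba = 5,
                                            Per2 = 15, Cry1 = 19, Dbp = 11)),
               class = "clockloops_argument_error")
})

test_that("log-normal noise factors have unit mean (law of large numbers)", {
  prof <- generate_profiles(noise_sd = 0.15, replicates = 1, n_days = 1,
                            dt = 2, seed = 21)
  clean <- generate_profiles(noise_sd = 0, replicates = 1, n_days = 1,
                             dt = 2, seed = 21)
  # regenerate many replicates to average the noise factor
  many <- generate_profiles(noise_sd = 0.15, replicates = 2000, n_days = 1,
                            dt = 12, seed = 22)
  clean12 <- generate_profiles(noise_sd = 0, replicates = 1, n_days = 1,
                               dt = 12, seed = 1)
  joined <- merge(many, clean12[, c("gene", "time_h", "value")],
                  by = c("gene", "time_h"), suffixes = c("", "_clean"))
  factors <- joined$value / joined$value_clean
  n <- length(factors)
  expect_gt(n, 10000)
  se <- sd(factors) / sqrt(n)
  expect_lt(abs(mean(factors) - 1), 4 * se + 1e-3)
  expect_true(all(prof$value > 0) && all(clean$value > 0))
})

test_that("normalisation gives unit whole-cycle means and scale invariance", {
  prof <- generate_profiles(noise_sd = 0.2, seed = 8)
  norm <- normalize_profiles(prof)
  means <- tapply(norm$value, norm$gene, mean)
  expect_equal(as.numeric(means), rep(1, 5), tolerance = 1e-9)
  scaled <- prof
  scaled$value <- scaled$value * 7
  expect_equal(normalize_profiles(scaled)$value, norm$value,
               tolerance = 1e-12)
  flat <- prof
  flat$value <- 3.2
  expect_true(all(normalize_profiles(flat)$value == 1))
  neg <- prof
  neg$value[1] <- -1
  expect_error(normalize_profiles(neg), class = "clockloops_domain_error")
})

test_that("a budget of one evaluation returns the initial guess", {
  m <- test_model()
  prof <- generate_profiles(noise_sd = 0, replicates = 1)
  fit <- fit_clock(m, prof, c("actn_1_2", "inh_4_3"), budget = 1, seed = 2)
  expect_equal(unname(fit$par),
               unname(clock_params(m)[c("actn_1_2", "inh_4_3")]))
  expect_equal(fit$n_eval, 1)
  expect_true(is.finite(fit$cost))
  expect_error(fit_clock(m, prof, "zzz"), class = "clockloops_argument_error")
})

test_that("fit cost is invariant under rescaling of the profiles", {
  m <- test_model()
  prof <- generate_profiles(noise_sd = 0, replicates = 1)
  f1 <- fit_clock(m, prof, "actn_1_2", budget = 1, seed = 2)
  prof2 <- prof
  prof2$value <- prof2$value * 11
  f2 <- fit_clock(m, prof2, "actn_1_2", budget = 1, seed = 2)
  expect_equal(f1$cost, f2$cost, tolerance = 1e-10)
})

test_that("noise-free self-generated profiles are recovered within 10%", {
  m <- test_model()
  truth <- clock_params(m)
  free <- c("inh_4_3", "inh_3_2", "d_3", "V_4")
  traj <- simulate_clock(m, t_end = 500)
  prof <- profiles_from_trajectory(traj, t_start = 400)
  # perturbed template: fitting must travel back to the truth
  start <- m
  start <- set_clock_param(start, "inh_4_3", truth[["inh_4_3"]] * 0.5)
  start <- set_clock_param(start, "inh_3_2", truth[["inh_3_2"]] * 2.0)
  start <- set_clock_param(start, "d_3", truth[["d_3"]] * 0.7)
  start <- set_clock_param(start, "V_4", truth[["V_4"]] * 1.5)
  lower <- truth[free] * 0.3
  upper <- truth[free] * 3
  upper["inh_4_3"] <- min(upper["inh_4_3"], 0.99)
  upper["inh_3_2"] <- min(upper["inh_3_2"], 0.99)
  fit <- fit_clock(start, prof, free, lower = lower, upper = upper,
                   budget = 2400, pop = 20, seed = 4)
  expect_lt(fit$cost, 1e-3)
  rel_err <- abs(fit$par - truth[free]) / truth[free]
  expect_true(all(rel_err < 0.10),
              info = paste(names(rel_err), round(rel_err, 3), collapse = "; "))
  # deterministic for fixed seed and budget
  fit2 <- fit_clock(start, prof, free, lower = lower, upper = upper,
                    budget = 2400, pop = 20, seed = 4)
  expect_identical(fit$par, fit2$par)
})
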