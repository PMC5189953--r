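test_that("default config carries the published kinetic constants", {
  m <- test_model()
  p <- clock_params(m)
  expect_length(p, 34)
  expect_false(any(duplicated(names(p))))
  expect_equal(unname(p["d_4"]), 0.2)       # Cry1 mRNA degradation
  expect_equal(unname(p["tau_3"]), 3.82)    # Per2 delay
  expect_equal(unname(p["tau_4"]), 3.13)    # Cry1 (self-loop) delay
  expect_equal(unname(p["actn_1_2"]), 3.26) # Bmal1 -> Rev-erba activation
  expect_equal(unname(p["inh_4_3"]), 0.37)  # Cry1 -| Per2 inhibition
})

test_that("topology invariants hold: 17 edges, 7 + 10 signs, key motifs", {
  m <- test_model()
  e <- m$regulations
  expect_equal(nrow(e), 17)
  expect_equal(sum(e$sign == "activation"), 7)
  expect_equal(sum(e$sign == "inhibition"), 10)
  # repressilator cycle, all inhibitory
  expect_true(all(c("inh_3_2", "inh_2_4", "inh_4_3") %in% e$param))
  # Cry1 self-inhibition and the Cry1 -| Dbp -> Per2 feedforward path
  expect_true("inh_4_4" %in% e$param)
  expect_true(all(c("inh_4_5", "actn_5_3") %in% e$param))
  # no Rev-erba self-regulation in the reconstruction
  expect_false(any(e$source == "Rev_erba" & e$target == "Rev_erba"))
})

test_that("loading rejects malformed configs loudly", {
  path <- system.file("extdata", "clock-model.yaml", package = "clockloops")
  cfg <- yaml::read_yaml(path)

  bad <- cfg
  bad$regulations <- bad$regulations[-1]            # 16 edges
  f1 <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(bad, f1)
  expect_error(load_model(f1), class = "clockloops_topology_error")

  bad <- cfg
  bad$regulations[[1]]$strength <- NULL             # missing parameter
  f2 <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(bad, f2)
  expect_error(load_model(f2), regexp = "strength",
               class = "clockloops_config_error")

  bad <- cfg
  i_act <- which(vapply(cfg$regulations, function(r)
    identical(r$sign, "activation"), TRUE))[1]
  bad$regulations[[i_act]]$sign <- "inhibition"     # 6/11 sign split
  f3 <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(bad, f3)
  expect_error(load_model(f3), class = "clockloops_topology_error")

  bad <- cfg
  bad$genes[[2]]$degradation <- NULL                # missing gene constant
  f4 <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(bad, f4)
  expect_error(load_model(f4), class = "clockloops_config_error")

  expect_error(load_model(withr::local_tempfile(fileext = ".yaml")),
               class = "clockloops_config_error")   # no such file
})

test_that("write/load round-trip reproduces the model", {
  m <- test_model()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_model(m, f)
  m2 <- load_model(f)
  expect_equal(clock_params(m2), clock_params(m), tolerance = 1e-12)
  expect_equal(m2$clamp_means, m$clamp_means, tolerance = 1e-12)
  expect_equal(m2$regulations$param, m$regulations$param)
})

test_that("parameter access by name works and rejects unknowns", {
  m <- test_model()
  m2 <- set_clock_param(m, "tau_3", 5)
  expect_equal(get_clock_param(m2, "tau_3"), 5)
  expect_equal(get_clock_param(m2, "d_4"), 0.2) # untouched
  m3 <- set_clock_param(m, "h_inh", 3)
  expect_true(all(m3$regulations$exponent[m3$regulations$sign == "inhibition"] == 3))
  expect_error(set_clock_param(m, "nope", 1),
               class = "clockloops_argument_error")
  expect_error(get_clock_param(m, "tau_9"),
               class = "clockloops_argument_error")
})

test_that("regulation factors are bounded, monotone and clampable", {
  m <- test_model()
  act <- as.list(m$regulations[m$regulations$param == "actn_1_2", ])
  inh <- as.list(m$regulations[m$regulations$param == "inh_4_3", ])
  # boundary: absent activator contributes the basal factor 1
  expect_equal(regulation_factor(act, 0), 1)
  expect_equal(regulation_factor(inh, 0), 1)
  # saturation: factor approaches the strength bound
  expect_equal(regulation_factor(act, 1e9), act$strength, tolerance = 1e-4)
  expect_equal(regulation_factor(inh, 1e9), inh$strength, tolerance = 1e-4)
  # monotonicity against a dense brute-force grid
  y <- seq(0, 20, by = 0.01)
  expect_true(all(diff(regulation_factor(act, y)) >= 0))
  expect_true(all(diff(regulation_factor(inh, y)) <= 0))
  expect_true(all(regulation_factor(act, y) >= 1 - 1e-12) &&
              all(regulation_factor(act, y) <= act$strength + 1e-12))
  expect_true(all(regulation_factor(inh, y) > 0))
  # clamping: the factor ignores y entirely
  actc <- act; actc$clamped <- TRUE
  v <- regulation_factor(actc, c(0, 1, 100), mean = 0.8)
  expect_true(all(v == regulation_factor(act, 0.8)))
  expect_error(regulation_factor(act, -1), class = "clockloops_domain_error")
  expect_error(regulation_factor(actc, 1, mean = NULL),
               class = "clockloops_domain_error")
})
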