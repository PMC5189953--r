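test_that("canonical edge order is fixed and documented", {
  ce <- canonical_edges(test_model())
  expect_equal(nrow(ce), 17)
  expect_equal(ce$bit, 1:17)
  # sorted by (target index, source index) and stable across calls
  expect_equal(ce$param[1], "inh_2_1")      # only regulator of Bmal1
  expect_identical(ce, canonical_edges(test_model()))
  expect_equal(sort(repressilator_bits(test_model())),
               ce$bit[ce$param %in% c("inh_3_2", "inh_2_4", "inh_4_3")])
})

test_that("all-ON equals the unclamped model; all-OFF and full node clamps freeze", {
  m <- test_model()
  t_ref <- simulate_clock(m, t_end = 150)
  t_on <- simulate_clock(clamp_edges(m, on = rep(TRUE, 17)), t_end = 150)
  expect_identical(as.data.frame(t_on), as.data.frame(t_ref))

  t_off <- simulate_clock(clamp_edges(m, on = rep(FALSE, 17)), t_end = 300)
  rng <- apply(as.matrix(t_off[t_off$time_h > 200, -1]), 2, function(v)
    diff(range(v)))
  expect_true(all(rng < 1e-6))

  t_all <- simulate_clock(clamp_nodes(m, clockloops:::clock_gene_names),
                          t_end = 50)
  expect_true(all(apply(as.matrix(t_all[, -1]), 2, function(v)
    diff(range(v))) == 0))
  rep_all <- classify_oscillation(t_all, transient = 10)
  expect_false(rep_all$oscillating)
})

test_that("node clamping equals clamping all outgoing edges, for other genes", {
  m <- test_model()
  for (g in c("Dbp", "Bmal1")) {
    by_node <- simulate_clock(clamp_nodes(m, g), t_end = 200)
    out_edges <- m$regulations$param[m$regulations$source == g]
    by_edges <- simulate_clock(clamp_edges(m, clamp = out_edges), t_end = 200)
    others <- setdiff(clockloops:::clock_gene_names, g)
    expect_equal(as.matrix(by_node[, others]), as.matrix(by_edges[, others]),
                 tolerance = 1e-12)
  }
  expect_error(clamp_nodes(m, "Per3"), class = "clockloops_argument_error")
})

test_that("clamping operations demand precomputed clamp means", {
  m <- test_model()
  m$clamp_means <- NULL
  expect_error(clamp_nodes(m, "Dbp"), class = "clockloops_state_error")
  expect_error(clamp_edges(m, on = rep(FALSE, 17)),
               class = "clockloops_state_error")
  expect_error(edge_census(m, config_ids = 0:3),
               class = "clockloops_state_error")
})

test_that("census is a pure function of model and settings", {
  m <- test_model()
  # all configurations with at least 15 edges ON (downscaled smoke census)
  full_on <- 2^17 - 1
  ids <- full_on
  for (i in 1:17) ids <- c(ids, bitwXor(full_on, bitwShiftL(1L, i - 1L)))
  for (i in 1:16) for (j in (i + 1):17)
    ids <- c(ids, bitwXor(full_on, bitwOr(bitwShiftL(1L, i - 1L),
                                          bitwShiftL(1L, j - 1L))))
  cen <- edge_census(m, config_ids = ids, t_end = 400, transient = 250)
  expect_equal(nrow(cen), 1 + 17 + choose(17, 2))
  # the unclamped configuration is in there and oscillates
  expect_true(cen$oscillating[cen$config_id == full_on])
  expect_equal(cen$n_on[cen$config_id == full_on], 17)

  # iteration order and chunking do not change the result
  cen_shuf <- edge_census(m, config_ids = rev(ids), t_end = 400,
                          transient = 250, chunk = 37)
  expect_identical(as.data.frame(cen), as.data.frame(cen_shuf))
})

test_that("census checkpointing resumes after a corrupted tail", {
  m <- test_model()
  ids <- 0:59 # mostly-clamped configs integrate fast
  ck <- withr::local_tempfile(fileext = ".csv")
  ref <- edge_census(m, config_ids = ids, t_end = 300, transient = 200)
  part <- edge_census(m, config_ids = ids[1:40], t_end = 300, transient = 200,
                      checkpoint = ck, chunk = 20)
  # corrupt the checkpoint tail
  lines <- readLines(ck)
  writeLines(c(lines[1:30], "garbage,,,,NA,bad"), ck)
  expect_warning(
    res <- edge_census(m, config_ids = ids, t_end = 300, transient = 200,
                       checkpoint = ck, chunk = 20),
    regexp = "corrupt|checkpoint")
  res <- res[, names(ref)]
  expect_equal(as.data.frame(res), as.data.frame(ref), tolerance = 1e-12)
})

test_that("edge importance is exactly 0.5 over the unfiltered space", {
  # combinatorial symmetry: every edge is ON in half of all 2^17 configs;
  # feed the full configuration space in as if everything oscillated
  fake <- tibble::tibble(config_id = 0:(2^17 - 1), oscillating = TRUE)
  imp <- edge_importance(fake, test_model())
  expect_equal(imp$on_frequency, rep(0.5, 17))
  empty <- tibble::tibble(config_id = 0:10, oscillating = FALSE)
  expect_error(edge_importance(empty, test_model()),
               class = "clockloops_state_error")
})

test_that("motif frequency counts joint ON membership", {
  cen <- tibble::tibble(config_id = c(7L, 5L, 3L, 8L),
                        oscillating = c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(motif_frequency(cen, bits = 1:2), 2 / 3)
  expect_equal(motif_frequency(cen, bits = 3), 2 / 3)
})

test_that("loop enumeration matches an independent cycle oracle", {
  m <- test_model()
  loops <- enumerate_loops(m)
  # oracle: exhaustive enumeration over ordered gene tuples (anchored at
  # their smallest member so each cycle is counted once)
  gn <- clockloops:::clock_gene_names
  has_edge <- function(a, b) any(m$regulations$source == a &
                                 m$regulations$target == b)
  oracle_lengths <- integer(0)
  for (k in 1:5) {
    if (k == 1) {
      oracle_lengths <- c(oracle_lengths,
                          rep(1L, sum(vapply(gn, function(g)
                            has_edge(g, g), TRUE))))
      next
    }
    subsets <- utils::combn(gn, k, simplify = FALSE)
    for (s in subsets) {
      anchor <- s[which.min(match(s, gn))]
      rest <- setdiff(s, anchor)
      perms <- combinat_perms(rest)
      for (p in perms) {
        cyc <- c(anchor, p)
        ok <- all(vapply(seq_len(k), function(i)
          has_edge(cyc[i], cyc[if (i == k) 1 else i + 1]), TRUE))
        if (ok) oracle_lengths <- c(oracle_lengths, k)
      }
    }
  }
  expect_equal(nrow(loops), length(oracle_lengths))
  expect_equal(sort(loops$length), sort(oracle_lengths))
  # Cry1 self-inhibition: negative 1-loop with the short published delay
  self <- loops[loops$length == 1 & grepl("Cry1", loops$loop), ]
  expect_equal(nrow(self), 1)
  expect_equal(self$sign, -1)
  expect_equal(self$total_delay_h, 3.13)
  # repressilator triangle: three inhibitions, net negative
  tri <- loops[loops$length == 3 &
               vapply(loops$genes, function(gs)
                 setequal(gs, c("Per2", "Rev_erba", "Cry1")), TRUE), ]
  expect_true(any(tri$sign == -1))
  tau <- setNames(m$genes$delay, m$genes$name)
  expect_true(any(abs(tri$total_delay_h -
                      sum(tau[c("Per2", "Rev_erba", "Cry1")])) < 1e-12))
})

test_that("viability scan summarises one-at-a-time parameter variation", {
  m <- test_model()
  v <- subnetwork_viability(m, "Dbp", fold = 5, n_points = 3, t_end = 400,
                            transient = 250)
  expect_equal(v$n_points, 34 * 3)
  expect_equal(v$n_active, 4)
  expect_gt(v$fraction_oscillating, 0.5)
  expect_true(v$q25 <= v$median_period && v$median_period <= v$q75)
  det <- subnetwork_viability(m, "Dbp", fold = 5, n_points = 3, t_end = 400,
                              transient = 250, detail = TRUE)
  expect_equal(nrow(det), 34 * 3)
})
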