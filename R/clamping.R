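#' Canonical edge order of the network
#'
#' All edge-clamp configurations are encoded as 17 bits in a fixed
#' canonical order: edges sorted by (target index, source index). Bit `e`
#' of a configuration id corresponds to row `e` of this table; ON = TRUE
#' means the regulation is active, OFF means it is clamped at the
#' regulator's mean.
#'
#' @param model a `clock_model`.
#' @return tibble of the 17 regulations with a `bit` column (1..17) and a
#'   human-readable `label`.
#' @export
canonical_edges <- function(model = default_clock_model()) {
  e <- model$regulations
  tibble::tibble(
    bit = seq_len(nrow(e)), param = e$param, source = e$source,
    target = e$target, sign = e$sign,
    label = paste0(e$source, ifelse(e$sign == "activation", " -> ", " -| "),
                   e$target))
}

#' Clamp genes (nodes) to their limit-cycle means
#'
#' Clamped genes are held constant at the cached clamp means: their state
#' no longer changes, their outgoing regulations are evaluated at the mean
#' forever, and incoming regulations have no effect. This mimics
#' constitutive expression from a non-rhythmic promoter and is how
#' sub-networks are isolated.
#'
#' @param model a `clock_model` with `clamp_means` set
#'   (see [with_clamp_means()]).
#' @param genes character vector of gene names to clamp.
#' @return the clamped model.
#' @export
clamp_nodes <- function(model, genes) {
  bad <- setdiff(genes, clock_gene_names)
  if (length(bad))
    abort(paste0("unknown gene(s): ", paste(bad, collapse = ", ")),
          class = "clockloops_argument_error")
  if (is.null(model$clamp_means))
    abort("clamp means are not set; call with_clamp_means() first",
          class = "clockloops_state_error")
  model$node_clamps <- sort(unique(c(model$node_clamps, genes)))
  model
}

#' Clamp a set of regulations (edges)
#'
#' OFF edges evaluate their regulation factor at the regulator's clamp
#' mean forever; ON edges are untouched and all kinetic parameters stay
#' at their defaults.
#'
#' @param model a `clock_model` with `clamp_means` set.
#' @param on logical vector of length 17 in canonical edge order
#'   (TRUE = active); alternatively pass `clamp` instead.
#' @param clamp character vector of edge parameter names (e.g.
#'   `"actn_1_2"`) to clamp, all others stay active.
#' @return the model with edge clamps applied.
#' @export
clamp_edges <- function(model, on = NULL, clamp = NULL) {
  if (is.null(model$clamp_means))
    abort("clamp means are not set; call with_clamp_means() first",
          class = "clockloops_state_error")
  if (is.null(on)) {
    if (is.null(clamp))
      abort("give either `on` or `clamp`", class = "clockloops_argument_error")
    bad <- setdiff(clamp, model$regulations$param)
    if (length(bad))
      abort(paste0("unknown edge(s): ", paste(bad, collapse = ", ")),
            class = "clockloops_argument_error")
    on <- !(model$regulations$param %in% clamp)
  }
  if (length(on) != 17 || !is.logical(on))
    abort("`on` must be a logical vector of length 17",
          class = "clockloops_argument_error")
  model$regulations$clamped <- !on
  model
}

config_bits <- function(ids, n_edges = 17) {
  # rows of ON/OFF bits for integer configuration ids (bit 1 = edge 1)
  vapply(seq_len(n_edges), function(e)
    bitwAnd(ids, bitwShiftL(1L, e - 1L)) != 0L,
    logical(length(ids)))
}

#' Exhaustive (or subsampled) edge-clamp census
#'
#' Iterates ON/OFF configurations of the 17 regulations, simulates each
#' clamped model from the clamp-mean history, classifies the trajectory,
#' and records the verdict and period. The full space has
#' 2^17 = 131072 configurations; pass `config_ids` for a subset. The
#' result is a pure function of the model and classifier settings: worker
#' count, chunking and iteration order do not change it.
#'
#' @param model a `clock_model` with `clamp_means` set.
#' @param config_ids integer vector of configuration ids in
#'   `0:(2^17-1)` (bit `e` set = edge `e` of [canonical_edges()] active);
#'   default all.
#' @param t_end,step,transient simulation settings (defaults 500 h /
#'   0.05 h / 300 h).
#' @param settings classifier settings.
#' @param workers parallel workers (forked; results are order-stable).
#' @param checkpoint optional CSV path; finished chunks are appended and
#'   a rerun resumes after the last complete chunk (a corrupted tail is
#'   dropped with a warning).
#' @param chunk chunk granularity for checkpointing (default 4096).
#' @return a `config_census` tibble: `config_id`, `n_on`, `oscillating`,
#'   `period`, `rel_amp`, `cv`, `torus`.
#' @export
edge_census <- function(model, config_ids = NULL, t_end = 500, step = 0.05,
                        transient = 300, settings = oscillation_settings(),
                        workers = 1, checkpoint = NULL, chunk = 4096) {
  if (is.null(model$clamp_means))
    abort("clamp means are not set; call with_clamp_means() first",
          class = "clockloops_state_error")
  if (is.null(config_ids)) config_ids <- 0:(2^17 - 1)
  config_ids <- as.integer(config_ids)
  done <- NULL
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    done <- tryCatch(read.csv(checkpoint), error = function(e) NULL)
    ok_cols <- c("config_id", "n_on", "oscillating", "period", "rel_amp",
                 "cv", "torus")
    if (is.null(done) || !identical(names(done), ok_cols)) {
      warn("checkpoint unreadable; restarting census from scratch")
      done <- NULL
    } else {
      done$config_id <- suppressWarnings(as.integer(done$config_id))
      done$n_on <- suppressWarnings(as.integer(done$n_on))
      done$oscillating <- suppressWarnings(as.logical(done$oscillating))
      for (cc in c("period", "rel_amp", "cv"))
        done[[cc]] <- suppressWarnings(as.numeric(done[[cc]]))
      done$torus <- suppressWarnings(as.logical(done$torus))
      keep <- stats::complete.cases(done[, c("config_id", "oscillating")])
      if (!all(keep)) {
        warn(sprintf("dropping %d corrupt checkpoint row(s)", sum(!keep)))
        done <- done[keep, ]
      }
      done <- done[!duplicated(done$config_id), ]
      done <- done[done$config_id %in% config_ids, ]
    }
  }
  todo <- if (is.null(done)) config_ids else setdiff(config_ids, done$config_id)
  chunks <- split(todo, ceiling(seq_along(todo) / chunk))
  run_chunk <- function(ids) {
    bits <- config_bits(ids)
    if (is.null(dim(bits))) bits <- matrix(bits, nrow = 1)
    res <- cpp_census(model_to_cpp(model), matrix(as.integer(bits), ncol = 17),
                      t_end, step, transient, settings$eps_amp,
                      settings$eps_cv, settings$decay_tol, settings$min_peaks,
                      settings$prominence,
                      match(settings$ref_gene, clock_gene_names) - 1L)
    data.frame(config_id = ids, n_on = rowSums(bits),
               oscillating = res[, "oscillating"] == 1,
               period = res[, "period"], rel_amp = res[, "rel_amp"],
               cv = res[, "cv"], torus = res[, "torus"] == 1)
  }
  new <- list()
  if (length(chunks)) {
    if (workers > 1) {
      new <- parallel::mclapply(chunks, run_chunk, mc.cores = workers)
    } else {
      new <- lapply(chunks, run_chunk)
    }
    if (!is.null(checkpoint)) {
      for (df in new)
        suppressWarnings(write.table(
          df, checkpoint, sep = ",", row.names = FALSE,
          col.names = !file.exists(checkpoint), append = file.exists(checkpoint)))
    }
  }
  out <- dplyr::bind_rows(c(list(done), new))
  out <- dplyr::arrange(tibble::as_tibble(out), .data$config_id)
  structure(out, class = c("config_census", class(out)),
            total = length(config_ids))
}

#' Stratified subsample of the edge-configuration space
#'
#' Draws a deterministic (seeded) subsample of configuration ids,
#' stratified by the number of ON edges so the subsample's composition
#' matches the full 2^17 space and the oscillating fraction estimated
#' from it is unbiased.
#'
#' @param n subsample size.
#' @param seed RNG seed.
#' @return sorted integer vector of configuration ids.
#' @export
census_subsample_ids <- function(n = 4096, seed = 1) {
  all_ids <- 0:(2^17 - 1)
  pop <- rowSums(config_bits(all_ids))
  set.seed(seed)
  quota <- round(n * choose(17, 0:17) / 2^17)
  ids <- unlist(lapply(0:17, function(k) {
    stratum <- all_ids[pop == k]
    take <- min(quota[k + 1], length(stratum))
    if (take == 0) return(integer(0))
    sort(sample(stratum, take))
  }))
  sort(ids)
}

#' Per-edge importance over the oscillating configurations
#'
#' For each regulation, the relative frequency with which it is ON among
#' the oscillating configurations of a census. Over the unfiltered
#' configuration space every edge is ON in exactly half the
#' configurations, so values near 0.5 mark non-essential interactions and
#' values near 1 mark interactions almost every rhythm depends on.
#'
#' @param census a `config_census`.
#' @param model the model the census was run on (for edge labels).
#' @return tibble with one row per edge: `bit`, `label`, `sign`,
#'   `on_frequency`.
#' @export
edge_importance <- function(census, model = default_clock_model()) {
  osc <- census$config_id[census$oscillating]
  if (!length(osc))
    abort("no oscillating configurations; importance undefined",
          class = "clockloops_state_error")
  bits <- config_bits(as.integer(osc))
  if (is.null(dim(bits))) bits <- matrix(bits, nrow = 1)
  edges <- canonical_edges(model)
  edges$on_frequency <- colMeans(bits)
  structure(edges, class = c("edge_importance", class(edges)))
}

#' Joint ON-frequency of an edge set among oscillating configurations
#'
#' @param census a `config_census`.
#' @param bits integer vector of edge bits (rows of [canonical_edges()]).
#' @return fraction of oscillating configurations with all given edges ON.
#' @export
motif_frequency <- function(census, bits) {
  osc <- as.integer(census$config_id[census$oscillating])
  if (!length(osc))
    abort("no oscillating configurations", class = "clockloops_state_error")
  mask <- sum(bitwShiftL(1L, as.integer(bits) - 1L))
  mean(bitwAnd(osc, mask) == mask)
}

#' Bits of the repressilator motif
#'
#' Canonical bit positions of the three serial inhibitions
#' Per2 -| Rev_erba, Rev_erba -| Cry1 and Cry1 -| Per2.
#'
#' @param model a `clock_model`.
#' @return integer vector of length 3.
#' @export
repressilator_bits <- function(model = default_clock_model()) {
  ce <- canonical_edges(model)
  ce$bit[ce$param %in% c("inh_3_2", "inh_2_4", "inh_4_3")]
}

#' Oscillation viability of a node-clamped sub-network
#'
#' For the sub-network obtained by clamping `genes`, varies each of the
#' 34 kinetic parameters one at a time over a log-spaced grid from
#' `fold`-fold reduction to `fold`-fold increase, simulates every point,
#' and summarises the fraction of oscillating parameter points and the
#' median and quartile period among them.
#'
#' @param model a `clock_model` with clamp means.
#' @param genes genes to clamp (possibly empty).
#' @param fold fold-range of the one-at-a-time variation (default 5).
#' @param n_points grid points per parameter (default 200).
#' @param t_end,step,transient,settings simulation/classifier settings.
#' @param detail return the per-point table instead of the summary row.
#' @return one summary row (tibble): `clamped`, `n_active`,
#'   `fraction_oscillating`, `median_period`, `q25`, `q75`, `n_points`;
#'   or the full per-point table if `detail = TRUE`.
#' @export
subnetwork_viability <- function(model, genes, fold = 5, n_points = 200,
                                 t_end = 500, step = 0.05, transient = 300,
                                 settings = oscillation_settings(),
                                 detail = FALSE) {
  stopifnot(fold > 1, n_points >= 2)
  sub <- if (length(genes)) clamp_nodes(model, genes) else model
  # the verdict must be read off a gene that is still free to oscillate
  if (settings$ref_gene %in% genes) {
    pref <- c("Per2", "Rev_erba", "Cry1", "Bmal1", "Dbp")
    settings$ref_gene <- setdiff(pref, genes)[1]
  }
  pars <- clock_params(model)
  mult <- 10^seq(-log10(fold), log10(fold), length.out = n_points)
  rows <- purrr::map_dfr(names(pars), function(pn) {
    purrr::map_dfr(mult, function(m) {
      mm <- set_clock_param(sub, pn, pars[[pn]] * m)
      st <- min(step, max(min_active_delay(mm), step / 20))
      traj <- simulate_clock(mm, t_end = t_end, step = st)
      cls <- cpp_classify_series(traj$time_h, traj[[settings$ref_gene]],
                                 transient, settings$eps_amp, settings$eps_cv,
                                 settings$decay_tol, settings$min_peaks,
                                 settings$prominence)
      tibble::tibble(param = pn, multiplier = m,
                     oscillating = isTRUE(cls$oscillating),
                     period = if (isTRUE(cls$oscillating)) cls$period else NA_real_)
    })
  })
  if (detail) return(rows)
  per <- rows$period[rows$oscillating]
  tibble::tibble(
    clamped = paste(sort(genes), collapse = "+"),
    n_active = 5 - length(genes),
    fraction_oscillating = mean(rows$oscillating),
    median_period = if (length(per)) median(per) else NA_real_,
    q25 = if (length(per)) unname(quantile(per, 0.25)) else NA_real_,
    q75 = if (length(per)) unname(quantile(per, 0.75)) else NA_real_,
    n_points = nrow(rows))
}

#' Viability of every gene-subset sub-network
#'
#' Maps [subnetwork_viability()] over all clamp sets of the given sizes
#' (e.g. `sizes = 1` clamps each single gene, `sizes = 3` each triple,
#' leaving 2-gene sub-networks).
#'
#' @inheritParams subnetwork_viability
#' @param sizes clamp-set sizes to enumerate.
#' @return tibble with one row per clamp set.
#' @export
viability_scan <- function(model, sizes = 1:3, fold = 5, n_points = 200,
                           t_end = 500, step = 0.05, transient = 300,
                           settings = oscillation_settings()) {
  sets <- unlist(lapply(sizes, function(k)
    utils::combn(clock_gene_names, k, simplify = FALSE)), recursive = FALSE)
  purrr::map_dfr(sets, function(s)
    subnetwork_viability(model, s, fold = fold, n_points = n_points,
                         t_end = t_end, step = step, transient = transient,
                         settings = settings))
}

#' Enumerate feedback loops of the network
#'
#' All directed simple cycles of the 17-edge graph (self-loops included),
#' with the net sign (product of edge signs) and the total delay (sum of
#' the source-gene delays along the cycle).
#'
#' @param model a `clock_model`.
#' @return tibble: `loop` (readable path), `length`, `sign`
#'   (+1 / -1), `total_delay_h`, `genes` (list column of the cycle's gene
#'   names in order).
#' @export
enumerate_loops <- function(model) {
  e <- model$regulations
  tau <- setNames(model$genes$delay, model$genes$name)
  sgn <- ifelse(e$sign == "activation", 1, -1)
  adj <- split(seq_len(nrow(e)), e$source)
  loops <- list()
  # simple-cycle enumeration anchored at the smallest-index gene of the
  # cycle, so each cycle is produced exactly once
  for (start in seq_along(clock_gene_names)) {
    start_gene <- clock_gene_names[start]
    path <- function(gene, visited, edges_used) {
      for (ei in adj[[gene]] %||% integer(0)) {
        nxt <- e$target[ei]
        nxt_i <- match(nxt, clock_gene_names)
        if (nxt_i < start) next
        if (nxt == start_gene) {
          loops[[length(loops) + 1]] <<- c(edges_used, ei)
        } else if (!nxt %in% visited) {
          path(nxt, c(visited, nxt), c(edges_used, ei))
        }
      }
    }
    path(start_gene, start_gene, integer(0))
  }
  purrr::map_dfr(loops, function(eis) {
    genes <- e$source[eis]
    tibble::tibble(
      loop = paste(paste(genes, collapse = " -> "), "->", genes[1]),
      length = length(eis),
      sign = prod(sgn[eis]),
      total_delay_h = sum(tau[genes]),
      genes = list(genes))
  }) |> dplyr::arrange(.data$length, .data$loop)
}
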