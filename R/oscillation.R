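#' Classifier settings for limit-cycle detection
#'
#' Every census and sweep verdict depends on these thresholds, so they are
#' explicit configuration rather than hidden constants: a trajectory counts as a self-sustained oscillation when, after
#' the transient, the reference gene shows at least `min_peaks` peaks,
#' relative amplitude (max - min)/mean of at least `eps_amp`, and no
#' systematic amplitude decay beyond `decay_tol` per cycle. Regular
#' rhythms additionally have a peak-interval coefficient of variation
#' below `eps_cv`; rhythms above it are still classified as oscillating
#' but flagged as torus-like (two interacting frequencies).
#'
#' @param eps_amp minimal relative amplitude (default 1e-3).
#' @param eps_cv maximal coefficient of variation of successive peak
#'   intervals for a regular rhythm (default 0.01).
#' @param decay_tol maximal tolerated amplitude decay per cycle
#'   (default 0.01 = 1\% per cycle).
#' @param min_peaks minimal number of post-transient peaks (default 4).
#' @param prominence minimal prominence of a counted peak, as a fraction
#'   of the window range; suppresses harmonic shoulders (default 0.05).
#' @param ref_gene gene whose rhythm decides the verdict (default Per2).
#' @return a list of settings.
#' @export
oscillation_settings <- function(eps_amp = 1e-3, eps_cv = 0.01,
                                 decay_tol = 0.01, min_peaks = 4,
                                 prominence = 0.05, ref_gene = "Per2") {
  list(eps_amp = eps_amp, eps_cv = eps_cv, decay_tol = decay_tol,
       min_peaks = min_peaks, prominence = prominence, ref_gene = ref_gene)
}

#' Detect peaks of one gene's time course
#'
#' Strict local maxima within a window, refined by local quadratic
#' interpolation; optionally pruned by prominence.
#'
#' @param traj a `clock_trajectory` (or any data frame with `time_h`).
#' @param gene gene/column name.
#' @param window numeric length-2 time window (default: whole range);
#'   must be nonempty and should cover at least two candidate periods.
#' @param min_prominence prominence threshold as a fraction of the window
#'   range (0 = keep all strict maxima).
#' @return tibble with `peak_time` and `height`, ordered in time.
#' @export
detect_peaks <- function(traj, gene, window = NULL, min_prominence = 0) {
  if (!gene %in% names(traj))
    abort(paste0("no such gene/column: ", gene),
          class = "clockloops_argument_error")
  tt <- traj$time_h
  if (is.null(window)) window <- range(tt)
  keep <- tt >= window[1] & tt <= window[2]
  if (!any(keep))
    abort("empty window", class = "clockloops_argument_error")
  res <- cpp_detect_peaks(tt[keep], traj[[gene]][keep], min_prominence)
  tibble::tibble(peak_time = res$peak_times, height = res$peak_heights)
}

#' Classify a trajectory as oscillating or not
#'
#' Applies the limit-cycle criterion of [oscillation_settings()] to the
#' reference gene and derives per-gene amplitudes, peak phases and means.
#' Degenerate inputs never error; they classify as non-oscillating.
#'
#' @param traj a `clock_trajectory`.
#' @param transient hours discarded before analysis (default 300).
#' @param settings see [oscillation_settings()].
#' @return an `oscillation_report`: verdict, period (h), peak-interval
#'   coefficient of variation, torus flag, and a per-gene tibble with
#'   relative amplitude, mean and peak phase. [tidy()] returns the
#'   per-gene table, [glance()] the one-row summary.
#' @export
classify_oscillation <- function(traj, transient = 300,
                                 settings = oscillation_settings()) {
  genes <- attr(traj, "gene_names") %||%
    setdiff(names(traj), c("time_h", "replicate", "condition"))
  ref <- settings$ref_gene
  if (!ref %in% genes) ref <- genes[[1]]
  cls <- cpp_classify_series(traj$time_h, traj[[ref]], transient,
                             settings$eps_amp, settings$eps_cv,
                             settings$decay_tol, settings$min_peaks,
                             settings$prominence)
  per_gene <- purrr::map_dfr(genes, function(g) {
    gi <- cpp_classify_series(traj$time_h, traj[[g]], transient,
                              settings$eps_amp, settings$eps_cv,
                              settings$decay_tol, settings$min_peaks,
                              settings$prominence)
    phase <- NA_real_
    mean_lvl <- gi$mean_level
    if (isTRUE(cls$oscillating)) {
      mean_lvl <- cycle_average(traj$time_h, traj[[g]], cls$period, transient)
      if (length(gi$peak_times))
        phase <- circular_mean(gi$peak_times %% cls$period, cls$period)
    }
    tibble::tibble(gene = g, rel_amplitude = gi$rel_amp, mean = mean_lvl,
                   peak_phase = phase, n_peaks = gi$n_peaks)
  })
  structure(list(
    oscillating = isTRUE(cls$oscillating),
    period = if (isTRUE(cls$oscillating)) cls$period else NA_real_,
    cv = cls$cv, torus = isTRUE(cls$torus), damped = isTRUE(cls$damped),
    decay_per_cycle = cls$decay_per_cycle,
    rel_amplitude = cls$rel_amp,
    ref_gene = ref, transient = transient, settings = settings,
    genes = per_gene), class = "oscillation_report")
}

circular_mean <- function(x, period) {
  ang <- 2 * pi * x / period
  (atan2(mean(sin(ang)), mean(cos(ang))) %% (2 * pi)) * period / (2 * pi)
}

#' @export
print.oscillation_report <- function(x, ...) {
  if (x$oscillating) {
    cat(sprintf("<oscillation_report> oscillating, period %.2f h (cv %.2g%s)\n",
                x$period, x$cv, if (x$torus) ", torus-flagged" else ""))
  } else {
    cat("<oscillation_report> not oscillating",
        if (isTRUE(x$damped)) "(damped)" else "", "\n")
  }
  print(x$genes)
  invisible(x)
}

#' @export
tidy.oscillation_report <- function(x, ...) x$genes

#' @export
glance.oscillation_report <- function(x, ...) {
  tibble::tibble(oscillating = x$oscillating, period = x$period,
                 cv = x$cv, torus = x$torus, damped = x$damped,
                 rel_amplitude = x$rel_amplitude, ref_gene = x$ref_gene)
}

#' Circular phase difference between two genes
#'
#' Difference of peak phases modulo the period, in hours, in
#' `[0, period)`: how many hours `gene` peaks after `reference_gene`.
#'
#' @param report an oscillating `oscillation_report`.
#' @param gene,reference_gene gene names.
#' @return phase difference in hours.
#' @export
phase_of <- function(report, gene, reference_gene) {
  if (!isTRUE(report$oscillating))
    abort("phases are only defined for oscillating reports",
          class = "clockloops_state_error")
  ph <- setNames(report$genes$peak_phase, report$genes$gene)
  for (g in c(gene, reference_gene))
    if (!g %in% names(ph))
      abort(paste0("no such gene: ", g), class = "clockloops_argument_error")
  (ph[[gene]] - ph[[reference_gene]]) %% report$period
}

#' Write an oscillation report to CSV (one row)
#'
#' @param report an `oscillation_report`.
#' @param path output file.
#' @export
write_report <- function(report, path) {
  g <- report$genes
  row <- c(list(oscillating = report$oscillating, period_h = report$period,
                cv = report$cv, torus = report$torus),
           setNames(as.list(g$rel_amplitude), paste0("amp_", g$gene)),
           setNames(as.list(g$peak_phase), paste0("phase_", g$gene)),
           setNames(as.list(g$mean), paste0("mean_", g$gene)))
  write.csv(as.data.frame(row), path, row.names = FALSE)
  invisible(path)
}
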