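#' @keywords internal
clock_gene_names <- c("Bmal1", "Rev_erba", "Per2", "Cry1", "Dbp")

# canonical topology of the 5-gene network: 7 activations, 10 inhibitions.
# Bmal1 activates E-box targets, Dbp activates D-box targets, Per2 and Cry1
# repress E-box targets (Per2 and Cry1 each carry a self-inhibition through
# their own E-boxes), Rev-erba represses Bmal1 and Cry1 through ROR elements.
clock_edge_table <- function() {
  act <- rbind(
    expand.grid(source = "Bmal1", target = c("Rev_erba", "Per2", "Cry1", "Dbp"),
                stringsAsFactors = FALSE),
    expand.grid(source = "Dbp", target = c("Rev_erba", "Per2", "Cry1"),
                stringsAsFactors = FALSE))
  inh <- rbind(
    expand.grid(source = "Rev_erba", target = c("Bmal1", "Cry1"),
                stringsAsFactors = FALSE),
    expand.grid(source = "Per2", target = c("Rev_erba", "Per2", "Cry1", "Dbp"),
                stringsAsFactors = FALSE),
    expand.grid(source = "Cry1", target = c("Rev_erba", "Per2", "Cry1", "Dbp"),
                stringsAsFactors = FALSE))
  act$sign <- "activation"
  inh$sign <- "inhibition"
  out <- rbind(act, inh)
  out$source_index <- match(out$source, clock_gene_names)
  out$target_index <- match(out$target, clock_gene_names)
  out <- out[order(out$target_index, out$source_index), ]
  prefix <- ifelse(out$sign == "activation", "actn", "inh")
  out$param <- paste0(prefix, "_", out$source_index, "_", out$target_index)
  rownames(out) <- NULL
  tibble::as_tibble(out[, c("source", "target", "source_index", "target_index",
                            "sign", "param")])
}

#' Construct the five-gene clock network model
#'
#' Builds the delay-differential gene-regulatory network of the core
#' mammalian circadian clock: five genes (Bmal1, Rev-erb-alpha -- written
#' `Rev_erba` throughout --, Per2, Cry1, Dbp) connected by 17 regulations
#' (7 activations, 10 inhibitions) with fixed topology. Gene `i` evolves as
#'
#' \deqn{x_i'(t) = V_i \prod_{j \to i} F_{ji}\big(x_j(t-\tau_j)\big) - d_i x_i(t)}
#'
#' where each regulation factor is bounded and saturating,
#' \eqn{F(y) = (1 + s u)/(1 + u)} with \eqn{u = (y/\bar y)^h}: activating
#' edges have strength \eqn{s > 1} (factor rises from 1 to \eqn{s}),
#' inhibiting edges \eqn{s < 1} (factor falls from 1 to \eqn{s}), and the
#' Hill exponent \eqn{h} sets the steepness. Post-transcriptional processing
#' is folded into one explicit delay \eqn{\tau_j} per regulator.
#'
#' The model has 34 distinct kinetic parameters: per gene a degradation
#' rate `d_i` (1/h), a regulatory delay `tau_i` (h) and a maximal
#' production rate `V_i`; per edge a strength (`actn_<src>_<tgt>` or
#' `inh_<src>_<tgt>`); and two shared Hill exponents `h_act` / `h_inh`.
#'
#' @param degradation named numeric, degradation rates in 1/h (all > 0).
#' @param delay named numeric, regulatory delays in h (all >= 0).
#' @param production named numeric, maximal production rates (> 0).
#' @param strengths named numeric of length 17, regulation strengths keyed
#'   by edge parameter names such as `actn_1_2` (Bmal1 activates Rev_erba).
#' @param exponents named numeric `c(activation =, inhibition =)`, the two
#'   shared Hill exponents.
#' @param ref_means per-gene reference levels used to normalise regulator
#'   inputs (defaults to 1, matching mean-normalised expression units).
#' @param clamp_means optional per-gene limit-cycle means used whenever
#'   nodes or edges are clamped; computed from the full model by
#'   [limit_cycle_means()].
#' @return an object of class `clock_model`.
#' @seealso [default_clock_model()], [load_model()], [simulate_clock()]
#' @export
clock_model <- function(degradation, delay, production, strengths,
                        exponents = c(activation = 3, inhibition = 4),
                        ref_means = NULL, clamp_means = NULL) {
  genes <- tibble::tibble(
    index = seq_along(clock_gene_names),
    name = clock_gene_names,
    degradation = as.numeric(degradation[clock_gene_names]),
    delay = as.numeric(delay[clock_gene_names]),
    production = as.numeric(production[clock_gene_names]))
  edges <- clock_edge_table()
  if (!all(edges$param %in% names(strengths))) {
    missing <- setdiff(edges$param, names(strengths))
    abort(paste0("missing regulation strength parameter(s): ",
                 paste(missing, collapse = ", ")),
          class = "clockloops_config_error")
  }
  edges$strength <- as.numeric(strengths[edges$param])
  edges$exponent <- ifelse(edges$sign == "activation",
                           exponents[["activation"]], exponents[["inhibition"]])
  edges$clamped <- FALSE
  if (is.null(ref_means)) ref_means <- setNames(rep(1, 5), clock_gene_names)
  m <- structure(list(
    genes = genes,
    regulations = edges,
    exponents = c(activation = as.numeric(exponents[["activation"]]),
                  inhibition = as.numeric(exponents[["inhibition"]])),
    ref_means = ref_means[clock_gene_names],
    clamp_means = if (is.null(clamp_means)) NULL else clamp_means[clock_gene_names],
    node_clamps = character(0)),
    class = "clock_model")
  validate_model(m)
  m
}

#' Validate a clock model
#'
#' Checks the type invariants: exactly 5 genes with the canonical names,
#' positive degradation and production rates, nonnegative delays, exactly
#' 17 regulations splitting into 7 activations and 10 inhibitions, strictly
#' positive strengths, positive exponents, 34 distinct kinetic parameters,
#' and presence of the repressilator cycle
#' (Per2 -| Rev_erba -| Cry1 -| Per2), the Cry1 self-inhibition and the
#' Cry1 -> Dbp -> Per2 feedforward path.
#'
#' @param model a `clock_model`.
#' @return the model, invisibly; aborts with class
#'   `clockloops_config_error` or `clockloops_topology_error` otherwise.
#' @export
validate_model <- function(model) {
  g <- model$genes
  if (nrow(g) != 5 || !identical(g$name, clock_gene_names))
    abort("model must contain exactly the 5 canonical genes",
          class = "clockloops_topology_error")
  if (any(!is.finite(g$degradation)) || any(g$degradation <= 0))
    abort("degradation rates d_i must be positive",
          class = "clockloops_config_error")
  if (any(!is.finite(g$delay)) || any(g$delay < 0))
    abort("delays tau_i must be nonnegative", class = "clockloops_config_error")
  if (any(!is.finite(g$production)) || any(g$production <= 0))
    abort("production rates V_i must be positive",
          class = "clockloops_config_error")
  e <- model$regulations
  if (nrow(e) != 17)
    abort(sprintf("expected 17 regulations, found %d", nrow(e)),
          class = "clockloops_topology_error")
  n_act <- sum(e$sign == "activation")
  if (n_act != 7 || nrow(e) - n_act != 10)
    abort(sprintf("expected 7 activations and 10 inhibitions, found %d/%d",
                  n_act, nrow(e) - n_act),
          class = "clockloops_topology_error")
  ref <- clock_edge_table()
  if (!identical(e[, c("source", "target", "sign")],
                 ref[, c("source", "target", "sign")]))
    abort("regulation list does not match the canonical 17-edge topology",
          class = "clockloops_topology_error")
  if (any(!is.finite(e$strength)) || any(e$strength <= 0))
    abort("regulation strengths must be positive",
          class = "clockloops_config_error")
  if (any(e$exponent <= 0))
    abort("Hill exponents must be positive", class = "clockloops_config_error")
  if (length(clock_params(model)) != 34)
    abort("model must expose exactly 34 kinetic parameters",
          class = "clockloops_config_error")
  invisible(model)
}

#' @export
print.clock_model <- function(x, ...) {
  n_eclamp <- sum(x$regulations$clamped)
  cat("<clock_model> 5 genes, 17 regulations (7 activating, 10 inhibiting)\n")
  cat(sprintf("  exponents: activation %g, inhibition %g\n",
              x$exponents[["activation"]], x$exponents[["inhibition"]]))
  if (length(x$node_clamps))
    cat("  node clamps:", paste(x$node_clamps, collapse = ", "), "\n")
  if (n_eclamp)
    cat(sprintf("  edge clamps: %d of 17\n", n_eclamp))
  if (is.null(x$clamp_means))
    cat("  clamp means: not set (run limit_cycle_means())\n")
  invisible(x)
}

#' Kinetic parameter vector of a clock model
#'
#' Returns the 34 kinetic parameters as a named numeric vector:
#' `d_1..d_5`, `tau_1..tau_5`, `V_1..V_5`, the 17 edge strengths
#' (`actn_<src>_<tgt>`, `inh_<src>_<tgt>`), and the shared Hill exponents
#' `h_act`, `h_inh`.
#'
#' @param model a `clock_model`.
#' @return named numeric vector of length 34.
#' @export
clock_params <- function(model) {
  g <- model$genes
  e <- model$regulations
  c(setNames(g$degradation, paste0("d_", g$index)),
    setNames(g$delay, paste0("tau_", g$index)),
    setNames(g$production, paste0("V_", g$index)),
    setNames(e$strength, e$param),
    h_act = model$exponents[["activation"]],
    h_inh = model$exponents[["inhibition"]])
}

#' Set a kinetic parameter by name
#'
#' @param model a `clock_model`.
#' @param name one of the 34 parameter names of [clock_params()].
#' @param value new numeric value.
#' @return the updated model.
#' @export
set_clock_param <- function(model, name, value) {
  value <- as.numeric(value)
  if (length(name) != 1 || length(value) != 1 || !is.finite(value))
    abort("need a single parameter name and a single finite value")
  if (grepl("^d_[1-5]$", name)) {
    model$genes$degradation[as.integer(substring(name, 3))] <- value
  } else if (grepl("^tau_[1-5]$", name)) {
    model$genes$delay[as.integer(substring(name, 5))] <- value
  } else if (grepl("^V_[1-5]$", name)) {
    model$genes$production[as.integer(substring(name, 3))] <- value
  } else if (name %in% model$regulations$param) {
    model$regulations$strength[model$regulations$param == name] <- value
  } else if (name == "h_act") {
    model$exponents[["activation"]] <- value
    model$regulations$exponent[model$regulations$sign == "activation"] <- value
  } else if (name == "h_inh") {
    model$exponents[["inhibition"]] <- value
    model$regulations$exponent[model$regulations$sign == "inhibition"] <- value
  } else {
    abort(paste0("unknown parameter: ", name),
          class = "clockloops_argument_error")
  }
  model
}

#' @rdname set_clock_param
#' @export
get_clock_param <- function(model, name) {
  p <- clock_params(model)
  if (!name %in% names(p))
    abort(paste0("unknown parameter: ", name),
          class = "clockloops_argument_error")
  unname(p[[name]])
}

#' Bounded regulation factor of one edge
#'
#' Evaluates the saturating factor \eqn{(1 + s u)/(1 + u)} with
#' \eqn{u = (y/\bar y)^h} that a regulator contributes to one target's
#' production term. A clamped edge ignores `y` and is evaluated at the
#' regulator's clamp mean forever, which is how an interaction is
#' prevented from transmitting rhythms.
#'
#' @param reg one row of `model$regulations` (or any list with entries
#'   `strength`, `exponent`, `sign`, `clamped`).
#' @param y regulator expression level (>= 0); vectorised.
#' @param mean clamp mean of the regulator, required when `reg$clamped`.
#' @param ybar reference level normalising the regulator (default 1).
#' @return numeric factor(s) in `[min(s,1), max(s,1)]`.
#' @export
regulation_factor <- function(reg, y, mean = NULL, ybar = 1) {
  if (any(y < 0))
    abort("regulator level y must be nonnegative",
          class = "clockloops_domain_error")
  if (isTRUE(reg$clamped)) {
    if (is.null(mean) || !is.finite(mean) || mean < 0)
      abort("clamped edge needs a finite nonnegative clamp mean",
            class = "clockloops_domain_error")
    y <- rep(mean, length(y))
  }
  u <- (y / ybar)^reg$exponent
  (1 + reg$strength * u) / (1 + u)
}

# ---------------------------------------------------------------------------
# configuration file i/o

#' Read a clock model from a YAML configuration file
#'
#' The file declares the five genes with their kinetic constants, the two
#' shared Hill exponents, the 17 regulation strengths, and optionally the
#' cached clamp means. Loading validates every invariant and fails loudly
#' on missing parameters or a wrong topology.
#'
#' @param path path to a YAML model configuration.
#' @return a `clock_model`.
#' @export
load_model <- function(path) {
  if (!file.exists(path))
    abort(paste0("no such config file: ", path),
          class = "clockloops_config_error")
  cfg <- yaml::read_yaml(path)
  for (key in c("genes", "exponents", "regulations"))
    if (is.null(cfg[[key]]))
      abort(paste0("config is missing the '", key, "' section"),
            class = "clockloops_config_error")
  gname <- vapply(cfg$genes, function(g) g$name %||% NA_character_, "")
  need <- function(gene, field) {
    v <- gene[[field]]
    if (is.null(v) || !is.numeric(v))
      abort(paste0("gene ", gene$name %||% "?", " is missing numeric '",
                   field, "'"), class = "clockloops_config_error")
    v
  }
  degradation <- setNames(vapply(cfg$genes, need, 0, field = "degradation"), gname)
  delay <- setNames(vapply(cfg$genes, need, 0, field = "delay"), gname)
  production <- setNames(vapply(cfg$genes, need, 0, field = "production"), gname)
  if (nrow(unique(do.call(rbind, lapply(cfg$regulations, function(r)
        data.frame(s = r$source, t = r$target))))) != length(cfg$regulations))
    abort("duplicate regulation in config", class = "clockloops_topology_error")
  if (length(cfg$regulations) != 17)
    abort(sprintf("config declares %d regulations, expected 17",
                  length(cfg$regulations)),
          class = "clockloops_topology_error")
  sign_counts <- table(vapply(cfg$regulations, function(r)
    r$sign %||% "?", ""))
  if (!identical(sort(names(sign_counts)), c("activation", "inhibition")) ||
      sign_counts[["activation"]] != 7 || sign_counts[["inhibition"]] != 10)
    abort("config must declare 7 activations and 10 inhibitions",
          class = "clockloops_topology_error")
  strengths <- setNames(
    vapply(cfg$regulations, function(r) {
      if (is.null(r$strength)) abort(
        paste0("regulation ", r$source, " -> ", r$target,
               " is missing 'strength'"), class = "clockloops_config_error")
      as.numeric(r$strength)
    }, 0),
    vapply(cfg$regulations, function(r) {
      si <- match(r$source, clock_gene_names)
      ti <- match(r$target, clock_gene_names)
      if (is.na(si) || is.na(ti))
        abort(paste0("unknown gene in regulation: ", r$source, " -> ",
                     r$target), class = "clockloops_config_error")
      paste0(ifelse(identical(r$sign, "activation"), "actn", "inh"),
             "_", si, "_", ti)
    }, ""))
  exponents <- c(activation = as.numeric(cfg$exponents$activation),
                 inhibition = as.numeric(cfg$exponents$inhibition))
  clamp_means <- NULL
  if (!is.null(cfg$clamp_means))
    clamp_means <- unlist(cfg$clamp_means)[clock_gene_names]
  ref_means <- NULL
  if (!is.null(cfg$reference_means))
    ref_means <- unlist(cfg$reference_means)[clock_gene_names]
  clock_model(degradation, delay, production, strengths,
              exponents = exponents, ref_means = ref_means,
              clamp_means = clamp_means)
}

#' Write a clock model to a YAML configuration file
#'
#' @param model a `clock_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  g <- model$genes
  cfg <- list(
    model = "circadian-5gene",
    genes = lapply(seq_len(5), function(i) list(
      index = g$index[i], name = g$name[i],
      degradation = g$degradation[i], delay = g$delay[i],
      production = g$production[i])),
    exponents = list(activation = unname(model$exponents[["activation"]]),
                     inhibition = unname(model$exponents[["inhibition"]])),
    reference_means = as.list(model$ref_means),
    regulations = lapply(seq_len(nrow(model$regulations)), function(i) {
      r <- model$regulations[i, ]
      list(source = r$source, target = r$target, sign = r$sign,
           strength = r$strength)
    }))
  if (!is.null(model$clamp_means))
    cfg$clamp_means <- as.list(model$clamp_means)
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' The calibrated default clock model
#'
#' Loads the default parameterisation shipped with the package
#' (`inst/extdata/clock-model.yaml`): degradation rates and delays set to
#' literature-scale values (with the Cry1 degradation 0.2/h, the Per2
#' delay 3.82 h and the Cry1 delay 3.13 h), and regulation strengths
#' calibrated against synthetic mean-normalised 24 h expression profiles
#' so that the full network oscillates with a circadian period and the
#' canonical phase order (Rev-erb-alpha, then Per2, then Cry1, with Bmal1
#' in antiphase). Clamp means are cached in the file.
#'
#' @return a `clock_model`.
#' @export
default_clock_model <- function() {
  load_model(system.file("extdata", "clock-model.yaml",
                         package = "clockloops", mustWork = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# plain-list mirror handed to the C++ integrator
model_to_cpp <- function(model) {
  g <- model$genes
  e <- model$regulations
  nclamp <- as.integer(g$name %in% model$node_clamps)
  cm <- model$clamp_means
  if (is.null(cm)) {
    if (any(nclamp == 1L) || any(e$clamped))
      abort("clamp means are not set; compute them with limit_cycle_means() on the full model first",
            class = "clockloops_state_error")
    cm <- model$ref_means
  }
  list(V = g$production, d = g$degradation, tau = g$delay,
       ybar = as.numeric(model$ref_means),
       src = e$source_index - 1L, tgt = e$target_index - 1L,
       strength = e$strength,
       hexp = e$exponent,
       eclamp = as.integer(e$clamped),
       nclamp = nclamp,
       nclamp_val = as.numeric(cm),
       clamp_mean = as.numeric(cm))
}
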