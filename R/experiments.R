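# Experiments: growth-regime classification, the carcinogen-proxy parameter
# sweeps (initial transcript load; transcription rate; antisense rate), the
# clamped-copy-number variant, and degradation-fate accounting.

.SEVERITY <- c(static = 1L, bounded = 2L, exponential = 3L)

# occurrences of a molecule type in each species label of a trajectory
.mol_occurrence <- function(labels, molecule) {
  vapply(labels, function(l) {
    body <- sub("@.*$", "", l)
    mols <- strsplit(body, ".", fixed = TRUE)[[1]]
    sum(sub("\\(.*$", "", mols) == molecule)
  }, numeric(1))
}

#' Classify the growth regime of a species' trajectory
#'
#' The study's figures distinguish three regimes by eye; this makes the
#' criterion explicit: a run that hit a count cap is `"exponential"`; else
#' the least-squares slope of `log(count + 1)` over the final third of the
#' run is compared against `slope_threshold` (with the additional demand of
#' at least a two-fold increase over that window) for `"exponential"`; a net
#' change of at most `static_band` counts over the whole run is `"static"`;
#' anything else is `"bounded"`.
#'
#' @param traj A `trajectory`.
#' @param species Molecule type name (complex-bound copies are included).
#' @param slope_threshold Tail log-slope threshold in s^-1 (default 2e-4).
#' @param static_band Net-change band for "static" (default 2 counts).
#' @return An object of class `regime_label`: list with `regime`,
#'   `tail_slope`, `cap_hit`, `initial`, `final`.
#' @export
classify_growth <- function(traj, species = "L1DNA",
                            slope_threshold = 2e-4, static_band = 2) {
  stopifnot(inherits(traj, "trajectory"))
  if (length(traj$time) < 10)
    stop("classify_growth: trajectory needs at least 10 grid points", call. = FALSE)
  occ <- .mol_occurrence(colnames(traj$counts), species)
  if (!any(occ > 0))
    stop("classify_growth: unknown species '", species, "'", call. = FALSE)
  x <- as.numeric(traj$counts[, occ > 0, drop = FALSE] %*% occ[occ > 0])
  n <- length(x)
  tail_idx <- seq.int(ceiling(2 * n / 3), n)
  tt <- traj$time[tail_idx]
  slope <- unname(stats::coef(stats::lm(log(x[tail_idx] + 1) ~ tt))[2])
  fold <- (x[n] + 1) / (x[tail_idx[1]] + 1)
  cap_hit <- identical(traj$status, "count-cap")
  regime <- if (cap_hit || (is.finite(slope) && slope > slope_threshold && fold >= 2)) {
    "exponential"
  } else if (abs(x[n] - x[1]) <= static_band) {
    "static"
  } else "bounded"
  structure(list(regime = regime, tail_slope = slope, cap_hit = cap_hit,
                 initial = x[1], final = x[n]),
            class = "regime_label")
}

#' @export
print.regime_label <- function(x, ...) {
  cat(sprintf("Regime: %s (initial %g, final %g, tail slope %.3g /s%s)\n",
              x$regime, x$initial, x$final, x$tail_slope,
              if (x$cap_hit) ", count-cap hit" else ""))
  invisible(x)
}

#' Specify a parameter sweep
#'
#' @param param One of `"initial_L1mRNA"` (initial nuclear transcript
#'   count), `"Kf_Make_L1mRNA"` (sense transcription rate, s^-1; the
#'   antisense rate follows at 1/8 of each value) or `"Kf_Make_Orf0"`
#'   (antisense rate, s^-1; the sense rate is set to 10x each value,
#'   matching the study design that paired 0.001 with 0.01 and 0.1 with
#'   1.0 s^-1).
#' @param values Sweep values (default: [default_sweep_values()]).
#' @param seeds Seeds per value (default 1:10).
#' @param stop A [stop_condition()]; the default samples every 10 s and
#'   stops at 5e5 total molecules, a practical stand-in for the original
#'   platform's overflow fault.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(param, values = default_sweep_values(param),
                       seeds = 1:10,
                       stop = stop_condition(t_end = 10000, grid_dt = 10,
                                             total_cap = 5e5)) {
  param <- match.arg(param, c("initial_L1mRNA", "Kf_Make_L1mRNA", "Kf_Make_Orf0"))
  structure(list(param = param, values = values, seeds = seeds, stop = stop),
            class = "sweep_spec")
}

# network variant for one sweep value
.sweep_variant <- function(net, param, value) {
  base <- net$model$parameters
  if (param == "initial_L1mRNA") {
    list(net = net,
         overrides = initial_conditions(ic("L1mRNA", "Nucleus", value)))
  } else if (param == "Kf_Make_L1mRNA") {
    p <- set_param(base, "Kf_Make_L1mRNA", value)
    p <- set_param(p, "Kf_Make_Orf0", value / 8)
    list(net = update_rates(net, p), overrides = NULL)
  } else {
    p <- set_param(base, "Kf_Make_Orf0", value)
    p <- set_param(p, "Kf_Make_L1mRNA", 10 * value)
    list(net = update_rates(net, p), overrides = NULL)
  }
}

.majority_regime <- function(regimes) {
  tab <- table(factor(regimes, levels = names(.SEVERITY)))
  win <- names(tab)[tab == max(tab)]
  win[which.max(.SEVERITY[win])]  # ties resolved towards higher severity
}

#' Run a parameter sweep on the merged model
#'
#' Runs replicate stochastic simulations at every sweep value, classifies
#' the genomic-copy-number growth regime of each run, aggregates regimes by
#' majority vote and reports the smallest value labelled exponential (the
#' activation threshold).
#'
#' @param x A [model_definition()] or an already-expanded
#'   `reaction_network`.
#' @param spec A [sweep_spec()].
#' @param species Species whose growth is classified (default `"L1DNA"`).
#' @return An object of class `sweep_result`: `runs` (one row per
#'   value x seed with regime, final counts and pathway tallies), `summary`
#'   (per value: majority regime, median net change, median pathway events)
#'   and `threshold`.
#' @export
sweep_experiment <- function(x, spec, species = "L1DNA") {
  stopifnot(inherits(spec, "sweep_spec"))
  net <- if (inherits(x, "reaction_network")) x else expand_rules(x)
  runs <- NULL
  for (value in spec$values) {
    var <- .sweep_variant(net, spec$param, value)
    for (seed in spec$seeds) {
      traj <- simulate_ssa(var$net, seed, spec$stop, var$overrides)
      lab <- classify_growth(traj, species)
      tl <- traj$tallies[nrow(traj$tallies), ]
      runs <- rbind(runs, data.frame(
        value = value, seed = seed, regime = lab$regime,
        tail_slope = lab$tail_slope,
        initial_dna = lab$initial, final_dna = lab$final,
        delta_dna = lab$final - lab$initial,
        rnase_events = tl[["rnase"]], risc_events = tl[["risc"]],
        sg_events = tl[["sg"]], mvb_events = tl[["mvb"]],
        rt_events = tl[["rt"]], status = traj$status,
        stringsAsFactors = FALSE))
    }
  }
  summ <- do.call(rbind, lapply(split(runs, runs$value), function(d) {
    data.frame(value = d$value[1],
               regime = .majority_regime(d$regime),
               median_delta_dna = stats::median(d$delta_dna),
               median_risc = stats::median(d$risc_events),
               median_sg = stats::median(d$sg_events),
               median_mvb = stats::median(d$mvb_events),
               n_cap = sum(d$status == "count-cap"),
               stringsAsFactors = FALSE)
  }))
  summ <- summ[order(summ$value), , drop = FALSE]
  rownames(summ) <- NULL
  expo <- summ$value[summ$regime == "exponential"]
  structure(list(param = spec$param, runs = runs, summary = summ,
                 threshold = if (length(expo)) min(expo) else NA_real_),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Sweep over %s (%d values x %d seeds)\n", x$param,
              length(unique(x$runs$value)), length(unique(x$runs$seed))))
  print(x$summary, row.names = FALSE)
  cat(sprintf("Threshold (smallest exponential value): %s\n",
              ifelse(is.na(x$threshold), "none", format(x$threshold))))
  invisible(x)
}

#' Sweep with the finite pools clamped
#'
#' Reruns a sweep with Exportin, MOV10_Zap, Dicer and RISC held at constant
#' copy number (every consumed copy replenished) and compares the detected
#' threshold with the unclamped sweep.
#'
#' @param x Model or network (as in [sweep_experiment()]).
#' @param spec A [sweep_spec()].
#' @param unclamped Optional precomputed unclamped `sweep_result` to compare
#'   against (avoids recomputation).
#' @return A list with `clamped` and `unclamped` sweep results,
#'   `same_threshold`, and `agreement` (per-value regime comparison).
#' @export
clamped_variant_sweep <- function(x, spec, unclamped = NULL) {
  net <- if (inherits(x, "reaction_network")) x else expand_rules(x)
  if (is.null(unclamped)) unclamped <- sweep_experiment(net, spec)
  cnet <- apply_clamp(net, data.frame(
    molecule = c("Exportin", "MOV10_Zap", "Dicer", "RISC"),
    compartment = c("Nucleus", "Cytoplasm", "Cytoplasm", "Cytoplasm"),
    stringsAsFactors = FALSE))
  clamped <- sweep_experiment(cnet, spec)
  agreement <- merge(unclamped$summary[, c("value", "regime")],
                     clamped$summary[, c("value", "regime")],
                     by = "value", suffixes = c("_unclamped", "_clamped"))
  agreement$agree <- agreement$regime_unclamped == agreement$regime_clamped
  list(clamped = clamped, unclamped = unclamped,
       same_threshold = isTRUE(all.equal(clamped$threshold, unclamped$threshold)),
       agreement = agreement)
}

#' Degradation/sequestration fate accounting for a trajectory
#'
#' Partitions every RNA molecule ever present (initial plus synthesised)
#' into exactly one of: degraded by cytoplasmic RNase, cleaved by RISC,
#' sequestered into stress granules, sequestered into multivesicular bodies,
#' or surviving (no terminal event). Sequestration is counted at
#' translocation; later granule-internal degradation does not re-count a
#' molecule. Fractions partition unity exactly because they are computed
#' from event bookkeeping.
#'
#' @param traj A `trajectory` (must carry event tallies, i.e. from
#'   [simulate_ssa()]).
#' @param molecule RNA molecule type name (default `"RNA"`; use `"L1mRNA"`
#'   for the merged model).
#' @param synthesis_rules Rule names whose firings create new copies of the
#'   molecule (default `"make_l1_mrna"` where present).
#' @return An object of class `fate_report` with elements `total`,
#'   `fractions` (named: rnase, risc, sg, mvb, surviving) and `counts`.
#' @export
fate_accounting <- function(traj, molecule = "RNA",
                            synthesis_rules = "make_l1_mrna") {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(traj$rxn_count))
    stop("fate_accounting: trajectory has no event tallies", call. = FALSE)
  occ <- .mol_occurrence(traj$species$label, molecule)
  initial <- sum(traj$init_counts * occ)
  synth <- sum(traj$rxn_count[names(traj$rxn_count) %in% synthesis_rules])
  total <- initial + synth
  tl <- traj$tallies[nrow(traj$tallies), ]
  counts <- c(rnase = unname(tl[["rnase"]]), risc = unname(tl[["risc"]]),
              sg = unname(tl[["sg"]]), mvb = unname(tl[["mvb"]]))
  surviving <- total - sum(counts)
  counts <- c(counts, surviving = surviving)
  fractions <- if (total > 0) counts / total else
    c(rnase = 0, risc = 0, sg = 0, mvb = 0, surviving = 1)
  structure(list(total = total, counts = counts, fractions = fractions),
            class = "fate_report")
}

#' @export
print.fate_report <- function(x, ...) {
  cat(sprintf("Fate report over %g RNA molecules:\n", x$total))
  for (nm in names(x$fractions))
    cat(sprintf("  %-10s %8.3f%%\n", nm, 100 * x$fractions[[nm]]))
  invisible(x)
}

#' Run the standalone sequestration scenario
#'
#' Builds the stress-granule / multivesicular-body model, runs it to the
#' stop condition for each seed and returns the seed-averaged fate report.
#'
#' @param n_rna Initial cytoplasmic RNA count (the study used 100000 and
#'   300000).
#' @param seeds Integer seeds.
#' @param parameters Optional [parameter_set()] override.
#' @param stop A [stop_condition()].
#' @return A list with `mean_fractions`, `per_seed` (list of
#'   `fate_report`s) and `n_rna`.
#' @export
run_standalone_sequestration <- function(n_rna = 100000, seeds = 1:3,
                                         parameters = default_parameters("sequestration-v1"),
                                         stop = stop_condition(t_end = 10000,
                                                               grid_dt = 10)) {
  model <- build_sequestration_model(parameters = parameters, n_rna = n_rna)
  net <- expand_rules(model)
  reports <- lapply(seeds, function(s)
    fate_accounting(simulate_ssa(net, s, stop), molecule = "RNA",
                    synthesis_rules = character()))
  fr <- do.call(rbind, lapply(reports, `[[`, "fractions"))
  list(mean_fractions = colMeans(fr), per_seed = reports, n_rna = n_rna)
}
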