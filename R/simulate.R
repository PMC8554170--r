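# Simulation front end: exact stochastic simulation (Gibson-Bruck core in
# C++), deterministic mean-field ODE integration of the same network, clamped
# species, replicate runs and the trajectory container.

PATHWAYS <- c("rnase", "risc", "sg", "mvb", "rt", "other")

#' Stop condition for a simulation run
#'
#' @param t_end End time in seconds (default 10000, i.e. 2.7 h).
#' @param grid_dt Output sampling interval in seconds (default 1; the state
#'   is recorded on a fixed grid rather than per event, which bounds memory
#'   in exponential regimes).
#' @param total_cap Stop gracefully when total molecule count exceeds this
#'   (default 1e7); the run is flagged `"count-cap"`.
#' @param species_cap Per-species count cap (default `Inf`).
#' @param max_events Event-count cap (default `Inf`).
#' @return An object of class `stop_condition`.
#' @export
stop_condition <- function(t_end = 10000, grid_dt = 1, total_cap = 1e7,
                           species_cap = Inf, max_events = Inf) {
  stopifnot(t_end > 0, grid_dt > 0, total_cap > 0, species_cap > 0, max_events > 0)
  structure(list(t_end = t_end, grid_dt = grid_dt, total_cap = total_cap,
                 species_cap = species_cap, max_events = max_events),
            class = "stop_condition")
}

# species index of a free (unbound) molecule in a network
.free_index <- function(net, molecule, compartment) {
  model <- net$model
  lab <- canonical_label(free_species(molecule, compartment, model), model)
  idx <- match(lab, net$species$label)
  if (is.na(idx))
    stop("no species '", molecule, "' in compartment '", compartment,
         "' in this network", call. = FALSE)
  idx
}

#' Override initial counts / clamps on an expanded network
#'
#' @param net A `reaction_network`.
#' @param overrides An [initial_conditions()] table (or list of [ic()]
#'   entries); each row replaces the count (and clamp flag) of the matching
#'   free-molecule species.
#' @return The modified network.
#' @export
set_initial <- function(net, overrides) {
  stopifnot(inherits(net, "reaction_network"))
  if (!inherits(overrides, "initial_conditions")) overrides <- initial_conditions(overrides)
  for (i in seq_len(nrow(overrides))) {
    row <- overrides[i, ]
    if (row$count < 0 || row$count != round(row$count))
      stop("set_initial: count must be a non-negative integer", call. = FALSE)
    idx <- .free_index(net, row$molecule, row$compartment)
    net$init_counts[idx] <- row$count
    net$clamped[idx] <- row$clamped
  }
  net
}

#' Clamp (or unclamp) species in a network
#'
#' A clamped species keeps a constant molecule count during simulation: it
#' still contributes to propensities, but every consumed copy is replenished
#' (and produced copies removed) after each firing. Replenishment events are
#' not counted in degradation tallies.
#'
#' @param net A `reaction_network`.
#' @param molecule,compartment Identify the free-molecule species.
#' @param clamped Logical flag.
#' @return The modified network.
#' @export
clamp_species <- function(net, molecule, compartment, clamped = TRUE) {
  idx <- .free_index(net, molecule, compartment)
  net$clamped[idx] <- clamped
  net
}

#' @rdname clamp_species
#' @param species_set Data frame with columns `molecule`, `compartment` (or a
#'   list of `c(molecule, compartment)` pairs) to clamp.
#' @export
apply_clamp <- function(net, species_set) {
  if (is.data.frame(species_set)) {
    for (i in seq_len(nrow(species_set)))
      net <- clamp_species(net, species_set$molecule[i], species_set$compartment[i])
  } else {
    for (p in species_set) net <- clamp_species(net, p[[1]], p[[2]])
  }
  net
}

.make_grid <- function(stop) {
  g <- seq(0, stop$t_end, by = stop$grid_dt)
  if (g[length(g)] < stop$t_end) g <- c(g, stop$t_end)
  g
}

.engine_inputs <- function(net) {
  R <- length(net$reactions)
  re1 <- integer(R); re2 <- integer(R); ord <- integer(R)
  pw <- integer(R)
  for (i in seq_len(R)) {
    rx <- net$reactions[[i]]
    ord[i] <- rx$order
    if (rx$order >= 1) re1[i] <- rx$reactants[1]
    if (rx$order == 2) re2[i] <- rx$reactants[2]
    pw[i] <- match(rx$pathway, PATHWAYS)
  }
  list(re1 = re1, re2 = re2, order = ord,
       cvec = vapply(net$reactions, `[[`, numeric(1), "c"),
       nd_idx = lapply(net$net_delta, `[[`, "idx"),
       nd_delta = lapply(net$net_delta, `[[`, "delta"),
       dep = net$dep, pathway = pw)
}

#' Exact stochastic simulation (Gibson-Bruck next-reaction method)
#'
#' Simulates the expanded network exactly: tentative absolute firing times
#' are kept in an indexed priority queue; after each firing only the fired
#' reaction redraws while dependent reactions have their times rescaled.
#' Identical `(net, stop, seed)` yield identical trajectories (R
#' Mersenne-Twister RNG, recorded in the run metadata).
#'
#' @param net A `reaction_network` from [expand_rules()].
#' @param seed Integer RNG seed.
#' @param stop A [stop_condition()].
#' @param overrides Optional [initial_conditions()] overrides, applied via
#'   [set_initial()].
#' @return A `trajectory`: time grid, per-species count series, cumulative
#'   per-pathway event tallies, per-reaction firing counts, and the
#'   termination status (`"completed"`, `"count-cap"` or `"max-events"`).
#' @export
simulate_ssa <- function(net, seed, stop = stop_condition(), overrides = NULL) {
  stopifnot(inherits(net, "reaction_network"), inherits(stop, "stop_condition"))
  if (!is.null(overrides)) net <- set_initial(net, overrides)
  inp <- .engine_inputs(net)
  grid <- .make_grid(stop)
  set.seed(as.integer(seed))
  res <- .ssa_core(inp$re1, inp$re2, inp$order, inp$cvec, inp$nd_idx,
                   inp$nd_delta, inp$dep, inp$pathway,
                   as.numeric(net$init_counts), net$clamped, grid,
                   stop$t_end, stop$total_cap, stop$species_cap,
                   stop$max_events)
  colnames(res$counts) <- net$species$label
  colnames(res$tallies) <- PATHWAYS
  structure(list(
    time = grid,
    counts = res$counts,
    tallies = res$tallies,
    rxn_count = stats::setNames(res$rxn_count,
                                vapply(net$reactions, `[[`, character(1), "rule")),
    status = c("completed", "count-cap", "max-events")[res$status + 1L],
    t_final = res$t_final,
    n_events = res$n_events,
    seed = as.integer(seed),
    rng = "R Mersenne-Twister",
    method = "gibson-bruck",
    init_counts = net$init_counts,
    clamped = net$clamped,
    species = net$species
  ), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory (%s): %d species, t in [0, %g] s, %g events, status %s\n",
              x$method, ncol(x$counts), max(x$time), x$n_events, x$status))
  invisible(x)
}

#' Extract one species' count series from a trajectory
#'
#' @param traj A `trajectory`.
#' @param molecule Molecule type name; all species whose complexes contain
#'   this molecule are summed unless `free_only = TRUE`.
#' @param compartment Optional compartment filter.
#' @param free_only If `TRUE`, only the free (single-molecule) species.
#' @return Numeric vector along the trajectory's time grid.
#' @export
species_series <- function(traj, molecule, compartment = NULL, free_only = FALSE) {
  labs <- colnames(traj$counts)
  # count occurrences of the molecule in each complex label
  occ <- vapply(labs, function(l) {
    body <- sub("@.*$", "", l)
    mols <- strsplit(body, ".", fixed = TRUE)[[1]]
    sum(sub("\\(.*$", "", mols) == molecule)
  }, numeric(1))
  sel <- occ > 0
  if (free_only) {
    nm <- vapply(labs, function(l)
      length(strsplit(sub("@.*$", "", l), ".", fixed = TRUE)[[1]]), numeric(1))
    sel <- sel & nm == 1
  }
  if (!is.null(compartment))
    sel <- sel & grepl(paste0("@", compartment, "$"), labs)
  if (!any(sel)) return(rep(0, nrow(traj$counts)))
  as.numeric(traj$counts[, sel, drop = FALSE] %*% occ[sel])
}

#' Deterministic (mean-field ODE) simulation of a network
#'
#' Integrates the same mass-action network with counts as continuous
#' variables, using a stiff-capable adaptive integrator
#' (\code{deSolve::lsoda}). Clamped species have their derivatives zeroed.
#'
#' @param net A `reaction_network`.
#' @param stop A [stop_condition()] (the caps are ignored).
#' @param overrides Optional [initial_conditions()] overrides.
#' @param rel_tol,abs_tol Integrator tolerances.
#' @return A `trajectory` (tallies are reaction fluxes integrated per
#'   pathway).
#' @export
simulate_ode <- function(net, stop = stop_condition(), overrides = NULL,
                         rel_tol = 1e-8, abs_tol = 1e-8) {
  stopifnot(inherits(net, "reaction_network"))
  if (!is.null(overrides)) net <- set_initial(net, overrides)
  inp <- .engine_inputs(net)
  S <- nrow(net$species)
  R <- length(net$reactions)
  clamped <- net$clamped
  rhs <- function(t, y, parms) {
    x <- y[seq_len(S)]
    rates <- numeric(R)
    for (i in seq_len(R)) {
      rates[i] <- switch(as.character(inp$order[i]),
        "0" = inp$cvec[i],
        "1" = inp$cvec[i] * x[inp$re1[i]],
        "2" = if (inp$re1[i] == inp$re2[i])
                inp$cvec[i] * x[inp$re1[i]] * (x[inp$re1[i]] - 1) / 2
              else inp$cvec[i] * x[inp$re1[i]] * x[inp$re2[i]])
    }
    dx <- numeric(S)
    for (i in seq_len(R)) {
      nd <- net$net_delta[[i]]
      dx[nd$idx] <- dx[nd$idx] + rates[i] * nd$delta
    }
    dx[clamped] <- 0
    dpath <- numeric(6)
    for (p in 1:6) dpath[p] <- sum(rates[inp$pathway == p])
    list(c(dx, dpath))
  }
  grid <- .make_grid(stop)
  y0 <- c(as.numeric(net$init_counts), numeric(6))
  sol <- deSolve::lsoda(y0, grid, rhs, parms = NULL,
                        rtol = rel_tol, atol = abs_tol)
  if (attr(sol, "istate")[1] < 0)
    stop("simulate_ode: integrator failed (istate = ",
         attr(sol, "istate")[1], ")", call. = FALSE)
  counts <- unname(sol[, 1 + seq_len(S), drop = FALSE])
  colnames(counts) <- net$species$label
  tallies <- unname(sol[, 1 + S + 1:6, drop = FALSE])
  colnames(tallies) <- PATHWAYS
  structure(list(
    time = grid, counts = counts, tallies = tallies,
    rxn_count = NULL, status = "completed",
    t_final = max(grid), n_events = NA_real_, seed = NA_integer_,
    rng = NA_character_, method = "ode",
    init_counts = net$init_counts, clamped = net$clamped,
    species = net$species
  ), class = "trajectory")
}

#' Independent replicate stochastic runs with summary statistics
#'
#' @param net A `reaction_network`.
#' @param seeds Integer vector of RNG seeds (>= 1 seed).
#' @param stop A [stop_condition()].
#' @param overrides Optional initial-condition overrides.
#' @return A list with `trajectories` (one per seed) and `summary` (list of
#'   `mean` and `sd` matrices over the common sampling grid).
#' @export
run_replicates <- function(net, seeds, stop = stop_condition(), overrides = NULL) {
  stopifnot(length(seeds) >= 1)
  trajs <- lapply(seeds, function(s) simulate_ssa(net, s, stop, overrides))
  arr <- simplify2array(lapply(trajs, `[[`, "counts"))
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  m <- apply(arr, c(1, 2), mean)
  s <- apply(arr, c(1, 2), stats::sd)
  colnames(m) <- colnames(s) <- colnames(trajs[[1]]$counts)
  list(trajectories = trajs,
       summary = list(time = trajs[[1]]$time, mean = m, sd = s))
}
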