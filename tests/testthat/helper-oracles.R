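# Independent oracles for the test suite. These deliberately avoid the
# package's simulation/expansion code paths: the direct-method SSA is a
# from-scratch Gillespie loop in plain R, and the brute-force expander
# re-derives the reaction network without the worklist/pair bookkeeping of
# expand_rules().

# --- reference direct-method (first-reaction-free) Gillespie ---------------
# Works on the flat reaction description of a network: recomputes ALL
# propensities after every event, draws the waiting time from the total rate
# and the reaction index from the categorical distribution.
direct_ssa_events <- function(net, x0 = NULL, t_end = Inf, max_events = 1000) {
  rxns <- net$reactions
  R <- length(rxns)
  x <- if (is.null(x0)) as.numeric(net$init_counts) else as.numeric(x0)
  clamped <- net$clamped
  t <- 0
  times <- numeric(0); types <- integer(0)
  prop <- function() {
    vapply(rxns, function(rx) {
      if (rx$order == 0) return(rx$c)
      if (rx$order == 1) return(rx$c * x[rx$reactants[1]])
      i <- rx$reactants[1]; j <- rx$reactants[2]
      if (i == j) rx$c * x[i] * (x[i] - 1) / 2 else rx$c * x[i] * x[j]
    }, numeric(1))
  }
  for (ev in seq_len(max_events)) {
    a <- prop()
    a0 <- sum(a)
    if (a0 <= 0) break
    t <- t + stats::rexp(1, a0)
    if (t > t_end) break
    mu <- sample.int(R, 1, prob = a)
    nd <- net$net_delta[[mu]]
    for (k in seq_along(nd$idx)) {
      s <- nd$idx[k]
      if (!clamped[s]) x[s] <- x[s] + nd$delta[k]
    }
    times <- c(times, t); types <- c(types, mu)
  }
  list(times = times, types = types, x = x)
}

# first event (time, type) of the packaged next-reaction engine
nrm_first_event <- function(net, seed, t_end = 1e6) {
  tr <- simulate_ssa(net, seed,
                     stop_condition(t_end = t_end, grid_dt = t_end,
                                    max_events = 1))
  list(time = tr$t_final, type = which(tr$rxn_count > 0)[1])
}

# --- brute-force rule expander ---------------------------------------------
# Saturates the species set by scanning every rule against every species
# tuple of the full current list on every pass, with no dependency or
# frontier bookkeeping; reactions are accumulated the same way. Used to
# cross-check expand_rules() on small models.
brute_force_expand <- function(model, max_pass = 50) {
  types <- stats::setNames(model$molecule_types,
                           vapply(model$molecule_types, `[[`, character(1), "name"))
  labels <- character(); structs <- list()
  add <- function(sp) {
    lab <- canonical_label(sp, types)
    i <- match(lab, labels)
    if (!is.na(i)) return(i)
    labels[[length(labels) + 1L]] <<- lab
    structs[[length(structs) + 1L]] <<- sp
    length(labels)
  }
  for (i in seq_len(nrow(model$initial)))
    add(free_species(model$initial$molecule[i], model$initial$compartment[i], model))

  pat_aut <- function(pattern) line1sim:::.pattern_aut(pattern, types)
  rxn_keys <- character(); rxns <- list()

  apply_tuple <- function(rule, sidx) {
    specs <- structs[sidx]
    if (length(specs) == 2L && specs[[1]]$compartment != specs[[2]]$compartment)
      return(invisible(NULL))
    embeds <- lapply(seq_along(specs), function(k)
      line1sim:::.match_raw(rule$reactants[[k]], specs[[k]], types))
    if (any(lengths(embeds) == 0)) return(invisible(NULL))
    combos <- if (length(specs) == 1L) lapply(embeds[[1]], list) else {
      out <- list()
      for (e1 in embeds[[1]]) for (e2 in embeds[[2]])
        out[[length(out) + 1L]] <- list(e1, e2)
      out
    }
    aut <- prod(vapply(rule$reactants, pat_aut, integer(1)))
    tab <- list()
    for (cb in combos) {
      prods <- line1sim:::.apply_rule(rule, specs, cb, specs[[1]]$compartment, model)
      pidx <- sort(vapply(prods, add, integer(1)))
      key <- paste0("p:", paste(pidx, collapse = "+"))
      tab[[key]] <- if (is.null(tab[[key]])) 1L else tab[[key]] + 1L
    }
    for (key in names(tab)) {
      body <- sub("^p:", "", key)
      pidx <- if (nzchar(body)) as.integer(strsplit(body, "+", fixed = TRUE)[[1]]) else integer(0)
      rkey <- paste(rule$name, paste(sidx, collapse = ","), key, sep = "|")
      if (!rkey %in% rxn_keys) {
        rxn_keys <<- c(rxn_keys, rkey)
        rxns[[length(rxns) + 1L]] <<- list(rule = rule$name, reactants = sidx,
                                           products = pidx,
                                           factor = tab[[key]] / aut)
      }
    }
    invisible(NULL)
  }

  for (pass in seq_len(max_pass)) {
    n_before <- length(labels)
    for (rule in model$rules) {
      ar <- length(rule$reactants)
      if (ar == 0) {
        prods <- line1sim:::.apply_rule(rule, list(), list(), NA_character_, model)
        pidx <- sort(vapply(prods, add, integer(1)))
        rkey <- paste(rule$name, "", paste(pidx, collapse = "+"), sep = "|")
        if (!rkey %in% rxn_keys) {
          rxn_keys <- c(rxn_keys, rkey)
          rxns[[length(rxns) + 1L]] <- list(rule = rule$name, reactants = integer(0),
                                            products = pidx, factor = 1L)
        }
      } else if (ar == 1) {
        for (s in seq_along(labels)) apply_tuple(rule, s)
      } else {
        for (s in seq_along(labels)) for (t in seq_along(labels))
          apply_tuple(rule, c(s, t))
      }
    }
    if (length(labels) == n_before && pass > 1) break
  }
  # normalised comparable table
  df <- do.call(rbind, lapply(rxns, function(r) data.frame(
    rule = r$rule,
    reactants = paste(sort(labels[r$reactants]), collapse = " + "),
    products = paste(sort(labels[r$products]), collapse = " + "),
    factor = r$factor, stringsAsFactors = FALSE)))
  df <- df[order(df$rule, df$reactants, df$products), , drop = FALSE]
  rownames(df) <- NULL
  list(species = sort(labels), reactions = df)
}

# comparable table from an expand_rules() network
network_comparable <- function(net) {
  lab <- net$species$label
  df <- do.call(rbind, lapply(net$reactions, function(rx) data.frame(
    rule = rx$rule,
    reactants = paste(sort(lab[rx$reactants]), collapse = " + "),
    products = paste(sort(lab[rx$products]), collapse = " + "),
    factor = rx$factor, stringsAsFactors = FALSE)))
  df <- df[order(df$rule, df$reactants, df$products), , drop = FALSE]
  rownames(df) <- NULL
  list(species = sort(lab), reactions = df)
}

# molecule-count conversion factor for a compartment volume (molecules/uM)
uM_scale <- function(volume) 6.02214076e23 * volume * 1e-6
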