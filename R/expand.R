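# Network generation: fixed-point expansion of pattern-based rules over the
# seed species into a concrete mass-action reaction network
# (generate-and-saturate semantics).

#' Expand a rule-based model into a concrete reaction network
#'
#' Starting from the seed species (every initial-condition species plus the
#' products of zero-order rules), every rule is applied to every matching
#' species tuple until no new species appear. Each concrete reaction carries
#' its rule provenance, its statistical factor (number of symmetric
#' embeddings) and a stochastic propensity constant derived from the
#' macroscopic rate constant and the source compartment volume.
#'
#' Expansion terminates for any rule set without polymerisation because
#' complex composition is bounded; a species cap guards against runaway rule
#' sets and reports the offending rule.
#'
#' @param model A [model_definition()] that passes [validate_model()].
#' @param max_species Termination guard (default 10000).
#' @return An object of class `reaction_network`: species table, reaction
#'   list, net-stoichiometry and dependency maps, and the initial state
#'   (counts + clamp flags) mapped onto the species.
#' @export
expand_rules <- function(model, max_species = 10000) {
  errs <- validate_model(model)
  if (length(errs) > 0)
    stop("expand_rules: model fails validation:\n  ",
         paste(errs, collapse = "\n  "), call. = FALSE)
  types <- .types_by_name(model)

  labels <- character()
  structs <- list()
  lab_env <- new.env(parent = emptyenv())
  add_species <- function(sp, rule_name = NULL) {
    lab <- canonical_label(sp, types)
    idx <- lab_env[[lab]]
    if (!is.null(idx)) return(idx)
    if (length(labels) >= max_species)
      stop("expand_rules: species cap (", max_species, ") exceeded",
           if (!is.null(rule_name)) paste0(" while applying rule '", rule_name, "'"),
           call. = FALSE)
    idx <- length(labels) + 1L
    labels[[idx]] <<- lab
    structs[[idx]] <<- sp
    assign(lab, idx, envir = lab_env)
    idx
  }

  # seed species: all initial-condition entries (even zero counts, so that
  # overrides can target them)
  for (i in seq_len(nrow(model$initial))) {
    row <- model$initial[i, ]
    add_species(free_species(row$molecule, row$compartment, model))
  }

  # reaction accumulator, grouped by (rule, reactants, products)
  rxn_env <- new.env(parent = emptyenv())
  rxn_list <- list()
  add_reaction <- function(rule, reactant_idx, product_idx, n_embed) {
    key <- paste(rule$name, paste(reactant_idx, collapse = "+"),
                 paste(sort(product_idx), collapse = "+"), sep = "|")
    at <- rxn_env[[key]]
    if (is.null(at)) {
      at <- length(rxn_list) + 1L
      rxn_list[[at]] <<- list(rule = rule$name, pathway = rule$pathway,
                              reactants = reactant_idx,
                              products = sort(product_idx),
                              factor = 0L)
      assign(key, at, envir = rxn_env)
    }
    rxn_list[[at]]$factor <<- rxn_list[[at]]$factor + n_embed
  }

  rules <- model$rules
  arity <- vapply(rules, function(r) length(r$reactants), integer(1))
  rule_aut <- vapply(rules, function(r) {
    if (length(r$reactants) == 0L) return(1L)
    prod(vapply(r$reactants, .pattern_aut, integer(1), types = types))
  }, numeric(1))

  apply_and_record <- function(rule, rule_idx, r_species_idx) {
    specs <- structs[r_species_idx]
    embeds_per <- vector("list", length(specs))
    for (k in seq_along(specs)) {
      embeds_per[[k]] <- .match_raw(rule$reactants[[k]], specs[[k]], types)
      if (length(embeds_per[[k]]) == 0L) return(invisible(NULL))
    }
    if (length(specs) == 2L && specs[[1]]$compartment != specs[[2]]$compartment)
      return(invisible(NULL))
    ctx <- specs[[1]]$compartment
    combos <- if (length(specs) == 1L) {
      lapply(embeds_per[[1]], list)
    } else {
      out <- list()
      for (e1 in embeds_per[[1]]) for (e2 in embeds_per[[2]])
        out[[length(out) + 1L]] <- list(e1, e2)
      out
    }
    # group combos by product outcome
    outcomes <- new.env(parent = emptyenv())
    for (cb in combos) {
      prods <- .apply_rule(rule, specs, cb, ctx, model)
      pidx <- vapply(prods, function(p) add_species(p, rule$name), integer(1))
      key <- paste0("p:", paste(sort(pidx), collapse = "+"))
      cnt <- outcomes[[key]]
      assign(key, list(pidx = pidx,
                       n = if (is.null(cnt)) 1L else cnt$n + 1L),
             envir = outcomes)
    }
    aut <- rule_aut[rule_idx]
    for (key in ls(outcomes)) {
      oc <- outcomes[[key]]
      n_eff <- oc$n / aut
      if (abs(n_eff - round(n_eff)) > 1e-9)
        stop("expand_rules: non-integral statistical factor for rule ",
             rule$name, call. = FALSE)
      add_reaction(rule, r_species_idx, oc$pidx, as.integer(round(n_eff)))
    }
    invisible(NULL)
  }

  # zero-order rules fire once, context-free
  for (ri in which(arity == 0L)) {
    rule <- rules[[ri]]
    prods <- .apply_rule(rule, list(), list(), NA_character_, model)
    pidx <- vapply(prods, function(p) add_species(p, rule$name), integer(1))
    add_reaction(rule, integer(0), pidx, 1L)
  }

  processed <- 0L
  while (processed < length(labels)) {
    processed <- processed + 1L
    s <- processed
    for (ri in which(arity == 1L)) apply_and_record(rules[[ri]], ri, s)
    for (ri in which(arity == 2L)) {
      for (t in seq_len(processed)) {
        apply_and_record(rules[[ri]], ri, c(s, t))
        if (t != s) apply_and_record(rules[[ri]], ri, c(t, s))
      }
    }
  }

  # propensity constants
  vol_of <- stats::setNames(vapply(model$compartments, `[[`, numeric(1), "volume"),
                            .comp_names(model))
  for (i in seq_along(rxn_list)) {
    rx <- rxn_list[[i]]
    rule <- rules[[match(rx$rule, vapply(rules, `[[`, character(1), "name"))]]
    p <- model$parameters[[rule$rate]]
    ord <- length(rx$reactants)
    comp <- if (ord > 0) structs[[rx$reactants[1]]]$compartment
            else structs[[rx$products[1]]]$compartment
    k_st <- switch(p$units,
      "s-1" = p$value,
      "molec-1.s-1" = p$value,
      "molec.s-1" = p$value,
      "uM-1.s-1" = macroscopic_to_propensity(p$value, 2, vol_of[[comp]]),
      "uM.s-1" = macroscopic_to_propensity(p$value, 0, vol_of[[comp]]))
    rxn_list[[i]]$c <- k_st * rx$factor
    rxn_list[[i]]$order <- ord
    rxn_list[[i]]$rate <- rule$rate
    rxn_list[[i]]$comp <- comp
  }

  # net stoichiometry and dependency graph
  nspec <- length(labels)
  nd <- lapply(rxn_list, function(rx) {
    delta <- integer(0); idx <- integer(0)
    tab <- table(factor(c(rx$products, rx$reactants),
                        levels = sort(unique(c(rx$products, rx$reactants)))))
    for (sidx in as.integer(names(tab))) {
      d <- sum(rx$products == sidx) - sum(rx$reactants == sidx)
      if (d != 0L) { idx <- c(idx, sidx); delta <- c(delta, d) }
    }
    list(idx = idx, delta = delta)
  })
  # reactions indexed by reactant species
  by_reactant <- vector("list", nspec)
  for (i in seq_along(rxn_list)) {
    for (sidx in unique(rxn_list[[i]]$reactants))
      by_reactant[[sidx]] <- c(by_reactant[[sidx]], i)
  }
  dep <- lapply(seq_along(rxn_list), function(i) {
    ch <- nd[[i]]$idx
    sort(unique(unlist(by_reactant[ch])))
  })

  # initial state
  counts <- numeric(nspec)
  clamped <- logical(nspec)
  for (i in seq_len(nrow(model$initial))) {
    row <- model$initial[i, ]
    lab <- canonical_label(free_species(row$molecule, row$compartment, model), types)
    sidx <- lab_env[[lab]]
    counts[sidx] <- counts[sidx] + row$count
    clamped[sidx] <- clamped[sidx] || row$clamped
  }

  structure(list(
    model_name = model$name,
    model = model,
    species = data.frame(index = seq_len(nspec), label = labels,
                         compartment = vapply(structs, `[[`, character(1), "compartment"),
                         stringsAsFactors = FALSE),
    structs = structs,
    reactions = rxn_list,
    net_delta = nd,
    dep = dep,
    init_counts = counts,
    clamped = clamped
  ), class = "reaction_network")
}

#' Recompute propensity constants after a rate-constant change
#'
#' Changing a rate constant does not alter the network structure, so sweeps
#' over rate constants reuse one expansion and only refresh the propensity
#' constants.
#'
#' @param net A `reaction_network`.
#' @param params A [parameter_set()] (typically the model's set with some
#'   values overridden via [set_param()]).
#' @return The network with updated propensity constants (and the embedded
#'   model's parameter set replaced).
#' @export
update_rates <- function(net, params) {
  stopifnot(inherits(net, "reaction_network"), inherits(params, "parameter_set"))
  vol_of <- stats::setNames(
    vapply(net$model$compartments, `[[`, numeric(1), "volume"),
    vapply(net$model$compartments, `[[`, character(1), "name"))
  for (i in seq_along(net$reactions)) {
    rx <- net$reactions[[i]]
    p <- params[[rx$rate]]
    if (is.null(p))
      stop("update_rates: constant '", rx$rate, "' missing from parameter set",
           call. = FALSE)
    k_st <- switch(p$units,
      "s-1" = p$value,
      "molec-1.s-1" = p$value,
      "molec.s-1" = p$value,
      "uM-1.s-1" = macroscopic_to_propensity(p$value, 2, vol_of[[rx$comp]]),
      "uM.s-1" = macroscopic_to_propensity(p$value, 0, vol_of[[rx$comp]]))
    net$reactions[[i]]$c <- k_st * rx$factor
  }
  net$model$parameters <- params
  net
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("Reaction network for model '%s'\n", x$model_name))
  cat(sprintf("  species   : %d\n", nrow(x$species)))
  cat(sprintf("  reactions : %d\n", length(x$reactions)))
  invisible(x)
}

#' Summarise a reaction network
#'
#' @param net A [expand_rules()] result.
#' @return A list with `n_species`, `n_reactions`, `per_rule` (data frame of
#'   concrete-reaction counts per rule) and `dependency_degree` summary
#'   statistics. Deterministic across repeated expansions of the same model.
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "reaction_network"))
  rules <- vapply(net$reactions, `[[`, character(1), "rule")
  per_rule <- if (length(rules)) {
    df <- as.data.frame(table(rule = rules), stringsAsFactors = FALSE)
    names(df) <- c("rule", "n_reactions")
    df
  } else data.frame(rule = character(), n_reactions = integer())
  deg <- lengths(net$dep)
  list(n_species = nrow(net$species),
       n_reactions = length(net$reactions),
       per_rule = per_rule[order(per_rule$rule), , drop = FALSE],
       dependency_degree = if (length(deg)) summary(deg) else summary(integer(0)))
}

#' Flat reaction table of an expanded network
#'
#' One row per concrete reaction with reactant/product labels, the rule it
#' came from, its statistical factor and its stochastic propensity constant.
#'
#' @param net A `reaction_network`.
#' @return A data frame.
#' @export
reaction_table <- function(net) {
  stopifnot(inherits(net, "reaction_network"))
  lab <- net$species$label
  do.call(rbind, lapply(seq_along(net$reactions), function(i) {
    rx <- net$reactions[[i]]
    data.frame(
      id = i,
      rule = rx$rule,
      reactants = paste(lab[rx$reactants], collapse = " + "),
      products = if (length(rx$products)) paste(lab[rx$products], collapse = " + ") else "0",
      factor = rx$factor,
      c = rx$c,
      pathway = rx$pathway,
      stringsAsFactors = FALSE)
  }))
}
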