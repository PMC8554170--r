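# Domain types for rule-based compartmental models: compartments, molecule
# types with binding sites, parameter sets with provenance, initial
# conditions and the assembled model definition.

#' Define a compartment
#'
#' @param name Compartment identifier (single string).
#' @param volume Volume in liters; must be > 0. Volumes only matter for
#'   converting concentration-based bimolecular constants to stochastic
#'   propensities; the models are non-spatial.
#' @param parent Optional name of the containing compartment.
#' @return An object of class `compartment`.
#' @export
compartment <- function(name, volume, parent = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(volume) || length(volume) != 1L || volume <= 0)
    stop("compartment: volume must be a single positive number", call. = FALSE)
  structure(list(name = name, volume = volume, parent = parent),
            class = "compartment")
}

#' Define a molecule type with binding sites
#'
#' A molecule type declares named binding sites, the molecule types each site
#' may bind, optional classes of symmetric (interchangeable) sites, and the
#' compartments the molecule may occupy.
#'
#' @param name Molecule type identifier.
#' @param sites Named list: site name -> character vector of allowed partner
#'   molecule type names. Empty list for site-less molecules.
#' @param equivalent List of character vectors, each naming a class of
#'   mutually equivalent sites (e.g. the two ORF1p sites on LINE-1 mRNA).
#' @param compartments Character vector of compartment names the molecule may
#'   occupy.
#' @return An object of class `molecule_type`.
#' @export
molecule_type <- function(name, sites = list(), equivalent = list(),
                          compartments = character()) {
  stopifnot(is.character(name), length(name) == 1L, is.list(sites))
  if (length(sites) > 0 && anyDuplicated(names(sites)))
    stop("molecule_type: site names must be unique within a molecule", call. = FALSE)
  for (cls in equivalent) {
    if (!all(cls %in% names(sites)))
      stop("molecule_type: equivalence class names unknown site(s)", call. = FALSE)
  }
  structure(list(name = name, sites = sites, equivalent = equivalent,
                 compartments = compartments),
            class = "molecule_type")
}

#' Create a parameter-set entry
#'
#' @param value Non-negative numeric constant.
#' @param units One of `"s-1"` (unimolecular), `"uM-1.s-1"` (bimolecular,
#'   macroscopic), `"molec-1.s-1"` (bimolecular, stochastic per-pair),
#'   `"uM.s-1"` (zeroth order, macroscopic) or `"molec.s-1"` (zeroth order,
#'   stochastic).
#' @param provenance One of `"paper-printed"`, `"literature-cited"`,
#'   `"calibrated"`, `"placeholder"`.
#' @return A list usable inside [parameter_set()].
#' @export
param <- function(value, units = "s-1", provenance = "calibrated") {
  if (!is.numeric(value) || length(value) != 1L || value < 0 || !is.finite(value))
    stop("param: value must be a single finite non-negative number", call. = FALSE)
  units <- match.arg(units, c("s-1", "uM-1.s-1", "molec-1.s-1", "uM.s-1", "molec.s-1"))
  provenance <- match.arg(provenance,
                          c("paper-printed", "literature-cited", "calibrated", "placeholder"))
  list(value = value, units = units, provenance = provenance)
}

#' Assemble a named parameter set
#'
#' @param ... Named [param()] entries (or a single named list of them).
#' @return An object of class `parameter_set`.
#' @export
parameter_set <- function(...) {
  entries <- list(...)
  if (length(entries) == 1L && is.null(entries[[1]]$value)) entries <- entries[[1]]
  if (length(entries) > 0 && (is.null(names(entries)) || any(names(entries) == "")))
    stop("parameter_set: all entries must be named", call. = FALSE)
  structure(entries, class = "parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf("Parameter set with %d constants\n", length(x)))
  df <- as.data.frame.parameter_set(x)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.parameter_set <- function(x, ...) {
  data.frame(name = names(x),
             value = vapply(x, `[[`, numeric(1), "value"),
             units = vapply(x, `[[`, character(1), "units"),
             provenance = vapply(x, `[[`, character(1), "provenance"),
             stringsAsFactors = FALSE)
}

#' Set or override a constant in a parameter set
#'
#' @param params A [parameter_set()].
#' @param name Constant name.
#' @param value New numeric value.
#' @param units,provenance Optional; defaults keep the existing entry's
#'   metadata (new entries default to `"s-1"` / `"calibrated"`).
#' @return The modified parameter set.
#' @export
set_param <- function(params, name, value, units = NULL, provenance = NULL) {
  stopifnot(inherits(params, "parameter_set"))
  old <- params[[name]]
  if (is.null(units)) units <- if (is.null(old)) "s-1" else old$units
  if (is.null(provenance)) provenance <- if (is.null(old)) "calibrated" else old$provenance
  params[[name]] <- param(value, units, provenance)
  params
}

#' Initial conditions table
#'
#' @param ... Entries created with [ic()] (or a single list of them).
#' @return A data frame of class `initial_conditions` with columns
#'   `molecule`, `compartment`, `count`, `clamped`.
#' @export
initial_conditions <- function(...) {
  entries <- list(...)
  if (length(entries) == 1L && is.null(entries[[1]]$molecule)) entries <- entries[[1]]
  df <- do.call(rbind, lapply(entries, function(e)
    data.frame(molecule = e$molecule, compartment = e$compartment,
               count = e$count, clamped = e$clamped, stringsAsFactors = FALSE)))
  if (is.null(df)) df <- data.frame(molecule = character(), compartment = character(),
                                    count = integer(), clamped = logical())
  class(df) <- c("initial_conditions", "data.frame")
  df
}

#' One initial-condition entry
#'
#' @param molecule Molecule type name (a free, unbound molecule).
#' @param compartment Compartment name.
#' @param count Non-negative integer molecule count.
#' @param clamped If `TRUE` the species count is held constant during
#'   simulation (consumed copies are replenished).
#' @return A list usable inside [initial_conditions()].
#' @export
ic <- function(molecule, compartment, count, clamped = FALSE) {
  list(molecule = molecule, compartment = compartment,
       count = count, clamped = clamped)
}

#' Assemble a model definition
#'
#' @param name Model name.
#' @param compartments List of [compartment()]s.
#' @param molecule_types List of [molecule_type()]s.
#' @param rules List of [reaction_rule()]s.
#' @param parameters A [parameter_set()].
#' @param initial An [initial_conditions()] table.
#' @param notes Optional free-text provenance notes.
#' @param rule_provenance Optional data frame documenting the origin of each
#'   rule (shipped with the merged model).
#' @return An object of class `model_definition`.
#' @export
model_definition <- function(name, compartments, molecule_types, rules,
                             parameters, initial, notes = NULL,
                             rule_provenance = NULL) {
  structure(list(name = name,
                 compartments = compartments,
                 molecule_types = molecule_types,
                 rules = rules,
                 parameters = parameters,
                 initial = initial,
                 notes = notes,
                 rule_provenance = rule_provenance),
            class = "model_definition")
}

#' @export
print.model_definition <- function(x, ...) {
  cat(sprintf("Rule-based model '%s'\n", x$name))
  cat(sprintf("  compartments   : %d (%s)\n", length(x$compartments),
              paste(vapply(x$compartments, `[[`, character(1), "name"), collapse = ", ")))
  cat(sprintf("  molecule types : %d\n", length(x$molecule_types)))
  cat(sprintf("  reaction rules : %d\n", length(x$rules)))
  cat(sprintf("  parameters     : %d\n", length(x$parameters)))
  cat(sprintf("  initial species: %d nonzero\n", sum(x$initial$count > 0)))
  errs <- validate_model(x)
  if (length(errs) == 0) cat("  validation     : OK\n")
  else cat(sprintf("  validation     : %d error(s); see validate_model()\n", length(errs)))
  invisible(x)
}

# internal: look-up helpers ---------------------------------------------------

.comp_names <- function(model) vapply(model$compartments, `[[`, character(1), "name")
.type_names <- function(model) vapply(model$molecule_types, `[[`, character(1), "name")
.get_type <- function(model, name) {
  idx <- match(name, .type_names(model))
  if (is.na(idx)) NULL else model$molecule_types[[idx]]
}
.get_volume <- function(model, comp) {
  idx <- match(comp, .comp_names(model))
  if (is.na(idx)) stop("unknown compartment: ", comp, call. = FALSE)
  model$compartments[[idx]]$volume
}

#' Validate a model definition
#'
#' Structural checks: dangling references (compartments, molecule types,
#' sites, rate constants), unit/order mismatches, negative counts or
#' constants, and pattern bond consistency. Errors are returned as data, not
#' raised.
#'
#' @param model A [model_definition()].
#' @return Character vector of error messages; empty iff the model is
#'   well-formed. Warnings (non-fatal observations) are attached as the
#'   `"warnings"` attribute.
#' @export
validate_model <- function(model) {
  errs <- character()
  warns <- character()
  cn <- .comp_names(model)
  tn <- .type_names(model)

  if (anyDuplicated(cn)) errs <- c(errs, "duplicate compartment names")
  if (anyDuplicated(tn)) errs <- c(errs, "duplicate molecule type names")
  for (co in model$compartments) {
    if (co$volume <= 0) errs <- c(errs, sprintf("compartment %s: volume <= 0", co$name))
    if (!is.null(co$parent) && !co$parent %in% cn)
      errs <- c(errs, sprintf("compartment %s: unknown parent %s", co$name, co$parent))
  }
  for (ty in model$molecule_types) {
    for (sn in names(ty$sites)) {
      bad <- setdiff(ty$sites[[sn]], tn)
      if (length(bad))
        errs <- c(errs, sprintf("molecule %s site %s: unknown partner type(s) %s",
                                ty$name, sn, paste(bad, collapse = ",")))
    }
    bad <- setdiff(ty$compartments, cn)
    if (length(bad))
      errs <- c(errs, sprintf("molecule %s: unknown compartment(s) %s",
                              ty$name, paste(bad, collapse = ",")))
  }
  for (nm in names(model$parameters)) {
    p <- model$parameters[[nm]]
    if (!is.numeric(p$value) || p$value < 0)
      errs <- c(errs, sprintf("parameter %s: negative or non-numeric value", nm))
    if (p$provenance == "placeholder")
      warns <- c(warns, sprintf("parameter %s is a placeholder value", nm))
  }

  unit_order <- c("s-1" = 1, "uM-1.s-1" = 2, "molec-1.s-1" = 2,
                  "uM.s-1" = 0, "molec.s-1" = 0)
  for (r in model$rules) {
    if (length(r$reactants) > 2L)
      errs <- c(errs, sprintf("rule %s: more than 2 reactant patterns", r$name))
    p <- model$parameters[[r$rate]]
    if (is.null(p)) {
      errs <- c(errs, sprintf("rule %s: rate constant '%s' not in parameter set",
                              r$name, r$rate))
    } else {
      ord <- sum(vapply(r$reactants, function(pp) length(pp$molecules), integer(1)) > 0)
      ord <- length(r$reactants)
      if (unit_order[[p$units]] != ord)
        errs <- c(errs, sprintf("rule %s: order %d but constant '%s' has units %s",
                                r$name, ord, r$rate, p$units))
    }
    for (pp in r$reactants) {
      errs <- c(errs, .validate_pattern(pp, model, r$name))
    }
    errs <- c(errs, .validate_ops(r, model))
  }

  for (i in seq_len(nrow(model$initial))) {
    row <- model$initial[i, ]
    if (is.na(row$count) || row$count < 0 || row$count != round(row$count))
      errs <- c(errs, sprintf("initial condition %s@%s: count %s is not a non-negative integer",
                              row$molecule, row$compartment, format(row$count)))
    if (!row$molecule %in% tn)
      errs <- c(errs, sprintf("initial condition: unknown molecule %s", row$molecule))
    if (!row$compartment %in% cn)
      errs <- c(errs, sprintf("initial condition: unknown compartment %s", row$compartment))
  }

  structure(unique(errs), warnings = unique(warns))
}

# internal: check one complex pattern
.validate_pattern <- function(pp, model, rule_name) {
  errs <- character()
  cn <- .comp_names(model)
  if (!is.null(pp$compartment) && !pp$compartment %in% cn)
    errs <- c(errs, sprintf("rule %s: pattern names unknown compartment %s",
                            rule_name, pp$compartment))
  bonds <- list()
  for (i in seq_along(pp$molecules)) {
    pm <- pp$molecules[[i]]
    ty <- .get_type(model, pm$type)
    if (is.null(ty)) {
      errs <- c(errs, sprintf("rule %s: pattern names unknown molecule type %s",
                              rule_name, pm$type))
      next
    }
    for (sn in names(pm$sites)) {
      if (!sn %in% names(ty$sites)) {
        errs <- c(errs, sprintf("rule %s: molecule %s has no site '%s'",
                                rule_name, pm$type, sn))
        next
      }
      v <- pm$sites[[sn]]
      if (is.numeric(v) && v > 0) {
        key <- as.character(v)
        bonds[[key]] <- c(bonds[[key]], sprintf("%d.%s", i, sn))
      }
    }
  }
  for (key in names(bonds)) {
    if (length(bonds[[key]]) != 2L)
      errs <- c(errs, sprintf("rule %s: bond %s has %d endpoints (needs exactly 2)",
                              rule_name, key, length(bonds[[key]])))
  }
  errs
}

# internal: check rule transformation ops
.validate_ops <- function(r, model) {
  errs <- character()
  tn <- .type_names(model)
  cn <- .comp_names(model)
  nref <- function(ref) {
    # ref = c(reactant index, molecule index); mixed refs like c(1, 1, "site")
    # arrive as character vectors, so coerce explicitly
    if (length(ref) != 2L) return(FALSE)
    ri <- suppressWarnings(as.integer(ref[[1]]))
    mi <- suppressWarnings(as.integer(ref[[2]]))
    !is.na(ri) && !is.na(mi) && ri >= 1 && ri <= length(r$reactants) &&
      mi >= 1 && mi <= length(r$reactants[[ri]]$molecules)
  }
  for (op in r$ops) {
    ok <- switch(op$op,
      bind = nref(op$a[1:2]) && nref(op$b[1:2]),
      unbind = nref(op$a[1:2]),
      create = op$type %in% tn && (is.null(op$compartment) || op$compartment %in% cn),
      destroy = nref(op$target),
      destroy_others = all(vapply(op$keep, nref, logical(1))),
      transport = op$to %in% cn,
      dissolve = TRUE,
      FALSE)
    if (!isTRUE(ok))
      errs <- c(errs, sprintf("rule %s: invalid op '%s'", r$name, op$op))
  }
  errs
}
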