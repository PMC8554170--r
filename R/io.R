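# Configuration, serialisation and logging: YAML run configs, trajectory
# CSV + JSON metadata writers, and SBML Level 3 export / import of expanded
# networks.

.KNOWN_MODELS <- c("rnai", "sequestration", "lifecycle", "merged")

#' Load a run configuration from a YAML file
#'
#' Recognised top-level keys: `model` (one of rnai / sequestration /
#' lifecycle / merged), `parameters` (name -> value overrides), `initial`
#' (list of \{molecule, compartment, count, clamped\}), `clamp` (list of
#' \{molecule, compartment\}), `stop` (t_end, grid_dt, total_cap,
#' species_cap, max_events), `seeds`, `output_dir`. Unknown keys, unknown
#' parameter names and negative counts are rejected.
#'
#' @param path Path to a YAML file.
#' @return An object of class `run_config` with defaults applied.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  known <- c("model", "parameters", "initial", "clamp", "stop", "seeds", "output_dir")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("load_config: unknown key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  model_name <- raw$model
  if (is.null(model_name) || !model_name %in% .KNOWN_MODELS)
    stop("load_config: 'model' must be one of ",
         paste(.KNOWN_MODELS, collapse = ", "), call. = FALSE)
  model <- switch(model_name,
                  rnai = build_rnai_model(),
                  sequestration = build_sequestration_model(),
                  lifecycle = build_lifecycle_model(),
                  merged = build_merged_model())
  params <- model$parameters
  for (nm in names(raw$parameters)) {
    if (is.null(params[[nm]]))
      stop("load_config: unknown parameter '", nm, "' for model ", model_name,
           call. = FALSE)
    v <- raw$parameters[[nm]]
    if (!is.numeric(v) || length(v) != 1L || v < 0)
      stop("load_config: parameter '", nm, "' must be a single non-negative number",
           call. = FALSE)
    params <- set_param(params, nm, v)
  }
  model$parameters <- params
  ics <- NULL
  for (e in raw$initial) {
    if (is.null(e$molecule) || is.null(e$compartment) || is.null(e$count))
      stop("load_config: each 'initial' entry needs molecule, compartment, count",
           call. = FALSE)
    if (!is.numeric(e$count) || e$count < 0 || e$count != round(e$count))
      stop("load_config: initial count for ", e$molecule,
           " must be a non-negative integer", call. = FALSE)
    ics <- c(ics, list(ic(e$molecule, e$compartment, e$count,
                          isTRUE(e$clamped))))
  }
  stop_args <- raw$stop
  if (!is.null(stop_args)) {
    bad <- setdiff(names(stop_args),
                   c("t_end", "grid_dt", "total_cap", "species_cap", "max_events"))
    if (length(bad))
      stop("load_config: unknown stop key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  stopc <- do.call(stop_condition, as.list(stop_args))
  structure(list(model_name = model_name, model = model,
                 initial_overrides = if (is.null(ics)) NULL else initial_conditions(ics),
                 clamp = raw$clamp,
                 stop = stopc,
                 seeds = if (is.null(raw$seeds)) 1L else as.integer(raw$seeds),
                 output_dir = if (is.null(raw$output_dir)) "." else raw$output_dir),
            class = "run_config")
}

#' Expand a run configuration into a ready-to-simulate network
#'
#' @param config A [load_config()] result.
#' @return A `reaction_network` with overrides and clamps applied.
#' @export
compile_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  net <- expand_rules(config$model)
  if (!is.null(config$initial_overrides))
    net <- set_initial(net, config$initial_overrides)
  for (cl in config$clamp)
    net <- clamp_species(net, cl$molecule, cl$compartment)
  net
}

# tiny polynomial rolling hash for parameter-set fingerprints (no external
# dependency; stability matters, cryptographic strength does not)
.fnv1a <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 5381
  for (b in bytes) h <- (h * 131 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Fingerprint of a parameter set
#'
#' Embedded in run metadata so that any output is regenerable
#' bit-identically from (model, parameter hash, seed).
#'
#' @param params A [parameter_set()].
#' @return 8-hex-digit string.
#' @export
param_hash <- function(params) {
  df <- as.data.frame(params)
  .fnv1a(paste(df$name, format(df$value, digits = 17), df$units,
               collapse = ";"))
}

#' Write a trajectory as CSV plus a JSON metadata sidecar
#'
#' @param traj A `trajectory`.
#' @param path CSV output path; metadata goes to `<path>.meta.json`.
#' @param params Optional [parameter_set()] whose hash is recorded.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, params = NULL) {
  df <- data.frame(time = traj$time, traj$counts, traj$tallies,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(seed = traj$seed, rng = traj$rng, method = traj$method,
               status = traj$status, t_final = traj$t_final,
               n_events = traj$n_events,
               parameter_hash = if (is.null(params)) NA else param_hash(params))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

# --- SBML Level 3 ------------------------------------------------------------

.sbml_id <- function(i) sprintf("s%d", i)

#' Export an expanded network as SBML Level 3
#'
#' Compartments carry their volumes; species carry initial amounts (in
#' molecules, `hasOnlySubstanceUnits`) with clamped species flagged as
#' boundary conditions; each concrete reaction gets an elementary
#' mass-action kinetic law with its stochastic propensity constant as a
#' local parameter. A round-trip through [import_sbml()] reproduces the
#' reaction table exactly.
#'
#' @param x A [model_definition()] (expanded internally) or a
#'   `reaction_network`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_sbml <- function(x, path) {
  net <- if (inherits(x, "reaction_network")) x else expand_rules(x)
  doc <- xml2::xml_new_root("sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version2/core",
    level = "3", version = "2")
  mdl <- xml2::xml_add_child(doc, "model", id = net$model_name)
  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (co in net$model$compartments) {
    xml2::xml_add_child(lc, "compartment", id = co$name,
                        size = format(co$volume, digits = 17),
                        spatialDimensions = "3", constant = "true")
  }
  ls_ <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(net$species))) {
    xml2::xml_add_child(ls_, "species", id = .sbml_id(i),
                        name = net$species$label[i],
                        compartment = net$species$compartment[i],
                        initialAmount = format(net$init_counts[i], digits = 17),
                        hasOnlySubstanceUnits = "true",
                        boundaryCondition = tolower(as.character(net$clamped[i])),
                        constant = "false")
  }
  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  mathns <- "http://www.w3.org/1998/Math/MathML"
  for (i in seq_along(net$reactions)) {
    rx <- net$reactions[[i]]
    rn <- xml2::xml_add_child(lr, "reaction", id = sprintf("r%d", i),
                              name = rx$rule, reversible = "false")
    if (length(rx$reactants)) {
      lre <- xml2::xml_add_child(rn, "listOfReactants")
      for (s in unique(rx$reactants))
        xml2::xml_add_child(lre, "speciesReference", species = .sbml_id(s),
                            stoichiometry = as.character(sum(rx$reactants == s)),
                            constant = "true")
    }
    if (length(rx$products)) {
      lpr <- xml2::xml_add_child(rn, "listOfProducts")
      for (s in unique(rx$products))
        xml2::xml_add_child(lpr, "speciesReference", species = .sbml_id(s),
                            stoichiometry = as.character(sum(rx$products == s)),
                            constant = "true")
    }
    kl <- xml2::xml_add_child(rn, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math", xmlns = mathns)
    ap <- xml2::xml_add_child(math, "apply")
    xml2::xml_add_child(ap, "times")
    xml2::xml_add_child(ap, "cn", format(rx$c, digits = 17))
    for (s in rx$reactants) xml2::xml_add_child(ap, "ci", .sbml_id(s))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Import an SBML Level 3 network written by [export_sbml()]
#'
#' @param path SBML file.
#' @return A list with `species` (data frame: id, label, compartment,
#'   initial, clamped) and `reactions` (data frame: id, rule, reactants,
#'   products, c) mirroring [reaction_table()] of the exported network.
#' @export
import_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version2/core")
  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  species <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    label = xml2::xml_attr(sp, "name"),
    compartment = xml2::xml_attr(sp, "compartment"),
    initial = as.numeric(xml2::xml_attr(sp, "initialAmount")),
    clamped = xml2::xml_attr(sp, "boundaryCondition") == "true",
    stringsAsFactors = FALSE)
  lab_of <- stats::setNames(species$label, species$id)
  rx <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  reactions <- do.call(rbind, lapply(rx, function(r) {
    refs <- function(xp) {
      nodes <- xml2::xml_find_all(r, xp, ns)
      ids <- xml2::xml_attr(nodes, "species")
      st <- as.integer(xml2::xml_attr(nodes, "stoichiometry"))
      paste(rep(lab_of[ids], st), collapse = " + ")
    }
    cn <- xml2::xml_find_first(r, ".//s:kineticLaw//*[local-name()='cn']", ns)
    rr <- refs("./s:listOfReactants/s:speciesReference")
    pp <- refs("./s:listOfProducts/s:speciesReference")
    data.frame(id = xml2::xml_attr(r, "id"),
               rule = xml2::xml_attr(r, "name"),
               reactants = rr,
               products = if (nzchar(pp)) pp else "0",
               c = as.numeric(xml2::xml_text(cn)),
               stringsAsFactors = FALSE)
  }))
  list(species = species, reactions = reactions)
}
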