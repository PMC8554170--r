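# Reaction rules: complex patterns over site-graph molecules plus an explicit
# list of transformation operations. Rules are elementary mass action with at
# most two reactant patterns; products are derived by applying the ops to the
# matched complexes.

#' Build a complex pattern
#'
#' A pattern describes a (sub)complex: one or more molecule patterns, bonds
#' between them, and an optional compartment constraint. Patterns are matched
#' against concrete species as subgraphs.
#'
#' @param ... Molecule patterns created with [pmol()].
#' @param compartment Optional compartment name the species must occupy.
#' @return An object of class `complex_pattern`.
#' @export
complex_pattern <- function(..., compartment = NULL) {
  structure(list(molecules = list(...), compartment = compartment),
            class = "complex_pattern")
}

#' Molecule pattern inside a [complex_pattern()]
#'
#' @param .type Molecule type name (dotted to avoid partial matching against
#'   site names passed through `...`).
#' @param ... Site constraints, named by site: `0` requires the site unbound,
#'   `"+"` requires it bound (to anything), a positive integer is a bond
#'   label shared with the matching site on the partner molecule pattern.
#'   Unmentioned sites are unconstrained.
#' @return A molecule-pattern list.
#' @export
pmol <- function(.type, ...) {
  sites <- list(...)
  for (v in sites) {
    ok <- (is.numeric(v) && length(v) == 1L && v >= 0) ||
      (is.character(v) && identical(v, "+"))
    if (!ok) stop("pmol: site constraint must be 0, '+' or a positive bond label",
                  call. = FALSE)
  }
  list(type = .type, sites = sites)
}

#' Define a reaction rule
#'
#' An elementary mass-action rule: zero, one or two reactant
#' [complex_pattern()]s, a rate-constant name resolving into the model's
#' [parameter_set()], and a list of transformation operations applied to the
#' matched complexes to derive the products.
#'
#' Supported ops (each a list with an `op` element):
#' \itemize{
#'   \item `list(op = "bind", a = c(ri, mi, "site"), b = c(rj, mj, "site"))` -
#'     form a bond between two matched sites (`ri`/`rj` reactant pattern
#'     index, `mi`/`mj` molecule index inside the pattern).
#'   \item `list(op = "unbind", a = c(ri, mi, "site"))` - break the bond at a
#'     matched site.
#'   \item `list(op = "create", type = , compartment = NULL, count = 1)` -
#'     add free molecule(s); default compartment is the reaction context.
#'   \item `list(op = "destroy", target = c(ri, mi))` - remove a matched
#'     molecule (its bonds are broken).
#'   \item `list(op = "destroy_others", keep = list(c(ri, mi), ...))` -
#'     remove every molecule of the matched complex except those kept.
#'   \item `list(op = "dissolve")` - break every bond in the complex.
#'   \item `list(op = "transport", to = "Compartment")` - move all products
#'     to another compartment.
#' }
#'
#' @param name Rule identifier.
#' @param reactants List of [complex_pattern()]s (length 0, 1 or 2).
#' @param rate Name of the rate constant in the model's parameter set.
#' @param ops List of transformation operations (see Details).
#' @param pathway Pathway tag used for event tallies: one of `"rnase"`,
#'   `"risc"`, `"sg"`, `"mvb"`, `"rt"`, `"other"`.
#' @return An object of class `reaction_rule`.
#' @export
reaction_rule <- function(name, reactants, rate, ops = list(),
                          pathway = "other") {
  pathway <- match.arg(pathway, c("rnase", "risc", "sg", "mvb", "rt", "other"))
  if (length(reactants) > 2L)
    stop("reaction_rule: at most 2 reactant patterns (elementary mass action)",
         call. = FALSE)
  structure(list(name = name, reactants = reactants, rate = rate,
                 ops = ops, pathway = pathway),
            class = "reaction_rule")
}

#' @export
print.reaction_rule <- function(x, ...) {
  lhs <- if (length(x$reactants) == 0) "0" else
    paste(vapply(x$reactants, function(p)
      paste(vapply(p$molecules, `[[`, character(1), "type"), collapse = "."),
      character(1)), collapse = " + ")
  cat(sprintf("Rule %-24s %s  [%s, pathway=%s]\n", x$name, lhs, x$rate, x$pathway))
  invisible(x)
}
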