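# Concrete species: site-graph complexes with canonical labels, subgraph
# pattern matching (with symmetric-site collapsing) and rule application.
#
# A concrete species is
#   list(molecules = list(list(type, sites = named integer vector)),
#        compartment = "name")
# where a site value of 0 means unbound and a positive integer is a bond id
# shared by exactly two sites. Canonical labels are BioNetGen-flavoured
# strings, e.g. "L1mRNA(orf0,orf1_a!1,orf1_b,orf2)@Cytoplasm".

# small permutation generator (n is tiny: molecules within a tied group,
# sites within an equivalence class)
.perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in .perms(n - 1L)) {
      rest <- seq_len(n)[-i]
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

#' Construct a free (fully unbound) molecule species
#'
#' @param type Molecule type name.
#' @param compartment Compartment name.
#' @param model The [model_definition()] supplying the type declaration.
#' @return A concrete species structure.
#' @export
free_species <- function(type, compartment, model) {
  ty <- .get_type(model, type)
  if (is.null(ty)) stop("free_species: unknown molecule type ", type, call. = FALSE)
  sites <- stats::setNames(integer(length(ty$sites)), names(ty$sites))
  list(molecules = list(list(type = type, sites = sites)),
       compartment = compartment)
}

# partner lookup: returns c(molecule index, site name) of the other endpoint
.bond_partner <- function(sp, mi, site) {
  b <- sp$molecules[[mi]]$sites[[site]]
  if (b == 0) return(NULL)
  for (j in seq_along(sp$molecules)) {
    ss <- sp$molecules[[j]]$sites
    for (sn in names(ss)) {
      if (ss[[sn]] == b && !(j == mi && sn == site)) return(list(mol = j, site = sn))
    }
  }
  NULL
}

# coarse per-molecule signature used to limit permutation search; includes
# optional marks so that marked canonicalisation stays correct
.mol_signature <- function(sp, i, types) {
  m <- sp$molecules[[i]]
  ty <- types[[m$type]]
  cls_of <- stats::setNames(names(ty$sites), names(ty$sites))
  for (k in seq_along(ty$equivalent)) {
    for (s in ty$equivalent[[k]]) cls_of[[s]] <- paste0("~eq", k)
  }
  toks <- character()
  for (sn in names(m$sites)) {
    if (m$sites[[sn]] > 0) {
      p <- .bond_partner(sp, i, sn)
      toks <- c(toks, paste0(cls_of[[sn]], ":", sp$molecules[[p$mol]]$type))
    }
  }
  paste0(m$type, "|", if (!is.null(m$mark)) m$mark else "", "|",
         paste(sort(toks), collapse = ","))
}

# encode molecules in a given order with per-molecule site permutations
# applied to equivalence classes; bonds renumbered by first appearance
.encode <- function(sp, order, site_perm_choice, types) {
  bond_map <- new.env(parent = emptyenv())
  counter <- 0L
  parts <- character(length(order))
  for (k in seq_along(order)) {
    i <- order[[k]]
    m <- sp$molecules[[i]]
    ty <- types[[m$type]]
    site_names <- names(m$sites)
    vals <- m$sites
    marks <- m$site_marks  # optional named chr vector
    # apply equivalence-class value permutation
    choice <- site_perm_choice[[k]]
    if (!is.null(choice)) {
      for (ci in seq_along(ty$equivalent)) {
        cls <- ty$equivalent[[ci]]
        pp <- choice[[ci]]
        vals[cls] <- vals[cls][pp]
        if (!is.null(marks)) {
          mv <- marks[cls]; names(mv) <- cls
          marks[cls] <- mv[pp]
        }
      }
    }
    toks <- character(length(site_names))
    for (s in seq_along(site_names)) {
      sn <- site_names[[s]]
      v <- vals[[sn]]
      tok <- sn
      if (v > 0) {
        key <- as.character(v)
        idx <- bond_map[[key]]
        if (is.null(idx)) { counter <- counter + 1L; idx <- counter; assign(key, idx, envir = bond_map) }
        tok <- paste0(tok, "!", idx)
      }
      if (!is.null(marks) && !is.na(marks[sn]) && nzchar(marks[sn]))
        tok <- paste0(tok, "*", marks[[sn]])
      toks[[s]] <- tok
    }
    head <- m$type
    if (!is.null(m$mark)) head <- paste0(head, "[", m$mark, "]")
    parts[[k]] <- paste0(head, "(", paste(toks, collapse = ","), ")")
  }
  paste0(paste(parts, collapse = "."), "@", sp$compartment)
}

#' Canonical label of a concrete species
#'
#' Two structurally identical complexes (up to molecule reordering and
#' permutation of declared-equivalent sites) receive the same label. The
#' search is brute force over orderings within identical-signature molecule
#' groups and over equivalence-class site permutations, which is exact for
#' the complex sizes this model produces (at most a few molecules).
#'
#' @param sp A concrete species structure.
#' @param model The [model_definition()] (or a named list of molecule types).
#' @return A single string.
#' @export
canonical_label <- function(sp, model) {
  types <- .types_by_name(model)
  n <- length(sp$molecules)
  if (n == 0L) return(paste0("<empty>@", sp$compartment))
  sigs <- vapply(seq_len(n), function(i) .mol_signature(sp, i, types), character(1))
  # radix (byte) ordering keeps canonical labels locale-independent
  base_order <- order(sigs, method = "radix")
  groups <- lapply(sort(unique(sigs), method = "radix"),
                   function(sg) base_order[sigs[base_order] == sg])
  # documented limit: beyond this many candidate orderings (large complexes
  # of identical molecules, which the packaged models never produce) fall
  # back to the deterministic signature ordering
  if (prod(factorial(lengths(groups))) > 720) {
    groups <- lapply(base_order, identity)
  }
  group_perms <- lapply(groups, function(g) {
    if (length(g) == 1L) list(g) else lapply(.perms(length(g)), function(p) g[p])
  })
  # cartesian product over group orderings (groups sorted by signature)
  ord_candidates <- Reduce(function(acc, gp) {
    out <- list()
    for (a in acc) for (g in gp) out[[length(out) + 1L]] <- c(a, g)
    out
  }, group_perms, accumulate = FALSE, right = FALSE, init = list(integer()))

  best <- NULL
  for (ord in ord_candidates) {
    # site-permutation candidates per molecule in this order
    sp_choices <- lapply(ord, function(i) {
      ty <- types[[sp$molecules[[i]]$type]]
      if (length(ty$equivalent) == 0L) return(list(NULL))
      combos <- list(list())
      for (ci in seq_along(ty$equivalent)) {
        cls <- ty$equivalent[[ci]]
        ps <- .perms(length(cls))
        combos <- unlist(lapply(combos, function(cc)
          lapply(ps, function(p) c(cc, list(p)))), recursive = FALSE)
      }
      combos
    })
    combo_sets <- Reduce(function(acc, ch) {
      out <- list()
      for (a in acc) for (c1 in ch) out[[length(out) + 1L]] <- c(a, list(c1))
      out
    }, sp_choices, init = list(list()))
    for (cs in combo_sets) {
      lab <- .encode(sp, ord, cs, types)
      if (is.null(best) ||
          (lab != best && sort(c(lab, best), method = "radix")[1] == lab))
        best <- lab
    }
  }
  best
}

.types_by_name <- function(model) {
  if (inherits(model, "model_definition")) {
    stats::setNames(model$molecule_types, .type_names(model))
  } else model
}

# connected components of a species' bond graph; returns list of species
.components <- function(sp) {
  n <- length(sp$molecules)
  if (n == 0L) return(list())
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (sn in names(sp$molecules[[i]]$sites)) {
        if (sp$molecules[[i]]$sites[[sn]] > 0) {
          p <- .bond_partner(sp, i, sn)
          if (!is.null(p) && comp[p$mol] != comp[i]) {
            newc <- min(comp[p$mol], comp[i])
            comp[comp == comp[p$mol] | comp == comp[i]] <- newc
            changed <- TRUE
          }
        }
      }
    }
    if (!changed) break
  }
  lapply(unique(comp), function(cc) {
    list(molecules = sp$molecules[comp == cc], compartment = sp$compartment)
  })
}

# --- pattern matching --------------------------------------------------------

# number of automorphisms of the pattern itself arising from permutations of
# equivalent sites with identical constraints; raw embedding counts are
# divided by this so that e.g. a pattern constraining both symmetric sites
# "unbound" yields statistical factor 1, while a pattern constraining only
# one of them yields factor 2 on a doubly-free species. Distinct bond labels
# are treated as distinct constraints (conservative; the packaged models
# never contain two indistinguishable pattern molecules).
.pattern_aut <- function(pattern, types) {
  aut <- 1L
  for (pm in pattern$molecules) {
    ty <- types[[pm$type]]
    for (cls in ty$equivalent) {
      constrained <- cls[cls %in% names(pm$sites)]
      if (length(constrained) < 2L) next
      keys <- vapply(constrained, function(sn) {
        v <- pm$sites[[sn]]
        if (identical(v, "+")) "+" else as.character(v)
      }, character(1))
      aut <- aut * prod(factorial(table(keys)))
    }
  }
  as.integer(aut)
}

# raw embeddings of a complex pattern into a species. Each embedding is
# list(mol_map = integer vector, site_map = list of named chr vectors).
.match_raw <- function(pattern, sp, types) {
  if (!is.null(pattern$compartment) && pattern$compartment != sp$compartment)
    return(list())
  pms <- pattern$molecules
  np <- length(pms)
  ns <- length(sp$molecules)
  if (np > ns) return(list())
  out <- list()

  # site assignment candidates for pattern molecule pm on species molecule si
  site_assigns <- function(pm, si) {
    ty <- types[[pm$type]]
    cons <- pm$sites
    if (length(cons) == 0L) return(list(stats::setNames(character(0), character(0))))
    cls_of <- stats::setNames(names(ty$sites), names(ty$sites))
    for (k in seq_along(ty$equivalent))
      for (s in ty$equivalent[[k]]) cls_of[[s]] <- paste0("~eq", k)
    by_cls <- split(names(cons), vapply(names(cons), function(s) cls_of[[s]], character(1)))
    svals <- sp$molecules[[si]]$sites
    cls_sites <- split(names(svals), vapply(names(svals), function(s) cls_of[[s]], character(1)))
    combos <- list(character(0))
    for (cl in names(by_cls)) {
      pnames <- by_cls[[cl]]
      snames <- cls_sites[[cl]]
      if (is.null(snames) || length(pnames) > length(snames)) return(list())
      # injective assignments pattern sites -> physical sites in this class
      assigns <- list()
      idx_perms <- utils::combn(length(snames), length(pnames), simplify = FALSE)
      for (sel in idx_perms) {
        for (p in .perms(length(pnames))) {
          assigns[[length(assigns) + 1L]] <-
            stats::setNames(snames[sel][p], pnames)
        }
      }
      # filter by unary constraints (bond cross-check happens later)
      assigns <- Filter(function(a) {
        all(vapply(names(a), function(pn) {
          v <- cons[[pn]]; sv <- svals[[a[[pn]]]]
          if (identical(v, "+")) sv > 0
          else if (is.numeric(v) && v == 0) sv == 0
          else sv > 0  # pattern bond id: must be bound; identity checked later
        }, logical(1)))
      }, assigns)
      if (length(assigns) == 0L) return(list())
      combos <- unlist(lapply(combos, function(cc)
        lapply(assigns, function(a) c(cc, a))), recursive = FALSE)
    }
    combos
  }

  rec <- function(pi, mol_map, used, site_map) {
    if (pi > np) {
      # cross-check pattern bonds
      bond_ends <- list()
      for (qi in seq_len(np)) {
        cons <- pms[[qi]]$sites
        for (pn in names(cons)) {
          v <- cons[[pn]]
          if (is.numeric(v) && v > 0) {
            key <- as.character(v)
            bond_ends[[key]] <- c(bond_ends[[key]],
                                  list(list(mol = mol_map[qi], site = site_map[[qi]][[pn]])))
          }
        }
      }
      for (key in names(bond_ends)) {
        ends <- bond_ends[[key]]
        if (length(ends) != 2L) return(invisible(NULL))
        b1 <- sp$molecules[[ends[[1]]$mol]]$sites[[ends[[1]]$site]]
        b2 <- sp$molecules[[ends[[2]]$mol]]$sites[[ends[[2]]$site]]
        if (b1 == 0 || b1 != b2) return(invisible(NULL))
      }
      out[[length(out) + 1L]] <<- list(mol_map = mol_map, site_map = site_map)
      return(invisible(NULL))
    }
    pm <- pms[[pi]]
    for (si in seq_len(ns)) {
      if (used[si]) next
      if (sp$molecules[[si]]$type != pm$type) next
      for (a in site_assigns(pm, si)) {
        mm <- mol_map; mm[pi] <- si
        u <- used; u[si] <- TRUE
        smap <- site_map; smap[[pi]] <- a
        rec(pi + 1L, mm, u, smap)
      }
    }
    invisible(NULL)
  }
  rec(1L, integer(np), logical(ns), vector("list", np))
  out
}

#' Match a complex pattern against a concrete species
#'
#' Returns the distinct embeddings of `pattern` into `species`. Embeddings
#' that differ only by a permutation of declared-equivalent sites (or of
#' indistinguishable molecules) are collapsed into one entry whose `factor`
#' element records the number of raw symmetric embeddings - the statistical
#' factor applied to the mass-action propensity of reactions generated from
#' this match.
#'
#' @param pattern A [complex_pattern()].
#' @param species A concrete species structure.
#' @param model The [model_definition()] declaring the molecule types.
#' @return A list of embeddings, each `list(mol_map, site_map, factor)`.
#' @export
match_pattern <- function(pattern, species, model) {
  types <- .types_by_name(model)
  raw <- .match_raw(pattern, species, types)
  if (length(raw) == 0L) return(list())
  # group raw embeddings by marked canonical label
  labs <- vapply(raw, function(e) {
    msp <- species
    for (qi in seq_along(e$mol_map)) {
      mi <- e$mol_map[qi]
      msp$molecules[[mi]]$mark <- as.character(qi)
      sm <- e$site_map[[qi]]
      if (length(sm) > 0) {
        marks <- stats::setNames(rep(NA_character_, length(msp$molecules[[mi]]$sites)),
                                 names(msp$molecules[[mi]]$sites))
        for (pn in names(sm)) marks[sm[[pn]]] <- paste0(qi, ".", pn)
        msp$molecules[[mi]]$site_marks <- marks
      }
    }
    canonical_label(msp, types)
  }, character(1))
  aut <- .pattern_aut(pattern, types)
  idx <- split(seq_along(raw), labs)
  out <- lapply(idx, function(ii) {
    e <- raw[[ii[1]]]
    e$factor <- length(ii) %/% aut
    e
  })
  unname(out)
}

# --- rule application --------------------------------------------------------

# apply rule ops to matched reactant species; returns list of product species
# (possibly empty). `embeds` is a list of raw embeddings parallel to
# `reactant_species`.
.apply_rule <- function(rule, reactant_species, embeds, context_compartment, model) {
  types <- .types_by_name(model)
  # merge molecules with disjoint bond ids
  mols <- list()
  offset_bond <- 0L
  offsets <- integer(length(reactant_species))
  for (ri in seq_along(reactant_species)) {
    spi <- reactant_species[[ri]]
    offsets[ri] <- length(mols)
    for (m in spi$molecules) {
      m$sites <- vapply(m$sites, function(v) if (v > 0) v + offset_bond else 0L,
                        integer(1))
      m$mark <- NULL; m$site_marks <- NULL
      mols[[length(mols) + 1L]] <- m
    }
    mb <- unlist(lapply(spi$molecules, function(m) m$sites))
    offset_bond <- offset_bond + (if (length(mb)) max(mb) else 0L)
  }
  alive <- rep(TRUE, length(mols))
  target_comp <- context_compartment
  next_bond <- offset_bond + 1L
  created <- list()

  resolve <- function(ref) {
    ri <- as.integer(ref[[1]]); mi <- as.integer(ref[[2]])
    gi <- offsets[ri] + embeds[[ri]]$mol_map[mi]
    site <- if (length(ref) >= 3L) {
      sm <- embeds[[ri]]$site_map[[mi]]
      pn <- ref[[3]]
      if (!is.null(sm) && pn %in% names(sm)) sm[[pn]] else pn
    } else NULL
    list(gi = gi, site = site)
  }
  break_bond_at <- function(gi, site) {
    b <- mols[[gi]]$sites[[site]]
    if (b == 0) return(invisible(NULL))
    for (j in seq_along(mols)) {
      sj <- mols[[j]]$sites
      hit <- names(sj)[sj == b]
      for (sn in hit) mols[[j]]$sites[[sn]] <<- 0L
    }
    invisible(NULL)
  }
  destroy_mol <- function(gi) {
    for (sn in names(mols[[gi]]$sites))
      if (mols[[gi]]$sites[[sn]] > 0) break_bond_at(gi, sn)
    alive[gi] <<- FALSE
  }

  for (op in rule$ops) {
    switch(op$op,
      bind = {
        a <- resolve(op$a); b <- resolve(op$b)
        if (mols[[a$gi]]$sites[[a$site]] != 0 || mols[[b$gi]]$sites[[b$site]] != 0)
          stop("rule ", rule$name, ": bind on occupied site", call. = FALSE)
        mols[[a$gi]]$sites[[a$site]] <- next_bond
        mols[[b$gi]]$sites[[b$site]] <- next_bond
        next_bond <- next_bond + 1L
      },
      unbind = {
        a <- resolve(op$a)
        break_bond_at(a$gi, a$site)
      },
      create = {
        cnt <- if (is.null(op$count)) 1L else op$count
        comp <- if (is.null(op$compartment)) target_comp else op$compartment
        for (k in seq_len(cnt))
          created[[length(created) + 1L]] <- list(type = op$type, compartment = comp)
      },
      destroy = {
        a <- resolve(op$target)
        destroy_mol(a$gi)
      },
      destroy_others = {
        keep <- vapply(op$keep, function(ref) resolve(ref)$gi, integer(1))
        for (gi in seq_along(mols)) if (alive[gi] && !(gi %in% keep)) destroy_mol(gi)
      },
      dissolve = {
        for (gi in seq_along(mols)) {
          if (!alive[gi]) next
          for (sn in names(mols[[gi]]$sites)) mols[[gi]]$sites[[sn]] <- 0L
        }
      },
      transport = { target_comp <- op$to },
      stop("unknown op: ", op$op, call. = FALSE)
    )
  }

  remaining <- list(molecules = mols[alive], compartment = target_comp)
  prods <- .components(remaining)
  for (cr in created) {
    ty <- types[[cr$type]]
    sites <- stats::setNames(integer(length(ty$sites)), names(ty$sites))
    prods[[length(prods) + 1L]] <-
      list(molecules = list(list(type = cr$type, sites = sites)),
           compartment = cr$compartment)
  }
  prods
}
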