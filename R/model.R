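#' Create a chemical species
#'
#' Species are the state variables of a signaling model. Concentrations are
#' expressed in micromolar throughout; time is in seconds.
#'
#' @param id Unique identifier token (character scalar).
#' @param name Free-text display name; defaults to `id`.
#' @param initial_concentration Non-negative initial concentration, uM.
#' @param is_boundary If `TRUE` the concentration is clamped (a model input
#'   such as a ligand dose) and its time derivative is held at zero.
#' @param tags Character vector of labels, e.g. `"observable:ppERK"`.
#' @return An object of class `sig_species`.
#' @export
species <- function(id, name = id, initial_concentration = 0,
                    is_boundary = FALSE, tags = character()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.numeric(initial_concentration) || length(initial_concentration) != 1L ||
      is.na(initial_concentration) || initial_concentration < 0) {
    stop("initial_concentration must be a single non-negative number (uM)")
  }
  structure(
    list(id = id, name = name,
         initial_concentration = as.numeric(initial_concentration),
         is_boundary = isTRUE(is_boundary), tags = as.character(tags)),
    class = "sig_species"
  )
}

#' Create a mass-action rate constant
#'
#' First-order constants carry units of 1/s; second-order constants
#' 1/(uM s). The unit string is derived from the kinetic order.
#'
#' @param id Unique identifier token.
#' @param value Non-negative numeric value.
#' @param order Kinetic order, 1 or 2.
#' @return An object of class `sig_rate_constant`.
#' @export
rate_constant <- function(id, value, order = 1L) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.numeric(value) || length(value) != 1L || is.na(value) || value < 0) {
    stop("rate constant value must be a single non-negative number")
  }
  order <- as.integer(order)
  if (!order %in% c(1L, 2L)) stop("rate constant order must be 1 or 2")
  structure(
    list(id = id, value = as.numeric(value), order = order,
         units = if (order == 1L) "s-1" else "uM-1 s-1"),
    class = "sig_rate_constant"
  )
}

#' Create a mass-action reaction
#'
#' Reactions follow pure mass-action kinetics: the forward velocity is
#' `kf * prod(reactant concentrations ^ stoichiometry)` and, for reversible
#' reactions, the reverse velocity `kr * prod(products ^ stoichiometry)` is
#' subtracted. Total reactant stoichiometry must be 1 or 2 (uni- or
#' bimolecular); for reversible reactions the same holds on the product side
#' so the reverse constant has a well-defined order.
#'
#' @param id Unique identifier token.
#' @param reactants Named integer vector: species id -> positive stoichiometry.
#' @param products Named integer vector: species id -> positive stoichiometry.
#'   May be empty for a pure degradation step.
#' @param kf Forward [rate_constant] (or a bare number, promoted with a
#'   derived id and the order implied by the reactants).
#' @param kr Reverse [rate_constant] for reversible reactions, else `NULL`.
#' @param reversible Logical; must agree with the presence of `kr`.
#' @return An object of class `sig_reaction`.
#' @export
reaction <- function(id, reactants, products, kf, kr = NULL,
                     reversible = !is.null(kr)) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  reactants <- normalize_stoich(reactants, "reactants")
  products <- normalize_stoich(products, "products")
  if (length(reactants) == 0L) stop("a reaction needs at least one reactant")
  r_order <- sum(reactants)
  if (!r_order %in% c(1L, 2L)) {
    stop("total reactant stoichiometry must be 1 or 2 (mass-action uni/bimolecular)")
  }
  if (is.numeric(kf)) kf <- rate_constant(paste0("kf_", id), kf, r_order)
  stopifnot(inherits(kf, "sig_rate_constant"))
  if (isTRUE(reversible) && is.null(kr)) stop("reversible reaction requires kr")
  if (!isTRUE(reversible) && !is.null(kr)) stop("kr given for an irreversible reaction")
  if (!is.null(kr)) {
    p_order <- sum(products)
    if (!p_order %in% c(1L, 2L)) {
      stop("reversible reaction requires total product stoichiometry 1 or 2")
    }
    if (is.numeric(kr)) kr <- rate_constant(paste0("kr_", id), kr, p_order)
    stopifnot(inherits(kr, "sig_rate_constant"))
  }
  structure(
    list(id = id, reactants = reactants, products = products,
         reversible = isTRUE(reversible), kf = kf, kr = kr),
    class = "sig_reaction"
  )
}

normalize_stoich <- function(x, what) {
  if (length(x) == 0L) return(stats::setNames(integer(0), character(0)))
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop(what, " must be a named vector (species id -> stoichiometry)")
  }
  v <- as.integer(x)
  if (any(is.na(v)) || any(v <= 0L)) stop(what, " stoichiometries must be positive integers")
  stats::setNames(v, names(x))
}

#' Create a model rule
#'
#' Two SBML-core rule kinds are supported. An `assignment` rule sets its
#' target species (or parameter) to the value of `expression` before every
#' right-hand-side evaluation; a `rate` rule adds `expression` to the target
#' species' time derivative. Expressions are arithmetic over declared species
#' ids and parameter names.
#'
#' @param id Unique identifier token.
#' @param kind `"assignment"` or `"rate"`.
#' @param target Species or parameter id.
#' @param expression Character scalar holding the arithmetic expression.
#' @return An object of class `sig_rule`.
#' @export
rule <- function(id, kind = c("assignment", "rate"), target, expression) {
  kind <- match.arg(kind)
  stopifnot(is.character(id), length(id) == 1L,
            is.character(target), length(target) == 1L,
            is.character(expression), length(expression) == 1L)
  structure(list(id = id, kind = kind, target = target, expression = expression),
            class = "sig_rule")
}

#' Assemble a signaling model
#'
#' A model bundles an ordered species list, an ordered reaction list, global
#' parameters (numeric constants available to rules) and rules. Structure
#' counts (species, reactions, parameters, rules) are queryable via
#' [model_counts()]; the parameter count is the number of distinct rate
#' constants plus the number of global parameters.
#'
#' @param name Model name.
#' @param species List of [species()] objects (order defines state order).
#' @param reactions List of [reaction()] objects.
#' @param rules List of [rule()] objects.
#' @param parameters Named numeric vector of global parameters.
#' @param condition_label Free label, conventionally `"untreated"` or
#'   `"treated"`.
#' @param validate If `TRUE` (default), stop on a non-empty validation report.
#' @return An object of class `sig_model`.
#' @export
sig_model <- function(name, species, reactions, rules = list(),
                      parameters = numeric(), condition_label = "untreated",
                      validate = TRUE) {
  stopifnot(is.list(species), is.list(reactions), is.list(rules))
  m <- structure(
    list(name = name, condition_label = condition_label,
         species = species, reactions = reactions, rules = rules,
         parameters = parameters),
    class = "sig_model"
  )
  if (validate) {
    rep <- validate_model(m)
    if (nrow(rep) > 0L) {
      stop("model '", name, "' failed validation:\n",
           paste(sprintf("  [%s] %s", rep$type, rep$message), collapse = "\n"))
    }
  }
  m
}

#' @export
print.sig_model <- function(x, ...) {
  cnt <- model_counts(x)
  cat(sprintf("<sig_model> %s (%s)\n", x$name, x$condition_label))
  cat(sprintf("  %d species, %d reactions, %d parameters, %d rule(s)\n",
              cnt[["species"]], cnt[["reactions"]], cnt[["parameters"]],
              cnt[["rules"]]))
  invisible(x)
}

#' @rdname sig_model
#' @param model A `sig_model`.
#' @return `model_counts()`: named integer vector with elements `species`,
#'   `reactions`, `parameters`, `rules`.
#' @export
model_counts <- function(model) {
  stopifnot(inherits(model, "sig_model"))
  kids <- unlist(lapply(model$reactions, function(r) {
    c(r$kf$id, if (!is.null(r$kr)) r$kr$id)
  }))
  c(species = length(model$species),
    reactions = length(model$reactions),
    parameters = length(unique(kids)) + length(model$parameters),
    rules = length(model$rules))
}

species_ids <- function(model) vapply(model$species, `[[`, character(1), "id")
reaction_ids <- function(model) vapply(model$reactions, `[[`, character(1), "id")

#' Initial state vector of a model
#'
#' @param model A `sig_model`.
#' @return Named numeric vector of initial concentrations (uM) in species
#'   order.
#' @export
initial_state <- function(model) {
  stats::setNames(
    vapply(model$species, `[[`, numeric(1), "initial_concentration"),
    species_ids(model)
  )
}

#' Validate a model
#'
#' Checks id uniqueness, undeclared species references, negative values,
#' rate-constant order/unit consistency with stoichiometry, and rule targets.
#' The model is usable iff the returned report has zero rows.
#'
#' @param model A `sig_model`.
#' @return A data frame with columns `type` (structural / value / units /
#'   rule) and `message`; zero rows for a well-formed model.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "sig_model"))
  issues <- list()
  add <- function(type, msg) issues[[length(issues) + 1L]] <<- list(type = type, message = msg)

  sids <- species_ids(model)
  dup <- unique(sids[duplicated(sids)])
  for (d in dup) add("structural", sprintf("duplicate species id '%s'", d))
  rids <- reaction_ids(model)
  dup <- unique(rids[duplicated(rids)])
  for (d in dup) add("structural", sprintf("duplicate reaction id '%s'", d))

  for (sp in model$species) {
    if (sp$initial_concentration < 0) {
      add("value", sprintf("species '%s' has negative initial concentration", sp$id))
    }
  }

  known_params <- names(model$parameters)
  for (r in model$reactions) {
    refs <- c(names(r$reactants), names(r$products))
    missing <- setdiff(refs, sids)
    for (mss in missing) {
      add("structural", sprintf("reaction '%s' references undeclared species '%s'", r$id, mss))
    }
    if (r$kf$value < 0) add("value", sprintf("reaction '%s': negative kf", r$id))
    ro <- sum(r$reactants)
    if (r$kf$order != ro) {
      add("units", sprintf(
        "reaction '%s': kf order %d does not match total reactant stoichiometry %d",
        r$id, r$kf$order, ro))
    }
    if (r$reversible) {
      if (is.null(r$kr)) {
        add("structural", sprintf("reaction '%s' reversible but kr missing", r$id))
      } else {
        po <- sum(r$products)
        if (r$kr$order != po) {
          add("units", sprintf(
            "reaction '%s': kr order %d does not match total product stoichiometry %d",
            r$id, r$kr$order, po))
        }
        if (r$kr$value < 0) add("value", sprintf("reaction '%s': negative kr", r$id))
      }
    }
  }

  for (rl in model$rules) {
    if (!(rl$target %in% sids) && !(rl$target %in% known_params)) {
      add("rule", sprintf("rule '%s' targets undeclared id '%s'", rl$id, rl$target))
    }
    expr_syms <- tryCatch(
      all.vars(str2lang(rl$expression)),
      error = function(e) {
        add("rule", sprintf("rule '%s': unparsable expression", rl$id))
        character()
      })
    undecl <- setdiff(expr_syms, c(sids, known_params))
    for (u in undecl) {
      add("rule", sprintf("rule '%s' references undeclared symbol '%s'", rl$id, u))
    }
  }

  if (length(issues) == 0L) {
    data.frame(type = character(), message = character(), stringsAsFactors = FALSE)
  } else {
    data.frame(type = vapply(issues, `[[`, character(1), "type"),
               message = vapply(issues, `[[`, character(1), "message"),
               stringsAsFactors = FALSE)
  }
}
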