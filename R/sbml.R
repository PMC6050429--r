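#' Write a model as SBML
#'
#' Emits SBML Level 3 Version 1 with a single dimensionless compartment of
#' size 1. Every reaction carries an explicit mass-action kinetic law
#' (`kf * prod(reactants) - kr * prod(products)`, the two-term form for
#' reversible reactions) with its rate constants as local parameters;
#' global parameters and assignment/rate rules are preserved. Species tags
#' and the condition label are stored in SBML notes so a round trip is
#' faithful.
#'
#' @param model A validated `sig_model`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_sbml <- function(model, path) {
  stopifnot(inherits(model, "sig_model"))
  rep <- validate_model(model)
  if (nrow(rep) > 0L) stop("refusing to write an invalid model")
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    sprintf('<model id="%s" name="%s">', make_sbml_id(model$name), esc(model$name)),
    sprintf('<notes><body xmlns="http://www.w3.org/1999/xhtml"><p>condition: %s</p></body></notes>',
            esc(model$condition_label)),
    '<listOfCompartments>',
    '<compartment id="cell" size="1" constant="true"/>',
    '</listOfCompartments>',
    '<listOfSpecies>')
  for (sp in model$species) {
    notes <- if (length(sp$tags) > 0L) {
      sprintf('<notes><body xmlns="http://www.w3.org/1999/xhtml"><p>tags: %s</p></body></notes>',
              esc(paste(sp$tags, collapse = ";")))
    } else ""
    open_tag <- sprintf(
      '<species id="%s" name="%s" compartment="cell" initialConcentration="%.17g" boundaryCondition="%s" hasOnlySubstanceUnits="false" constant="false"',
      sp$id, esc(sp$name), sp$initial_concentration,
      if (sp$is_boundary) "true" else "false")
    out <- c(out, if (nzchar(notes)) {
      c(paste0(open_tag, ">"), notes, "</species>")
    } else paste0(open_tag, "/>"))
  }
  out <- c(out, '</listOfSpecies>')
  if (length(model$parameters) > 0L) {
    out <- c(out, '<listOfParameters>',
             sprintf('<parameter id="%s" value="%.17g" constant="false"/>',
                     names(model$parameters), unname(model$parameters)),
             '</listOfParameters>')
  }
  if (length(model$rules) > 0L) {
    out <- c(out, '<listOfRules>')
    for (rl in model$rules) {
      tag <- if (rl$kind == "assignment") "assignmentRule" else "rateRule"
      out <- c(out,
               sprintf('<%s variable="%s">', tag, rl$target),
               '<math xmlns="http://www.w3.org/1998/Math/MathML">',
               expr_to_mathml(str2lang(rl$expression)),
               '</math>',
               sprintf('</%s>', tag))
    }
    out <- c(out, '</listOfRules>')
  }
  out <- c(out, '<listOfReactions>')
  for (r in model$reactions) {
    out <- c(out, sprintf('<reaction id="%s" reversible="%s">', r$id,
                          if (r$reversible) "true" else "false"))
    side <- function(list_tag, stoich) {
      if (length(stoich) == 0L) return(character())
      c(sprintf('<%s>', list_tag),
        sprintf('<speciesReference species="%s" stoichiometry="%d" constant="true"/>',
                names(stoich), unname(stoich)),
        sprintf('</%s>', list_tag))
    }
    out <- c(out, side("listOfReactants", r$reactants),
             side("listOfProducts", r$products))
    term <- function(k_id, stoich) {
      cis <- c(sprintf('<ci> %s </ci>', k_id),
               unlist(mapply(function(s, n) rep(sprintf('<ci> %s </ci>', s), n),
                             names(stoich), stoich, SIMPLIFY = FALSE)))
      c('<apply>', '<times/>', cis, '</apply>')
    }
    fwd <- term(r$kf$id, r$reactants)
    math <- if (r$reversible) {
      c('<apply>', '<minus/>', fwd, term(r$kr$id, r$products), '</apply>')
    } else fwd
    locals <- c(sprintf('<localParameter id="%s" value="%.17g"/>',
                        r$kf$id, r$kf$value),
                if (r$reversible) sprintf('<localParameter id="%s" value="%.17g"/>',
                                          r$kr$id, r$kr$value))
    out <- c(out, '<kineticLaw>',
             '<math xmlns="http://www.w3.org/1998/Math/MathML">', math, '</math>',
             '<listOfLocalParameters>', locals, '</listOfLocalParameters>',
             '</kineticLaw>', '</reaction>')
  }
  out <- c(out, '</listOfReactions>', '</model>', '</sbml>')
  writeLines(out, path)
  invisible(path)
}

make_sbml_id <- function(x) {
  x <- gsub("[^A-Za-z0-9_]", "_", x)
  if (!grepl("^[A-Za-z_]", x)) x <- paste0("m_", x)
  x
}

# R expression -> MathML (plus, minus, times, divide, power, ci, cn)
expr_to_mathml <- function(e) {
  if (is.numeric(e)) return(sprintf('<cn> %.17g </cn>', e))
  if (is.name(e)) return(sprintf('<ci> %s </ci>', as.character(e)))
  if (is.call(e)) {
    op <- as.character(e[[1]])
    tag <- switch(op, "+" = "plus", "-" = "minus", "*" = "times",
                  "/" = "divide", "^" = "power", "(" = NA_character_,
                  stop("cannot express operator '", op, "' in MathML subset"))
    if (is.na(tag)) return(expr_to_mathml(e[[2]]))
    args <- lapply(as.list(e)[-1], expr_to_mathml)
    return(c('<apply>', sprintf('<%s/>', tag), unlist(args), '</apply>'))
  }
  stop("cannot express ", class(e)[1], " in MathML")
}

# MathML node -> R expression string
mathml_to_expr <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "math") {
    kids <- xml2::xml_children(node)
    if (length(kids) != 1L) stop("expected a single MathML root expression")
    return(mathml_to_expr(kids[[1]]))
  }
  if (nm == "ci") return(trimws(xml2::xml_text(node)))
  if (nm == "cn") {
    txt <- trimws(xml2::xml_text(node))
    if (!grepl("^[-+0-9.eE]+$", txt)) stop("unsupported <cn> content: ", txt)
    return(txt)
  }
  if (nm == "apply") {
    kids <- xml2::xml_children(node)
    op <- xml2::xml_name(kids[[1]])
    args <- vapply(kids[-1], mathml_to_expr, character(1))
    sym <- switch(op, plus = "+", minus = "-", times = "*", divide = "/",
                  power = "^", NA_character_)
    if (is.na(sym)) stop("unsupported MathML operator <", op, ">")
    if (op == "minus" && length(args) == 1L) return(paste0("(-", args, ")"))
    if (length(args) < 2L) stop("operator <", op, "> needs two operands")
    return(paste0("(", paste(args, collapse = sym), ")"))
  }
  stop("unsupported MathML element <", nm, ">")
}

#' Read a model from SBML
#'
#' Accepts SBML Level 2 or Level 3 documents with a single compartment.
#' Kinetic laws are parsed from their MathML and verified to be pure
#' mass-action: the law is evaluated numerically at random positive states
#' and must equal `kf * prod(reactants) - kr * prod(products)` for
#' constants `kf`, `kr` recovered by linear solve; any other rate law
#' (e.g. Michaelis-Menten) is rejected with a diagnostic naming the
#' reaction and the offending expression.
#'
#' @param path Path to an SBML file.
#' @return List with `model` (a `sig_model`) and `info` (level, version,
#'   model name, and counts of species/reactions/parameters/rules as
#'   declared in the document).
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)   # malformed XML errors here
  xml2::xml_ns_strip(doc)
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "sbml") stop("not an SBML document: ", path)
  level <- as.integer(xml2::xml_attr(root, "level"))
  version <- as.integer(xml2::xml_attr(root, "version"))
  if (!level %in% c(2L, 3L)) stop("unsupported SBML level: ", level)
  mnode <- xml2::xml_find_first(root, "./model")
  if (is.na(xml2::xml_name(mnode))) stop("no <model> element")
  mname <- xml2::xml_attr(mnode, "name")
  if (is.na(mname)) mname <- xml2::xml_attr(mnode, "id")
  condition <- "untreated"
  cond_note <- xml2::xml_find_first(mnode, "./notes//p[starts-with(text(), 'condition:')]")
  if (!is.na(xml2::xml_name(cond_note))) {
    condition <- trimws(sub("^condition:", "", xml2::xml_text(cond_note)))
  }

  sp_nodes <- xml2::xml_find_all(mnode, "./listOfSpecies/species")
  sp <- lapply(sp_nodes, function(n) {
    init <- xml2::xml_attr(n, "initialConcentration")
    if (is.na(init)) init <- xml2::xml_attr(n, "initialAmount")
    tags <- character()
    tn <- xml2::xml_find_first(n, "./notes//p[starts-with(text(), 'tags:')]")
    if (!is.na(xml2::xml_name(tn))) {
      tags <- trimws(strsplit(sub("^tags:", "", xml2::xml_text(tn)), ";")[[1]])
    }
    nm <- xml2::xml_attr(n, "name")
    species(xml2::xml_attr(n, "id"),
            name = if (is.na(nm)) xml2::xml_attr(n, "id") else nm,
            initial_concentration = if (is.na(init)) 0 else as.numeric(init),
            is_boundary = identical(xml2::xml_attr(n, "boundaryCondition"), "true"),
            tags = tags)
  })
  sids <- vapply(sp, `[[`, character(1), "id")

  par_nodes <- xml2::xml_find_all(mnode, "./listOfParameters/parameter")
  params <- stats::setNames(
    as.numeric(xml2::xml_attr(par_nodes, "value")),
    xml2::xml_attr(par_nodes, "id"))
  if (length(params) == 0L) params <- numeric()

  rule_nodes <- xml2::xml_find_all(
    mnode, "./listOfRules/assignmentRule | ./listOfRules/rateRule")
  rules <- lapply(seq_along(rule_nodes), function(i) {
    n <- rule_nodes[[i]]
    kind <- if (xml2::xml_name(n) == "assignmentRule") "assignment" else "rate"
    math <- xml2::xml_find_first(n, "./math")
    if (is.na(xml2::xml_name(math))) stop("rule without MathML")
    rule(sprintf("rule_%d", i), kind, xml2::xml_attr(n, "variable"),
         mathml_to_expr(math))
  })

  rx_nodes <- xml2::xml_find_all(mnode, "./listOfReactions/reaction")
  n_local_params <- 0L
  rxns <- lapply(rx_nodes, function(n) {
    rid <- xml2::xml_attr(n, "id")
    rev <- identical(xml2::xml_attr(n, "reversible"), "true")
    get_side <- function(xp) {
      refs <- xml2::xml_find_all(n, xp)
      if (length(refs) == 0L) return(stats::setNames(integer(0), character(0)))
      st <- xml2::xml_attr(refs, "stoichiometry")
      st[is.na(st)] <- "1"
      out <- stats::setNames(as.integer(round(as.numeric(st))),
                             xml2::xml_attr(refs, "species"))
      tapply_sum <- tapply(out, names(out), sum)
      stats::setNames(as.integer(tapply_sum), names(tapply_sum))
    }
    reactants <- get_side("./listOfReactants/speciesReference")
    products <- get_side("./listOfProducts/speciesReference")
    kl <- xml2::xml_find_first(n, "./kineticLaw")
    if (is.na(xml2::xml_name(kl))) {
      stop("reaction '", rid, "' has no kinetic law")
    }
    lp_nodes <- xml2::xml_find_all(
      kl, "./listOfLocalParameters/localParameter | ./listOfParameters/parameter")
    lp <- stats::setNames(as.numeric(xml2::xml_attr(lp_nodes, "value")),
                          xml2::xml_attr(lp_nodes, "id"))
    n_local_params <<- n_local_params + length(lp)
    math <- xml2::xml_find_first(kl, "./math")
    if (is.na(xml2::xml_name(math))) stop("reaction '", rid, "' kinetic law has no MathML")
    expr_str <- tryCatch(mathml_to_expr(math), error = function(e) {
      stop("reaction '", rid, "': unsupported rate law (", conditionMessage(e), ")")
    })
    ma <- recover_mass_action(expr_str, reactants, products, rev,
                              sids, c(params, lp), rid, local_ids = names(lp))
    reaction(rid, reactants, products,
             kf = rate_constant(ma$kf_id, ma$kf, sum(reactants)),
             kr = if (rev) rate_constant(ma$kr_id, ma$kr, sum(products)) else NULL,
             reversible = rev)
  })

  model <- sig_model(if (is.na(mname)) "sbml_model" else mname, sp, rxns,
                     rules = rules, parameters = params,
                     condition_label = condition)
  cnt <- model_counts(model)
  info <- list(level = level, version = version, model_name = mname,
               n_species = unname(cnt["species"]),
               n_reactions = unname(cnt["reactions"]),
               n_parameters = unname(cnt["parameters"]),
               n_rules = unname(cnt["rules"]))
  list(model = model, info = info)
}

# Verify a kinetic-law expression is mass action and recover kf/kr.
# The law is evaluated at random positive states; flux must satisfy
# flux = kf * prod(reactants^stoich) - kr * prod(products^stoich) with
# constant non-negative kf, kr (kr = 0 if irreversible).
recover_mass_action <- function(expr_str, reactants, products, reversible,
                                sids, consts, rid, local_ids = names(consts)) {
  expr <- tryCatch(str2lang(expr_str), error = function(e) {
    stop("reaction '", rid, "': unparsable rate expression: ", expr_str)
  })
  syms <- all.vars(expr)
  unknown <- setdiff(syms, c(sids, names(consts)))
  if (length(unknown) > 0L) {
    stop("reaction '", rid, "': rate law references unknown symbol(s) ",
         paste(unknown, collapse = ", "), " in: ", expr_str)
  }
  n_probe <- 12L
  set <- function(i) {
    # deterministic probe states, positive and spread over scales
    vals <- 0.1 + ((seq_along(sids) * 7 + i * 13) %% 29) / 7
    env <- list2env(as.list(c(stats::setNames(vals, sids), consts)))
    env
  }
  A <- B <- flux <- numeric(n_probe)
  for (i in seq_len(n_probe)) {
    env <- set(i)
    flux[i] <- tryCatch(eval(expr, env), error = function(e) {
      stop("reaction '", rid, "': cannot evaluate rate law: ", expr_str)
    })
    state <- mget(sids, envir = env)
    A[i] <- prod(vapply(names(reactants), function(s) {
      state[[s]]^reactants[[s]]
    }, numeric(1)))
    B[i] <- if (length(products) > 0L) {
      prod(vapply(names(products), function(s) state[[s]]^products[[s]],
                  numeric(1)))
    } else 0
  }
  X <- if (reversible) cbind(A, -B) else cbind(A)
  coef <- tryCatch(qr.solve(X, flux), error = function(e) {
    stop("reaction '", rid, "': rate law is not mass action: ", expr_str)
  })
  resid <- flux - X %*% coef
  scale <- max(abs(flux), 1e-12)
  if (max(abs(resid)) > 1e-8 * scale || any(coef < -1e-12)) {
    stop("reaction '", rid, "': rate law is not pure mass action: ", expr_str)
  }
  kf <- max(coef[1], 0)
  kr <- if (reversible) max(coef[2], 0) else 0
  # keep original local-parameter ids when they match the recovered values
  match_id <- function(value, fallback, exclude = character()) {
    lc <- consts[names(consts) %in% setdiff(local_ids, exclude)]
    hit <- names(lc)[abs(lc - value) <= 1e-9 * max(abs(value), 1)]
    if (length(hit) > 0L) hit[1] else fallback
  }
  kf_id <- match_id(kf, paste0("kf_", rid))
  list(kf = kf, kr = kr, kf_id = kf_id,
       kr_id = if (reversible) {
         match_id(kr, paste0("kr_", rid), exclude = kf_id)
       } else NULL)
}
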