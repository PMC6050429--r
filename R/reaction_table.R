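#' Parse a reaction-table TSV
#'
#' The documented dialect has a header line and the tab-separated columns
#' `reaction_id`, `reactants`, `products`, `reversible`, `kf`, `kr`,
#' `notes`. Species tokens are case-sensitive identifiers separated by
#' `" + "`; a stoichiometric coefficient is written as a leading integer
#' separated by a space (`"2 EGFR_EGF"`). The `reversible` column accepts
#' `1`/`0`, `true`/`false`, `yes`/`no` or a literal arrow (`<->` or the
#' unicode equilibrium arrow); `kr` must be non-empty exactly for reversible
#' rows. An empty `products` field denotes a degradation step.
#'
#' @param path Path to the TSV file.
#' @return A list of row records (class `reaction_table`), each with fields
#'   `reaction_id`, `reactants` / `products` (named integer stoichiometry),
#'   `reversible`, `kf`, `kr` (`NA` if irreversible), `notes`, `line`.
#'   Malformed rows abort with an error listing every offending line number.
#' @export
parse_reaction_table <- function(path) {
  if (!file.exists(path)) stop("reaction table not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*#", lines)]
  if (length(lines) == 0L || all(!nzchar(trimws(lines)))) {
    warning("empty reaction table: ", path)
    return(structure(list(), class = "reaction_table"))
  }
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  required <- c("reaction_id", "reactants", "products", "reversible", "kf", "kr")
  if (!all(required %in% header)) {
    stop("reaction table header is missing column(s): ",
         paste(setdiff(required, header), collapse = ", "))
  }
  body <- lines[-1]
  body_ln <- which(nzchar(trimws(body))) # 1-based within body
  rows <- list()
  errors <- character()
  for (i in body_ln) {
    ln <- i + 1L  # file line number
    fields <- strsplit(body[[i]], "\t", fixed = TRUE)[[1]]
    length(fields) <- length(header)
    fields[is.na(fields)] <- ""
    rec <- stats::setNames(as.list(fields), header)
    rev <- parse_reversible(rec$reversible)
    if (is.na(rev)) {
      errors <- c(errors, sprintf("line %d: unrecognized reversible flag '%s'",
                                  ln, rec$reversible))
      next
    }
    kf <- suppressWarnings(as.numeric(rec$kf))
    if (is.na(kf) || kf < 0) {
      errors <- c(errors, sprintf("line %d: non-numeric or negative kf '%s'",
                                  ln, rec$kf))
      next
    }
    kr <- NA_real_
    if (rev) {
      kr <- suppressWarnings(as.numeric(rec$kr))
      if (is.na(kr) || kr < 0) {
        errors <- c(errors, sprintf(
          "line %d: reversible row needs a non-negative kr, got '%s'", ln, rec$kr))
        next
      }
    } else if (nzchar(trimws(rec$kr))) {
      errors <- c(errors, sprintf("line %d: kr given for an irreversible row", ln))
      next
    }
    reactants <- try(parse_side(rec$reactants), silent = TRUE)
    products <- try(parse_side(rec$products), silent = TRUE)
    if (inherits(reactants, "try-error") || inherits(products, "try-error")) {
      errors <- c(errors, sprintf("line %d: unparsable species tokens", ln))
      next
    }
    if (length(reactants) == 0L) {
      errors <- c(errors, sprintf("line %d: empty reactant side", ln))
      next
    }
    rows[[length(rows) + 1L]] <- list(
      reaction_id = rec$reaction_id, reactants = reactants,
      products = products, reversible = rev, kf = kf, kr = kr,
      notes = if (is.null(rec$notes)) "" else rec$notes, line = ln)
  }
  if (length(errors) > 0L) {
    stop("malformed reaction table rows:\n  ", paste(errors, collapse = "\n  "))
  }
  structure(rows, class = "reaction_table")
}

parse_reversible <- function(x) {
  x <- trimws(x)
  if (x %in% c("1", "true", "TRUE", "yes", "<->", "<=>", "⇄", "⇌")) return(TRUE)
  if (x %in% c("0", "false", "FALSE", "no", "->", "")) return(FALSE)
  NA
}

parse_side <- function(x) {
  x <- trimws(x)
  if (!nzchar(x)) return(stats::setNames(integer(0), character(0)))
  tokens <- trimws(strsplit(x, "+", fixed = TRUE)[[1]])
  out <- integer(0)
  for (tok in tokens) {
    m <- regmatches(tok, regexec("^([0-9]+)\\s+(.+)$", tok))[[1]]
    if (length(m) == 3L) {
      coef <- as.integer(m[2]); sp <- m[3]
    } else {
      coef <- 1L; sp <- tok
    }
    if (!grepl("^[A-Za-z][A-Za-z0-9_]*$", sp)) stop("bad species token: ", tok)
    if (sp %in% names(out)) out[[sp]] <- out[[sp]] + coef else out[[sp]] <- coef
  }
  out
}

#' Condition specification
#'
#' Names a condition and the ligand inputs that define it, e.g. a nonzero
#' tamoxifen dose for the treated condition and zero for the untreated one.
#'
#' @param condition_label `"untreated"`, `"treated"`, or another label.
#' @param ligand_settings Named numeric vector: species id -> initial (or
#'   clamped) concentration, uM.
#' @return An object of class `condition_spec`.
#' @export
condition_spec <- function(condition_label, ligand_settings = numeric()) {
  stopifnot(is.character(condition_label), length(condition_label) == 1L)
  if (length(ligand_settings) > 0L && is.null(names(ligand_settings))) {
    stop("ligand_settings must be named (species id -> concentration)")
  }
  structure(list(condition_label = condition_label,
                 ligand_settings = ligand_settings),
            class = "condition_spec")
}

#' Assemble a model from parsed reaction-table rows
#'
#' The species set is the union of all tokens in order of first appearance.
#' Initial concentrations, boundary flags and tags come from the optional
#' species table; the condition's ligand settings override initial
#' concentrations last. Each species id listed in `clamp` is held constant
#' by an assignment rule `X = X_dose` backed by a global parameter `X_dose`
#' (initialized from the post-condition initial concentration), so a
#' clamped input contributes one rule and one parameter to the model.
#'
#' @param rows A `reaction_table` from [parse_reaction_table()].
#' @param condition A [condition_spec()].
#' @param species_table Optional data frame with columns `id`,
#'   `initial_concentration`, `is_boundary` (0/1), `tags`
#'   (semicolon-separated, may be empty). Species absent from it default to
#'   initial 0, non-boundary, no tags.
#' @param clamp Character vector of species ids to clamp by rule.
#' @param name Model name.
#' @return A validated `sig_model`.
#' @export
assemble_model <- function(rows, condition, species_table = NULL,
                           clamp = character(), name = "assembled") {
  stopifnot(inherits(rows, "reaction_table"), inherits(condition, "condition_spec"))
  rids <- vapply(rows, `[[`, character(1), "reaction_id")
  dup <- unique(rids[duplicated(rids)])
  if (length(dup) > 0L) {
    stop("duplicate reaction ids: ", paste(dup, collapse = ", "))
  }
  tokens <- unlist(lapply(rows, function(r) c(names(r$reactants), names(r$products))))
  sids <- unique(tokens)

  info <- list()
  if (!is.null(species_table)) {
    st <- as.data.frame(species_table)
    req <- c("id", "initial_concentration", "is_boundary")
    if (!all(req %in% names(st))) {
      stop("species_table must have columns: ", paste(req, collapse = ", "))
    }
    extra <- setdiff(st$id, sids)
    sids <- c(sids, extra)  # species declared but not in any reaction (rare)
    for (i in seq_len(nrow(st))) info[[st$id[i]]] <- st[i, , drop = FALSE]
  }

  lig <- condition$ligand_settings
  unknown <- setdiff(names(lig), sids)
  if (length(unknown) > 0L) {
    stop("condition references undeclared species: ", paste(unknown, collapse = ", "))
  }
  unknown <- setdiff(clamp, sids)
  if (length(unknown) > 0L) {
    stop("clamp references undeclared species: ", paste(unknown, collapse = ", "))
  }

  sp <- lapply(sids, function(s) {
    init <- 0; boundary <- FALSE; tags <- character()
    if (s %in% names(info)) {
      row <- info[[s]]
      init <- as.numeric(row$initial_concentration)
      boundary <- as.logical(as.integer(row$is_boundary))
      if ("tags" %in% names(row) && !is.na(row$tags) && nzchar(row$tags)) {
        tags <- trimws(strsplit(row$tags, ";", fixed = TRUE)[[1]])
      }
    }
    if (s %in% names(lig)) init <- as.numeric(lig[[s]])
    if (s %in% clamp) boundary <- TRUE
    species(s, initial_concentration = init, is_boundary = boundary, tags = tags)
  })

  rxns <- lapply(rows, function(r) {
    kf <- rate_constant(paste0("kf_", r$reaction_id), r$kf, sum(r$reactants))
    kr <- if (r$reversible) {
      rate_constant(paste0("kr_", r$reaction_id), r$kr, sum(r$products))
    } else NULL
    reaction(r$reaction_id, r$reactants, r$products, kf = kf, kr = kr,
             reversible = r$reversible)
  })

  params <- numeric()
  rules <- list()
  init_by_id <- stats::setNames(
    vapply(sp, `[[`, numeric(1), "initial_concentration"),
    vapply(sp, `[[`, character(1), "id"))
  for (s in clamp) {
    pname <- paste0(s, "_dose")
    params[[pname]] <- init_by_id[[s]]
    rules[[length(rules) + 1L]] <- rule(paste0("clamp_", s), "assignment", s, pname)
  }

  sig_model(name, sp, rxns, rules = rules, parameters = params,
            condition_label = condition$condition_label)
}

#' Read a species table TSV
#'
#' Companion file of the reaction-table dialect: tab-separated columns
#' `id`, `initial_concentration`, `is_boundary`, `tags`.
#'
#' @param path Path to the TSV.
#' @return Data frame suitable for the `species_table` argument of
#'   [assemble_model()].
#' @export
read_species_table <- function(path) {
  st <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          comment.char = "#")
  req <- c("id", "initial_concentration", "is_boundary")
  if (!all(req %in% names(st))) {
    stop("species table is missing column(s): ",
         paste(setdiff(req, names(st)), collapse = ", "))
  }
  if (!"tags" %in% names(st)) st$tags <- ""
  st$tags[is.na(st$tags)] <- ""
  st
}
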