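#' Net mass-action flux of one reaction
#'
#' Evaluates `kf * prod([reactants]^stoich) - kr * prod([products]^stoich)`
#' (the reverse term only for reversible reactions). Stoichiometric
#' coefficients above 1 raise the concentration to that power.
#'
#' @param reaction A [reaction()].
#' @param state Named numeric vector of concentrations (uM) containing every
#'   species the reaction references.
#' @return Net flux in uM/s (positive in the forward direction).
#' @export
mass_action_flux <- function(reaction, state) {
  stopifnot(inherits(reaction, "sig_reaction"))
  refs <- c(names(reaction$reactants), names(reaction$products))
  missing <- setdiff(refs, names(state))
  if (length(missing) > 0L) {
    stop("state is missing species: ", paste(missing, collapse = ", "))
  }
  if (any(state[refs] < 0)) stop("negative concentration in state")
  fwd <- reaction$kf$value * prod(state[names(reaction$reactants)]^reaction$reactants)
  rev <- if (reaction$reversible) {
    reaction$kr$value * prod(state[names(reaction$products)]^reaction$products)
  } else 0
  unname(fwd - rev)
}

#' Stoichiometry matrix of a model
#'
#' @param model A `sig_model`.
#' @return Integer matrix `N` with one row per species (model order) and one
#'   column per reaction; `N[i, j]` is the net (product minus reactant)
#'   stoichiometry of species `i` in reaction `j`. Row and column names carry
#'   the species and reaction ids.
#' @export
stoichiometry_matrix <- function(model) {
  stopifnot(inherits(model, "sig_model"))
  sids <- species_ids(model)
  N <- matrix(0L, nrow = length(sids), ncol = length(model$reactions),
              dimnames = list(sids, reaction_ids(model)))
  for (j in seq_along(model$reactions)) {
    r <- model$reactions[[j]]
    for (s in names(r$reactants)) N[s, j] <- N[s, j] - r$reactants[[s]]
    for (s in names(r$products)) N[s, j] <- N[s, j] + r$products[[s]]
  }
  N
}

# Precompute index vectors so the RHS avoids per-reaction list traversal.
# Reactant/product slots hold species indices (0 = unused); a stoichiometric
# coefficient of 2 occupies both slots of its side.
compile_model <- function(model) {
  sids <- species_ids(model)
  idx <- stats::setNames(seq_along(sids), sids)
  nr <- length(model$reactions)
  r1 <- r2 <- p1 <- p2 <- integer(nr)
  kf <- kr <- numeric(nr)
  rev <- logical(nr)
  for (j in seq_len(nr)) {
    r <- model$reactions[[j]]
    ri <- rep(idx[names(r$reactants)], r$reactants)
    r1[j] <- ri[1]; r2[j] <- if (length(ri) > 1) ri[2] else 0L
    kf[j] <- r$kf$value
    rev[j] <- r$reversible
    if (r$reversible) {
      pi_ <- rep(idx[names(r$products)], r$products)
      p1[j] <- pi_[1]; p2[j] <- if (length(pi_) > 1) pi_[2] else 0L
      kr[j] <- r$kr$value
    }
  }
  boundary <- vapply(model$species, `[[`, logical(1), "is_boundary")
  assign_targets <- vapply(model$rules, function(rl) {
    if (rl$kind == "assignment") rl$target else NA_character_
  }, character(1))
  boundary <- boundary | sids %in% assign_targets
  rules <- lapply(model$rules, function(rl) {
    list(kind = rl$kind, target = rl$target, expr = str2lang(rl$expression),
         target_idx = if (rl$target %in% sids) idx[[rl$target]] else NA_integer_)
  })
  list(N = stoichiometry_matrix(model), r1 = r1, r2 = r2, p1 = p1, p2 = p2,
       kf = kf, kr = kr, rev = rev, boundary = boundary, idx = idx,
       rules = rules, params = as.list(model$parameters), sids = sids)
}

rhs_compiled <- function(cm, state, time = 0) {
  x <- state
  if (length(cm$rules) > 0L) {
    env <- list2env(cm$params)
    for (i in seq_along(x)) assign(cm$sids[[i]], x[[i]], envir = env)
    for (rl in cm$rules) {
      if (rl$kind == "assignment" && !is.na(rl$target_idx)) {
        x[rl$target_idx] <- eval(rl$expr, env)
        assign(cm$sids[[rl$target_idx]], x[rl$target_idx], envir = env)
      }
    }
  }
  v <- cm$kf * x[cm$r1] * ifelse(cm$r2 > 0L, x[pmax(cm$r2, 1L)], 1)
  if (any(cm$rev)) {
    vr <- cm$kr * ifelse(cm$p1 > 0L, x[pmax(cm$p1, 1L)], 1) *
      ifelse(cm$p2 > 0L, x[pmax(cm$p2, 1L)], 1)
    v <- v - ifelse(cm$rev, vr, 0)
  }
  dx <- as.numeric(cm$N %*% v)
  dx[cm$boundary] <- 0
  if (length(cm$rules) > 0L) {
    env <- list2env(cm$params)
    for (i in seq_along(x)) assign(cm$sids[[i]], x[[i]], envir = env)
    for (rl in cm$rules) {
      if (rl$kind == "rate" && !is.na(rl$target_idx)) {
        dx[rl$target_idx] <- dx[rl$target_idx] + eval(rl$expr, env)
      }
    }
  }
  names(dx) <- cm$sids
  dx
}

#' Right-hand side of the model ODE system
#'
#' Computes `N %*% v(state)` where `v` is the vector of net mass-action
#' fluxes, with assignment rules applied to the state beforehand, rate rules
#' added afterwards, and boundary (clamped) species held at derivative zero.
#'
#' @param model A `sig_model`.
#' @param state Named numeric vector in species order (uM).
#' @param time Time in seconds (unused by autonomous mass-action systems but
#'   part of the ODE contract).
#' @return Named numeric derivative vector, uM/s.
#' @export
ode_rhs <- function(model, state, time = 0) {
  stopifnot(inherits(model, "sig_model"))
  if (length(state) != length(model$species)) {
    stop("state length ", length(state), " does not match species count ",
         length(model$species))
  }
  if (any(!is.finite(state))) stop("non-finite concentration in state")
  rhs_compiled(compile_model(model), as.numeric(state), time)
}

#' Conserved moieties of a model
#'
#' Finds an integer basis of the left null space of the stoichiometry matrix
#' restricted to non-boundary species: vectors `c >= 0 | c in Z` with
#' `t(c) %*% N == 0`, i.e. weighted species totals invariant under every
#' reaction (e.g. total receptor across free, phosphorylated and
#' internalized forms). The computation is exact over the rationals
#' (fraction-free Gaussian elimination on integers), avoiding floating-point
#' rank decisions.
#'
#' @param model A `sig_model`.
#' @return List of named integer vectors (one per conservation relation),
#'   each of length equal to the number of non-boundary species, names being
#'   species ids. Empty list if the network has full row rank.
#' @export
conserved_moieties <- function(model) {
  stopifnot(inherits(model, "sig_model"))
  N <- stoichiometry_matrix(model)
  boundary <- vapply(model$species, `[[`, logical(1), "is_boundary")
  assign_targets <- vapply(model$rules, function(rl) {
    if (rl$kind == "assignment") rl$target else NA_character_
  }, character(1))
  boundary <- boundary | rownames(N) %in% assign_targets
  Nf <- N[!boundary, , drop = FALSE]
  if (nrow(Nf) == 0L) return(list())
  basis <- integer_left_null_basis(Nf)
  lapply(basis, function(v) stats::setNames(v, rownames(Nf)))
}

# Integer basis of {c : t(c) %*% A == 0} via exact fraction-free
# (Bareiss-style) elimination on t(A). All arithmetic stays on integers
# (doubles are exact well past the magnitudes reachable here).
integer_left_null_basis <- function(A) {
  M <- t(A)                      # solve M c = 0, M is reactions x species
  M <- matrix(as.numeric(M), nrow = nrow(M))
  n <- ncol(M)
  # exact rational RREF via numerator matrix + common row denominators
  den <- rep(1, nrow(M))
  pivots <- integer(0)
  prow <- 0L
  for (col in seq_len(n)) {
    if (prow >= nrow(M)) break
    pr <- 0L
    for (i in (prow + 1L):nrow(M)) {
      if (M[i, col] != 0) { pr <- i; break }
    }
    if (pr == 0L) next
    if (pr != prow + 1L) {
      M[c(prow + 1L, pr), ] <- M[c(pr, prow + 1L), ]
      den[c(prow + 1L, pr)] <- den[c(pr, prow + 1L)]
    }
    prow <- prow + 1L
    piv <- M[prow, col]
    for (i in seq_len(nrow(M))) {
      if (i == prow || M[i, col] == 0) next
      # row_i <- row_i - (M[i,col]/piv) * row_prow, kept integral
      M[i, ] <- M[i, ] * piv - M[prow, ] * M[i, col]
      den[i] <- den[i] * piv
      g <- gcd_vec(c(M[i, ], den[i]))
      if (g > 1) { M[i, ] <- M[i, ] / g; den[i] <- den[i] / g }
    }
    pivots <- c(pivots, col)
  }
  free <- setdiff(seq_len(n), pivots)
  basis <- list()
  for (f in free) {
    v_num <- numeric(n); v_den <- rep(1, n)
    v_num[f] <- 1
    for (k in seq_along(pivots)) {
      col <- pivots[k]
      # row k has pivot at col: M[k,col]*c[col] + M[k,f]*c[f] = 0
      if (M[k, f] != 0) {
        v_num[col] <- -M[k, f]
        v_den[col] <- M[k, col]
      }
    }
    l <- lcm_vec(v_den)
    v <- v_num * (l / v_den)
    g <- gcd_vec(v)
    if (g > 1) v <- v / g
    if (sum(v) < 0) v <- -v
    basis[[length(basis) + 1L]] <- as.integer(round(v))
  }
  basis
}

gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- b; b <- a %% b; a <- t }
  a
}
gcd_vec <- function(x) {
  x <- abs(x[x != 0])
  if (length(x) == 0L) return(1)
  Reduce(gcd2, x)
}
lcm_vec <- function(x) {
  x <- abs(x[x != 0])
  if (length(x) == 0L) return(1)
  Reduce(function(a, b) a / gcd2(a, b) * b, x)
}
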