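#' Local normalized sensitivity of an observable
#'
#' Central finite-difference estimate of the normalized (relative)
#' sensitivity time series
#' `S(t) = (dy/dp) * (p / y(t))`,
#' where `p` is either a species initial/clamped concentration (perturb mode
#' `"initial"`, used e.g. for the tamoxifen input) or a rate constant
#' (`"parameter"`). The quantity is perturbed to `(1 - delta_rel) * p` and
#' `(1 + delta_rel) * p`, the model re-integrated, and the difference
#' quotient normalized by the baseline trajectory. Baseline values below
#' `y_floor` are masked to avoid division blow-ups.
#'
#' @param model A `sig_model`.
#' @param obs A [observable()].
#' @param perturb Id of the perturbed quantity (species id, rate-constant
#'   id, or global parameter name).
#' @param delta_rel Relative perturbation step (default 0.01 = 1%).
#' @param t_end,n_points,rtol,atol Integration settings, see
#'   [integrate_model()].
#' @param y_floor Baseline floor below which S is set to 0 (default `atol`).
#' @return A `sig_sensitivity`: the time grid, the coefficient series `S`,
#'   and scalar summaries `max_abs` and `mean_abs` (time-averaged |S|).
#' @export
local_sensitivity <- function(model, obs, perturb, delta_rel = 0.01,
                              t_end = 3600, n_points = 600,
                              rtol = 1e-6, atol = 1e-9, y_floor = atol) {
  stopifnot(inherits(model, "sig_model"), inherits(obs, "sig_observable"),
            delta_rel > 0, delta_rel < 1)
  p0 <- get_quantity(model, perturb)
  if (p0 == 0) {
    stop("cannot take a relative perturbation of '", perturb, "': value is 0")
  }
  base <- integrate_model(model, t_end, n_points, rtol, atol)
  y0 <- observable_timecourse(base, obs)
  if (all(y0 <= y_floor)) {
    stop("observable '", obs$name, "' never exceeds the floor; sensitivity undefined")
  }
  y_lo <- observable_timecourse(
    integrate_model(set_quantity(model, perturb, p0 * (1 - delta_rel)),
                    t_end, n_points, rtol, atol), obs)
  y_hi <- observable_timecourse(
    integrate_model(set_quantity(model, perturb, p0 * (1 + delta_rel)),
                    t_end, n_points, rtol, atol), obs)
  dy_dp <- (y_hi - y_lo) / (2 * delta_rel * p0)
  S <- ifelse(y0 > y_floor, dy_dp * p0 / y0, 0)
  structure(
    list(observable = obs$name, perturbed = perturb, delta_rel = delta_rel,
         times = base$times, S = S,
         max_abs = max(abs(S)), mean_abs = mean(abs(S))),
    class = "sig_sensitivity"
  )
}

#' @export
print.sig_sensitivity <- function(x, ...) {
  cat(sprintf("<sig_sensitivity> %s w.r.t. %s: max|S| = %.4g, mean|S| = %.4g\n",
              x$observable, x$perturbed, x$max_abs, x$mean_abs))
  invisible(x)
}

# read / replace a perturbable quantity (species initial concentration,
# rate constant, or global parameter) by id
get_quantity <- function(model, id) {
  sid <- species_ids(model)
  if (id %in% sid) {
    return(model$species[[match(id, sid)]]$initial_concentration)
  }
  if (id %in% names(model$parameters)) return(model$parameters[[id]])
  for (r in model$reactions) {
    if (r$kf$id == id) return(r$kf$value)
    if (!is.null(r$kr) && r$kr$id == id) return(r$kr$value)
  }
  stop("no species, parameter or rate constant with id '", id, "'")
}

set_quantity <- function(model, id, value) {
  sid <- species_ids(model)
  if (id %in% sid) {
    i <- match(id, sid)
    model$species[[i]]$initial_concentration <- value
    return(model)
  }
  if (id %in% names(model$parameters)) {
    model$parameters[[id]] <- value
    return(model)
  }
  for (j in seq_along(model$reactions)) {
    r <- model$reactions[[j]]
    if (r$kf$id == id) { model$reactions[[j]]$kf$value <- value; return(model) }
    if (!is.null(r$kr) && r$kr$id == id) {
      model$reactions[[j]]$kr$value <- value; return(model)
    }
  }
  stop("no species, parameter or rate constant with id '", id, "'")
}

#' Rank observables by sensitivity to one input
#'
#' Computes [local_sensitivity()] for each observable with respect to the
#' same perturbed quantity (typically the tamoxifen input) and orders them
#' descending by `max_abs`; ties are broken by `mean_abs`, then
#' alphabetically by name. If every summary is zero the ranking degenerates
#' to name order and a warning is raised.
#'
#' @param model A `sig_model`.
#' @param observables List of [observable()]s.
#' @param perturb Id of the perturbed quantity.
#' @param zero_tol Summaries at or below this value are treated as zero (a
#'   floor absorbing integrator noise; default 1e-6).
#' @param ... Passed to [local_sensitivity()].
#' @return A data frame with columns `observable`, `max_abs_S`,
#'   `mean_abs_S`, `rank` (1 = most sensitive), ordered by rank.
#' @export
rank_sensitivities <- function(model, observables, perturb, zero_tol = 1e-6,
                               ...) {
  stopifnot(length(observables) >= 1L)
  res <- lapply(observables, function(o) local_sensitivity(model, o, perturb, ...))
  df <- data.frame(
    observable = vapply(res, `[[`, character(1), "observable"),
    max_abs_S = vapply(res, `[[`, numeric(1), "max_abs"),
    mean_abs_S = vapply(res, `[[`, numeric(1), "mean_abs"),
    stringsAsFactors = FALSE
  )
  df$max_abs_S[df$max_abs_S <= zero_tol] <- 0
  df$mean_abs_S[df$max_abs_S == 0] <- 0
  if (all(df$max_abs_S == 0)) {
    warning("degenerate ranking: all sensitivity summaries are zero")
  }
  ord <- order(-df$max_abs_S, -df$mean_abs_S, df$observable)
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}
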