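#' Integrate a model through time
#'
#' Solves the mass-action ODE system on a uniform time grid with a
#' stiff-capable solver (`deSolve::lsoda`, which switches automatically
#' between stiff BDF and non-stiff Adams methods). Failure is reported with
#' the last successful time, never silently.
#'
#' @param model A `sig_model`.
#' @param t_end Final time, seconds (> 0).
#' @param n_points Number of output points on the uniform grid (including
#'   t = 0).
#' @param rtol,atol Relative and absolute (uM) integrator tolerances.
#' @return A `sig_trajectory`: list with `times` (seconds),
#'   `concentrations` (matrix, time x species, uM), `model`, and
#'   `diagnostics` (success flag, solver steps, tolerances, clip count).
#'   Concentrations more negative than `-atol` abort; values in
#'   `[-atol, 0)` are clipped to 0 and counted.
#' @export
integrate_model <- function(model, t_end = 3600, n_points = 600,
                            rtol = 1e-6, atol = 1e-9) {
  stopifnot(inherits(model, "sig_model"), t_end > 0, n_points >= 2)
  cm <- compile_model(model)
  y0 <- initial_state(model)
  # clamped species start at their rule-assigned value so output row 1 is
  # consistent with the dynamics
  if (length(cm$rules) > 0L) {
    d0 <- rhs_compiled(cm, y0)   # applies assignment rules internally
    env <- list2env(cm$params)
    for (i in seq_along(y0)) assign(cm$sids[[i]], y0[[i]], envir = env)
    for (rl in cm$rules) {
      if (rl$kind == "assignment" && !is.na(rl$target_idx)) {
        y0[rl$target_idx] <- eval(rl$expr, env)
      }
    }
  }
  times <- seq(0, t_end, length.out = n_points)
  fun <- function(t, y, p) list(rhs_compiled(cm, y, t))
  out <- try(deSolve::lsoda(y = y0, times = times, func = fun, parms = NULL,
                            rtol = rtol, atol = atol), silent = TRUE)
  if (inherits(out, "try-error")) {
    stop("integration failed: ", attr(out, "condition")$message)
  }
  diag_ <- attributes(out)
  conc <- unname(as.matrix(out[, -1, drop = FALSE]))
  colnames(conc) <- cm$sids
  success <- nrow(conc) == n_points && all(is.finite(conc))
  if (!success) {
    last_t <- out[nrow(out), 1]
    stop(sprintf("integration failed at t = %.6g s (of %.6g s requested)",
                 last_t, t_end))
  }
  if (any(conc < -atol)) {
    stop(sprintf("integration produced concentrations below -atol (min %.3g uM)",
                 min(conc)))
  }
  n_clip <- sum(conc < 0)
  conc[conc < 0] <- 0
  structure(
    list(times = times, concentrations = conc, model = model,
         diagnostics = list(success = TRUE,
                            steps = unname(diag_$istate[3]),
                            rtol = rtol, atol = atol, n_clipped = n_clip)),
    class = "sig_trajectory"
  )
}

#' @export
print.sig_trajectory <- function(x, ...) {
  cat(sprintf("<sig_trajectory> %s: %d points over [0, %g] s, %d species\n",
              x$model$name, length(x$times), max(x$times),
              ncol(x$concentrations)))
  invisible(x)
}

#' Define an observable
#'
#' An observable is a named sum of species concentrations, e.g. ppERK as the
#' total of all doubly-phosphorylated-ERK-containing pools.
#'
#' @param name Observable name.
#' @param members Character vector of member species ids.
#' @return An object of class `sig_observable`.
#' @export
observable <- function(name, members) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(members), length(members) >= 1L)
  structure(list(name = name, members = members), class = "sig_observable")
}

#' Build an observable from species tags
#'
#' Collects every species tagged `"observable:<name>"` in the model.
#'
#' @param model A `sig_model`.
#' @param name Observable name (the part after the colon in the tag).
#' @return A [observable()] over the tagged species.
#' @export
observable_from_tags <- function(model, name) {
  tag <- paste0("observable:", name)
  members <- species_ids(model)[vapply(model$species, function(s) tag %in% s$tags,
                                       logical(1))]
  if (length(members) == 0L) stop("no species tagged '", tag, "' in model")
  observable(name, members)
}

#' Time course of an observable
#'
#' @param traj A `sig_trajectory`.
#' @param obs A [observable()].
#' @return Numeric vector: the pointwise sum of member species
#'   concentrations along the trajectory (uM).
#' @export
observable_timecourse <- function(traj, obs) {
  stopifnot(inherits(traj, "sig_trajectory"), inherits(obs, "sig_observable"))
  missing <- setdiff(obs$members, colnames(traj$concentrations))
  if (length(missing) > 0L) {
    stop("observable '", obs$name, "' members not in model: ",
         paste(missing, collapse = ", "))
  }
  rowSums(traj$concentrations[, obs$members, drop = FALSE])
}

#' Trapezoidal area under a curve
#'
#' @param times Strictly increasing time grid, s.
#' @param values Numeric values on the grid.
#' @return Trapezoid-rule integral (uM * s for a concentration observable).
#' @export
trapezoid_auc <- function(times, values) {
  stopifnot(length(times) == length(values), length(times) >= 2)
  sum(diff(times) * (utils::head(values, -1) + utils::tail(values, -1)) / 2)
}

summary_metrics <- function(times, y) {
  ipk <- which.max(y)
  list(peak = y[ipk], time_to_peak = times[ipk],
       auc = trapezoid_auc(times, y), terminal = y[length(y)])
}

#' Compare an observable between two conditions
#'
#' Integrates both models, extracts the observable, and summarizes each
#' condition by peak value, time to peak, area under the curve and terminal
#' value, plus treated/untreated ratios. The verdict flag
#' `treated_exceeds_untreated` is `TRUE` iff both the peak and the AUC are
#' strictly larger under treatment.
#'
#' @param model_untreated,model_treated Two `sig_model`s sharing the same
#'   species ordering (typically the same network under different ligand
#'   inputs).
#' @param obs A [observable()] defined on both models.
#' @param t_end Horizon, s.
#' @param n_points Grid size.
#' @param rtol,atol Integrator tolerances.
#' @return A `sig_comparison`: per-condition metric lists, `ratios`
#'   (treated / untreated; `NA` where the untreated metric is 0), the
#'   verdict flag, and both observable time courses.
#' @export
compare_conditions <- function(model_untreated, model_treated, obs,
                               t_end = 3600, n_points = 600,
                               rtol = 1e-6, atol = 1e-9) {
  if (!identical(species_ids(model_untreated), species_ids(model_treated))) {
    stop("models do not share species ordering")
  }
  tr_u <- integrate_model(model_untreated, t_end, n_points, rtol, atol)
  tr_t <- integrate_model(model_treated, t_end, n_points, rtol, atol)
  y_u <- observable_timecourse(tr_u, obs)
  y_t <- observable_timecourse(tr_t, obs)
  m_u <- summary_metrics(tr_u$times, y_u)
  m_t <- summary_metrics(tr_t$times, y_t)
  ratio <- function(a, b) if (b == 0) NA_real_ else a / b
  structure(
    list(observable = obs$name,
         untreated = m_u, treated = m_t,
         ratios = list(peak = ratio(m_t$peak, m_u$peak),
                       auc = ratio(m_t$auc, m_u$auc),
                       terminal = ratio(m_t$terminal, m_u$terminal)),
         treated_exceeds_untreated = (m_t$peak > m_u$peak) && (m_t$auc > m_u$auc),
         times = tr_u$times, untreated_timecourse = y_u,
         treated_timecourse = y_t),
    class = "sig_comparison"
  )
}

#' @export
print.sig_comparison <- function(x, ...) {
  cat(sprintf("<sig_comparison> %s\n", x$observable))
  cat(sprintf("  untreated: peak %.4g uM @ %.0f s, AUC %.4g uM*s\n",
              x$untreated$peak, x$untreated$time_to_peak, x$untreated$auc))
  cat(sprintf("  treated:   peak %.4g uM @ %.0f s, AUC %.4g uM*s\n",
              x$treated$peak, x$treated$time_to_peak, x$treated$auc))
  cat(sprintf("  peak ratio %.3g, AUC ratio %.3g, treated_exceeds_untreated = %s\n",
              x$ratios$peak, x$ratios$auc, x$treated_exceeds_untreated))
  invisible(x)
}

#' Export a trajectory as a data frame / TSV
#'
#' @param traj A `sig_trajectory`.
#' @param path Optional path; when given, a TSV (time column + one column
#'   per species) is written there.
#' @param observables Optional list of [observable()]s appended as extra
#'   columns.
#' @return Invisibly, the data frame.
#' @export
trajectory_to_table <- function(traj, path = NULL, observables = NULL) {
  df <- data.frame(time = traj$times, traj$concentrations,
                   check.names = FALSE)
  for (obs in observables) {
    df[[obs$name]] <- observable_timecourse(traj, obs)
  }
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(df)
}
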