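#' Propagate a single trajectory
#'
#' Integrates Hamilton's equations with an adaptive 8th-order Runge-Kutta
#' method (Dormand-Prince 8(5,3)), with optional dissociation event
#' detection (first crossing of \code{q1} or \code{q2} above the
#' \code{q_dissoc} threshold, root-refined to below 1 fs) and optional
#' co-integration of the variational equations for the fast Lyapunov
#' indicator \eqn{FLI(t) = \sup_{s \le t} \log_{10} \lVert v(s) \rVert},
#' with renormalisation bookkeeping so the tangent norm never overflows.
#'
#' @param ic one-row data frame giving the initial condition, either in
#'   phase-space columns \code{q1..p3} or action-angle columns
#'   \code{J1..theta3}.
#' @param params a \code{\link{bunker_params}} object.
#' @param t_final integration horizon, ps.
#' @param dt_out output sampling interval, ps.
#' @param events if TRUE, stop at the first dissociation event.
#' @param tangent if TRUE, co-integrate the tangent dynamics and record FLI.
#' @param v0 initial tangent vector (6 components in \eqn{(q,p)}); default
#'   is the generic direction \eqn{(1,...,1)/\sqrt 6}.
#' @param rtol,atol integrator tolerances.
#' @param series if TRUE keep the sampled phase-space series.
#' @param drift_tol relative energy-drift audit threshold; a trajectory
#'   exceeding it is flagged (with a warning), never silently accepted.
#' @return An object of class \code{trajectory}: list with elements
#'   \code{times} (ps), \code{phase} (tibble of the sampled series, if
#'   requested), \code{fli} (if requested), \code{lifetime} (ps;
#'   \code{Inf} sentinel when the trajectory never dissociates),
#'   \code{dissociated}, \code{bond}, \code{drift_max}, \code{energy0}
#'   (cm^-1), \code{flagged}.
#' @examples
#' p <- bunker_params(epsilon = 0)
#' aa <- tibble::tibble(J1 = 2, J2 = 3, J3 = 1,
#'                      theta1 = 0, theta2 = 1, theta3 = 2)
#' tr <- propagate(aa, p, t_final = 1)
#' tr$lifetime   # Inf: uncoupled bound motion never dissociates
#' @export
propagate <- function(ic, params, t_final = 40, dt_out = 0.002,
                      events = TRUE, tangent = FALSE, v0 = NULL,
                      rtol = 1e-11, atol = 1e-11, series = TRUE,
                      drift_tol = 1e-8) {
  stopifnot(nrow(ic) == 1, t_final > 0, dt_out > 0)
  if (all(phase_cols %in% names(ic))) {
    pt <- ic[phase_cols]
  } else if (all(aa_cols %in% names(ic))) {
    pt <- act_to_phase(ic, params)
  } else {
    stop("initial condition must have phase-space or action-angle columns")
  }
  if (is.null(v0)) v0 <- rep(1, 6) / sqrt(6)
  res <- integrate_cpp(as.numeric(pt[1, ]), par_vector(params),
                       ps_to_au(t_final), ps_to_au(dt_out), rtol, atol,
                       events, tangent, v0, series)
  flagged <- res$drift_max > drift_tol
  if (flagged)
    warning(sprintf("relative energy drift %.2e exceeds audit threshold %.2e",
                    res$drift_max, drift_tol))
  out <- list(
    times = au_to_ps(res$t),
    lifetime = if (res$dissociated) au_to_ps(res$lifetime) else Inf,
    dissociated = res$dissociated,
    bond = res$bond,
    drift_max = res$drift_max,
    energy0 = hartree_to_cm(res$energy0),
    n_steps = res$n_steps,
    flagged = flagged,
    final = stats::setNames(as.list(res$y_final), phase_cols),
    params_hash = rlang::hash(params))
  if (series) {
    ph <- res$y
    colnames(ph) <- phase_cols
    out$phase <- tibble::as_tibble(ph)
  }
  if (tangent) {
    out$fli <- res$fli
    out$fli_final <- res$fli_final
  }
  class(out) <- "trajectory"
  out
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d samples to %.3f ps\n",
              length(x$times), max(x$times)))
  if (x$dissociated)
    cat(sprintf("  dissociated: bond %d at %.4f ps\n", x$bond, x$lifetime))
  else cat("  undissociated (lifetime sentinel Inf)\n")
  cat(sprintf("  energy %.2f cm^-1, max relative drift %.1e%s\n", x$energy0,
              x$drift_max, if (x$flagged) " [FLAGGED]" else ""))
  if (!is.null(x$fli_final)) cat(sprintf("  final FLI %.2f\n", x$fli_final))
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' @export
as_tibble.trajectory <- function(x, ...) {
  if (is.null(x$phase)) stop("trajectory was propagated without series")
  out <- dplyr::mutate(x$phase, t = x$times, .before = 1)
  if (!is.null(x$fli)) out$fli <- x$fli
  out
}

#' Action-angle series of a propagated trajectory
#'
#' @param traj a \code{\link{propagate}} result with series.
#' @param params the \code{\link{bunker_params}} used for propagation.
#' @return tibble with \code{t} (ps), actions and angles per sample.
#' @export
trajectory_actions <- function(traj, params) {
  if (is.null(traj$phase)) stop("trajectory was propagated without series")
  aa <- phase_to_act(traj$phase, params)
  dplyr::mutate(aa, t = traj$times, .before = 1)
}

#' Propagate an ensemble of initial conditions
#'
#' @param ics data frame of initial conditions, one row each (phase-space or
#'   action-angle columns).
#' @param params a \code{\link{bunker_params}} object.
#' @param ... passed to \code{\link{propagate}}.
#' @param keep if TRUE, keep each \code{trajectory} object in a list-column.
#' @return tibble with one row per trajectory: \code{id}, \code{lifetime}
#'   (ps, \code{Inf} if undissociated), \code{dissociated}, \code{bond},
#'   \code{drift_max}, \code{flagged}, and \code{fli} when tangent dynamics
#'   were requested.
#' @export
propagate_ensemble <- function(ics, params, ..., keep = FALSE) {
  rows <- purrr::map(seq_len(nrow(ics)), function(i) {
    tr <- propagate(ics[i, , drop = FALSE], params, series = keep, ...)
    row <- tibble::tibble(id = i, lifetime = tr$lifetime,
                          dissociated = tr$dissociated, bond = tr$bond,
                          drift_max = tr$drift_max, flagged = tr$flagged)
    if (!is.null(tr$fli_final)) row$fli <- tr$fli_final
    if (keep) row$trajectory <- list(tr)
    row
  })
  dplyr::bind_rows(rows)
}
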