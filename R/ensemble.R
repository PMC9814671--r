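#' Microcanonical initial conditions on the energy shell
#'
#' Draws \code{n} phase-space points satisfying \eqn{H(p_0, q_0) = E} to
#' within \eqn{10^{-10}} relative. Sampling scheme (declared, since the
#' density on the shell is a modelling choice): coordinates are drawn
#' uniformly in the energetically allowed region by rejection on
#' \eqn{V(q) < E}; the momentum direction is then drawn uniformly on the
#' sphere and mapped onto the kinetic-energy ellipsoid
#' \eqn{\tfrac12 p^T A p = E - V(q)} (with \eqn{A} the coupled kinetic
#' matrix), and the magnitude scaled to match the energy exactly.
#'
#' @param params a \code{\link{bunker_params}} object.
#' @param n number of points (>= 1).
#' @param seed integer seed; identical seeds give identical ensembles.
#' @return tibble with phase-space columns \code{q1..p3} and the realised
#'   \code{energy} (cm^-1).
#' @export
sample_energy_shell <- function(params, n, seed = 1L) {
  stopifnot(n >= 1)
  E <- params$E_au
  if (E <= 0) stop("total energy must exceed the potential minimum")
  G <- params$G0
  A <- G * (params$epsilon + diag(1 - params$epsilon, 3))  # kinetic matrix
  R <- chol(A)
  # allowed coordinate box
  lims <- q_limits(params)
  vfun <- function(q) {
    params$D_au[1] * (1 - exp(-params$alpha[1] * (q[, 1] - params$q0[1])))^2 +
    params$D_au[2] * (1 - exp(-params$alpha[2] * (q[, 2] - params$q0[2])))^2 +
    0.5 * params$w_au[3]^2 * (q[, 3] - params$q0[3])^2 / G[3, 3]
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  qs <- matrix(NA_real_, 0, 3)
  while (nrow(qs) < n) {
    m <- max(2 * (n - nrow(qs)), 64)
    cand <- cbind(stats::runif(m, lims[1, 1], lims[1, 2]),
                  stats::runif(m, lims[2, 1], lims[2, 2]),
                  stats::runif(m, lims[3, 1], lims[3, 2]))
    keep <- vfun(cand) < E
    qs <- rbind(qs, cand[keep, , drop = FALSE])
  }
  qs <- qs[seq_len(n), , drop = FALSE]
  K <- E - vfun(qs)
  u <- matrix(stats::rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  p <- t(backsolve(R, t(u))) * sqrt(2 * K)  # (1/2) p^T A p = K exactly
  out <- tibble::tibble(q1 = qs[, 1], q2 = qs[, 2], q3 = qs[, 3],
                        p1 = p[, 1], p2 = p[, 2], p3 = p[, 3])
  out <- ham_energy(out, params)
  bad <- abs(out$energy - params$E) / params$E > 1e-10
  if (any(bad)) stop("energy-shell construction failed for ", sum(bad),
                     " points")
  out
}

# Energetically allowed coordinate box at total energy E (au internals).
q_limits <- function(params) {
  E <- params$E_au
  lim <- matrix(0, 3, 2)
  for (k in 1:2) {
    r <- sqrt(min(E / params$D_au[k], 1))
    qmin <- params$q0[k] - log(1 + r) / params$alpha[k]
    qmax <- if (E < params$D_au[k])
      params$q0[k] - log(1 - r) / params$alpha[k] else params$q_dissoc
    lim[k, ] <- c(qmin, qmax)
  }
  a3 <- sqrt(2 * params$G0[3, 3] * E) / params$w_au[3]
  lim[3, ] <- params$q0[3] + c(-a3, a3)
  # bend angle physically within (0, pi)
  lim[3, 1] <- max(lim[3, 1], 1e-3)
  lim[3, 2] <- min(lim[3, 2], pi - 1e-3)
  lim
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Fixed-angle slice of the energy shell on a uniform action grid
#'
#' Emulates the angle-slice ensembles: on a uniform \eqn{(J_1, J_2)} grid
#' with the angles held at \code{theta}, the third action is obtained by
#' solving the full coupled \eqn{H(J, \theta^*) = E} for \eqn{J_3 \ge 0}
#' (bracketing + root polishing; the coupling term shifts the shell whenever
#' \eqn{\epsilon > 0}). Cells admitting no non-negative root are flagged
#' infeasible; where several roots exist the smallest non-negative one is
#' taken, continuous with the \eqn{\epsilon = 0} closed form.
#'
#' @param params a \code{\link{bunker_params}} object.
#' @param theta fixed angles \eqn{(\theta_1, \theta_2, \theta_3)}, radians.
#' @param n grid resolution per axis (length 1 or 2, >= 2).
#' @param j1_range,j2_range action ranges (hbar); defaults to
#'   \eqn{[0, 0.99\, J_{max}]}, inside which the stretch coordinate stays
#'   below the dissociation threshold for every angle.
#' @return tibble with one row per cell: indices \code{i, j}, actions
#'   \code{J1, J2, J3}, \code{feasible}, phase-space columns and realised
#'   \code{energy} (cm^-1, NA when infeasible). Attributes record the slice
#'   specification.
#' @export
angle_slice_grid <- function(params, theta = c(pi / 2, pi / 2, 0),
                             n = c(100, 100),
                             j1_range = NULL, j2_range = NULL) {
  if (length(n) == 1) n <- c(n, n)
  stopifnot(all(n >= 2), length(theta) == 3)
  jm <- j_max(params)
  if (is.null(j1_range)) j1_range <- c(0, 0.99 * jm[1])
  if (is.null(j2_range)) j2_range <- c(0, 0.99 * jm[2])
  if (j1_range[1] < 0 || j2_range[1] < 0 ||
      j1_range[2] >= jm[1] || j2_range[2] >= jm[2])
    stop("action ranges must lie within the bound domain [0, Jmax)")
  j1 <- seq(j1_range[1], j1_range[2], length.out = n[1])
  j2 <- seq(j2_range[1], j2_range[2], length.out = n[2])
  grid <- tidyr::expand_grid(i = seq_len(n[1]), j = seq_len(n[2]))
  grid$J1 <- j1[grid$i]
  grid$J2 <- j2[grid$j]
  grid$J3 <- slice_solve_j3(params, grid$J1, grid$J2, theta)
  grid$feasible <- is.finite(grid$J3)
  ph <- matrix(NA_real_, nrow(grid), 6, dimnames = list(NULL, phase_cols))
  if (any(grid$feasible)) {
    aa <- tibble::tibble(J1 = grid$J1[grid$feasible],
                         J2 = grid$J2[grid$feasible],
                         J3 = grid$J3[grid$feasible],
                         theta1 = theta[1], theta2 = theta[2],
                         theta3 = theta[3])
    ph[grid$feasible, ] <- as.matrix(act_to_phase(aa, params))
  }
  out <- dplyr::bind_cols(grid, tibble::as_tibble(ph))
  out$energy <- NA_real_
  if (any(out$feasible))
    out$energy[out$feasible] <-
      ham_energy(out[out$feasible, phase_cols], params)$energy
  attr(out, "theta") <- theta
  attr(out, "E") <- params$E
  attr(out, "epsilon") <- params$epsilon
  class(out) <- c("slice_grid", class(out))
  out
}

# Solve H(J1, J2, J3, theta*) = E for the smallest non-negative J3, per cell.
# Returns NA where infeasible. Vectorised bracket scan + vectorised bisection
# (all cells advance together; each iteration is one batched Hamiltonian
# evaluation).
slice_solve_j3 <- function(params, J1, J2, theta, n_scan = 48) {
  E <- params$E
  j3_hi <- E / params$omega[3] + 2
  ncell <- length(J1)
  feval <- function(j1, j2, j3) {
    aa <- tibble::tibble(J1 = j1, J2 = j2, J3 = j3,
                         theta1 = theta[1], theta2 = theta[2],
                         theta3 = theta[3])
    ham_energy(act_to_phase(aa, params), params)$energy - E
  }
  scan <- seq(0, j3_hi, length.out = n_scan)
  big <- tidyr::expand_grid(cell = seq_len(ncell), J3 = scan)
  f <- feval(J1[big$cell], J2[big$cell], big$J3)
  fm <- matrix(f, nrow = n_scan)            # scan index x cell
  lo <- rep(NA_real_, ncell); hi <- rep(NA_real_, ncell)
  for (c in seq_len(ncell)) {
    fc <- fm[, c]
    if (fc[1] > 0) next                     # no non-negative root
    sgn <- which(fc[-n_scan] <= 0 & fc[-1] > 0)
    if (length(sgn) == 0) next
    lo[c] <- scan[sgn[1]]; hi[c] <- scan[sgn[1] + 1]
  }
  act <- which(is.finite(lo))
  if (length(act)) {
    for (it in 1:52) {
      mid <- 0.5 * (lo[act] + hi[act])
      fmid <- feval(J1[act], J2[act], mid)
      up <- fmid > 0
      hi[act][up] <- mid[up]
      lo[act][!up] <- mid[!up]
    }
  }
  0.5 * (lo + hi)
}
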