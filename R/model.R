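phase_cols <- c("q1", "q2", "q3", "p1", "p2", "p3")
aa_cols <- c("J1", "J2", "J3", "theta1", "theta2", "theta3")

phase_matrix <- function(points) {
  if (!all(phase_cols %in% names(points)))
    stop("expected phase-space columns ", paste(phase_cols, collapse = ", "))
  m <- as.matrix(points[phase_cols])
  if (any(!is.finite(m))) stop("non-finite phase-space point")
  m
}

#' Total energy of phase-space points
#'
#' Evaluates the coupled Hamiltonian
#' \deqn{H = \sum_i [\tfrac12 G^{(0)}_{ii} p_i^2 + V_i(q_i)] +
#'   \epsilon \sum_{i<j} G^{(0)}_{ij} p_i p_j}
#' with Morse potentials for the stretches and a harmonic bend, at each row
#' of \code{points}.
#'
#' @param points data frame with columns \code{q1, q2, q3} (bohr, bohr,
#'   radian) and \code{p1, p2, p3} (atomic units).
#' @param params a \code{\link{bunker_params}} object.
#' @return the input as a tibble with an added \code{energy} column (cm^-1,
#'   zero at the potential minimum with zero momenta).
#' @examples
#' p <- bunker_params()
#' pt <- tibble::tibble(q1 = p$q0[1], q2 = p$q0[2], q3 = p$q0[3],
#'                      p1 = 0, p2 = 0, p3 = 0)
#' ham_energy(pt, p)$energy  # 0
#' @export
ham_energy <- function(points, params) {
  e <- hamiltonian_cpp(phase_matrix(points), par_vector(params))
  dplyr::mutate(tibble::as_tibble(points), energy = hartree_to_cm(e))
}

#' Hamilton's equations of motion
#'
#' Time derivatives \eqn{\dot q_i = \partial H/\partial p_i},
#' \eqn{\dot p_i = -\partial H/\partial q_i} at each row of \code{points},
#' reported per picosecond.
#'
#' @inheritParams ham_energy
#' @return tibble with columns \code{dq1..dq3} (bohr/ps, radian/ps) and
#'   \code{dp1..dp3} (au momentum /ps).
#' @export
equations_of_motion <- function(points, params) {
  d <- eom_cpp(phase_matrix(points), par_vector(params)) * PS_AU
  colnames(d) <- c("dq1", "dq2", "dq3", "dp1", "dp2", "dp3")
  tibble::as_tibble(d)
}
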