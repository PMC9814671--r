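#' Fourier coefficients of the kinetic coupling on an unperturbed torus
#'
#' The coupling of the model is \eqn{\epsilon V(J, \theta)} with
#' \eqn{V = \sum_{i<j} G^{(0)}_{ij} p_i(J_i,\theta_i) p_j(J_j,\theta_j)}.
#' For a fixed action point this function performs a 2-D discrete Fourier
#' analysis of each mode-pair term over a uniform angle grid of the
#' unperturbed torus and returns the complex coefficients
#' \eqn{c_{l_1 l_2}} of \eqn{e^{i(l_1\theta_i + l_2\theta_j)}} up to
#' \code{max_order} per angle. Because the harmonic bend momentum is a pure
#' tone, the (1,3) and (2,3) tables carry bend harmonics \eqn{\pm 1} only.
#' The real amplitude of a resonant harmonic \eqn{\cos/\sin(l_1\theta_i +
#' l_2\theta_j + \phi)} is \eqn{2 |c_{l_1 l_2}|}.
#'
#' @param params a \code{\link{bunker_params}} object.
#' @param J actions \code{c(J1, J2, J3)} (hbar) of the evaluation torus.
#' @param max_order highest retained harmonic per angle (>= 1).
#' @param n_theta angle-grid resolution per dimension (power of 2 advised).
#' @return tibble with columns \code{pair} ("12", "13", "23"), harmonics
#'   \code{l1, l2} (signed, of the first/second angle of the pair), \code{re,
#'   im} and \code{amp} \eqn{= 2|c|} (cm^-1, except the constant term);
#'   attribute \code{J} records the torus.
#' @export
fourier_table <- function(params, J, max_order = 10, n_theta = 256) {
  if (max_order < 1) stop("max_order must be >= 1")
  jm <- j_max(params)
  if (J[1] < 0 || J[2] < 0 || J[3] < 0 || J[1] >= jm[1] || J[2] >= jm[2])
    stop("J outside the bound action domain")
  th <- 2 * pi * (0:(n_theta - 1)) / n_theta
  G <- params$G0
  # per-mode momentum series on the angle grid (au)
  p1 <- morse_aa_to_xp(J[1], th, params$D[1], params$omega[1],
                       params$D_au[1], params$alpha[1], G[1, 1])$p
  p2 <- morse_aa_to_xp(J[2], th, params$D[2], params$omega[2],
                       params$D_au[2], params$alpha[2], G[2, 2])$p
  p3 <- -sqrt(2 * params$w_au[3] * J[3] / G[3, 3]) * sin(th)
  mom <- list(`1` = p1, `2` = p2, `3` = p3)
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  sig <- function(idx) ifelse(idx - 1 > n_theta / 2, idx - 1 - n_theta, idx - 1)
  keep <- which(abs(sig(seq_len(n_theta))) <= max_order)
  res <- lapply(pairs, function(pr) {
    Tij <- G[pr[1], pr[2]] * outer(mom[[pr[1]]], mom[[pr[2]]]) * HARTREE_CM
    C <- stats::fft(Tij) / n_theta^2     # coefficients of e^{+i(l1 th_i + l2 th_j)}
    tibble::tibble(
      pair = paste0(pr[1], pr[2]),
      l1 = rep(sig(keep), times = length(keep)),
      l2 = rep(sig(keep), each = length(keep)),
      re = as.vector(Re(C[keep, keep])),
      im = as.vector(Im(C[keep, keep])))
  })
  out <- dplyr::bind_rows(res)
  out$amp <- 2 * sqrt(out$re^2 + out$im^2)
  out$amp[out$l1 == 0 & out$l2 == 0] <- sqrt(
    out$re[out$l1 == 0 & out$l2 == 0]^2 + out$im[out$l1 == 0 & out$l2 == 0]^2)
  attr(out, "J") <- J
  attr(out, "max_order") <- max_order
  out
}

#' Evaluate the coupling from a Fourier table at given angles
#'
#' Reconstructs \eqn{V(J, \theta)} (the coupling with the \eqn{\epsilon}
#' factor removed) from the tabulated harmonics; used to verify the table
#' against the direct evaluation \eqn{(H - H_0)/\epsilon}.
#'
#' @param tab a \code{\link{fourier_table}} result (possibly truncated).
#' @param theta data frame or list with columns/elements \code{theta1,
#'   theta2, theta3} (radians, equal length).
#' @return numeric vector of coupling energies, cm^-1.
#' @export
fourier_reconstruct <- function(tab, theta) {
  ang <- cbind(theta$theta1, theta$theta2, theta$theta3)
  first <- as.integer(substr(tab$pair, 1, 1))
  second <- as.integer(substr(tab$pair, 2, 2))
  v <- numeric(nrow(ang))
  for (r in seq_len(nrow(tab))) {
    ph <- tab$l1[r] * ang[, first[r]] + tab$l2[r] * ang[, second[r]]
    v <- v + tab$re[r] * cos(ph) - tab$im[r] * sin(ph)
  }
  v
}

#' Direct evaluation of the coupling
#'
#' \eqn{V(J,\theta) = (H(J,\theta) - H_0(J))/\epsilon}, computed by mapping
#' the action-angle point to phase space and evaluating the full
#' Hamiltonian. Independent of the Fourier route.
#'
#' @param aa data frame with action-angle columns.
#' @param params a \code{\link{bunker_params}} object; \code{epsilon} must be
#'   non-zero (the coupling shape does not depend on it).
#' @return numeric vector, cm^-1.
#' @export
coupling_direct <- function(aa, params) {
  eps <- params$epsilon
  if (eps == 0) {
    params$epsilon <- 1
    eps <- 1
  }
  h <- ham_energy(act_to_phase(aa, params), params)$energy
  (h - h0(aa, params)$h0) / eps
}

#' Amplitude of one resonant Fourier harmonic
#'
#' @param tab a \code{\link{fourier_table}} result.
#' @param pair mode pair, e.g. "13".
#' @param l1,l2 harmonics of the pair's first and second angle.
#' @return real amplitude \eqn{2|c_{l_1 l_2}|} in cm^-1.
#' @export
resonant_amplitude <- function(tab, pair, l1, l2) {
  row <- tab[tab$pair == pair & tab$l1 == l1 & tab$l2 == l2, ]
  if (nrow(row) == 0) stop("harmonic (", l1, ",", l2, ") of pair ", pair,
                           " not in table")
  row$amp[1]
}
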