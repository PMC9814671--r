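#' Zeroth-order (uncoupled) energy in action variables
#'
#' \deqn{H_0(J) = \sum_{k=1,2} \omega_k J_k (1 - \omega_k J_k / 4 D_k) +
#'   \omega_3 J_3}
#'
#' @param aa data frame with action columns \code{J1, J2, J3} (hbar); angle
#'   columns are ignored if present.
#' @param params a \code{\link{bunker_params}} object.
#' @return input as tibble with an added \code{h0} column (cm^-1).
#' @export
h0 <- function(aa, params) {
  w <- params$omega; D <- params$D
  e <- w[1] * aa$J1 * (1 - w[1] * aa$J1 / (4 * D[1])) +
       w[2] * aa$J2 * (1 - w[2] * aa$J2 / (4 * D[2])) +
       w[3] * aa$J3
  dplyr::mutate(tibble::as_tibble(aa), h0 = e)
}

#' Nonlinear (anharmonic) mode frequencies
#'
#' Gradient of the zeroth-order Hamiltonian:
#' \eqn{\Omega_k = \omega_k (1 - \omega_k J_k / 2 D_k)} for the stretches and
#' \eqn{\Omega_3 = \omega_3} (the harmonic bend is isochronous).
#'
#' @inheritParams h0
#' @return input as tibble with added \code{Omega1, Omega2, Omega3} (cm^-1).
#' @export
nonlinear_frequencies <- function(aa, params) {
  w <- params$omega; D <- params$D
  dplyr::mutate(tibble::as_tibble(aa),
                Omega1 = w[1] * (1 - w[1] * .data$J1 / (2 * D[1])),
                Omega2 = w[2] * (1 - w[2] * .data$J2 / (2 * D[2])),
                Omega3 = w[3])
}

# Per-mode Morse action-angle -> (x, p) in au; vectorized. J in hbar.
# Convention: theta = 0 at the inner turning point, increasing with time.
morse_aa_to_xp <- function(J, theta, D_cm, w_cm, D_au, alpha, G) {
  n <- max(length(J), length(theta))
  J <- rep_len(J, n); theta <- rep_len(theta, n)
  eps <- w_cm * J * (1 - w_cm * J / (4 * D_cm)) / D_cm   # E/D
  se <- sqrt(pmax(eps, 0))
  den <- 1 - se * cos(theta)
  x <- ifelse(J == 0, 0, log(den / (1 - eps)) / alpha)
  p <- ifelse(J == 0, 0,
              sqrt(2 * D_au * pmax(eps * (1 - eps), 0) / G) * sin(theta) / den)
  list(x = x, p = p)
}

#' Exact action-angle to phase-space transform
#'
#' Canonical per-mode transform: closed-form Morse bound-orbit solution for
#' the stretches (angle origin at the inner turning point), harmonic
#' convention \eqn{q_3 - q_3^0 = \sqrt{2 G^{(0)}_{33} J_3/\omega_3}
#' \cos\theta_3}, \eqn{p_3 = -\sqrt{2 \omega_3 J_3/G^{(0)}_{33}}
#' \sin\theta_3} for the bend.
#'
#' @param aa data frame with columns \code{J1, J2, J3} (hbar, within the
#'   bound domain \eqn{J_k < 2D_k/\omega_k} for the stretches) and
#'   \code{theta1, theta2, theta3} (radians).
#' @param params a \code{\link{bunker_params}} object.
#' @return tibble with phase-space columns \code{q1..q3, p1..p3}.
#' @export
act_to_phase <- function(aa, params) {
  if (!all(aa_cols %in% names(aa)))
    stop("expected action-angle columns ", paste(aa_cols, collapse = ", "))
  jm <- j_max(params)
  if (any(aa$J1 < 0 | aa$J2 < 0 | aa$J3 < 0))
    stop("actions must be non-negative")
  if (any(aa$J1 >= jm[1]) || any(aa$J2 >= jm[2]))
    stop("stretch action outside the bound Morse domain J < 2D/omega")
  G <- params$G0
  m1 <- morse_aa_to_xp(aa$J1, aa$theta1, params$D[1], params$omega[1],
                       params$D_au[1], params$alpha[1], G[1, 1])
  m2 <- morse_aa_to_xp(aa$J2, aa$theta2, params$D[2], params$omega[2],
                       params$D_au[2], params$alpha[2], G[2, 2])
  w3 <- params$w_au[3]
  x3 <- sqrt(2 * G[3, 3] * aa$J3 / w3) * cos(aa$theta3)
  p3 <- -sqrt(2 * w3 * aa$J3 / G[3, 3]) * sin(aa$theta3)
  tibble::tibble(q1 = params$q0[1] + m1$x, q2 = params$q0[2] + m2$x,
                 q3 = params$q0[3] + x3,
                 p1 = m1$p, p2 = m2$p, p3 = p3)
}

#' Phase-space to action-angle transform
#'
#' Inverse of \code{\link{act_to_phase}}: per-mode (uncoupled) energies are
#' mapped to actions through the Morse and harmonic closed forms, angles
#' recovered from the coordinate and the sign of the momentum. Each
#' instantaneous uncoupled mode energy must be below its dissociation limit.
#'
#' @param points data frame with phase-space columns \code{q1..p3}.
#' @param params a \code{\link{bunker_params}} object.
#' @param clamp if TRUE, samples whose instantaneous uncoupled stretch
#'   energy reaches the dissociation limit (possible transiently when the
#'   coupling exchanges energy, since \eqn{E > D}) are clamped to the
#'   boundary of the bound domain instead of raising an error. Used by the
#'   time-frequency analysis, where brief excursions merely perturb a
#'   time-localised transform.
#' @return tibble with columns \code{J1..J3} (hbar) and
#'   \code{theta1..theta3} (radians in \eqn{[0, 2\pi)}).
#' @export
phase_to_act <- function(points, params, clamp = FALSE) {
  G <- params$G0
  out <- list()
  for (k in 1:2) {
    x <- points[[paste0("q", k)]] - params$q0[k]
    p <- points[[paste0("p", k)]]
    E <- 0.5 * G[k, k] * p^2 +
      params$D_au[k] * (1 - exp(-params$alpha[k] * x))^2
    eps <- E / params$D_au[k]
    if (any(eps >= 1)) {
      if (!clamp)
        stop("unbound instantaneous energy in stretch mode ", k,
             " (E >= D); action-angle transform undefined")
      eps <- pmin(eps, 1 - 1e-9)
    }
    J <- (2 * params$D[k] / params$omega[k]) * (1 - sqrt(1 - eps))
    se <- sqrt(eps)
    ct <- ifelse(eps > 0, (1 - (1 - eps) * exp(params$alpha[k] * x)) / se, 1)
    ct <- pmin(pmax(ct, -1), 1)
    pscale <- sqrt(2 * params$D_au[k] * pmax(eps * (1 - eps), 0) / G[k, k])
    st <- ifelse(pscale > 0, p * (1 - se * ct) / pscale, 0)
    th <- atan2(st, ct) %% (2 * pi)
    out[[paste0("J", k)]] <- J
    out[[paste0("theta", k)]] <- ifelse(eps > 0, th, 0)
  }
  w3 <- params$w_au[3]
  x3 <- points$q3 - params$q0[3]
  p3 <- points$p3
  E3 <- 0.5 * G[3, 3] * p3^2 + 0.5 * w3^2 * x3^2 / G[3, 3]
  J3 <- E3 / w3
  ct <- ifelse(J3 > 0, x3 / sqrt(2 * G[3, 3] * J3 / w3), 1)
  st <- ifelse(J3 > 0, -p3 / sqrt(2 * w3 * J3 / G[3, 3]), 0)
  out$J3 <- J3
  out$theta3 <- ifelse(J3 > 0, atan2(st, ct) %% (2 * pi), 0)
  tibble::as_tibble(out)[aa_cols]
}
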