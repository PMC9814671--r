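gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
gcd3 <- function(v) Reduce(gcd2, abs(v)[abs(v) > 0])

# Line coefficients of a resonance (l, m, n) in the (J1, J2) plane:
# l*Omega1 + m*Omega2 + n*omega3 = 0 with Omega_k linear in J_k gives
# A*J1 + B*J2 = C.
line_coef <- function(v, params) {
  w <- params$omega; D <- params$D
  list(A = v[1] * w[1]^2 / (2 * D[1]),
       B = v[2] * w[2]^2 / (2 * D[2]),
       C = v[1] * w[1] + v[2] * w[2] + v[3] * w[3])
}

#' Analytic resonance lines in the action plane
#'
#' Enumerates coprime resonance vectors \eqn{(l, m, n)} of order
#' \eqn{\mathcal{O} = |l| + |m| + |n| \le} \code{max_order} whose condition
#' \eqn{l\Omega_1 + m\Omega_2 + n\Omega_3 = 0} admits solutions in the bound
#' action domain. Because \eqn{\Omega_3 \equiv \omega_3} and the stretch
#' frequencies are linear in their actions, every resonance is a straight
#' line in \eqn{(J_1, J_2)}: stretch-bend resonances \eqn{(l, 0, -m)} and
#' \eqn{(0, l, -m)} are vertical/horizontal, stretch-stretch resonances are
#' sloped.
#'
#' @param params a \code{\link{bunker_params}} object.
#' @param max_order maximum resonance order (>= 2).
#' @param window optional list with \code{j1}, \code{j2} ranges used to
#'   filter lines (defaults to the bound domain).
#' @return tibble with columns \code{l, m, n}, \code{order}, \code{type}
#'   (vertical/horizontal/sloped), line coefficients \code{A, B, C}
#'   (\eqn{A J_1 + B J_2 = C}) and, for axis-parallel lines, the constant
#'   action \code{J_const}.
#' @examples
#' resonance_lines(bunker_params(), max_order = 3)
#' @export
resonance_lines <- function(params, max_order = 5, window = NULL) {
  if (max_order < 2) stop("max_order must be >= 2")
  jm <- j_max(params)
  if (is.null(window)) window <- list(j1 = c(0, jm[1]), j2 = c(0, jm[2]))
  rng <- -max_order:max_order
  cand <- tidyr::expand_grid(l = rng, m = rng, n = rng)
  cand <- cand[rowSums(abs(cand)) > 0 & rowSums(abs(cand)) <= max_order, ]
  cand <- cand[apply(cand, 1, function(v) gcd3(v) == 1), ]
  # canonical sign: first non-zero entry positive
  flip <- apply(cand, 1, function(v) v[which(v != 0)[1]] < 0)
  cand[flip, ] <- -cand[flip, ]
  cand <- dplyr::distinct(cand)
  rows <- purrr::pmap(cand, function(l, m, n) {
    v <- c(l, m, n)
    co <- line_coef(v, params)
    if (co$A == 0 && co$B == 0) return(NULL)       # bend-only: no line
    type <- if (co$B == 0) "vertical" else if (co$A == 0) "horizontal"
            else "sloped"
    jc <- NA_real_
    if (type == "vertical") {
      jc <- co$C / co$A
      if (jc < window$j1[1] || jc > window$j1[2] || jc < 0 || jc >= jm[1])
        return(NULL)
    } else if (type == "horizontal") {
      jc <- co$C / co$B
      if (jc < window$j2[1] || jc > window$j2[2] || jc < 0 || jc >= jm[2])
        return(NULL)
    } else {
      # keep if the line crosses the window rectangle
      j1 <- window$j1; j2 <- (co$C - co$A * j1) / co$B
      jlo <- min(j2); jhi <- max(j2)
      if (jhi < window$j2[1] || jlo > window$j2[2]) return(NULL)
    }
    tibble::tibble(l = l, m = m, n = n, order = sum(abs(v)), type = type,
                   A = co$A, B = co$B, C = co$C, J_const = jc)
  })
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$order, .data$l, .data$m, .data$n)
}

resvec_label <- function(v) paste0("(", v[1], ",", v[2], ",", v[3], ")")

#' Resonance-junction locations
#'
#' Intersections of pairs of independent resonance lines: multiplicity-2
#' junctions (the maximum for three degrees of freedom), denoted
#' \eqn{\mathcal{M}} with the two resonance vectors as labels. Also returns
#' the frequency-ratio coordinates \eqn{(f_1, f_2) = (\Omega_1/\Omega_3,
#' \Omega_2/\Omega_3)} of the junction and, optionally, the combination
#' resonances \eqn{\mu\, r_1 + \nu\, r_2} up to \eqn{|\mu| + |\nu| \le 3}
#' that also pass through it.
#'
#' @param params a \code{\link{bunker_params}} object.
#' @param pairs list of 2-element lists/length-3 integer vectors; default is
#'   the four junctions of stretch-bend resonances discussed in the text:
#'   (1,0,-1)x(0,1,-1), (2,0,-3)x(0,2,-3), (2,0,-3)x(0,1,-1),
#'   (1,0,-1)x(0,2,-3).
#' @param combos if TRUE, attach a list-column of combination resonances.
#' @return tibble with \code{label}, the two resonance vectors, junction
#'   coordinates \code{J1, J2} (hbar), ratio coordinates \code{f1, f2},
#'   multiplicity \code{r} and a bound-domain validity flag.
#' @examples
#' junctions(bunker_params())   # M(1,0,-1|0,1,-1) near J1 ~ J2 ~ 6.3
#' @export
junctions <- function(params, pairs = NULL, combos = FALSE) {
  if (is.null(pairs)) pairs <- default_junction_pairs()
  jm <- j_max(params)
  rows <- purrr::map(pairs, function(pr) {
    v1 <- as.integer(pr[[1]]); v2 <- as.integer(pr[[2]])
    for (v in list(v1, v2))
      if (all(v == 0) || gcd3(v) != 1)
        stop("resonance vectors must be non-zero and coprime: ",
             resvec_label(v))
    # linear independence of the two resonance vectors
    cr <- c(v1[2] * v2[3] - v1[3] * v2[2],
            v1[3] * v2[1] - v1[1] * v2[3],
            v1[1] * v2[2] - v1[2] * v2[1])
    if (all(cr == 0))
      stop("resonance vectors ", resvec_label(v1), " and ", resvec_label(v2),
           " are dependent (same resonance line)")
    c1 <- line_coef(v1, params); c2 <- line_coef(v2, params)
    det <- c1$A * c2$B - c1$B * c2$A
    if (abs(det) < 1e-12)
      stop("resonance lines ", resvec_label(v1), " and ", resvec_label(v2),
           " are parallel; no junction")
    J1 <- (c1$C * c2$B - c1$B * c2$C) / det
    J2 <- (c1$A * c2$C - c1$C * c2$A) / det
    fr <- nonlinear_frequencies(tibble::tibble(J1 = J1, J2 = J2, J3 = 0),
                                params)
    out <- tibble::tibble(
      label = paste0("M[", paste(v1, collapse = ","), "|",
                     paste(v2, collapse = ","), "]"),
      l1 = v1[1], m1 = v1[2], n1 = v1[3],
      l2 = v2[1], m2 = v2[2], n2 = v2[3],
      J1 = J1, J2 = J2,
      f1 = fr$Omega1 / fr$Omega3, f2 = fr$Omega2 / fr$Omega3,
      r = 2L,
      valid = J1 >= 0 && J1 < jm[1] && J2 >= 0 && J2 < jm[2])
    if (combos) {
      cmb <- tidyr::expand_grid(mu = -3:3, nu = -3:3)
      cmb <- cmb[abs(cmb$mu) + abs(cmb$nu) > 0 &
                 abs(cmb$mu) + abs(cmb$nu) <= 3, ]
      vecs <- t(apply(cmb, 1, function(x) x[1] * v1 + x[2] * v2))
      cmb$l <- vecs[, 1]; cmb$m <- vecs[, 2]; cmb$n <- vecs[, 3]
      out$combinations <- list(cmb[rowSums(abs(vecs)) > 0, ])
    }
    out
  })
  dplyr::bind_rows(rows)
}

default_junction_pairs <- function() {
  list(list(c(1, 0, -1), c(0, 1, -1)),
       list(c(2, 0, -3), c(0, 2, -3)),
       list(c(2, 0, -3), c(0, 1, -1)),
       list(c(1, 0, -1), c(0, 2, -3)))
}

#' Fast Lyapunov indicator map on an angle slice (the Arnold web)
#'
#' For every feasible cell of an \code{\link{angle_slice_grid}}, integrates
#' the trajectory together with its tangent dynamics up to the horizon and
#' records the final FLI and the dissociation lifetime. At cells that
#' dissociate before the horizon the FLI is frozen at the event time (the
#' cell is kept, not excluded). The map is deterministic: no randomness
#' enters this module.
#'
#' @param params a \code{\link{bunker_params}} object.
#' @param slice an \code{\link{angle_slice_grid}}; if NULL one is built from
#'   \code{theta} and \code{n}.
#' @param theta,n passed to \code{\link{angle_slice_grid}} when
#'   \code{slice} is NULL.
#' @param t_horizon integration horizon, ps (40 matches the reference
#'   ensembles; use \code{quick = TRUE} for the standard cheap short-horizon
#'   FLI variant).
#' @param quick if TRUE, use a 4 ps horizon.
#' @param rtol,atol integrator tolerances (map defaults trade a little
#'   accuracy for speed; the FLI is a coarse-grained indicator).
#' @return tibble of class \code{fli_map}: the slice columns plus
#'   \code{fli}, \code{lifetime} (ps, \code{Inf} when undissociated within
#'   the horizon) and \code{error} flags.
#' @export
compute_fli_map <- function(params, slice = NULL,
                            theta = c(pi / 2, pi / 2, 0), n = c(100, 100),
                            t_horizon = 40, quick = FALSE,
                            rtol = 1e-10, atol = 1e-10) {
  if (quick) t_horizon <- 4
  if (is.null(slice)) slice <- angle_slice_grid(params, theta = theta, n = n)
  pv <- par_vector(params)
  v0 <- rep(1, 6) / sqrt(6)
  nr <- nrow(slice)
  fli <- rep(NA_real_, nr); lt <- rep(NA_real_, nr); err <- rep(FALSE, nr)
  idx <- which(slice$feasible)
  for (i in idx) {
    y0 <- as.numeric(slice[i, phase_cols])
    res <- tryCatch(
      integrate_cpp(y0, pv, ps_to_au(t_horizon), ps_to_au(0.5),
                    rtol, atol, TRUE, TRUE, v0, FALSE),
      error = function(e) NULL)
    if (is.null(res)) { err[i] <- TRUE; next }
    fli[i] <- res$fli_final
    lt[i] <- if (res$dissociated) au_to_ps(res$lifetime) else Inf
  }
  out <- dplyr::mutate(tibble::as_tibble(slice), fli = fli, lifetime = lt,
                       error = err)
  attr(out, "theta") <- attr(slice, "theta")
  attr(out, "t_horizon") <- t_horizon
  attr(out, "epsilon") <- params$epsilon
  attr(out, "params_hash") <- rlang::hash(params)
  class(out) <- c("fli_map", class(out))
  out
}

#' Classify map cells as regular, resonant or chaotic
#'
#' Deterministic labelling calibrated per (\eqn{\epsilon}, horizon) from
#' two reference ensembles rather than hard-coded FLI constants (the
#' absolute FLI scale depends on the tangent-vector normalisation): an
#' integrable reference curve (median FLI versus time of the slice at
#' \eqn{\epsilon = 0}, tangent growth from anharmonic shear alone) and a
#' strongly chaotic reference curve (the same at \eqn{\epsilon = 1}).
#' Because dissociating cells carry an FLI frozen at the event time, every
#' comparison happens at the cell's own effective time. A cell is chaotic
#' when its FLI exceeds the integrable curve by \code{margin_chaotic} or
#' lies closer to the chaotic than to the integrable curve; it is resonant
#' when its FLI falls below the integrable curve by \code{margin_resonant}
#' (pendulum-like libration suppresses the shear); otherwise regular.
#' Margins are in FLI (log10) units.
#'
#' @param map a \code{\link{compute_fli_map}} result.
#' @param params the parameter set used for the map.
#' @param references optional list with elements \code{map0} (an
#'   \eqn{\epsilon = 0} FLI map on the same grid, giving the per-cell
#'   integrable baseline), \code{curve0} (integrable median FLI curve,
#'   giving the baseline's time dependence) and \code{curve1} (strongly
#'   chaotic median curve); computed when NULL.
#' @param margin_chaotic,margin_resonant classification margins.
#' @return the map with an added \code{label} column and attribute
#'   \code{fli_reference} (the reference list).
#' @export
classify_map <- function(map, params, references = NULL,
                         margin_chaotic = 1, margin_resonant = 0.15) {
  horizon <- attr(map, "t_horizon")
  theta <- attr(map, "theta")
  if (is.null(references)) {
    p0 <- params; p0$epsilon <- 0
    slice0 <- angle_slice_grid(p0, theta = theta,
                               n = c(max(map$i), max(map$j)),
                               j1_range = range(map$J1),
                               j2_range = range(map$J2))
    references <- list(
      map0 = compute_fli_map(p0, slice = slice0, t_horizon = horizon),
      curve0 = fli_reference_curve(params, theta = theta,
                                   t_horizon = horizon, epsilon = 0),
      curve1 = fli_reference_curve(params, theta = theta,
                                   t_horizon = horizon, epsilon = 1))
  }
  t_eff <- pmin(ifelse(is.finite(map$lifetime), map$lifetime, horizon),
                horizon)
  # per-cell integrable baseline, shifted in time along the median shape
  ref0_final <- references$map0$fli[match(paste(map$i, map$j),
                                          paste(references$map0$i,
                                                references$map0$j))]
  ref0_final[is.na(ref0_final)] <-
    stats::median(references$map0$fli, na.rm = TRUE)
  c0 <- references$curve0
  shape <- stats::approx(c0$t, c0$fli, xout = t_eff, rule = 2)$y -
    c0$fli[nrow(c0)]
  ref0 <- ref0_final + shape
  ref1 <- stats::approx(references$curve1$t, references$curve1$fli,
                        xout = t_eff, rule = 2)$y
  lab <- rep(NA_character_, nrow(map))
  ok <- !is.na(map$fli)
  chaotic <- ok & (map$fli > ref0 + margin_chaotic |
                     abs(map$fli - ref1) < abs(map$fli - ref0))
  lab[chaotic] <- "chaotic"
  lab[ok & is.na(lab) & map$fli < ref0 - margin_resonant] <- "resonant"
  lab[ok & is.na(lab)] <- "regular"
  out <- dplyr::mutate(map, label = lab)
  attr(out, "fli_reference") <- references
  out
}

#' Reference FLI curve of a calibration ensemble
#'
#' Median FLI as a function of time over a thinned slice grid at a chosen
#' coupling: with \code{epsilon = 0} this is the integrable tangent-growth
#' baseline produced by anharmonic shear alone; with \code{epsilon = 1} it
#' is the strongly chaotic exemplar. Dissociation events are disabled for
#' the integrable reference; for coupled references the median at each time
#' is taken over cells still undissociated then.
#'
#' @param params a \code{\link{bunker_params}} object.
#' @param theta angle slice.
#' @param t_horizon horizon, ps.
#' @param n thinned grid resolution.
#' @param epsilon coupling of the calibration ensemble.
#' @return tibble with columns \code{t} (ps) and \code{fli}. For the
#'   integrable ensemble this is the median FLI-versus-time curve (made
#'   non-decreasing). For a coupled, dissociating ensemble it is the median
#'   frozen FLI as a function of the dissociation time — the exemplar
#'   against which a cell frozen at the same time is compared.
#' @export
fli_reference_curve <- function(params, theta = c(pi / 2, pi / 2, 0),
                                t_horizon = 40, n = 10, epsilon = 0) {
  p0 <- params; p0$epsilon <- epsilon
  slice <- angle_slice_grid(p0, theta = theta, n = c(n, n))
  pv <- par_vector(p0)
  v0 <- rep(1, 6) / sqrt(6)
  dt <- t_horizon / 80
  tgrid <- seq(0, t_horizon, by = dt)
  if (epsilon == 0) {
    curves <- list()
    for (i in which(slice$feasible)) {
      res <- integrate_cpp(as.numeric(slice[i, phase_cols]), pv,
                           ps_to_au(t_horizon), ps_to_au(dt), 1e-10, 1e-10,
                           FALSE, TRUE, v0, FALSE)
      curves[[length(curves) + 1]] <- res$fli
    }
    fli <- apply(do.call(cbind, curves), 1, stats::median)
    return(tibble::tibble(t = tgrid, fli = cummax(fli)))
  }
  # coupled exemplar: frozen FLI against effective (dissociation) time
  te <- numeric(); fe <- numeric()
  for (i in which(slice$feasible)) {
    res <- integrate_cpp(as.numeric(slice[i, phase_cols]), pv,
                         ps_to_au(t_horizon), ps_to_au(dt), 1e-10, 1e-10,
                         TRUE, TRUE, v0, FALSE)
    te <- c(te, if (res$dissociated) au_to_ps(res$lifetime) else t_horizon)
    fe <- c(fe, res$fli_final)
  }
  ord <- order(te)
  te <- te[ord]; fe <- fe[ord]
  # binned running medians over effective time
  nb <- max(4, min(16, floor(length(te) / 8)))
  qs <- unique(stats::quantile(te, probs = seq(0, 1, length.out = nb + 1)))
  bin <- cut(te, qs, include.lowest = TRUE)
  tm <- tapply(te, bin, stats::median)
  fm <- tapply(fe, bin, stats::median)
  ok <- is.finite(tm) & is.finite(fm)
  tibble::tibble(t = c(0, as.numeric(tm[ok])),
                 fli = cummax(c(0, as.numeric(fm[ok]))))
}

#' Extract a resonance ridge from an FLI map
#'
#' Within a window of \eqn{J_1} (or \eqn{J_2}), finds per grid row the
#' action of extreme FLI contrast against the row median — the visible
#' signature of a resonance line (librational cells depress the FLI below
#' the non-resonant background at small coupling) — and returns the median
#' extracted position across rows.
#'
#' @param map a \code{\link{compute_fli_map}} result.
#' @param axis \code{"J1"} for a vertical line, \code{"J2"} horizontal.
#' @param window numeric range of the scanned action.
#' @param other_range range of the transverse action used for the rows.
#' @return list with \code{position} (median extracted action),
#'   \code{per_row} (tibble), and \code{cell} (grid spacing).
#' @export
map_ridge <- function(map, axis = c("J1", "J2"), window,
                      other_range = NULL) {
  axis <- match.arg(axis)
  other <- if (axis == "J1") "J2" else "J1"
  df <- dplyr::filter(tibble::as_tibble(map), .data$feasible,
                      .data[[axis]] >= window[1], .data[[axis]] <= window[2])
  if (!is.null(other_range))
    df <- dplyr::filter(df, .data[[other]] >= other_range[1],
                        .data[[other]] <= other_range[2])
  rowvar <- if (axis == "J1") "j" else "i"
  per_row <- df |>
    dplyr::group_by(.data[[rowvar]]) |>
    dplyr::filter(dplyr::n() >= 5) |>
    dplyr::mutate(dev = abs(.data$fli - stats::median(.data$fli))) |>
    dplyr::slice_max(.data$dev, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  vals <- sort(unique(map[[axis]]))
  list(position = stats::median(per_row[[axis]]),
       per_row = per_row,
       cell = stats::median(diff(vals)))
}

#' Chirikov resonance-overlap threshold
#'
#' Pendulum-approximation estimate of the coupling strength at which two
#' neighbouring stretch-bend resonances overlap, signalling widespread
#' chaos. Each resonance \eqn{(l, 0, -m)} (or \eqn{(0, l, -m)}) has
#' half-width \eqn{\Delta J = 2\sqrt{\epsilon |V_{res}(J)| / |\partial^2 H_0
#' /\partial J^2|}} along its fast action, with \eqn{|\partial^2 H_0/
#' \partial J_k^2| = \omega_k^2 / 2 D_k} and \eqn{V_{res}} the resonant
#' Fourier amplitude of the kinetic coupling evaluated numerically on the
#' resonant torus; \eqn{\epsilon^*} solves (sum of half-widths) =
#' (action-space distance between the lines). The evaluation torus of each
#' resonance sits on its line at the ensemble energy, the remaining energy
#' split equally between the other two modes.
#'
#' @param params a \code{\link{bunker_params}} object.
#' @param res1 primary resonance vector; default the dominant (1, 0, -1).
#' @param res2 neighbouring resonance; default (2, 0, -1), the nearest
#'   stretch-bend neighbour with a non-vanishing first-order coupling
#'   coefficient (the harmonic bend only carries first harmonics).
#' @param max_order,n_theta passed to \code{\link{fourier_table}}.
#' @return list of class \code{chirikov_estimate}: \code{epsilon_star},
#'   \code{distance} (hbar), per-resonance amplitudes (cm^-1), width
#'   coefficients and evaluation tori.
#' @export
chirikov_threshold <- function(params, res1 = c(1, 0, -1),
                               res2 = c(2, 0, -1), max_order = 10,
                               n_theta = 256) {
  info <- lapply(list(res1, res2), function(v) {
    stretch <- if (v[1] != 0 && v[2] == 0) 1L
               else if (v[1] == 0 && v[2] != 0) 2L
               else stop("resonance ", resvec_label(v),
                         " is not a stretch-bend resonance (l,0,-m)/(0,l,-m)")
    if (v[3] == 0) stop("resonance ", resvec_label(v), " has no bend component")
    co <- line_coef(v, params)
    jline <- if (stretch == 1) co$C / co$A else co$C / co$B
    if (jline < 0 || jline >= j_max(params)[stretch])
      stop("resonance ", resvec_label(v), " lies outside the bound domain")
    list(v = v, stretch = stretch, jline = jline)
  })
  if (info[[1]]$stretch != info[[2]]$stretch)
    stop("the two resonances must involve the same stretching mode so ",
         "their widths overlap along one action axis")
  ks <- info[[1]]$stretch
  M <- params$omega[ks]^2 / (2 * params$D[ks])   # |d2 H0 / dJ^2|, cm^-1/hbar^2
  est <- lapply(info, function(inf) {
    J <- torus_on_line(params, inf$stretch, inf$jline)
    tab <- fourier_table(params, J, max_order = max_order, n_theta = n_theta)
    pair <- if (inf$stretch == 1) "13" else "23"
    lstretch <- inf$v[inf$stretch]
    amp <- resonant_amplitude(tab, pair, lstretch, -1L)
    if (amp <= 0)
      stop("resonant Fourier coefficient of ", resvec_label(inf$v),
           " vanishes on the evaluation torus")
    list(J = J, amplitude = amp, width_coef = 2 * sqrt(amp / M))
  })
  d <- abs(info[[1]]$jline - info[[2]]$jline)
  eps_star <- overlap_epsilon(est[[1]]$amplitude, est[[2]]$amplitude, M, M, d)
  out <- list(epsilon_star = eps_star, distance = d, M = M,
              res1 = res1, res2 = res2,
              J1_line = info[[1]]$jline, J2_line = info[[2]]$jline,
              amplitude1 = est[[1]]$amplitude, amplitude2 = est[[2]]$amplitude,
              torus1 = est[[1]]$J, torus2 = est[[2]]$J)
  class(out) <- "chirikov_estimate"
  out
}

# Torus on a stretch-bend resonance line at the ensemble energy: the
# resonant stretch action is fixed by the line; the remaining energy is
# split equally between the other two modes (zeroth-order bookkeeping).
torus_on_line <- function(params, stretch, jline) {
  w <- params$omega; D <- params$D
  e_line <- w[stretch] * jline * (1 - w[stretch] * jline / (4 * D[stretch]))
  e_rest <- params$E - e_line
  if (e_rest <= 0) stop("resonant torus infeasible at the ensemble energy")
  other <- if (stretch == 1) 2L else 1L
  e_half <- e_rest / 2
  # invert E = w J (1 - w J / 4D) for the other stretch (smaller root)
  disc <- 1 - e_half / D[other]
  if (disc < 0) stop("resonant torus infeasible: other stretch unbound")
  j_other <- (2 * D[other] / w[other]) * (1 - sqrt(disc))
  J <- numeric(3)
  J[stretch] <- jline
  J[other] <- j_other
  J[3] <- e_half / w[3]
  J
}

#' @export
print.chirikov_estimate <- function(x, ...) {
  cat(sprintf("Chirikov overlap estimate: epsilon* = %.3f\n", x$epsilon_star))
  cat(sprintf("  %s at J = %.3f (V = %.1f cm^-1), %s at J = %.3f (V = %.1f cm^-1)\n",
              resvec_label(x$res1), x$J1_line, x$amplitude1,
              resvec_label(x$res2), x$J2_line, x$amplitude2))
  cat(sprintf("  line separation %.3f hbar\n", x$distance))
  invisible(x)
}

#' Overlap coupling from widths and separation
#'
#' Solves \eqn{2\sqrt{\epsilon V_1/M_1} + 2\sqrt{\epsilon V_2/M_2} = d} for
#' \eqn{\epsilon}. As either amplitude tends to zero with the geometry
#' fixed, the threshold diverges.
#'
#' @param V1,V2 resonant amplitudes (cm^-1).
#' @param M1,M2 anharmonicity curvatures \eqn{|\partial^2 H_0/\partial
#'   J^2|} (cm^-1 / hbar^2).
#' @param d action-space separation of the lines (hbar).
#' @return the overlap coupling \eqn{\epsilon^*} (dimensionless).
#' @export
overlap_epsilon <- function(V1, V2, M1, M2, d) {
  (d / (2 * sqrt(V1 / M1) + 2 * sqrt(V2 / M2)))^2
}
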