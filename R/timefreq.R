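# Continuous Morlet wavelet transform of a complex signal, FFT-based.
# Returns the modulus matrix (n_scales x n). Frequencies are angular, in
# the same units as 1/dt. No dedicated CWT package is available in the
# stack, so the standard analytic-Morlet transform is implemented here
# directly on top of stats::fft.
morlet_cwt_mod <- function(z, dt, omega_grid, omega0 = 6) {
  n <- length(z)
  # pad past the widest wavelet support to avoid wrap-around
  pad <- ceiling(8 * (omega0 / min(omega_grid)) / dt)
  N <- 2^ceiling(log2(n + pad))
  zhat <- stats::fft(c(z, rep(0, N - n)))
  wk <- 2 * pi * (0:(N - 1)) / (N * dt)
  wk <- ifelse(0:(N - 1) <= N / 2, wk, wk - 2 * pi / dt)
  mod <- matrix(0, length(omega_grid), n)
  for (j in seq_along(omega_grid)) {
    s <- omega0 / omega_grid[j]
    # L1 normalisation: a pure tone of frequency w peaks exactly at s = w0/w
    psi <- exp(-0.5 * (s * wk - omega0)^2) * (wk > 0)
    w <- stats::fft(zhat * psi, inverse = TRUE) / N
    mod[j, ] <- Mod(w[seq_len(n)])
  }
  mod
}

# Ridge of a modulus matrix: per time sample the scale of maximum modulus,
# refined by log-parabolic interpolation across neighbouring scales.
ridge_extract <- function(mod, omega_grid) {
  idx <- max.col(t(mod), ties.method = "first")
  ns <- length(omega_grid)
  lw <- log(omega_grid)
  out <- lw[idx]
  inner <- idx > 1 & idx < ns
  if (any(inner)) {
    ii <- which(inner)
    y0 <- log(pmax(mod[cbind(idx[ii] - 1, ii)], 1e-300))
    y1 <- log(pmax(mod[cbind(idx[ii], ii)], 1e-300))
    y2 <- log(pmax(mod[cbind(idx[ii] + 1, ii)], 1e-300))
    den <- y0 - 2 * y1 + y2
    shift <- ifelse(abs(den) > 0, 0.5 * (y0 - y2) / den, 0)
    shift <- pmin(pmax(shift, -0.5), 0.5)
    dlw <- lw[2] - lw[1]
    out[ii] <- lw[idx[ii]] + shift * dlw
  }
  list(omega = exp(out), amp = mod[cbind(idx, seq_len(ncol(mod)))])
}

#' Wavelet ridge frequencies of a trajectory
#'
#' Instantaneous mode frequencies \eqn{\Omega_k(t)} by continuous Morlet
#' wavelet transform of the per-mode complex signals
#' \eqn{z_k(t) = \sqrt{2 J_k(t)}\, e^{i \theta_k(t)}}; at each time the
#' ridge (scale of maximum transform modulus) gives the dominant frequency.
#' The bend frequency is taken from its own ridge rather than assumed equal
#' to \eqn{\omega_3}, so the analysis generalises to anharmonic bends (for
#' this model the two agree). Samples within one wavelet support of either
#' end are flagged as edge-affected.
#'
#' @param traj a \code{\link{propagate}} result with a phase-space series
#'   sampled at no coarser than 2 fs, at least 1 ps long.
#' @param params the \code{\link{bunker_params}} used for propagation.
#' @param freq_range scanned frequency band, cm^-1.
#' @param voices scales per octave.
#' @param omega0 Morlet centre-frequency parameter.
#' @param smooth temporal ridge-regularisation window, ps (running median
#'   over the ridge frequencies; 0 disables). The default, about two bend
#'   periods, suppresses voice-quantisation jitter without masking genuine
#'   frequency drift.
#' @return tibble of class \code{freq_track}: \code{t} (ps),
#'   \code{Omega1..Omega3} (cm^-1), ratios \code{f1 = Omega1/Omega3},
#'   \code{f2 = Omega2/Omega3}, ridge amplitudes \code{amp1..amp3} and an
#'   \code{edge} flag.
#' @export
wavelet_frequencies <- function(traj, params, freq_range = c(300, 1400),
                                voices = 32, omega0 = 6, smooth = 0.1) {
  if (is.null(traj$phase)) stop("trajectory was propagated without series")
  tt <- traj$times
  if (length(tt) < 8) stop("trajectory too short for wavelet analysis")
  dt_ps <- stats::median(diff(tt))
  if (dt_ps > 0.002 + 1e-12)
    stop("wavelet analysis requires sampling at <= 2 fs, got ",
         signif(dt_ps * 1000, 3), " fs")
  if (max(tt) < 1) stop("wavelet analysis requires >= 1 ps of signal")
  dt <- ps_to_au(dt_ps)
  aa <- phase_to_act(traj$phase, params, clamp = TRUE)
  n_oct <- log2(freq_range[2] / freq_range[1])
  f_cm <- freq_range[1] * 2^(seq(0, n_oct, by = 1 / voices))
  omega_grid <- cm_to_hartree(f_cm)   # angular frequency, au (hbar = 1)
  out <- tibble::tibble(t = tt)
  nsm <- if (smooth > 0) {
    w <- round(smooth / dt_ps)
    max(3, w + (w + 1) %% 2)    # odd window
  } else 0
  for (k in 1:3) {
    z <- sqrt(2 * aa[[paste0("J", k)]]) * exp(1i * aa[[paste0("theta", k)]])
    mod <- morlet_cwt_mod(z, dt, omega_grid, omega0)
    rd <- ridge_extract(mod, omega_grid)
    om <- hartree_to_cm(rd$omega)
    if (nsm > 0 && length(om) > nsm)
      om <- as.numeric(stats::runmed(om, nsm, endrule = "median"))
    out[[paste0("Omega", k)]] <- om
    out[[paste0("amp", k)]] <- rd$amp
  }
  out$f1 <- out$Omega1 / out$Omega3
  out$f2 <- out$Omega2 / out$Omega3
  # edge margin: one wavelet support (~2 s) at the slowest scanned scale
  margin <- au_to_ps(2 * omega0 / min(omega_grid))
  out$edge <- out$t < margin | out$t > max(tt) - margin
  attr(out, "dt") <- dt_ps
  attr(out, "freq_range") <- freq_range
  attr(out, "lifetime") <- traj$lifetime
  class(out) <- c("freq_track", class(out))
  out
}

#' Visitation density in frequency-ratio space
#'
#' Accumulates per-sample visits of \eqn{(f_1, f_2)} cells over a set of
#' frequency tracks — the frequency-ratio-space (FRS) density map in which
#' resonances are rational lines and junctions rational points. Edge-flagged
#' samples are excluded.
#'
#' @param tracks a \code{freq_track} or list of them.
#' @param cell cell width on each ratio axis.
#' @param f1_range,f2_range axis ranges; defaults span the data.
#' @return tibble of class \code{frs_density}: cell centres \code{f1, f2},
#'   \code{count}, \code{density} (normalised over occupied cells) and
#'   \code{log_density} (natural log).
#' @export
ratio_density <- function(tracks, cell = 0.01, f1_range = NULL,
                          f2_range = NULL) {
  if (inherits(tracks, "freq_track")) tracks <- list(tracks)
  if (length(tracks) == 0) stop("empty track selection")
  f1 <- unlist(lapply(tracks, function(x) x$f1[!x$edge]))
  f2 <- unlist(lapply(tracks, function(x) x$f2[!x$edge]))
  if (length(f1) == 0) stop("no non-edge samples in the selected tracks (",
                            length(tracks), " tracks)")
  if (is.null(f1_range)) f1_range <- range(f1)
  if (is.null(f2_range)) f2_range <- range(f2)
  i1 <- floor((f1 - f1_range[1]) / cell)
  i2 <- floor((f2 - f2_range[1]) / cell)
  ok <- f1 >= f1_range[1] & f1 <= f1_range[2] &
        f2 >= f2_range[1] & f2 <= f2_range[2]
  key <- paste(i1[ok], i2[ok])
  tab <- table(key)
  ij <- do.call(rbind, strsplit(names(tab), " "))
  out <- tibble::tibble(
    f1 = f1_range[1] + (as.integer(ij[, 1]) + 0.5) * cell,
    f2 = f2_range[1] + (as.integer(ij[, 2]) + 0.5) * cell,
    count = as.integer(tab))
  out$density <- out$count / sum(out$count)
  out$log_density <- log(out$density)
  attr(out, "cell") <- cell
  class(out) <- c("frs_density", class(out))
  out
}

#' Detect resonance locking near junctions
#'
#' Finds contiguous intervals during which both frequency ratios of a track
#' stay within \code{tol} of a junction's rational point \eqn{(f_1, f_2)}
#' for at least \code{min_dwell}. When several junctions claim the same
#' sample, it is assigned to the junction with the smaller ratio residual.
#'
#' @param track a \code{\link{wavelet_frequencies}} result.
#' @param junctions data frame with columns \code{label, f1, f2}; e.g. the
#'   output of \code{\link{junctions}}.
#' @param tol tolerance on each ratio.
#' @param min_dwell minimum event duration, ps (default 0.25 ps, about five
#'   bend periods).
#' @return tibble of locking events: \code{junction}, \code{start},
#'   \code{end}, \code{duration} (ps). Zero rows when no locking occurs.
#' @export
detect_locking <- function(track, junctions, tol = 0.02, min_dwell = 0.25) {
  if (nrow(junctions) == 0) stop("junction list is empty")
  nt <- nrow(track)
  resid <- matrix(Inf, nt, nrow(junctions))
  for (j in seq_len(nrow(junctions))) {
    r1 <- abs(track$f1 - junctions$f1[j])
    r2 <- abs(track$f2 - junctions$f2[j])
    within <- r1 <= tol & r2 <= tol & !track$edge
    resid[within, j] <- sqrt(r1[within]^2 + r2[within]^2)
  }
  best <- apply(resid, 1, which.min)
  best[!is.finite(apply(resid, 1, min))] <- NA_integer_
  r <- rle(ifelse(is.na(best), 0L, as.integer(best)))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  rows <- list()
  for (i in seq_along(r$values)) {
    if (r$values[i] == 0) next
    t0 <- track$t[starts[i]]; t1 <- track$t[ends[i]]
    if (t1 - t0 < min_dwell) next
    rows[[length(rows) + 1]] <- tibble::tibble(
      junction = junctions$label[r$values[i]],
      start = t0, end = t1, duration = t1 - t0)
  }
  if (length(rows) == 0)
    return(tibble::tibble(junction = character(), start = numeric(),
                          end = numeric(), duration = numeric()))
  dplyr::bind_rows(rows)
}

#' Longest and total locking time of a track
#'
#' @param events output of \code{\link{detect_locking}}.
#' @return one-row tibble with \code{longest} and \code{total} locking
#'   times (ps; zero when no events).
#' @export
locking_times <- function(events) {
  tibble::tibble(longest = if (nrow(events)) max(events$duration) else 0,
                 total = if (nrow(events)) sum(events$duration) else 0)
}

#' Mode of a locking-time distribution
#'
#' Histogram mode (midpoint of the fullest bin) of per-trajectory locking
#' times; zero-locking trajectories are excluded.
#'
#' @param x numeric vector of locking times, ps.
#' @param binwidth histogram bin width, ps (default a few times the minimum
#'   dwell, giving stable counts for ensembles of a few hundred tracks).
#' @return the mode, ps.
#' @export
locking_mode <- function(x, binwidth = 1) {
  x <- x[x > 0]
  if (length(x) == 0) stop("no positive locking times")
  breaks <- seq(0, max(x) + binwidth, by = binwidth)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  h$mids[which.max(h$counts)]
}

#' Resonance-locking survey of undissociated trajectories
#'
#' Runs the full time-frequency pipeline at study scale: seeded
#' microcanonical ensembles are propagated in batches until at least
#' \code{n_survivors} trajectories remain undissociated at \code{t_final};
#' each survivor is re-propagated with fine output sampling, its wavelet
#' ridge frequencies extracted, and locking near the supplied junctions
#' detected. Dissociating trajectories are discarded.
#'
#' @param params a \code{\link{bunker_params}} object.
#' @param junctions junction tibble (default \code{\link{junctions}}).
#' @param n_survivors target number of undissociated trajectories.
#' @param t_final horizon, ps.
#' @param seed master seed; batch seeds are derived from it.
#' @param batch ensemble size per batch.
#' @param max_batches stop after this many batches even short of target.
#' @param tol,min_dwell locking criteria (see \code{\link{detect_locking}}).
#' @param smooth ridge smoothing window, ps.
#' @return tibble with one row per surviving trajectory: \code{seed},
#'   \code{id}, \code{longest}, \code{total} locking times (ps).
#' @export
locking_survey <- function(params, junctions = NULL, n_survivors = 200,
                           t_final = 40, seed = 1L, batch = 400,
                           max_batches = 10, tol = 0.02, min_dwell = 0.25,
                           smooth = 0.5) {
  if (is.null(junctions)) junctions <- arnoldweb::junctions(params)
  rows <- list()
  got <- 0L
  for (b in seq_len(max_batches)) {
    bseed <- (as.integer(seed) * 1000L + b) %% .Machine$integer.max
    ics <- sample_energy_shell(params, batch, seed = bseed)
    res <- propagate_ensemble(ics[phase_cols], params, t_final = t_final,
                              dt_out = 0.5, events = TRUE)
    for (i in which(!res$dissociated)) {
      tr <- propagate(ics[i, phase_cols], params, t_final = t_final,
                      dt_out = 0.002, events = FALSE)
      trk <- wavelet_frequencies(tr, params, smooth = smooth)
      lt <- locking_times(detect_locking(trk, junctions, tol = tol,
                                         min_dwell = min_dwell))
      rows[[length(rows) + 1]] <- dplyr::mutate(lt, seed = bseed, id = i)
    }
    got <- got + sum(!res$dissociated)
    if (got >= n_survivors) break
  }
  dplyr::bind_rows(rows)
}
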