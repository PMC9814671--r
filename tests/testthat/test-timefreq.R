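# synthetic freq_track builder for the locking logic tests
fake_track <- function(t, f1, f2) {
  trk <- tibble::tibble(t = t, Omega1 = f1 * 632, Omega2 = f2 * 632,
                        Omega3 = 632, f1 = f1, f2 = f2,
                        amp1 = 1, amp2 = 1, amp3 = 1, edge = FALSE)
  class(trk) <- c("freq_track", class(trk))
  trk
}

test_that("ridge extraction recovers a pure tone within grid resolution", {
  dt <- ps_to_au(0.002)
  tt <- seq(0, ps_to_au(4), by = dt)
  for (nu in c(500, 800, 1200)) {
    z <- exp(1i * cm_to_hartree(nu) * tt)
    f_cm <- 300 * 2^(seq(0, log2(1400 / 300), by = 1 / 32))
    mod <- arnoldweb:::morlet_cwt_mod(z, dt, cm_to_hartree(f_cm))
    rd <- arnoldweb:::ridge_extract(mod, cm_to_hartree(f_cm))
    mid <- seq(500, length(tt) - 500)
    expect_equal(stats::median(hartree_to_cm(rd$omega[mid])), nu,
                 tolerance = 0.005)
  }
})

test_that("ridge tracks a linear chirp within 2% away from edges", {
  dt <- ps_to_au(0.002)
  tt <- seq(0, ps_to_au(10), by = dt)
  w0 <- cm_to_hartree(600); w1 <- cm_to_hartree(700)
  rate <- (w1 - w0) / max(tt)
  z <- exp(1i * (w0 * tt + 0.5 * rate * tt^2))
  f_cm <- 300 * 2^(seq(0, log2(1400 / 300), by = 1 / 32))
  mod <- arnoldweb:::morlet_cwt_mod(z, dt, cm_to_hartree(f_cm))
  rd <- arnoldweb:::ridge_extract(mod, cm_to_hartree(f_cm))
  inst <- hartree_to_cm(w0 + rate * tt)
  mid <- seq(1000, length(tt) - 1000)
  expect_lt(max(abs(hartree_to_cm(rd$omega[mid]) - inst[mid]) / inst[mid]),
            0.02)
})

test_that("integrable trajectories give constant ridge frequencies equal to
           the nonlinear frequencies", {
  p0 <- params_eps(0)
  aa <- tibble::tibble(J1 = 4, J2 = 5, J3 = 2,
                       theta1 = 0.3, theta2 = 1.2, theta3 = 2.2)
  tr <- propagate(aa, p0, t_final = 4, dt_out = 0.002, events = FALSE)
  trk <- wavelet_frequencies(tr, p0)
  om <- nonlinear_frequencies(aa, p0)
  mid <- !trk$edge
  for (k in 1:3) {
    ridge <- trk[[paste0("Omega", k)]][mid]
    expect_lt(max(abs(ridge - om[[paste0("Omega", k)]])) /
                om[[paste0("Omega", k)]], 0.01)
  }
  expect_error(wavelet_frequencies(
    propagate(aa, p0, t_final = 2, dt_out = 0.01, events = FALSE), p0),
    "2 fs")
})

test_that("locking events are segmented and attributed correctly", {
  jn <- junctions(base_params)
  t <- seq(0, 10, by = 0.01)
  # locked at (1,1) for the first 2 ps, then far away
  trk <- fake_track(t, ifelse(t <= 2, 1, 1.3), ifelse(t <= 2, 1, 1.3))
  ev <- detect_locking(trk, jn)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration, 2, tolerance = 0.02)
  expect_equal(ev$junction, "M[1,0,-1|0,1,-1]")
  lt <- locking_times(ev)
  expect_equal(lt$longest, lt$total)

  # two separated 1 ps episodes: longest 1, total 2
  in1 <- (t >= 1 & t <= 2) | (t >= 5 & t <= 6)
  trk2 <- fake_track(t, ifelse(in1, 1.5, 1.2), ifelse(in1, 1.5, 1.2))
  lt2 <- locking_times(detect_locking(trk2, jn))
  expect_equal(lt2$longest, 1, tolerance = 0.02)
  expect_equal(lt2$total, 2, tolerance = 0.03)

  # sub-dwell events are dropped
  brief <- (t >= 1 & t <= 1.1)
  trk3 <- fake_track(t, ifelse(brief, 1, 2), ifelse(brief, 1, 2))
  expect_equal(nrow(detect_locking(trk3, jn)), 0)

  # overlapping claims resolve to the smaller residual
  trk4 <- fake_track(t, rep(1.005, length(t)), rep(1.008, length(t)))
  ev4 <- detect_locking(trk4, jn, tol = 0.5)
  expect_equal(unique(ev4$junction), "M[1,0,-1|0,1,-1]")
})

test_that("enlarging the tolerance never decreases the total locking time", {
  jn <- junctions(base_params)
  set.seed(41)
  t <- seq(0, 20, by = 0.01)
  f1 <- 1 + 0.05 * sin(t) + stats::rnorm(length(t), 0, 0.01)
  f2 <- 1 + 0.04 * cos(1.3 * t) + stats::rnorm(length(t), 0, 0.01)
  trk <- fake_track(t, f1, f2)
  tots <- vapply(c(0.01, 0.02, 0.05, 0.1), function(tol)
    locking_times(detect_locking(trk, jn, tol = tol))$total, numeric(1))
  expect_true(all(diff(tots) >= 0))
})

test_that("ratio densities concentrate where the tracks sit", {
  t <- seq(0, 3, by = 0.01)
  jn <- junctions(base_params)
  d1 <- ratio_density(fake_track(t, rep(1, length(t)), rep(1, length(t))),
                      cell = 0.05, f1_range = c(0.5, 2), f2_range = c(0.5, 2))
  expect_equal(nrow(d1), 1)
  expect_equal(d1$density, 1)
  expect_equal(c(d1$f1, d1$f2), c(1.025, 1.025))
  # two disjoint single-cell tracks share the mass equally
  d2 <- ratio_density(list(
    fake_track(t, rep(1, length(t)), rep(1, length(t))),
    fake_track(t, rep(1.5, length(t)), rep(1.5, length(t)))),
    cell = 0.05, f1_range = c(0.5, 2), f2_range = c(0.5, 2))
  expect_equal(nrow(d2), 2)
  expect_equal(d2$density, c(0.5, 0.5))
  expect_equal(d2$log_density, log(d2$density))
  expect_error(ratio_density(list()), "empty")
})

test_that("integrable ensembles occupy isolated ratio cells", {
  p0 <- params_eps(0)
  set.seed(43)
  tracks <- lapply(1:3, function(i) {
    aa <- random_aa(1, seed = 50 + i, jmax_frac = 0.5)
    aa$J3 <- aa$J3 + 1
    tr <- propagate(aa, p0, t_final = 2, dt_out = 0.002, events = FALSE)
    wavelet_frequencies(tr, p0)
  })
  d <- ratio_density(tracks, cell = 0.02)
  # each constant-ratio trajectory contributes a tight cluster
  expect_lte(nrow(d), 9)
  expect_gte(sum(d$count > 100), 3)
})

test_that("locking mode summarises the distribution histogram", {
  x <- c(0.3, rep(2.2, 5), rep(2.4, 3), 7, 0, 0)
  expect_equal(locking_mode(x), 2.5)
  expect_equal(locking_mode(x, binwidth = 0.5), 2.25)
  expect_error(locking_mode(c(0, 0)), "no positive")
})
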