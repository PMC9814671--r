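test_that("uncoupled bend-only motion conserves its action for 40 ps", {
  p0 <- params_eps(0)
  aa <- tibble::tibble(J1 = 0.5, J2 = 0.4, J3 = 6,
                       theta1 = 0.3, theta2 = 2.1, theta3 = 1.0)
  tr <- propagate(aa, p0, t_final = 40, dt_out = 0.5, events = FALSE)
  acts <- trajectory_actions(tr, p0)
  expect_lt(max(abs(acts$J3 - 6)) / 6, 1e-8)
  expect_false(tr$dissociated)
  expect_identical(tr$lifetime, Inf)
  expect_true(all(diff(tr$times) > 0))
})

test_that("an unbound stretch dissociates with a monotone exit", {
  p0 <- params_eps(0)
  # kinetic energy above D1 in mode 1 alone
  pt <- tibble::tibble(q1 = p0$q0[1], q2 = p0$q0[2], q3 = p0$q0[3],
                       p1 = sqrt(2.2 * p0$D_au[1] / p0$G0[1, 1]),
                       p2 = 0, p3 = 0)
  tr <- propagate(pt, p0, t_final = 5, dt_out = 0.01)
  expect_true(tr$dissociated)
  expect_equal(tr$bond, 1)
  expect_lt(tr$lifetime, 1)
  q1 <- tr$phase$q1
  expect_true(all(diff(q1) > 0))
  expect_gt(max(q1), 7.49)
})

test_that("lifetimes are stable to 1 fs under a tighter tolerance", {
  p <- base_params
  g <- cached("slice32", angle_slice_grid(p, n = c(32, 32)))
  ic <- g[g$feasible, ][10, ]
  t1 <- propagate(ic, p, t_final = 10, rtol = 1e-10, atol = 1e-10,
                  dt_out = 0.1, series = FALSE)$lifetime
  t2 <- propagate(ic, p, t_final = 10, rtol = 5e-11, atol = 5e-11,
                  dt_out = 0.1, series = FALSE)$lifetime
  expect_true(is.finite(t1))
  expect_lt(abs(t1 - t2), 1e-3)
})

test_that("integration is time-reversible within the drift budget", {
  p <- base_params
  aa <- tibble::tibble(J1 = 5, J2 = 4, J3 = 2,
                       theta1 = 1, theta2 = 2, theta3 = 3)
  fw <- propagate(aa, p, t_final = 5, dt_out = 5, events = FALSE)
  end <- tibble::as_tibble(fw$final)
  flip <- dplyr::mutate(end, p1 = -p1, p2 = -p2, p3 = -p3)
  bw <- propagate(flip, p, t_final = 5, dt_out = 5, events = FALSE)
  start <- act_to_phase(aa, p)
  back <- tibble::as_tibble(bw$final)
  expect_equal(as.numeric(back[c("q1", "q2", "q3")]),
               as.numeric(start[c("q1", "q2", "q3")]), tolerance = 1e-7)
  expect_equal(-as.numeric(back[c("p1", "p2", "p3")]),
               as.numeric(start[c("p1", "p2", "p3")]), tolerance = 1e-7)
})

test_that("measured orbital periods match the nonlinear frequencies", {
  p0 <- params_eps(0)
  for (J in c(2, 8)) {
    aa <- tibble::tibble(J1 = J, J2 = 0, J3 = 0,
                         theta1 = 0.01, theta2 = 0, theta3 = 0)
    om <- nonlinear_frequencies(aa, p0)$Omega1
    tr <- propagate(aa, p0, t_final = 10, dt_out = 2e-4, events = FALSE)
    x <- tr$phase$q1 - p0$q0[1]
    up <- which(x[-1] > 0 & x[-length(x)] <= 0)
    period <- mean(diff(tr$times[up]))
    expect_equal(period, au_to_ps(2 * pi / cm_to_hartree(om)),
                 tolerance = 1e-3)
  }
})

test_that("FLI series is monotone and distinguishes dynamical regimes", {
  p0 <- params_eps(0)
  # isochronous bend only: no tangent growth beyond bounded oscillation
  bend <- tibble::tibble(J1 = 0, J2 = 0, J3 = 8,
                         theta1 = 0, theta2 = 0, theta3 = 0.4)
  tr_b <- propagate(bend, p0, t_final = 40, dt_out = 0.5, events = FALSE,
                    tangent = TRUE)
  expect_true(all(diff(tr_b$fli) >= 0))
  # bounded: after the first oscillations the sup stops growing entirely
  expect_lt(tr_b$fli_final - tr_b$fli[tr_b$times == 2], 0.05)
  expect_lt(tr_b$fli_final, 2.5)

  # integrable shear from two excited anharmonic stretches: ~log10(t) growth
  tw <- tibble::tibble(J1 = 6, J2 = 6, J3 = 1,
                       theta1 = 1, theta2 = 2, theta3 = 3)
  tr_i <- cached("fli_integrable",
                 propagate(tw, p0, t_final = 40, dt_out = 0.5,
                           events = FALSE, tangent = TRUE))
  expect_true(all(diff(tr_i$fli) >= 0))
  fit <- stats::lm(fli ~ log10(t), data = tibble::tibble(
    t = tr_i$times[-(1:4)], fli = tr_i$fli[-(1:4)]))
  expect_gt(summary(fit)$r.squared, 0.95)

  # full coupling: approximately linear growth, far above the shear curve
  # at matched times (most eps = 1 trajectories dissociate early, which
  # freezes the FLI, so the comparison is made at the event time)
  p1 <- base_params
  g <- cached("slice32", angle_slice_grid(p1, n = c(32, 32)))
  ics <- g[g$feasible, ]
  found <- FALSE
  for (i in seq_len(nrow(ics))) {
    tr_c <- propagate(ics[i, ], p1, t_final = 40, dt_out = 0.5,
                      events = TRUE, tangent = TRUE, series = FALSE)
    t_eff <- min(tr_c$lifetime, 40)
    if (t_eff < 2) next
    found <- TRUE
    ref <- stats::approx(tr_i$times, tr_i$fli, xout = t_eff, rule = 2)$y
    expect_gt(tr_c$fli_final, ref + 2)
    break
  }
  expect_true(found)
})

test_that("energy drift beyond the audit threshold is flagged, not silent", {
  p <- base_params
  aa <- tibble::tibble(J1 = 6, J2 = 6, J3 = 1,
                       theta1 = 1, theta2 = 2, theta3 = 3)
  expect_warning(
    tr <- propagate(aa, p, t_final = 2, dt_out = 0.1, events = FALSE,
                    rtol = 1e-3, atol = 1e-3, drift_tol = 1e-12),
    "drift")
  expect_true(tr$flagged)
})
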