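test_that("zero action maps to the equilibrium point", {
  p <- base_params
  aa <- tibble::tibble(J1 = 0, J2 = 0, J3 = 0,
                       theta1 = 1, theta2 = 2, theta3 = 3)
  ph <- act_to_phase(aa, p)
  expect_equal(as.numeric(ph), c(p$q0, 0, 0, 0), tolerance = 1e-14)
  expect_equal(h0(aa, p)$h0, 0)
})

test_that("action-angle round trip is the identity", {
  p <- base_params
  aa <- random_aa(200)
  back <- phase_to_act(act_to_phase(aa, p), p)
  expect_equal(as.matrix(back), as.matrix(aa), tolerance = 1e-10)
})

test_that("the action equals the (1/2pi) loop integral of p dq", {
  p <- base_params
  nq <- 200001
  th <- seq(0, 2 * pi, length.out = nq)
  for (J in c(1.3, 6.5, 12)) {
    aa <- tibble::tibble(J1 = J, J2 = 0, J3 = 0, theta1 = th,
                         theta2 = 0, theta3 = 0)
    ph <- act_to_phase(aa, p)
    dq <- diff(ph$q1)
    pm <- (ph$p1[-1] + ph$p1[-nq]) / 2
    expect_equal(sum(pm * dq) / (2 * pi), J, tolerance = 1e-8)
  }
  # harmonic bend too
  aa3 <- tibble::tibble(J1 = 0, J2 = 0, J3 = 3.7, theta1 = 0, theta2 = 0,
                        theta3 = th)
  ph3 <- act_to_phase(aa3, p)
  expect_equal(abs(sum((ph3$p3[-1] + ph3$p3[-nq]) / 2 * diff(ph3$q3))) /
                 (2 * pi), 3.7, tolerance = 1e-8)
})

test_that("h0 equals the full Hamiltonian on the uncoupled shell", {
  p0 <- params_eps(0)
  aa <- random_aa(1000, seed = 5)
  h_direct <- ham_energy(act_to_phase(aa, p0), p0)$energy
  expect_equal(h_direct, h0(aa, p0)$h0, tolerance = 1e-8)
  # dissociation limit of a single stretch
  jm <- j_max(p0)
  lim <- tibble::tibble(J1 = jm[1] * (1 - 1e-12), J2 = 0, J3 = 0)
  expect_equal(h0(lim, p0)$h0, p0$D[1], tolerance = 1e-9)
})

test_that("nonlinear frequencies follow the Morse/harmonic frequency map", {
  p <- base_params
  z <- nonlinear_frequencies(tibble::tibble(J1 = 0, J2 = 0, J3 = 0), p)
  expect_equal(c(z$Omega1, z$Omega2, z$Omega3), c(1112, 1040, 632))
  jm <- j_max(p)
  edge <- nonlinear_frequencies(tibble::tibble(J1 = jm[1], J2 = 0, J3 = 0), p)
  expect_equal(edge$Omega1, 0, tolerance = 1e-12)
  # stretch-2 action resonant with the bend
  j2 <- (2 * p$D[2] / p$omega[2]) * (1 - p$omega[3] / p$omega[2])
  r <- nonlinear_frequencies(tibble::tibble(J1 = 0, J2 = j2, J3 = 0), p)
  expect_equal(r$Omega2, 632, tolerance = 1e-10)
  expect_equal(j2, 6.33, tolerance = 0.01)
})

test_that("domain violations raise errors; clamp bounds them instead", {
  p <- base_params
  jm <- j_max(p)
  expect_error(act_to_phase(tibble::tibble(
    J1 = jm[1] + 0.1, J2 = 1, J3 = 1,
    theta1 = 0, theta2 = 0, theta3 = 0), p), "bound")
  expect_error(act_to_phase(tibble::tibble(
    J1 = -0.1, J2 = 1, J3 = 1, theta1 = 0, theta2 = 0, theta3 = 0), p),
    "non-negative")
  unbound <- tibble::tibble(q1 = 6, q2 = p$q0[2], q3 = p$q0[3],
                            p1 = 25, p2 = 0, p3 = 0)
  expect_error(phase_to_act(unbound, p), "unbound")
  cl <- phase_to_act(unbound, p, clamp = TRUE)
  expect_lt(cl$J1, jm[1])
  expect_true(all(is.finite(as.matrix(cl))))
})
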