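test_that("energy-shell samples sit on the shell and are seed-reproducible", {
  p <- base_params
  s1 <- sample_energy_shell(p, 200, seed = 3)
  expect_true(all(abs(s1$energy - p$E) / p$E < 1e-10))
  s2 <- sample_energy_shell(p, 200, seed = 3)
  expect_identical(s1, s2)
  s3 <- sample_energy_shell(p, 200, seed = 4)
  expect_false(any(s1$q1 %in% s3$q1))
})

test_that("coordinate marginal agrees with an independent rejection oracle", {
  p <- base_params
  s <- sample_energy_shell(p, 3000, seed = 9)
  v_pkg <- ham_energy(dplyr::mutate(s, p1 = 0, p2 = 0, p3 = 0), p)$energy
  # independent oracle: rejection-sample q uniformly under V < E with the
  # potential written out directly
  set.seed(1234)
  E <- p$E_au
  vfun <- function(q1, q2, q3) {
    p$D_au[1] * (1 - exp(-p$alpha[1] * (q1 - p$q0[1])))^2 +
    p$D_au[2] * (1 - exp(-p$alpha[2] * (q2 - p$q0[2])))^2 +
    0.5 * p$w_au[3]^2 * (q3 - p$q0[3])^2 / p$G0[3, 3]
  }
  r1 <- sqrt(min(E / p$D_au[1], 1)); r2 <- sqrt(min(E / p$D_au[2], 1))
  lo1 <- p$q0[1] - log(1 + r1) / p$alpha[1]
  lo2 <- p$q0[2] - log(1 + r2) / p$alpha[2]
  a3 <- sqrt(2 * p$G0[3, 3] * E) / p$w_au[3]
  v_oracle <- c()
  while (length(v_oracle) < 3000) {
    q1 <- runif(4000, lo1, p$q_dissoc)
    q2 <- runif(4000, lo2, p$q_dissoc)
    q3 <- runif(4000, max(p$q0[3] - a3, 1e-3), min(p$q0[3] + a3, pi - 1e-3))
    v <- vfun(q1, q2, q3)
    v_oracle <- c(v_oracle, v[v < E])
  }
  ks <- suppressWarnings(
    stats::ks.test(v_pkg, hartree_to_cm(v_oracle[1:3000])))
  expect_gt(ks$p.value, 0.01)
})

test_that("slice grid reproduces the eps = 0 closed form and flags
           infeasible cells", {
  p0 <- params_eps(0)
  g <- angle_slice_grid(p0, n = c(8, 8))
  fe <- g[g$feasible, ]
  e12 <- h0(dplyr::mutate(fe, J3 = 0), p0)$h0
  expect_equal(fe$J3, (p0$E - e12) / p0$omega[3], tolerance = 1e-9)
  # stretch-only energy above E leaves no room for J3 >= 0
  hi <- g[!g$feasible, ]
  expect_gt(nrow(hi), 0)
  e_hi <- h0(dplyr::mutate(hi, J3 = 0), p0)$h0
  expect_true(all(e_hi > p0$E))
})

test_that("the reference cell near the junction is feasible with J3 ~ 1.4-1.5", {
  p0 <- params_eps(0)
  g <- angle_slice_grid(p0, n = c(2, 2), j1_range = c(6.5, 6.6),
                        j2_range = c(6.3, 6.4))
  expect_true(g$feasible[1])
  expect_gt(g$J3[1], 1.4)
  expect_lt(g$J3[1], 1.5)
})

test_that("all feasible cells reproduce E through the full coupled
           Hamiltonian, for coupled slices too", {
  p <- params_eps(0.4)
  g <- angle_slice_grid(p, n = c(12, 12))
  fe <- g[g$feasible, ]
  expect_true(all(abs(fe$energy - p$E) / p$E < 1e-10))
  # round trip through the transform once more at the slice angles
  aa <- dplyr::mutate(fe, theta1 = pi / 2, theta2 = pi / 2, theta3 = 0)
  e2 <- ham_energy(act_to_phase(aa, p), p)$energy
  expect_true(all(abs(e2 - p$E) / p$E < 1e-10))
})

test_that("feasible region is row-contiguous and shrinks past the
           equal-energy contour", {
  p0 <- params_eps(0)
  g <- angle_slice_grid(p0, n = c(24, 24))
  by_row <- split(g$feasible, g$j)
  for (fr in by_row) {
    idx <- which(fr)
    if (length(idx)) expect_equal(idx, seq(min(idx), max(idx)))
  }
  n_feas <- vapply(split(g$feasible, g$i), sum, numeric(1))
  expect_true(all(diff(n_feas) <= 0))
})

test_that("slice specification is validated", {
  p <- base_params
  expect_error(angle_slice_grid(p, n = c(1, 5)), ">= 2")
  expect_error(angle_slice_grid(p, j1_range = c(0, 20)), "bound domain")
})
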