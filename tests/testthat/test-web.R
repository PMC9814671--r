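test_that("stretch-bend resonance lines sit at the analytic actions", {
  p <- base_params
  ln <- resonance_lines(p, max_order = 5)
  v101 <- ln[ln$l == 1 & ln$m == 0 & ln$n == -1, ]
  expect_equal(v101$type, "vertical")
  expect_equal(v101$J_const, 6.5168, tolerance = 1e-4)
  h011 <- ln[ln$l == 0 & ln$m == 1 & ln$n == -1, ]
  expect_equal(h011$type, "horizontal")
  expect_equal(h011$J_const, 6.3329, tolerance = 1e-4)
  # every returned vector is coprime with order <= max_order
  expect_true(all(ln$order <= 5))
  expect_true(all(mapply(function(l, m, n) {
    v <- abs(c(l, m, n)); v <- v[v > 0]
    Reduce(function(a, b) if (b == 0) a else Recall(b, a %% b), v) == 1
  }, ln$l, ln$m, ln$n)))
  expect_error(resonance_lines(p, max_order = 1), ">= 2")
})

test_that("points on a returned line satisfy the resonance condition", {
  p <- base_params
  ln <- resonance_lines(p, max_order = 5)
  sl <- ln[ln$type == "sloped", ][1:5, ]
  for (r in seq_len(nrow(sl))) {
    j1 <- 3
    j2 <- (sl$C[r] - sl$A[r] * j1) / sl$B[r]
    om <- nonlinear_frequencies(tibble::tibble(J1 = j1, J2 = j2, J3 = 0), p)
    resid <- abs(sl$l[r] * om$Omega1 + sl$m[r] * om$Omega2 +
                   sl$n[r] * om$Omega3)
    expect_lt(resid, 1e-9 * p$omega[3])
  }
  # the 1:1 stretch-stretch line passes through points of equal frequency
  ss <- ln[ln$l == 1 & ln$m == -1 & ln$n == 0, ]
  j1 <- 5
  j2 <- (ss$C - ss$A * j1) / ss$B
  om <- nonlinear_frequencies(tibble::tibble(J1 = j1, J2 = j2, J3 = 0), p)
  expect_equal(om$Omega1, om$Omega2, tolerance = 1e-10)
})

test_that("junction locations and labels follow the line intersections", {
  p <- base_params
  jn <- junctions(p)
  m11 <- jn[jn$label == "M[1,0,-1|0,1,-1]", ]
  expect_equal(m11$J1, 6.517, tolerance = 1e-3)
  expect_equal(m11$J2, 6.333, tolerance = 1e-3)
  expect_equal(c(m11$f1, m11$f2), c(1, 1), tolerance = 1e-10)
  m23 <- jn[jn$label == "M[2,0,-3|0,2,-3]", ]
  expect_equal(m23$J1, 2.227, tolerance = 1e-3)
  expect_equal(m23$J2, 1.428, tolerance = 1e-3)
  expect_equal(c(m23$f1, m23$f2), c(1.5, 1.5), tolerance = 1e-10)
  expect_true(all(jn$r == 2))
  expect_true(all(jn$valid))
})

test_that("degenerate junction pairs are rejected", {
  p <- base_params
  expect_error(junctions(p, list(list(c(1, 0, -1), c(2, 0, -2)))), "coprime")
  expect_error(junctions(p, list(list(c(1, 0, -1), c(1, 0, -1)))),
               "dependent")
  expect_error(junctions(p, list(list(c(1, 0, -1), c(2, 0, -1)))),
               "parallel")
})

test_that("combination resonances at a junction satisfy the condition", {
  p <- base_params
  jn <- junctions(p, list(list(c(1, 0, -1), c(0, 1, -1))), combos = TRUE)
  cmb <- jn$combinations[[1]]
  expect_true(all(abs(cmb$mu) + abs(cmb$nu) <= 3))
  om <- nonlinear_frequencies(tibble::tibble(J1 = jn$J1, J2 = jn$J2, J3 = 0),
                              p)
  resid <- abs(cmb$l * om$Omega1 + cmb$m * om$Omega2 + cmb$n * om$Omega3)
  expect_true(all(resid < 1e-9 * p$omega[3]))
})

test_that("Chirikov overlap threshold lands near the dominant-resonance
           estimate and behaves correctly in limits", {
  p <- base_params
  ch <- cached("chirikov", chirikov_threshold(p))
  expect_gt(ch$epsilon_star, 0.1)
  expect_lt(ch$epsilon_star, 0.4)
  # widths touch exactly at eps*
  M <- ch$M
  w <- 2 * sqrt(ch$epsilon_star * ch$amplitude1 / M) +
    2 * sqrt(ch$epsilon_star * ch$amplitude2 / M)
  expect_equal(w, ch$distance, tolerance = 1e-12)
  # vanishing coupling coefficient pushes the threshold to infinity
  expect_gt(overlap_epsilon(1e-8, 1e-8, M, M, ch$distance), 1e6)
  expect_equal(overlap_epsilon(400, 400, M, M, 4) /
                 overlap_epsilon(100, 100, M, M, 4), 1 / 4,
               tolerance = 1e-12)
  expect_error(chirikov_threshold(p, res1 = c(1, -1, 0)), "stretch-bend")
  expect_error(chirikov_threshold(p, res2 = c(0, 1, -1)),
               "same stretching mode")
})

test_that("FLI maps are deterministic and integrable maps are classified
           regular", {
  p0 <- params_eps(0)
  m1 <- compute_fli_map(p0, n = c(6, 6), quick = TRUE)
  m2 <- compute_fli_map(p0, n = c(6, 6), quick = TRUE)
  expect_identical(m1$fli, m2$fli)
  expect_identical(m1$lifetime, m2$lifetime)
  expect_true(all(is.na(m1$fli) | m1$feasible))
  c0 <- classify_map(m1, p0)
  expect_true(all(c0$label[c0$feasible] == "regular"))
})

test_that("strong coupling classifies predominantly chaotic at the full
           horizon", {
  p1 <- base_params
  m <- cached("map_eps1_40", compute_fli_map(p1, n = c(12, 12),
                                             t_horizon = 40))
  cl <- classify_map(m, p1)
  expect_gt(mean(cl$label[cl$feasible] == "chaotic"), 0.8)
})
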