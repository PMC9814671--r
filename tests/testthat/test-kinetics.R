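test_that("survival is a counting measure over retained lifetimes", {
  s <- survival_curve(c(1, 2, 3), t_grid = c(0, 2, 3))
  expect_equal(s$surv, c(1, 1 / 3, 0))
  expect_equal(attr(s, "n_retained"), 3)
  # sentinel lifetimes are discarded first
  s2 <- survival_curve(c(1, 2, 3, Inf, Inf), t_grid = c(0, 2, 3))
  expect_equal(s2$surv, s$surv)
  expect_error(survival_curve(c(Inf, Inf)), "undissociated")
  full <- survival_curve(c(1, 2, 3, Inf))
  expect_equal(full$surv[1], 1)
  expect_true(all(diff(full$surv) <= 0))
  expect_equal(full$surv[nrow(full)], 0)
})

test_that("exponential samples reproduce the analytic survival and density", {
  set.seed(31)
  k <- 2
  lt <- stats::rexp(1e4, k)
  s <- survival_curve(lt, t_grid = 1)
  se <- sqrt(exp(-2) * (1 - exp(-2)) / 1e4)
  expect_lt(abs(s$surv - exp(-2)), 3 * se)
  d <- lifetime_density(lt)
  expect_equal(sum(d$density * diff(range(lt)) / nrow(d)), 1,
               tolerance = 0.05)
  expect_equal(d$density[1], k, tolerance = 0.15)
  expect_equal(stats::median(lt), log(2) / k, tolerance = 0.05)
})

test_that("density is consistent with -dS/dt as bins refine", {
  set.seed(32)
  lt <- stats::rexp(1e4, 1)
  for (nb in c(20, 60)) {
    d <- lifetime_density(lt, bins = nb)
    edges <- seq(min(lt), max(lt), length.out = nb + 1)
    s <- survival_curve(lt, t_grid = edges)
    dsdt <- -diff(s$surv) / diff(edges)
    expect_lt(stats::median(abs(d$density - dsdt)), 0.05)
  }
  expect_equal(sum(d$density * diff(edges)), 1, tolerance = 1e-10)
})

test_that("single-exponential fits recover an exact rate", {
  t <- seq(0, 10, by = 0.1)
  curve <- tibble::tibble(t = t, surv = exp(-t), se = 0.01)
  attr(curve, "n_retained") <- 1e4
  f <- fit_survival(curve, 1)
  expect_equal(f$components$rate, 1, tolerance = 1e-6)
  expect_equal(f$components$amplitude, 1)
})

test_that("bi-exponential rates are recovered within 10% from sampled data,
           and model selection prefers the true order", {
  set.seed(33)
  n <- 1e4
  comp <- stats::runif(n) < 0.7
  lt <- ifelse(comp, stats::rexp(n, 3), stats::rexp(n, 0.3))
  curve <- survival_curve(lt, t_grid = seq(0, stats::quantile(lt, 0.999),
                                           length.out = 200))
  f2 <- fit_survival(curve, 2)
  expect_equal(f2$components$rate, c(3, 0.3), tolerance = 0.1)
  expect_equal(f2$components$amplitude, c(0.7, 0.3), tolerance = 0.1)
  f1 <- fit_survival(curve, 1)
  expect_gt(f1$aicc, f2$aicc)
  td <- generics::tidy(f2)
  expect_equal(nrow(td), 2)
  gl <- generics::glance(f2)
  expect_equal(gl$n_components, 2)
  expect_true(gl$converged)
})

test_that("fit residuals look like noise for data from the model class", {
  set.seed(34)
  lt <- stats::rexp(5e3, 1.5)
  curve <- survival_curve(lt, t_grid = seq(0, 4, length.out = 80))
  f <- fit_survival(curve, 1)
  # neighbouring values of the empirical S share samples, so the residuals
  # themselves are serially correlated by construction; their increments
  # carry the (approximately independent) per-bin counting noise
  r <- diff(curve$surv - f$fitted)
  signs <- sign(r[r != 0])
  runs <- sum(diff(signs) != 0) + 1
  n1 <- sum(signs > 0); n2 <- sum(signs < 0)
  mu <- 2 * n1 * n2 / (n1 + n2) + 1
  sd <- sqrt((mu - 1) * (mu - 2) / (n1 + n2 - 1))
  expect_lt(abs(runs - mu) / sd, 3)
})

test_that("summaries count dissociation correctly with sentinels", {
  s <- lifetime_summary(c(1, 2, 3, Inf), by_time = 2.5)
  expect_equal(s$frac_by, 0.5)
  expect_equal(s$median_lifetime, 2)
  expect_equal(s$n_dissociated, 3)
  expect_error(lifetime_summary(numeric(0)), "no lifetimes")
})

test_that("discarding undissociated trajectories only rescales S", {
  set.seed(35)
  lt <- c(stats::rexp(500, 1), rep(Inf, 250))
  grid <- seq(0, 5, by = 0.25)
  s_discard <- survival_curve(lt, t_grid = grid)$surv
  fin <- lt[is.finite(lt)]
  s_full <- vapply(grid, function(t) mean(lt > t), numeric(1))
  frac <- length(fin) / length(lt)
  # S over the full ensemble, minus the undissociated plateau, rescaled
  expect_equal((s_full - (1 - frac)) / frac, s_discard, tolerance = 1e-12)
})
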