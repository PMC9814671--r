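# Shared fixtures: parameter sets are cheap to build; anything integrated is
# memoised here so several test files can reuse it.

base_params <- bunker_params()                 # eps = 1
params_eps <- function(eps) bunker_params(epsilon = eps)

.cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

random_aa <- function(n, seed = 42, jmax_frac = 0.6, params = base_params) {
  set.seed(seed)
  jm <- j_max(params)
  tibble::tibble(
    J1 = runif(n, 0, jmax_frac * jm[1]),
    J2 = runif(n, 0, jmax_frac * jm[2]),
    J3 = runif(n, 0, 8),
    theta1 = runif(n, 0, 2 * pi),
    theta2 = runif(n, 0, 2 * pi),
    theta3 = runif(n, 0, 2 * pi))
}

# independent term-by-term Hamiltonian oracle (pure R, no shared code path)
ham_oracle <- function(pt, p) {
  G <- p$G0
  vmorse <- function(D, a, x) D * (1 - exp(-a * x))^2
  kin <- 0.5 * (G[1, 1] * pt$p1^2 + G[2, 2] * pt$p2^2 + G[3, 3] * pt$p3^2) +
    p$epsilon * (G[1, 2] * pt$p1 * pt$p2 + G[1, 3] * pt$p1 * pt$p3 +
                   G[2, 3] * pt$p2 * pt$p3)
  pot <- vmorse(p$D_au[1], p$alpha[1], pt$q1 - p$q0[1]) +
    vmorse(p$D_au[2], p$alpha[2], pt$q2 - p$q0[2]) +
    0.5 * p$w_au[3]^2 * (pt$q3 - p$q0[3])^2 / G[3, 3]
  (kin + pot) * 219474.6313632
}
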