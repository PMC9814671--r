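check_lifetimes <- function(lifetimes) {
  if (is.data.frame(lifetimes)) lifetimes <- lifetimes$lifetime
  if (is.null(lifetimes) || length(lifetimes) == 0) stop("no lifetimes given")
  if (any(is.na(lifetimes))) stop("NA lifetimes are not allowed")
  lifetimes
}

retained <- function(lifetimes) {
  lt <- check_lifetimes(lifetimes)
  fin <- lt[is.finite(lt)]
  if (length(fin) == 0)
    stop("all ", length(lt), " trajectories undissociated; survival ",
         "analysis requires at least one finite lifetime")
  fin
}

#' Empirical survival probability
#'
#' Undissociated trajectories (lifetime sentinel \code{Inf}) are discarded
#' first; \eqn{S(t)} is then the fraction of retained lifetimes exceeding
#' \eqn{t}, evaluated on \code{t_grid} (default: the sorted event times
#' prepended with 0). Standard errors are binomial,
#' \eqn{\sqrt{S(1-S)/N}}.
#'
#' @param lifetimes numeric vector of lifetimes (ps; \code{Inf} for
#'   undissociated), or a data frame with a \code{lifetime} column such as
#'   the output of \code{\link{propagate_ensemble}}.
#' @param t_grid optional evaluation times (ps).
#' @return tibble of class \code{survival_curve} with columns \code{t},
#'   \code{surv}, \code{se}; attribute \code{n_retained} gives the number of
#'   dissociating trajectories used.
#' @export
survival_curve <- function(lifetimes, t_grid = NULL) {
  fin <- retained(lifetimes)
  n <- length(fin)
  if (is.null(t_grid)) t_grid <- c(0, sort(unique(fin)))
  s <- vapply(t_grid, function(t) mean(fin > t), numeric(1))
  out <- tibble::tibble(t = t_grid, surv = s, se = sqrt(s * (1 - s) / n))
  attr(out, "n_retained") <- n
  class(out) <- c("survival_curve", class(out))
  out
}

#' Lifetime distribution density
#'
#' Normalised histogram estimate of \eqn{P(t) = -dS/dt}, the probability
#' density of dissociation times among dissociating trajectories.
#' Freedman-Diaconis binning by default.
#'
#' @inheritParams survival_curve
#' @param bins number of bins, or a vector of break points (ps).
#' @return tibble with columns \code{t} (bin midpoints), \code{density}
#'   (ps^-1, integrating to 1) and \code{count}.
#' @export
lifetime_density <- function(lifetimes, bins = NULL) {
  fin <- retained(lifetimes)
  breaks <- if (is.null(bins)) {
    nb <- max(grDevices::nclass.FD(fin), 1)
    seq(min(fin), max(fin), length.out = nb + 1)
  } else if (length(bins) == 1) {
    seq(min(fin), max(fin), length.out = bins + 1)
  } else bins
  h <- graphics::hist(fin, breaks = breaks, plot = FALSE)
  tibble::tibble(t = h$mids, density = h$density, count = h$counts)
}

#' Multi-exponential fit of a survival curve
#'
#' Weighted nonlinear least squares of
#' \eqn{S(t) = \sum_{i=1}^n a_i e^{-k_i t}} with \eqn{\sum a_i = 1},
#' \eqn{a_i \ge 0}, \eqn{k_i > 0}, used to compare single-exponential
#' (statistical, with \eqn{k(E)} the microcanonical rate constant) against
#' multi-exponential (nonstatistical) dissociation. Rates are parametrised
#' on the log scale and amplitudes through a softmax, with multi-start over
#' log-spaced rate seeds; weights are inverse binomial standard errors with
#' a small-count floor. Model comparison uses the small-sample corrected
#' Akaike information criterion.
#'
#' @param curve a \code{\link{survival_curve}} (>= 10 points).
#' @param n_components number of exponential components (1, 2 or 3).
#' @param n_starts multi-start attempts.
#' @return object of class \code{survival_fit} with \code{components}
#'   (tibble of amplitudes and rates, sorted by decreasing rate),
#'   \code{rss}, \code{aicc}, \code{n_obs}, \code{fitted}.
#' @export
fit_survival <- function(curve, n_components = 1, n_starts = 8) {
  stopifnot(n_components %in% 1:3)
  if (nrow(curve) < 10) stop("survival curve has fewer than 10 points")
  t <- curve$t; s <- curve$surv
  n0 <- attr(curve, "n_retained") %||% 1000
  floor_se <- sqrt(0.5 / n0 * (1 - 0.5 / n0) / n0)
  w <- 1 / pmax(curve$se %||% rep(0, length(s)), floor_se,
                .Machine$double.eps)
  nc <- n_components
  model <- function(par) {
    lk <- par[seq_len(nc)]
    a <- softmax(c(0, par[-seq_len(nc)]))
    colSums(a * exp(-exp(lk) %o% t))
  }
  resid_fun <- function(par) w * (model(par) - s)
  t_scale <- stats::median(t[t > 0])
  best <- NULL
  start_rates <- function(i) exp(seq(log(0.2 / max(t)), log(5 / t_scale),
                                     length.out = nc) + 0.5 * (i - 1))
  for (i in seq_len(n_starts)) {
    k0 <- start_rates(i)
    par0 <- c(log(k0), rep(0, nc - 1))
    fit <- tryCatch(
      minpack.lm::nls.lm(par0, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss_w) best <- list(fit = fit, rss_w = rss)
  }
  if (is.null(best))
    stop("multi-exponential fit failed to converge from any of ", n_starts,
         " starts (n = ", nc, ", ", length(t), " points)")
  par <- best$fit$par
  k <- exp(par[seq_len(nc)])
  a <- softmax(c(0, par[-seq_len(nc)]))
  ord <- order(-k)
  fitted <- colSums(a * exp(-k %o% t))
  m <- length(t)
  p <- 2 * nc - 1
  rss_w <- best$rss_w
  aicc <- m * log(rss_w / m) + 2 * p +
    if (m - p - 1 > 0) 2 * p * (p + 1) / (m - p - 1) else Inf
  out <- list(components = tibble::tibble(amplitude = a[ord], rate = k[ord]),
              n_components = nc, rss = sum((fitted - s)^2), rss_w = rss_w,
              aicc = aicc, n_obs = m, fitted = fitted, t = t,
              converged = best$fit$info %in% 1:4)
  class(out) <- "survival_fit"
  out
}

softmax <- function(x) { e <- exp(x - max(x)); e / sum(e) }

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("%d-exponential survival fit (%d points)\n",
              x$n_components, x$n_obs))
  for (i in seq_len(nrow(x$components)))
    cat(sprintf("  a = %.3f, k = %.4f ps^-1 (tau = %.3f ps)\n",
                x$components$amplitude[i], x$components$rate[i],
                1 / x$components$rate[i]))
  cat(sprintf("  RSS = %.3e, AICc = %.2f\n", x$rss, x$aicc))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.survival_fit <- function(x, ...) {
  dplyr::mutate(x$components, term = paste0("component", dplyr::row_number()),
                .before = 1)
}

#' @export
glance.survival_fit <- function(x, ...) {
  tibble::tibble(n_components = x$n_components, rss = x$rss, aicc = x$aicc,
                 n_obs = x$n_obs, converged = x$converged)
}

#' @export
predict.survival_fit <- function(object, t = object$t, ...) {
  colSums(object$components$amplitude *
            exp(-object$components$rate %o% t))
}

#' Summary statistics of a lifetime ensemble
#'
#' Median lifetime over the retained (dissociating) trajectories, and the
#' fraction of the full ensemble (undissociated included) that has
#' dissociated by \code{by_time}.
#'
#' @inheritParams survival_curve
#' @param by_time reference time for the dissociated fraction, ps.
#' @return one-row tibble: \code{n}, \code{n_dissociated},
#'   \code{median_lifetime}, \code{frac_by}, \code{by_time}.
#' @export
lifetime_summary <- function(lifetimes, by_time = 2) {
  lt <- check_lifetimes(lifetimes)
  fin <- lt[is.finite(lt)]
  if (length(lt) == 0) stop("empty lifetime input")
  tibble::tibble(n = length(lt), n_dissociated = length(fin),
                 median_lifetime = if (length(fin)) stats::median(fin) else NA,
                 frac_by = mean(lt <= by_time), by_time = by_time)
}
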