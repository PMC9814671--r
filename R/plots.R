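#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an FLI or lifetime map
#'
#' Renders the Arnold-web picture with the conventional projection
#' (\eqn{J_1} horizontal, \eqn{J_2} vertical). Lifetimes are shown on a
#' log10 scale with undissociated cells at the horizon value.
#'
#' @param object a \code{\link{compute_fli_map}} result.
#' @param what \code{"fli"} or \code{"lifetime"}.
#' @param cap upper display cap for the FLI colour scale (values above are
#'   saturated, mirroring the usual presentation).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.fli_map <- function(object, what = c("fli", "lifetime"), cap = NULL,
                             ...) {
  what <- match.arg(what)
  df <- dplyr::filter(object, .data$feasible)
  if (what == "fli") {
    if (!is.null(cap)) df$fli <- pmin(df$fli, cap)
    val <- "fli"; lab <- "FLI"
  } else {
    horizon <- attr(object, "t_horizon") %||% max(df$lifetime[is.finite(df$lifetime)])
    df$lifetime_plot <- log10(pmin(df$lifetime, horizon))
    val <- "lifetime_plot"; lab <- "log10 lifetime (ps)"
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$J1, .data$J2,
                                   fill = .data[[val]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "inferno", name = lab) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "J1 (hbar)", y = "J2 (hbar)") +
    ggplot2::theme_minimal()
}

#' Overlay analytic resonance lines on a map plot
#'
#' @param gg a ggplot from \code{\link{autoplot.fli_map}}.
#' @param lines a \code{\link{resonance_lines}} tibble.
#' @param colour line colour.
#' @return the ggplot with line layers added.
#' @export
add_resonance_lines <- function(gg, lines, colour = "cyan") {
  for (r in seq_len(nrow(lines))) {
    ln <- lines[r, ]
    gg <- gg + switch(ln$type,
      vertical = ggplot2::geom_vline(xintercept = ln$J_const,
                                     colour = colour, linewidth = 0.2),
      horizontal = ggplot2::geom_hline(yintercept = ln$J_const,
                                       colour = colour, linewidth = 0.2),
      sloped = ggplot2::geom_abline(slope = -ln$A / ln$B,
                                    intercept = ln$C / ln$B,
                                    colour = colour, linewidth = 0.2))
  }
  gg
}

#' Plot a survival curve with optional fits
#'
#' @param object a \code{\link{survival_curve}}.
#' @param fits optional list of \code{\link{fit_survival}} results to
#'   overlay.
#' @param ... unused.
#' @return a ggplot object (log survival axis).
#' @export
autoplot.survival_curve <- function(object, fits = NULL, ...) {
  gg <- ggplot2::ggplot(object, ggplot2::aes(.data$t, .data$surv)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "t (ps)", y = "S(t)") +
    ggplot2::theme_minimal()
  if (!is.null(fits)) {
    if (inherits(fits, "survival_fit")) fits <- list(fits)
    for (f in fits) {
      df <- tibble::tibble(t = object$t, surv = predict(f, object$t),
                           n = factor(f$n_components))
      gg <- gg + ggplot2::geom_line(data = df,
                                    ggplot2::aes(colour = .data$n))
    }
    gg <- gg + ggplot2::labs(colour = "components")
  }
  gg
}

#' Plot a frequency-ratio-space density map
#'
#' Natural-log colour scale, junctions appearing as bright rational points.
#'
#' @param object a \code{\link{ratio_density}} result.
#' @param junctions optional junction tibble to mark.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.frs_density <- function(object, junctions = NULL, ...) {
  gg <- ggplot2::ggplot(object, ggplot2::aes(.data$f1, .data$f2,
                                             fill = .data$log_density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "ln density") +
    ggplot2::labs(x = "f1 = Omega1/Omega3", y = "f2 = Omega2/Omega3") +
    ggplot2::theme_minimal()
  if (!is.null(junctions))
    gg <- gg + ggplot2::geom_point(data = junctions,
                                   ggplot2::aes(.data$f1, .data$f2),
                                   inherit.aes = FALSE, shape = 3,
                                   colour = "red")
  gg
}

#' Plot instantaneous frequency ratios of a track
#'
#' @param object a \code{\link{wavelet_frequencies}} result.
#' @param ... unused.
#' @return a ggplot object with \eqn{f_1(t)} and \eqn{f_2(t)}.
#' @export
autoplot.freq_track <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "t", "f1", "f2"),
    c("f1", "f2"), names_to = "ratio")
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$value,
                                   colour = .data$ratio)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "t (ps)", y = "frequency ratio") +
    ggplot2::theme_minimal()
}
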