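#' Plot a fractogram's detector traces
#'
#' UV, dRI and (optionally) one light-scattering trace, each normalised to
#' its own maximum so the elution profiles overlay.
#'
#' @param fractogram A fractogram tibble.
#' @param detectors Columns to show (default UV and dRI).
#' @return A ggplot object.
#' @export
plot_fractogram <- function(fractogram, detectors = c("uv_au", "dri_riu")) {
  detectors <- intersect(detectors, names(fractogram))
  long <- tidyr::pivot_longer(
    fractogram[, c("time_min", detectors)],
    cols = all_of(detectors), names_to = "detector", values_to = "signal"
  )
  long <- group_by(long, .data$detector)
  long <- mutate(long, signal = .data$signal / max(abs(.data$signal)))
  long <- ungroup(long)
  ggplot2::ggplot(long, ggplot2::aes(.data$time_min, .data$signal,
                                     colour = .data$detector)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Elution time (min)", y = "Signal (normalised)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot deconvolution
#' @export
autoplot.deconvolution <- function(object, data = NULL, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(data)) {
    p <- p + ggplot2::geom_point(
      data = data, ggplot2::aes(.data$time_min, .data$signal),
      size = 0.3, alpha = 0.4)
  }
  grid <- if (!is.null(data)) data$time_min else
    seq(min(object$peaks$center - 4 * object$peaks$sigma),
        max(object$peaks$center + 4 * object$peaks$sigma), length.out = 500)
  comp <- list_rbind(map(seq_len(nrow(object$peaks)), function(k) {
    pk <- object$peaks[k, ]
    tibble(time_min = grid,
           signal = pk$amplitude * exp(-(grid - pk$center)^2 / (2 * pk$sigma^2)),
           label = pk$label)
  }))
  p +
    ggplot2::geom_line(data = comp,
                       ggplot2::aes(.data$time_min, .data$signal,
                                    colour = .data$label)) +
    ggplot2::labs(x = "Elution time (min)", y = "Signal", colour = "Component") +
    ggplot2::theme_minimal()
}

#' @method autoplot guinier_fit
#' @export
autoplot.guinier_fit <- function(object, data = NULL, ...) {
  if (is.null(data)) {
    abort("Supply the scattering curve via `data` to plot a Guinier fit.",
          class = "af4saxs_domain_error")
  }
  pos <- data[data$intensity > 0, ]
  df <- tibble(q2 = pos$q^2, lni = log(pos$intensity),
               in_fit = pos$q >= object$q_range[1] & pos$q <= object$q_range[2])
  line <- tibble(q2 = df$q2,
                 lni = log(object$i_zero) - df$q2 * object$rg_nm^2 / 3)
  ggplot2::ggplot(df, ggplot2::aes(.data$q2, .data$lni)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$in_fit), size = 0.6) +
    ggplot2::geom_line(data = line, colour = "red") +
    ggplot2::coord_cartesian(xlim = c(0, (2 * object$q_range[2])^2)) +
    ggplot2::labs(x = expression(q^2 ~ (nm^-2)), y = "ln I(q)",
                  colour = "In Guinier window") +
    ggplot2::theme_minimal()
}

#' @method autoplot pddf
#' @export
autoplot.pddf <- function(object, ...) {
  ggplot2::ggplot(object$pr, ggplot2::aes(.data$r, .data$p)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::labs(x = "r (nm)", y = "p(r)") +
    ggplot2::theme_minimal()
}

#' @method autoplot binding_isotherm
#' @export
autoplot.binding_isotherm <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("molar_ratio_added", "gaz_per_monomer",
                          "gaz_per_dimer", "overall")],
    cols = -"molar_ratio_added", names_to = "ratio", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$molar_ratio_added, .data$value,
                                     colour = .data$ratio)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Added ligand : albumin (mol/mol)",
                  y = "Bound ligand per albumin (mol/mol)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot scattering_curve
#' @export
autoplot.scattering_curve <- function(object, ...) {
  pos <- object[object$intensity > 0, ]
  ggplot2::ggplot(pos, ggplot2::aes(.data$q, .data$intensity)) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(q ~ (nm^-1)), y = "I(q)") +
    ggplot2::theme_minimal()
}
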