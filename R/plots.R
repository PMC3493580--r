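#' Plot a fluctuation profile
#'
#' Line plot of a per-atom or per-residue profile; the zero line is drawn
#' for difference profiles, where departures from zero localise
#' binding-induced perturbation.
#'
#' @param object A `fluct_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.fluct_profile <- function(object, ...) {
  xvar <- if ("residue_id" %in% names(object)) "residue_id" else "atom_serial"
  kind <- object$kind[1]
  lab <- c(rmsf = "RMSF (nm)", residue_rmsd = "per-residue RMSD (nm)",
           delta_rmsd = "ΔRMSD (nm)")[kind]
  p <- ggplot2::ggplot(object, ggplot2::aes(.data[[xvar]], .data$value_nm)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = xvar, y = lab) +
    ggplot2::theme_minimal()
  if (kind == "delta_rmsd") {
    p <- p + ggplot2::geom_hline(yintercept = 0, linetype = 2)
  }
  p
}

#' Plot an essential-plane projection as a density cloud
#' @param object An `ed_projection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ed_projection <- function(object, ...) {
  k <- attr(object, "eigenvectors") %||% c(1, 2)
  ggplot2::ggplot(object, ggplot2::aes(.data$p1, .data$p2)) +
    ggplot2::geom_bin2d(bins = 60) +
    ggplot2::labs(x = sprintf("projection on eigenvector %d (nm)", k[1]),
                  y = sprintf("projection on eigenvector %d (nm)", k[2])) +
    ggplot2::theme_minimal()
}

#' Plot stacking descriptors as phi/r and psi/r clouds
#' @param object A `stacking_series`.
#' @param ... Unused.
#' @return A ggplot object (two descriptor panels via facetting).
#' @exportS3Method ggplot2::autoplot
autoplot.stacking_series <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("phi_deg", "psi_deg"),
                              names_to = "angle", values_to = "degrees")
  ggplot2::ggplot(long, ggplot2::aes(.data$degrees, .data$r_nm)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::facet_wrap(~angle, labeller = ggplot2::as_labeller(
      c(phi_deg = "φ (deg)", psi_deg = "Ψ (deg)"))) +
    ggplot2::labs(x = "angle (deg)", y = "r (nm)") +
    ggplot2::theme_minimal()
}

#' Plot a thermodynamic-integration profile
#'
#' Per-lambda mean coupling derivative with block-standard-error bars; the
#' free-energy difference is the area under this curve.
#'
#' @param object A `ti_profile`.
#' @param n_blocks Blocks for the per-lambda error bars.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ti_profile <- function(object, n_blocks = 3L, ...) {
  lam <- sort(unique(object$lambda))
  df <- purrr::map_dfr(lam, function(l) {
    be <- block_standard_error(object$dhdl[object$lambda == l], n_blocks)
    tibble(lambda = l, mean = be$mean, se = be$standard_error)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$lambda, .data$mean)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$se,
                                          ymax = .data$mean + .data$se),
                             size = 0.2) +
    ggplot2::labs(x = expression(lambda),
                  y = "<dH/dλ> (kJ/mol)") +
    ggplot2::theme_minimal()
}
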