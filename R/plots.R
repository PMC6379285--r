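#' Concordance scatter plot
#'
#' X-Y plot of test against reference volumes with the line of equality
#' (dashed) and the reduced major axis fit (solid), annotated with Lin's
#' concordance statistics.
#'
#' @param x Reference volumes, mm^3.
#' @param y Test volumes, mm^3.
#' @param xlab,ylab Axis labels.
#' @return A ggplot object.
#' @export
plot_concordance <- function(x, y, xlab = "Reference volume (mm³)",
                             ylab = "Measured volume (mm³)") {
  cc <- lin_ccc(x, y)
  fit <- rma_fit(x, y)
  df <- data.frame(x = x, y = y)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = xlab, y = ylab,
      subtitle = sprintf("ρ = %.3f, C_b = %.3f, ρ_c = %.3f",
                         cc$rho, cc$c_b, cc$rho_c)
    ) +
    ggplot2::theme_minimal()
}

#' Percent Bland-Altman plot
#'
#' Percent differences against the reference volume, with bias (solid) and
#' 1.96-SD limits of agreement (dashed).
#'
#' @param x Reference volumes, mm^3.
#' @param y Test volumes, mm^3.
#' @param denominator Passed to [bland_altman_percent()].
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(x, y, denominator = "reference") {
  ba <- bland_altman_percent(x, y, denominator)
  df <- data.frame(x = x, d = ba$differences)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$d)) +
    ggplot2::geom_hline(yintercept = ba$bias) +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Reference volume (mm³)", y = "Difference (%)",
      subtitle = sprintf("bias %.1f%%, LoA [%.1f%%, %.1f%%]",
                         ba$bias, ba$loa_low, ba$loa_high)
    ) +
    ggplot2::theme_minimal()
}
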