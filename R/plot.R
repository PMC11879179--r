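#' Plot growth response curves
#'
#' Draws the food-limitation curves produced by [response_surface()]:
#' daily specific growth against prey density, one curve per temperature,
#' with dashed horizontal lines at the ad-libitum ceilings. Requires
#' ggplot2.
#'
#' @param surface A data.frame from [response_surface()].
#' @param file Optional output path (PNG); when `NULL` the plot object is
#'   returned.
#' @return The ggplot object, invisibly when written to file.
#' @export
plot_response_surface <- function(surface, file = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_response_surface: ggplot2 is required for plotting",
         call. = FALSE)
  }
  surface$temperature <- factor(surface$temperature_c)
  gg <- ggplot2::ggplot(surface,
                        ggplot2::aes(x = .data$density_m3, y = .data$sgr_daily,
                                     colour = .data$temperature,
                                     linetype = .data$temperature)) +
    ggplot2::geom_hline(
      data = unique(surface[, c("temperature", "sgr_ad_libitum")]),
      ggplot2::aes(yintercept = .data$sgr_ad_libitum), colour = "grey60",
      linetype = "dashed") +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey30", linewidth = 0.3) +
    ggplot2::labs(
      x = bquote("Prey density" ~ (m^-3)),
      y = bquote("Daylight specific growth rate" ~ (day^-1)),
      colour = "Temp (°C)", linetype = "Temp (°C)",
      title = sprintf("Stage %s feeding on %s",
                      surface$stage[1], surface$prey[1])) +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    ggplot2::ggsave(file, gg, width = 6, height = 4, dpi = 150)
    return(invisible(gg))
  }
  gg
}
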