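#' Plot a recruitment curve
#'
#' Reference (M-wave) and target (H-reflex) pooled sizes against stimulus
#' intensity: the M-wave rises then saturates, the H-reflex rises then
#' falls.
#'
#' @param rc A [build_recruitment_curve()] result.
#' @return A ggplot object.
#' @export
plot_recruitment_curve <- function(rc) {
  stopifnot(inherits(rc, "recruitment_curve"))
  pts <- rbind(
    data.frame(intensity = rc$points$intensity, size = rc$points$reference,
               response = "reference (M-wave)"),
    data.frame(intensity = rc$points$intensity, size = rc$points$target,
               response = "target (H-reflex)")
  )
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$intensity, y = .data$size,
                                    colour = .data$response,
                                    shape = .data$response)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "stimulus intensity (mA)",
                  y = sprintf("response size (mV, %s)", rc$method),
                  colour = NULL, shape = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a response-size distribution
#'
#' Histogram of target response sizes (Freedman-Diaconis bin widths,
#' display only) with the median and the up-/down-criterion percentile
#' lines.
#'
#' @param dist A [compute_distribution()] result.
#' @return A ggplot object.
#' @export
plot_distribution <- function(dist) {
  stopifnot(inherits(dist, "response_distribution"))
  bw <- 2 * stats::IQR(dist$sizes) / length(dist$sizes)^(1 / 3)
  if (!is.finite(bw) || bw <= 0) bw <- NULL
  lines <- data.frame(
    what = factor(c("median", "up criterion", "down criterion"),
                  levels = c("down criterion", "median", "up criterion")),
    x = c(dist$percentile_lines[["median"]], dist$percentile_lines[["up"]],
          dist$percentile_lines[["down"]])
  )
  ggplot2::ggplot(data.frame(size = dist$sizes), ggplot2::aes(x = .data$size)) +
    ggplot2::geom_histogram(binwidth = bw, fill = "grey70",
                            colour = "grey40") +
    ggplot2::geom_vline(data = lines,
                        ggplot2::aes(xintercept = .data$x,
                                     linetype = .data$what),
                        colour = "red") +
    ggplot2::labs(x = "target response size (mV)", y = "trials",
                  linetype = NULL) +
    ggplot2::theme_minimal()
}
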