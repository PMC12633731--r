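#' Polar plot of stroke-circle event timings
#'
#' Events are drawn on the stroke circle with the cycle start at 0 degrees
#' and the cycle proceeding counter-clockwise; the propulsive half
#' (0-180 degrees) is shaded. Angular means with angular-deviation bars
#' are overlaid per group.
#'
#' @param deg Angles in degrees.
#' @param group Optional factor of the same length; one colour per level.
#' @param main Plot title.
#' @export
plot_polar_timing <- function(deg, group = NULL, main = "Event timing") {
  check_angles(deg)
  if (is.null(group)) group <- rep("all", length(deg))
  group <- factor(group)
  th <- deg2rad(deg)
  graphics::plot(NA, xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", main = main)
  ang <- seq(0, pi, length.out = 100)
  graphics::polygon(c(0, cos(ang)), c(0, sin(ang)), col = "grey90",
                    border = NA)
  ang <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(cos(ang), sin(ang))
  graphics::segments(0, 0, 1.1, 0, lty = 2)
  graphics::text(1.2, 0, "0°"); graphics::text(-1.2, 0, "180°")
  cols <- seq_along(levels(group)) + 1
  graphics::points(cos(th), sin(th), col = cols[as.integer(group)], pch = 16,
                   cex = 0.7)
  for (g in seq_along(levels(group))) {
    s <- circ_summary(deg[group == levels(group)[g]])
    if (!is.na(s$mean_deg)) {
      m <- deg2rad(s$mean_deg)
      graphics::arrows(0, 0, s$R_bar * cos(m), s$R_bar * sin(m),
                       col = cols[g], lwd = 2, length = 0.08)
    }
  }
  if (nlevels(group) > 1)
    graphics::legend("topright", legend = levels(group), col = cols,
                     pch = 16, bty = "n")
  invisible(NULL)
}
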