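# Minimal convenience plot for coexistence maps. Not a publication figure.

#' Plot a coexistence scan
#'
#' Draws the tristate class map (black = no coexistence equilibrium, grey =
#' local attractor, white = global attractor) with the asymmetry parameter
#' on x and s on a log-like y axis (s = 0 is drawn as the bottom row).
#'
#' @param x a [scan_plane()] result.
#' @param ... passed to [graphics::image()].
#' @export
plot.scan_result <- function(x, ...) {
  codes <- matrix(match(x$classes,
                        c("none", "local_attractor", "global_attractor")),
                  nrow = nrow(x$classes))
  s <- x$s_grid
  y <- ifelse(s > 0, log10(s), if (any(s > 0)) min(log10(s[s > 0])) - 1 else 0)
  graphics::image(x = x$x_grid, y = y, z = codes, zlim = c(1, 3),
                  col = c("black", "grey60", "white"),
                  xlab = x$x_name, ylab = "log10(s)", ...)
  graphics::box()
  invisible(x)
}
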