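#' Court geometry
#'
#' A padel court is 20 m long and 10 m wide, divided by a net at mid-length.
#' All court-space positions in the package are interpreted in this frame:
#' `x` across the court (0..width), `y` along it (0..length), with the net at
#' `y = net_y`. The team on the `y < net_y` half is the "bottom" (B) team as
#' seen in the video, the other half the "top" (T) team.
#'
#' @param width court x-extent in meters.
#' @param length court y-extent in meters.
#' @param net_y y-coordinate of the net, defaults to mid-court.
#' @return an object of class `court_geometry`.
#' @examples
#' court_geometry()
#' @export
court_geometry <- function(width = 10, length = 20, net_y = length / 2) {
  stopifnot(width > 0, length > 0, net_y > 0, net_y < length)
  structure(list(width = width, length = length, net_y = net_y),
            class = "court_geometry")
}

#' @export
print.court_geometry <- function(x, ...) {
  cat(sprintf("<court %g x %g m, net at y = %g>\n", x$length, x$width, x$net_y))
  invisible(x)
}
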