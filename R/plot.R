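# Plot-data extraction and rendering.
#
# Every plot has two layers: plot_data() builds the exact table handed to
# the renderer (including the court overlay segments for spatial plots), and
# a thin ggplot2 adapter draws it. The data contract is the tested part;
# the aesthetics are replaceable.

#' Court overlay segments
#'
#' Line segments of the court (outline, net, service-box lines at 3 m from
#' the net) for underlaying spatial plots.
#'
#' @param geometry a [court_geometry()].
#' @return a tibble with columns `part`, `x`, `y`, `xend`, `yend`.
#' @export
court_overlay <- function(geometry = court_geometry()) {
  w <- geometry$width; l <- geometry$length; n <- geometry$net_y
  sv <- 3  # service line offset from the net
  tibble::tribble(
    ~part, ~x, ~y, ~xend, ~yend,
    "outline", 0, 0, w, 0,
    "outline", w, 0, w, l,
    "outline", w, l, 0, l,
    "outline", 0, l, 0, 0,
    "net", 0, n, w, n,
    "service", 0, n - sv, w, n - sv,
    "service", 0, n + sv, w, n + sv,
    "center", w / 2, n - sv, w / 2, n + sv
  )
}

first_matching <- function(cols, patterns) {
  for (p in patterns) {
    hit <- grep(p, cols, value = TRUE)
    if (length(hit)) return(hit[1])
  }
  NULL
}

need_col <- function(result, col, role, kind) {
  if (is.null(col) || !col %in% names(result)) {
    stop("plot_data('", kind, "') needs a column for '", role,
         "' (got '", col %||% "<none>", "'); available: ",
         paste(result_columns(result), collapse = ", "), call. = FALSE)
  }
  col
}

#' Extract the table behind a plot
#'
#' Returns exactly the data a renderer would draw, so plots can be tested
#' and re-rendered with any backend.
#'
#' @param result a query result.
#' @param kind one of `"positions"`, `"player_positions"`, `"directions"`,
#'   `"distribution"`, `"histogram"`, `"bar_chart"`.
#' @param x,y,color,ox,oy,dx,dy,value,group column names overriding the
#'   automatic mapping (origin/destination pairs for directions; `value` for
#'   distribution/histogram).
#' @param bins histogram bin count.
#' @param geometry court geometry for the overlay.
#' @return a `padel_plot_data` list: `kind`, `data` (tibble), `mapping`,
#'   and `court` (overlay segments or `NULL`).
#' @export
plot_data <- function(result, kind, x = NULL, y = NULL, color = NULL,
                      ox = NULL, oy = NULL, dx = NULL, dy = NULL,
                      value = NULL, group = NULL, bins = 10,
                      geometry = court_geometry()) {
  if (!inherits(result, "padel_result")) {
    result <- new_padel_result(tibble::as_tibble(result))
  }
  kind <- match.arg(kind, c("positions", "player_positions", "directions",
                            "distribution", "histogram", "bar_chart"))
  cols <- result_columns(result)
  out <- switch(kind,
    positions = {
      x <- need_col(result, x %||%
                      first_matching(cols, c("position\\.x$", "_x$", "^x$")),
                    "x", kind)
      y <- need_col(result, y %||%
                      first_matching(cols, c("position\\.y$", "_y$", "^y$")),
                    "y", kind)
      dat <- tibble::tibble(x = result[[x]], y = result[[y]])
      if (!is.null(color)) dat$color <- result[[need_col(result, color,
                                                         "color", kind)]]
      list(data = dat, mapping = list(x = x, y = y, color = color),
           court = court_overlay(geometry))
    },
    player_positions = {
      # wide per-player *_x/*_y pairs -> long (player, x, y)
      xs <- grep("(_x$)|(position\\.x$)", cols, value = TRUE)
      stems <- sub("(_x$)|(\\.position\\.x$)", "", xs)
      ys <- ifelse(endsWith(xs, "_x"), paste0(stems, "_y"),
                   paste0(stems, ".position.y"))
      keep <- ys %in% cols
      if (!any(keep)) {
        stop("plot_data('player_positions') found no *_x/*_y column pairs",
             call. = FALSE)
      }
      dat <- purrr::map_dfr(which(keep), function(i) {
        tibble::tibble(player = stems[i],
                       x = result[[xs[i]]], y = result[[ys[i]]])
      })
      list(data = dat, mapping = list(pairs = stems[keep]),
           court = court_overlay(geometry))
    },
    directions = {
      ox <- need_col(result, ox %||%
                       first_matching(cols, c("^hitter\\.position\\.x$",
                                              "origin_x", "_x$")), "origin x", kind)
      oy <- need_col(result, oy %||%
                       first_matching(cols, c("^hitter\\.position\\.y$",
                                              "origin_y", "_y$")), "origin y", kind)
      dx <- need_col(result, dx %||%
                       first_matching(cols, c("^next\\.hitter\\.position\\.x$",
                                              "dest_x")), "destination x", kind)
      dy <- need_col(result, dy %||%
                       first_matching(cols, c("^next\\.hitter\\.position\\.y$",
                                              "dest_y")), "destination y", kind)
      dat <- tibble::tibble(ox = result[[ox]], oy = result[[oy]],
                            dx = result[[dx]], dy = result[[dy]])
      if (!is.null(color)) dat$color <- result[[need_col(result, color,
                                                         "color", kind)]]
      dat <- dat[stats::complete.cases(dat[c("ox", "oy", "dx", "dy")]), ]
      list(data = dat, mapping = list(ox = ox, oy = oy, dx = dx, dy = dy,
                                      color = color),
           court = court_overlay(geometry))
    },
    distribution = {
      value <- need_col(result, value %||% color, "value", kind)
      dat <- tibble::tibble(value = result[[value]])
      if (!is.null(group)) dat$group <- result[[need_col(result, group,
                                                         "group", kind)]]
      list(data = dat[!is.na(dat$value), , drop = FALSE],
           mapping = list(value = value, group = group), court = NULL)
    },
    histogram = {
      value <- need_col(result, value, "value", kind)
      v <- result[[value]]
      # fixed-width bins over the observed range; counts conserve rows
      if (!length(v)) {
        dat <- tibble::tibble(mid = numeric(), count = integer())
      } else {
        rng <- range(v, na.rm = TRUE)
        if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
        brk <- seq(rng[1], rng[2], length.out = bins + 1)
        cut_i <- findInterval(v, brk, rightmost.closed = TRUE)
        cut_i[is.na(v)] <- NA
        dat <- tibble::tibble(
          mid = (brk[-1] + brk[-length(brk)]) / 2,
          count = vapply(seq_len(bins), function(b) sum(cut_i == b, na.rm = TRUE),
                         integer(1)))
      }
      list(data = dat, mapping = list(value = value, bins = bins), court = NULL)
    },
    bar_chart = {
      x <- need_col(result, x, "x", kind)
      y <- need_col(result, y, "y", kind)
      dat <- tibble::tibble(x = result[[x]], y = result[[y]])
      if (!is.null(color)) dat$color <- result[[need_col(result, color,
                                                         "color", kind)]]
      list(data = dat, mapping = list(x = x, y = y, color = color),
           court = NULL)
    }
  )
  structure(c(list(kind = kind), out), class = "padel_plot_data")
}

#' @export
print.padel_plot_data <- function(x, ...) {
  cat(sprintf("<plot data '%s': %d row(s)>\n", x$kind, nrow(x$data)))
  print(x$data, n = 5)
  invisible(x)
}

court_layers <- function(court) {
  list(
    ggplot2::geom_segment(
      data = court,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend),
      inherit.aes = FALSE, linewidth = 0.4, color = "grey40"),
    ggplot2::coord_fixed(),
    ggplot2::theme_minimal(),
    ggplot2::labs(x = "x (m)", y = "y (m)")
  )
}

#' Render plot data with ggplot2
#'
#' @param object a `padel_plot_data`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot padel_plot_data
#' @export
autoplot.padel_plot_data <- function(object, ...) {
  d <- object$data
  has_color <- "color" %in% names(d)
  has_group <- "group" %in% names(d)
  switch(object$kind,
    positions = {
      p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
        court_layers(object$court)
      p + if (has_color) {
        ggplot2::geom_point(ggplot2::aes(color = .data$color), size = 2)
      } else ggplot2::geom_point(size = 2)
    },
    player_positions = {
      ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                      color = .data$player)) +
        court_layers(object$court) +
        ggplot2::geom_point(size = 1, alpha = 0.6)
    },
    directions = {
      p <- ggplot2::ggplot(d) + court_layers(object$court)
      arr <- ggplot2::arrow(length = ggplot2::unit(2, "mm"))
      p <- p + if (has_color) {
        ggplot2::geom_segment(
          ggplot2::aes(x = .data$ox, y = .data$oy, xend = .data$dx,
                       yend = .data$dy, color = .data$color), arrow = arr)
      } else {
        ggplot2::geom_segment(
          ggplot2::aes(x = .data$ox, y = .data$oy, xend = .data$dx,
                       yend = .data$dy), arrow = arr)
      }
      p + ggplot2::geom_point(ggplot2::aes(x = .data$ox, y = .data$oy), size = 2)
    },
    distribution = {
      if (has_group) {
        ggplot2::ggplot(d, ggplot2::aes(x = .data$value, color = .data$group)) +
          ggplot2::geom_density() + ggplot2::theme_minimal()
      } else {
        ggplot2::ggplot(d, ggplot2::aes(x = .data$value)) +
          ggplot2::geom_density() + ggplot2::theme_minimal()
      }
    },
    histogram = {
      ggplot2::ggplot(d, ggplot2::aes(x = .data$mid, y = .data$count)) +
        ggplot2::geom_col() + ggplot2::theme_minimal()
    },
    bar_chart = {
      p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y))
      p <- p + if (has_color) {
        ggplot2::geom_col(ggplot2::aes(fill = .data$color),
                          position = "dodge")
      } else ggplot2::geom_col()
      p + ggplot2::theme_minimal() +
        ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                           hjust = 1))
    }
  )
}

#' Convenience plot wrappers
#'
#' Paper-style one-liners over [plot_data()] + [autoplot()]:
#' `plot_positions()` scatters item positions on the court,
#' `plot_player_positions()` overlays per-player tracks,
#' `plot_directions()` draws origin-to-receiver arrows,
#' `plot_distribution()` a density, `plot_histogram()` binned counts and
#' `plot_bar_chart()` grouped bars.
#'
#' @param result a query result.
#' @param ... passed to [plot_data()].
#' @return a ggplot object.
#' @export
plot_positions <- function(result, ...) {
  ggplot2::autoplot(plot_data(result, "positions", ...))
}

#' @rdname plot_positions
#' @export
plot_player_positions <- function(result, ...) {
  ggplot2::autoplot(plot_data(result, "player_positions", ...))
}

#' @rdname plot_positions
#' @export
plot_directions <- function(result, ...) {
  ggplot2::autoplot(plot_data(result, "directions", ...))
}

#' @rdname plot_positions
#' @export
plot_distribution <- function(result, ...) {
  ggplot2::autoplot(plot_data(result, "distribution", ...))
}

#' @rdname plot_positions
#' @export
plot_histogram <- function(result, ...) {
  ggplot2::autoplot(plot_data(result, "histogram", ...))
}

#' @rdname plot_positions
#' @export
plot_bar_chart <- function(result, ...) {
  ggplot2::autoplot(plot_data(result, "bar_chart", ...))
}
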