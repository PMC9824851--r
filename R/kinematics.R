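# Kinematics of frame-bound players.
#
# Everything here is a pure function of the per-frame positions table. The
# orientation convention: a player always faces the net, so for a player on
# the bottom half (y < net_y) "forward" is +y and the right wall is x = width;
# for the top half forward is -y and the right wall is x = 0. Wall distances,
# shot angles and their signs all follow from this single convention.

KINEMATIC_PROPS <- c(
  "position", "x", "y", "speed", "acceleration",
  "distance_to_net", "distance_to_back_wall", "distance_to_backwall",
  "distance_to_side_wall", "distance_to_right_wall", "distance_to_left_wall",
  "distance_from_prev_frame", "from_point_winning_team"
)

# fluent access: kinematic attributes of an unbound player follow the absent
# contract (so catalog queries stay total on sparse frame data); the exported
# function interface below is strict and errors instead.
bound_kinematic <- function(player, name) {
  if (!is_bound(player)) return(absent)
  frame <- player[["frame"]]
  mt <- frame_match(frame)
  pid <- player[["id"]]
  pos <- player_pos(mt, pid, frame[["row"]])
  if (is_absent(pos) && name != "from_point_winning_team") return(absent)
  geom <- ufield(mt, "geometry")
  switch(name,
    position = pos,
    x = pos$x,
    y = pos$y,
    distance_to_net = abs(pos$y - geom$net_y),
    distance_to_back_wall = ,
    distance_to_backwall = unname(wall_distances(pos, geom, player)["back"]),
    distance_to_side_wall = unname(wall_distances(pos, geom, player)["side"]),
    distance_to_right_wall = unname(wall_distances(pos, geom, player)["right"]),
    distance_to_left_wall = unname(wall_distances(pos, geom, player)["left"]),
    speed = finite_difference(player, order = 1L),
    acceleration = finite_difference(player, order = 2L),
    distance_from_prev_frame = step_distance(player),
    from_point_winning_team = {
      pt <- get_prop(frame, "point")
      w <- ufield(pt, "winner")
      if (is_absent(w) || is.null(w)) return(FALSE)
      pid %in% vapply(ufield(w, "players"), function(p) p[["id"]], character(1))
    },
    absent
  )
}

player_pos <- function(match, pid, row) {
  tbl <- ufield(match, "frames_tbl")
  xc <- tbl[[paste0(pid, "_x")]]
  if (is.null(xc)) return(absent)
  court_point(xc[row], tbl[[paste0(pid, "_y")]][row])
}

# (back, side, right, left) distances under the facing-the-net convention
wall_distances <- function(pos, geom, player = NULL) {
  bottom <- pos$y < geom$net_y
  if (pos$y == geom$net_y) {
    # facing is ambiguous on the net line: fall back to the player's team half
    lbl <- if (!is.null(player)) player[["team_label"]] else NA_character_
    bottom <- !identical(lbl, "T")
    warning("player exactly on the net line; facing taken from team half",
            call. = FALSE)
  }
  if (bottom) {
    right <- geom$width - pos$x
    left <- pos$x
    back <- pos$y
  } else {
    right <- pos$x
    left <- geom$width - pos$x
    back <- geom$length - pos$y
  }
  c(back = back, side = min(left, right), right = right, left = left)
}

# positions of one player over the frames of the enclosing point, as a matrix
point_track <- function(player) {
  frame <- player[["frame"]]
  mt <- frame_match(frame)
  pt <- get_prop(frame, "point")
  rows <- ufield(pt, "frame_rows")
  tbl <- ufield(mt, "frames_tbl")
  pid <- player[["id"]]
  list(
    x = tbl[[paste0(pid, "_x")]][rows],
    y = tbl[[paste0(pid, "_y")]][rows],
    t = tbl$frame_number[rows] / match_fps(mt),
    i = base::match(frame[["row"]], rows)
  )
}

# central finite differences over +/- window frames, truncated one-sided at
# the point boundaries; order 1 = velocity, order 2 = acceleration
finite_difference <- function(player, order = 1L, w = NULL) {
  frame <- player[["frame"]]
  mt <- frame_match(frame)
  if (is.null(w)) w <- match_config(mt)$speed_window
  tr <- point_track(player)
  n <- length(tr$t)
  if (n < 2L) {
    warning("point has fewer than 2 tracked frames; zero vector returned",
            call. = FALSE)
    return(court_vec(0, 0))
  }
  vel_at <- function(i) {
    i1 <- max(1L, i - w); i2 <- min(n, i + w)
    dt <- tr$t[i2] - tr$t[i1]
    if (dt == 0) return(c(0, 0))
    c((tr$x[i2] - tr$x[i1]) / dt, (tr$y[i2] - tr$y[i1]) / dt)
  }
  if (order == 1L) {
    v <- vel_at(tr$i)
    return(court_vec(v[1], v[2]))
  }
  i1 <- max(1L, tr$i - w); i2 <- min(n, tr$i + w)
  dt <- tr$t[i2] - tr$t[i1]
  if (dt == 0) return(court_vec(0, 0))
  a <- (vel_at(i2) - vel_at(i1)) / dt
  court_vec(a[1], a[2])
}

step_distance <- function(player) {
  tr <- point_track(player)
  if (tr$i <= 1L) return(0)
  sqrt((tr$x[tr$i] - tr$x[tr$i - 1L])^2 + (tr$y[tr$i] - tr$y[tr$i - 1L])^2)
}

court_vec <- function(x, y) {
  structure(list(x = x, y = y, magnitude = sqrt(x^2 + y^2)),
            class = "court_vec")
}

#' @export
format.court_vec <- function(x, ...) sprintf("(%.2f, %.2f)", x$x, x$y)

#' @export
print.court_vec <- function(x, ...) {
  cat(sprintf("<vector (%.3f, %.3f), |v| = %.3f>\n", x$x, x$y, x$magnitude))
  invisible(x)
}

# ---- exported strict interface ---------------------------------------------

#' Distance of a player to the net
#'
#' For a bound player, `|y - net_y|`. The two-argument form
#' `distance_to_net(frame, player)` binds `player` to `frame` first; this is
#' the form used in net-zone queries.
#'
#' @param x a bound `padel_player`, or a `padel_frame`.
#' @param player when `x` is a frame: the player to bind to it.
#' @return distance in meters.
#' @export
distance_to_net <- function(x, player = NULL) {
  if (inherits(x, "padel_frame")) {
    if (is_absent(player)) return(absent)
    return(distance_to_net(bind(player, x)))
  }
  if (is_absent(x)) return(absent)
  stopifnot(inherits(x, "padel_player"))
  if (!is_bound(x)) {
    stop("distance_to_net requires a frame context; use bind(player, frame)",
         call. = FALSE)
  }
  unname(bound_kinematic(x, "distance_to_net"))
}

#' Oriented wall distances of a bound player
#'
#' The reference walls are taken with respect to the player, who is assumed
#' to face the net: for the bottom half of the court the right wall is
#' `x = width`, for the top half it is `x = 0`. The back wall is the one
#' behind the player and the side distance is the nearer of left/right.
#'
#' @param player a bound `padel_player`.
#' @return a named numeric vector `(back, side, right, left)`, meters.
#' @export
oriented_wall_distances <- function(player) {
  stopifnot(inherits(player, "padel_player"))
  if (!is_bound(player)) {
    stop("wall distances require a frame context; use bind(player, frame)",
         call. = FALSE)
  }
  frame <- player[["frame"]]
  mt <- frame_match(frame)
  pos <- player_pos(mt, player[["id"]], frame[["row"]])
  if (is_absent(pos)) stop("no tracked position for this player at this frame",
                           call. = FALSE)
  wall_distances(pos, ufield(mt, "geometry"), player)
}

#' Speed and acceleration of a bound player
#'
#' Central finite differences of the player's court position over
#' `+/- window` frames of the same point (one-sided at point boundaries),
#' divided by elapsed time. Acceleration differentiates the speed the same
#' way. The default window is the match configuration's `speed_window`
#' (5 frames, about 0.33 s at 30 fps).
#'
#' @param player a bound `padel_player`.
#' @param window half-width of the differentiation window, frames.
#' @return a `court_vec` with components `x`, `y` and `magnitude`.
#' @export
player_speed <- function(player, window = NULL) {
  with_speed_window(player, window, order = 1L)
}

#' @rdname player_speed
#' @export
player_acceleration <- function(player, window = NULL) {
  with_speed_window(player, window, order = 2L)
}

with_speed_window <- function(player, window, order) {
  stopifnot(inherits(player, "padel_player"))
  if (!is_bound(player)) {
    stop("kinematics require a frame context; use bind(player, frame)",
         call. = FALSE)
  }
  finite_difference(player, order = order,
                    w = if (is.null(window)) NULL else as.integer(window))
}

#' Direction of a shot
#'
#' The origin is the hitter's position at the shot's start frame; the
#' destination is proxied by the position of the player who returns the ball
#' (the next shot's hitter at the next shot's start frame) since the ball
#' itself is not tracked. The angle is measured in degrees against the court
#' long axis oriented away from the hitter: 0 is straight down the line,
#' positive angles point toward the hitter's right.
#'
#' @param shot a `padel_shot`.
#' @return a list with `origin`, `destination` (court points), `angle` and
#'   `abs_angle` (degrees), or [absent] for the last shot of a point or when
#'   positions are untracked.
#' @export
shot_direction <- function(shot) {
  if (is_absent(shot)) return(absent)
  stopifnot(inherits(shot, "padel_shot"))
  nx <- nav_next(shot)
  if (is_absent(nx)) return(absent)
  mt <- frame_match(shot)
  o <- hit_position(shot)
  d <- hit_position(nx)
  if (is_absent(o) || is_absent(d)) return(absent)
  geom <- ufield(mt, "geometry")
  ang <- signed_angle(o, d, geom)
  structure(list(origin = o, destination = d,
                 angle = ang, abs_angle = abs(ang)),
            class = "shot_direction")
}

hit_position <- function(shot) {
  fr <- shot_frames(shot)
  if (!length(fr)) return(absent)
  mt <- frame_match(shot)
  player_pos(mt, ufield(shot, "hitter_id"), fr[[1]][["row"]])
}

signed_angle <- function(origin, dest, geom) {
  dx <- dest$x - origin$x
  dy <- dest$y - origin$y
  if (dx == 0 && dy == 0) return(0)
  bottom <- origin$y < geom$net_y
  ang <- if (bottom) atan2(dx, dy) else atan2(-dx, -dy)
  ang <- ang * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

shot_angle <- function(shot, absolute = FALSE) {
  sd <- shot_direction(shot)
  if (is_absent(sd)) return(absent)
  if (absolute) sd$abs_angle else sd$angle
}

match_config <- function(match) ufield(match, "config")
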