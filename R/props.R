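# Fluent property access.
#
# `$` on play units, players and teams resolves *computed* properties, so the
# notebook-style chained paths work interactively:
#
#   shot$point$winner
#   shot$nxt$hitter$distance_to_net
#   frame_unit$match$gender
#
# The same resolver backs the string expression grammar (see expr.R), where
# the dotted-path spelling `shot.next.hitter.distance_to_net` is used.
# Every accessor follows the absent contract: navigating past an edge or
# asking for position data that does not exist yields `absent`, not an error.

prop_missing <- structure(list(), class = "padel_prop_missing")
is_prop_missing <- function(x) inherits(x, "padel_prop_missing")

get_prop <- function(x, name) UseMethod("get_prop")

#' @export
get_prop.default <- function(x, name) {
  if (is.list(x) && name %in% names(x)) return(x[[name]])
  prop_missing
}

#' @export
get_prop.padel_absent <- function(x, name) absent

# ---- units ------------------------------------------------------------------

#' @export
get_prop.padel_unit <- function(x, name) {
  lvl <- unit_level(x)

  # navigation ---------------------------------------------------------------
  if (name %in% c("next", "nxt")) return(nav_next(x))
  if (name == "prev") return(nav_prev(x))
  if (name %in% PADEL_LEVELS) {
    lvl_i <- match(lvl, PADEL_LEVELS); tgt_i <- match(name, PADEL_LEVELS)
    if (tgt_i < lvl_i) return(nav_parent(x, name))
    if (tgt_i == lvl_i) return(x)
    # descendant level names fall through (a shot's "frame" is a property)
  }
  if (lvl != "frame" && name == CHILD_FIELD[[lvl]]) return(nav_children(x))

  # shared temporal contract -------------------------------------------------
  fps <- match_fps(frame_match(x))
  if (lvl == "frame") {
    if (name == "frame_number") return(x[["frame_number"]])
    if (name == "time") return(x[["frame_number"]] / fps)
    if (name %in% c("start_time", "end_time")) {
      return(x[["frame_number"]] / fps + if (name == "end_time") 1 / fps else 0)
    }
    if (name %in% c("start_frame", "end_frame")) {
      return(x[["frame_number"]] + if (name == "end_frame") 1L else 0L)
    }
    if (name == "duration") return(1 / fps)
    if (name == "number") return(x[["index"]])
    if (name == "tags") return(frame_tags_get(x))
    if (name == "id") return(x[["frame_number"]])
    if (name == "positions") return(frame_positions(x))
  } else {
    if (name %in% c("start_frame", "end_frame", "number")) {
      return(ufield(x, name) %||% prop_missing)
    }
    if (name == "start_time") return(ufield(x, "start_frame") / fps)
    if (name == "end_time") return(ufield(x, "end_frame") / fps)
    if (name == "tags") return(ufield(x, "tags"))
    if (name == "duration") {
      if (lvl == "shot") return(shot_duration(x))
      return((ufield(x, "end_frame") - ufield(x, "start_frame")) / fps)
    }
    if (name == "id") return(unit_id(x))
  }

  # level-specific -----------------------------------------------------------
  res <- switch(lvl,
    match = match_prop(x, name),
    set = ,
    game = scored_prop(x, name),
    point = point_prop(x, name),
    shot = shot_prop(x, name),
    frame = frame_prop(x, name),
    prop_missing
  )
  res
}

match_prop <- function(x, name) {
  if (name %in% c("title", "gender", "teams", "players", "video", "geometry",
                  "winner", "loser", "score", "scoring_mode")) {
    return(ufield(x, name) %||% absent)
  }
  prop_missing
}

scored_prop <- function(x, name) {
  if (name %in% c("winner", "loser", "score")) return(ufield(x, name) %||% absent)
  prop_missing
}

point_prop <- function(x, name) {
  if (name %in% c("winner", "loser", "valid", "score_after")) {
    return(ufield(x, name) %||% absent)
  }
  if (name == "serve") {
    sh <- ufield(x, "shots")
    return(if (length(sh)) sh[[1]] else absent)
  }
  prop_missing
}

shot_prop <- function(x, name) {
  if (name %in% c("shot_type", "shot_code", "type")) return(ufield(x, "shot_code"))
  if (name == "lob") return(isTRUE(ufield(x, "lob")))
  if (name == "hitter") return(shot_hitter(x))
  if (name == "receiver") {
    nx <- nav_next(x)
    if (is_absent(nx)) return(absent)
    return(shot_hitter(nx))
  }
  if (name == "frame") {
    fr <- shot_frames(x)
    return(if (length(fr)) fr[[1]] else absent)
  }
  if (name == "angle") return(shot_angle(x, absolute = FALSE))
  if (name == "abs_angle") return(shot_angle(x, absolute = TRUE))
  prop_missing
}

frame_prop <- function(x, name) {
  prop_missing
}

unit_id <- function(x) {
  switch(unit_level(x),
    match = ufield(x, "title") %||% "match",
    set = sprintf("s%d", ufield(x, "number")),
    game = sprintf("g%d-s%d", ufield(x, "number"),
                   ufield(nav_parent(x, "set"), "number")),
    point = point_id(x),
    shot = paste0(point_id(nav_parent(x, "point")), "-sh", ufield(x, "number")),
    "?"
  )
}

point_id <- function(p) {
  g <- nav_parent(p, "game"); s <- nav_parent(p, "set")
  sprintf("g%d-s%d-p%d", ufield(g, "number"), ufield(s, "number"),
          ufield(p, "number"))
}

# the player who hit a shot, bound to the shot's first tracked frame (or
# unbound if the frames table has no rows for the shot)
shot_hitter <- function(shot) {
  mt <- frame_match(shot)
  p <- match_player(mt, ufield(shot, "hitter_id"))
  if (is.null(p)) return(absent)
  fr <- shot_frames(shot)
  if (length(fr)) p[["frame"]] <- fr[[1]]
  p
}

match_player <- function(match, id) {
  for (p in ufield(match, "players")) if (identical(p[["id"]], id)) return(p)
  NULL
}

shot_duration <- function(shot) {
  nx <- nav_next(shot)
  if (is_absent(nx)) return(absent)
  fps <- match_fps(frame_match(shot))
  (ufield(nx, "start_frame") - ufield(shot, "start_frame")) / fps
}

frame_positions <- function(frame) {
  mt <- frame_match(frame)
  row <- frame[["row"]]
  out <- list()
  tbl <- ufield(mt, "frames_tbl")
  for (p in ufield(mt, "players")) {
    xc <- tbl[[paste0(p[["id"]], "_x")]][row]
    yc <- tbl[[paste0(p[["id"]], "_y")]][row]
    out[[p[["id"]]]] <- court_point(xc, yc)
  }
  out
}

court_point <- function(x, y) {
  if (is.na(x) || is.na(y)) return(absent)
  structure(list(x = x, y = y), class = "court_point")
}

#' @export
print.court_point <- function(x, ...) {
  cat(sprintf("(%.2f, %.2f)\n", x$x, x$y)); invisible(x)
}

#' @export
format.court_point <- function(x, ...) sprintf("(%.2f, %.2f)", x$x, x$y)

# ---- `$` methods ------------------------------------------------------------

#' @export
`$.padel_unit` <- function(x, name) {
  res <- get_prop(x, name)
  if (is_prop_missing(res)) {
    stop("unknown property '", name, "' for a ", unit_level(x),
         call. = FALSE)
  }
  res
}

#' @export
`$.padel_player` <- function(x, name) {
  res <- get_prop(x, name)
  if (is_prop_missing(res)) {
    stop("unknown property '", name, "' for a player", call. = FALSE)
  }
  res
}

#' @export
`$.padel_team` <- function(x, name) {
  res <- get_prop(x, name)
  if (is_prop_missing(res)) {
    stop("unknown property '", name, "' for a team", call. = FALSE)
  }
  res
}

#' @export
get_prop.padel_team <- function(x, name) {
  if (name %in% c("players", "label", "match")) return(ufield(x, name))
  if (name == "name") return(ufield(x, "label"))
  if (name %in% c("forehand_player", "backhand_player")) {
    return(ufield(x, name) %||% absent)
  }
  prop_missing
}

#' @export
get_prop.padel_player <- function(x, name) {
  if (name %in% c("first_name", "last_name", "gender", "id")) return(x[[name]])
  if (name == "team_label") return(x[["team_label"]])
  if (name == "team") {
    mt <- x[["match"]]
    if (is.null(mt)) return(absent)
    for (t in mt$teams) {
      if (x[["id"]] %in% vapply(ufield(t, "players"), function(p) p[["id"]], character(1))) return(t)
    }
    return(absent)
  }
  if (name == "frame") return(x$frame %||% absent)
  if (name == "partner") {
    tm <- get_prop(x, "team")
    if (is_absent(tm)) return(absent)
    other <- Filter(function(p) !identical(p[["id"]], x[["id"]]),
                    ufield(tm, "players"))[[1]]
    if (!is.null(x[["frame"]])) other[["frame"]] <- x[["frame"]]
    return(other)
  }
  if (name %in% KINEMATIC_PROPS) return(bound_kinematic(x, name))
  prop_missing
}
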