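# Temporal play units.
#
# A match decomposes into sets, games, points, shots and frames; every level
# shares the same contract: a [start_frame, end_frame) span, a 1-based
# ordinal within its parent, and a dynamic tag set. Match/set/game/point/shot
# are mutable environments (tags are added in place); frames are lightweight
# lists materialised on demand from the per-frame positions table, with their
# tags kept in a per-match side table keyed by frame number.

PADEL_LEVELS <- c("match", "set", "game", "point", "shot", "frame")
CHILD_FIELD <- c(match = "sets", set = "games", game = "points",
                 point = "shots", shot = "frames")
CHILD_LEVEL <- c(match = "set", set = "game", game = "point",
                 point = "shot", shot = "frame")

unit_level <- function(x) {
  cls <- class(x)[1]
  sub("^padel_", "", cls)
}

new_unit_env <- function(level, fields = list()) {
  u <- new.env(parent = emptyenv())
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = u)
  if (is.null(u$tags)) u$tags <- character(0)
  class(u) <- c(paste0("padel_", level), "padel_unit")
  u
}

ufield <- function(x, name) {
  if (is.environment(x)) {
    get0(name, envir = x, inherits = FALSE)
  } else {
    x[[name]]
  }
}

# the match a unit belongs to, walking parent references
frame_match <- function(x) {
  while (!inherits(x, "padel_match")) {
    x <- ufield(x, "parent")
    if (is.null(x)) stop("unit has no match ancestor", call. = FALSE)
  }
  x
}

match_fps <- function(match) ufield(match, "video")$fps

#' Navigate to the children of a play unit
#'
#' @param unit a play unit (match, set, game, point or shot).
#' @param kind the immediate child level: `"set"` for a match, `"game"` for a
#'   set, `"point"` for a game, `"shot"` for a point, `"frame"` for a shot.
#'   Defaults to the unit's immediate child level.
#' @return a list of child units in temporal order (possibly empty).
#' @export
nav_children <- function(unit, kind = NULL) {
  lvl <- unit_level(unit)
  if (lvl == "frame") stop("frames have no children", call. = FALSE)
  expected <- CHILD_LEVEL[[lvl]]
  if (is.null(kind)) kind <- expected
  kind <- sub("s$", "", tolower(kind))
  if (!identical(kind, expected)) {
    stop("a ", lvl, " has children of level '", expected,
         "' (requested '", kind, "')", call. = FALSE)
  }
  if (lvl == "shot") return(shot_frames(unit))
  ufield(unit, CHILD_FIELD[[lvl]]) %||% list()
}

#' Navigate to an ancestor of a play unit
#'
#' Skip-level access is allowed: `nav_parent(frame, "match")` equals the
#' fully chained `frame -> shot -> point -> game -> set -> match` walk.
#'
#' @param unit a play unit.
#' @param level the ancestor level name.
#' @return the unique ancestor unit.
#' @export
nav_parent <- function(unit, level) {
  level <- tolower(level)
  lvl_i <- match(unit_level(unit), PADEL_LEVELS)
  tgt_i <- match(level, PADEL_LEVELS)
  if (is.na(tgt_i)) stop("unknown level '", level, "'", call. = FALSE)
  if (tgt_i >= lvl_i) {
    stop("'", level, "' is not an ancestor level of a ", unit_level(unit),
         call. = FALSE)
  }
  x <- unit
  while (unit_level(x) != level) x <- ufield(x, "parent")
  x
}

#' Navigate to the next / previous sibling
#'
#' Siblings are ordered temporally within the same parent. Past either end
#' the [absent] sentinel is returned, never an error, so predicates such as
#' `shot.next.next.like("volley")` are safe on short rallies.
#'
#' @param unit a play unit with a parent.
#' @return the sibling unit, or [absent].
#' @export
nav_next <- function(unit) nav_sibling(unit, +1L)

#' @rdname nav_next
#' @export
nav_prev <- function(unit) nav_sibling(unit, -1L)

nav_sibling <- function(unit, step) {
  if (is_absent(unit)) return(absent)
  lvl <- unit_level(unit)
  if (lvl == "match") return(absent)
  if (lvl == "frame") {
    shot <- unit[["shot"]]
    sibs <- shot_frames(shot)
    i <- unit[["index"]] + step
    if (i < 1L || i > length(sibs)) return(absent)
    return(sibs[[i]])
  }
  parent <- ufield(unit, "parent")
  sibs <- ufield(parent, CHILD_FIELD[[unit_level(parent)]])
  i <- ufield(unit, "number") + step
  if (i < 1L || i > length(sibs)) return(absent)
  sibs[[i]]
}

# ---- frames -----------------------------------------------------------------

# Materialise the frame objects of a shot. `frame_rows` on the shot holds the
# row indices of the match frames table inside the shot's span.
shot_frames <- function(shot) {
  cached <- ufield(shot, ".frames_cache")
  if (!is.null(cached)) return(cached)
  rows <- ufield(shot, "frame_rows")
  if (is.null(rows) || length(rows) == 0L) return(list())
  mt <- frame_match(shot)
  fn <- ufield(mt, "frames_tbl")$frame_number[rows]
  out <- lapply(seq_along(rows), function(i) {
    new_frame(shot, rows[i], fn[i], i)
  })
  assign(".frames_cache", out, envir = shot)
  out
}

new_frame <- function(shot, row, frame_number, index) {
  mt <- frame_match(shot)
  structure(
    list(
      frame_number = frame_number,
      row = row,
      index = index,
      shot = shot,
      parent = shot,
      number = index,
      match = mt
    ),
    class = c("padel_frame", "padel_unit")
  )
}

frame_tags_get <- function(frame) {
  mt <- frame_match(frame)
  key <- as.character(frame[["frame_number"]])
  get0(key, envir = ufield(mt, "frame_tags"), inherits = FALSE) %||% character(0)
}

frame_tags_add <- function(frame, tag) {
  mt <- frame_match(frame)
  key <- as.character(frame[["frame_number"]])
  tags_env <- ufield(mt, "frame_tags")
  cur <- get0(key, envir = tags_env, inherits = FALSE) %||% character(0)
  assign(key, union(cur, tag), envir = tags_env)
  invisible(frame)
}

# ---- traversal --------------------------------------------------------------

# All units of a level inside a scope (a match or list of matches), in
# temporal order. This is the item stream behind query execution and tag
# application.
collect_units <- function(scope, level) {
  matches <- if (inherits(scope, "padel_match")) list(scope) else scope
  stopifnot(all(vapply(matches, inherits, logical(1), "padel_match")))
  out <- list()
  for (mt in matches) {
    items <- list(mt)
    lvl <- "match"
    while (lvl != level) {
      nxt_lvl <- CHILD_LEVEL[[lvl]]
      items <- unlist(lapply(items, function(u) nav_children(u, nxt_lvl)),
                      recursive = FALSE)
      lvl <- nxt_lvl
      if (length(items) == 0L) break
    }
    if (lvl == level) out <- c(out, items)
  }
  out
}

#' @export
print.padel_unit <- function(x, ...) {
  lvl <- unit_level(x)
  sf <- ufield(x, "start_frame") %||% ufield(x, "frame_number")
  ef <- ufield(x, "end_frame")
  span <- if (is.null(ef)) sprintf("frame %s", format(sf)) else
    sprintf("frames [%s, %s)", format(sf), format(ef))
  n <- ufield(x, "number")
  cat(sprintf("<%s%s %s>\n", lvl, if (is.null(n)) "" else paste0(" #", n), span))
  invisible(x)
}

#' @export
print.padel_match <- function(x, ...) {
  n_sets <- length(ufield(x, "sets"))
  n_points <- length(collect_units(x, "point"))
  n_shots <- length(collect_units(x, "shot"))
  cat(sprintf("<padel match '%s': %d set(s), %d point(s), %d shot(s), %g fps>\n",
              ufield(x, "title") %||% "untitled", n_sets, n_points, n_shots,
              match_fps(x)))
  invisible(x)
}

#' @export
Ops.padel_unit <- function(e1, e2) {
  if (missing(e2)) {
    if (.Generic == "!") return(!truthy(e1))
    stop("operation '", .Generic, "' is not defined for play units", call. = FALSE)
  }
  if (is_absent(e1) || is_absent(e2)) {
    return(switch(.Generic, "==" = FALSE, "!=" = FALSE, FALSE))
  }
  ueq <- function(a, b) {
    if (inherits(a, "padel_unit") && inherits(b, "padel_unit")) {
      if (is.environment(a) && is.environment(b)) return(identical(a, b))
      return(identical(unclass(a)[c("frame_number", "row")],
                       unclass(b)[c("frame_number", "row")]) &&
               identical(a[["shot"]], b[["shot"]]))
    }
    FALSE
  }
  switch(.Generic,
    "==" = ueq(e1, e2),
    "!=" = !ueq(e1, e2),
    stop("operation '", .Generic, "' is not defined for play units", call. = FALSE)
  )
}
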