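# Players and teams.
#
# A Player carries identity only (name, gender, team). Positional and
# kinematic attributes exist only once a player is *bound* to a frame of the
# video; `bind()` attaches the frame context and the bound player then
# exposes position, speed, wall distances etc. Equality between players
# always compares identity and ignores any binding, so
# `shot.next.hitter == shot.next.next.next.hitter` asks "same person?" even
# though the two hitters are bound to different frames.

player_id_from_name <- function(last_name) {
  id <- tolower(trimws(last_name))
  id <- iconv(id, from = "UTF-8", to = "ASCII//TRANSLIT")
  gsub("[^a-z0-9]+", "", id)
}

new_player <- function(first_name, last_name, gender = NA_character_,
                       team_label = NA_character_, match = NULL) {
  structure(
    list(
      first_name = first_name,
      last_name = last_name,
      gender = gender,
      team_label = team_label,
      id = player_id_from_name(last_name),
      match = match,
      frame = NULL  # unbound
    ),
    class = "padel_player"
  )
}

new_team <- function(label, players, match = NULL) {
  t <- new.env(parent = emptyenv())
  t$label <- label            # "T" (top) or "B" (bottom) at the match's first point
  t$players <- players        # list of two padel_player
  t$forehand_player <- NULL   # filled during assembly
  t$backhand_player <- NULL
  t$match <- match
  class(t) <- "padel_team"
  t
}

#' Bind a player to a frame
#'
#' Attaches a frame context to a player so that positional and kinematic
#' attributes (`position`, `speed`, `distance_to_net`, ...) become available.
#'
#' @param player a `padel_player`, typically obtained from navigation
#'   (`shot$hitter` is already bound to the shot's start frame).
#' @param frame a `padel_frame` of the same match.
#' @return the player, bound to `frame`.
#' @export
bind <- function(player, frame) {
  if (is_absent(player) || is_absent(frame)) return(absent)
  stopifnot(inherits(player, "padel_player"), inherits(frame, "padel_unit"))
  mt <- frame_match(frame)
  ids <- vapply(ufield(mt, "players"), function(p) p[["id"]], character(1))
  if (!player[["id"]] %in% ids) {
    stop("player '", player[["last_name"]], "' is not part of this match", call. = FALSE)
  }
  player[["frame"]] <- frame
  player
}

is_bound <- function(player) !is.null(player[["frame"]])

#' @export
print.padel_player <- function(x, ...) {
  bound <- if (is_bound(x)) {
    sprintf(" @ frame %d", x[["frame"]][["frame_number"]])
  } else ""
  cat(sprintf("<player %s %s (%s team)%s>\n",
              x[["first_name"]], x[["last_name"]],
              x[["team_label"]] %||% "?", bound))
  invisible(x)
}

#' @export
print.padel_team <- function(x, ...) {
  nm <- vapply(ufield(x, "players"), function(p) p[["last_name"]], character(1))
  cat(sprintf("<team %s: %s>\n", x$label, paste(nm, collapse = " / ")))
  invisible(x)
}

player_eq <- function(a, b) {
  pa <- inherits(a, "padel_player"); pb <- inherits(b, "padel_player")
  if (pa && pb) return(identical(a[["id"]], b[["id"]]))
  # player compared against a tag-like string: match on id or last name
  if (pa && is.character(b)) return(tolower(b) %in% c(a[["id"]], tolower(a[["last_name"]])))
  if (pb && is.character(a)) return(tolower(a) %in% c(b[["id"]], tolower(b[["last_name"]])))
  FALSE
}

#' @export
Ops.padel_player <- function(e1, e2) {
  if (missing(e2)) {
    if (.Generic == "!") return(FALSE)
    stop("operation '", .Generic, "' is not defined for players", call. = FALSE)
  }
  if (is_absent(e1) || is_absent(e2)) {
    return(switch(.Generic, "==" = FALSE, "!=" = FALSE,
                  stop("operation '", .Generic, "' is not defined for players",
                       call. = FALSE)))
  }
  switch(.Generic,
    "==" = player_eq(e1, e2),
    "!=" = {
      # equality ignores binding; inequality is its plain negation
      !player_eq(e1, e2)
    },
    stop("operation '", .Generic, "' is not defined for players", call. = FALSE)
  )
}

#' @export
Ops.padel_team <- function(e1, e2) {
  if (missing(e2)) {
    if (.Generic == "!") return(FALSE)
    stop("operation '", .Generic, "' is not defined for teams", call. = FALSE)
  }
  if (is_absent(e1) || is_absent(e2)) {
    return(switch(.Generic, "==" = FALSE, "!=" = FALSE,
                  stop("operation '", .Generic, "' is not defined for teams",
                       call. = FALSE)))
  }
  teq <- function(a, b) {
    if (inherits(a, "padel_team") && inherits(b, "padel_team")) {
      return(identical(ufield(a, "label"), ufield(b, "label")) &&
               identical(ufield(a, "match"), ufield(b, "match")))
    }
    if (inherits(a, "padel_team") && is.character(b)) return(toupper(b) == ufield(a, "label"))
    if (inherits(b, "padel_team") && is.character(a)) return(toupper(a) == ufield(b, "label"))
    FALSE
  }
  switch(.Generic,
    "==" = teq(e1, e2),
    "!=" = !teq(e1, e2),
    stop("operation '", .Generic, "' is not defined for teams", call. = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
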