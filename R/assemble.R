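# Assembling the match hierarchy from the three tables.

#' Ingest configuration
#'
#' @param fps frames per second; `NULL` infers it from the points table's
#'   duration columns via [infer_fps()].
#' @param scoring_mode `"auto"` picks the mode (advantage vs golden point)
#'   that best reproduces the printed score columns, ties going to
#'   `"advantage"`.
#' @param lenient if `TRUE` (default), printed score columns that disagree
#'   with the automaton replay degrade to warnings -- truncated tables (with
#'   points removed) still parse; if `FALSE` they are an error naming the
#'   first divergent point.
#' @param clamp_tolerance_frames shots annotated slightly outside their
#'   point's span (frame numbers in these datasets are approximate) are
#'   clamped into the nearest point if within this many frames; beyond it,
#'   ingest errors.
#' @param bounds_tolerance meters of slack outside the court rectangle
#'   before a position is flagged by [validate_match()] (players step through
#'   the net-side openings and tracking error is ~0.3 m).
#' @param speed_window half-width in frames of the finite-difference window
#'   for speed/acceleration.
#' @param spanish_aliases whether tag matching also accepts the Spanish
#'   shot-type expansions.
#' @param video_url optional URL of the source video, used for deep links.
#' @param forehand optional named list/character overriding the inferred
#'   forehand player per team, e.g. `list(T = "Sainz", B = "Salazar")`.
#' @return a `padel_config` list.
#' @export
padel_config <- function(fps = NULL,
                         scoring_mode = c("auto", "advantage", "golden_point"),
                         lenient = TRUE,
                         clamp_tolerance_frames = 30L,
                         bounds_tolerance = 0.5,
                         speed_window = 5L,
                         spanish_aliases = FALSE,
                         video_url = NULL,
                         forehand = NULL) {
  structure(list(
    fps = fps,
    scoring_mode = match.arg(scoring_mode),
    lenient = lenient,
    clamp_tolerance_frames = as.integer(clamp_tolerance_frames),
    bounds_tolerance = bounds_tolerance,
    speed_window = as.integer(speed_window),
    spanish_aliases = spanish_aliases,
    video_url = video_url,
    forehand = forehand
  ), class = "padel_config")
}

split_name <- function(full) {
  full <- trimws(full)
  parts <- strsplit(full, "\\s+")[[1]]
  if (length(parts) == 1L) return(c(first = "", last = parts))
  c(first = paste(parts[-length(parts)], collapse = " "),
    last = parts[length(parts)])
}

#' Assemble a match from the three tables
#'
#' Builds the navigable match hierarchy: the roster and the two teams come
#' from the points table's corner names; games and sets are reconstructed by
#' replaying the winner column through [score_automaton()] (checking the
#' printed score columns along the way); each shot is attributed to a player
#' through its enclosing point's corner map and owns the frames in the
#' half-open interval up to the next shot; built-in tags (shot type, serve,
#' lob, hitter, winning) are inserted.
#'
#' @param points,shots,frames tibbles from [read_points()], [read_shots()],
#'   [read_frames()] (or the synthetic generator).
#' @param config a [padel_config()].
#' @param title match title (used as match id in query provenance).
#' @param gender optional category label.
#' @return a `padel_match` object.
#' @export
assemble_match <- function(points, shots = NULL, frames = NULL,
                           config = padel_config(), title = "match",
                           gender = NA_character_) {
  if (nrow(points) == 0L) stop("points table is empty", call. = FALSE)
  points <- dplyr::arrange(points, .data$start)
  fps <- config$fps %||% infer_fps(points)
  if (is.null(shots)) shots <- tibble::tibble(
    frame = integer(), corner = character(), shot_code = character(),
    lob = logical())
  if (is.null(frames)) frames <- tibble::tibble(frame_number = integer())

  mt <- new_unit_env("match", list(
    title = title, gender = gender,
    video = list(url = config$video_url, fps = as.numeric(fps)),
    geometry = court_geometry(),
    config = config,
    frame_tags = new.env(parent = emptyenv()),
    start_frame = min(points$start), end_frame = max(points$end)
  ))

  # ---- roster & teams -------------------------------------------------------
  roster_names <- unique(c(t(as.matrix(points[, CORNERS]))))
  if (length(roster_names) != 4L) {
    stop("expected exactly 4 distinct player names across the corner ",
         "columns, found ", length(roster_names), call. = FALSE)
  }
  first_pt <- points[1, ]
  top_names <- c(first_pt$tl, first_pt$tr)
  players <- lapply(roster_names, function(nm) {
    sp <- split_name(nm)
    new_player(sp[["first"]], sp[["last"]], gender = gender,
               team_label = if (nm %in% top_names) "T" else "B", match = mt)
  })
  ids <- vapply(players, function(p) p[["id"]], character(1))
  if (anyDuplicated(ids)) {
    stop("player last names must be unique within a match: ",
         paste(roster_names, collapse = ", "), call. = FALSE)
  }
  mt$players <- players
  team_of <- function(lbl) {
    new_team(lbl, Filter(function(p) identical(p[["team_label"]], lbl), players),
             match = mt)
  }
  mt$teams <- list(T = team_of("T"), B = team_of("B"))

  # name lookup per point: corner code -> player id
  name2id <- stats::setNames(ids, roster_names)
  corner_maps <- lapply(seq_len(nrow(points)), function(i) {
    stats::setNames(unname(name2id[unlist(points[i, CORNERS])]), CORNERS)
  })
  # team of the winner label for a given point (top/bottom identity is taken
  # per point from the corner names, never assumed constant)
  point_team <- function(i, lbl) {
    top_ids <- unname(corner_maps[[i]][c("tl", "tr")])
    t_ids <- vapply(ufield(mt$teams$T, "players"), function(p) p[["id"]],
                    character(1))
    top_is_T <- all(top_ids %in% t_ids)
    if (identical(lbl, "T")) {
      if (top_is_T) mt$teams$T else mt$teams$B
    } else {
      if (top_is_T) mt$teams$B else mt$teams$T
    }
  }

  # ---- score reconstruction -------------------------------------------------
  has_printed <- !is.null(points[["points_T"]]) && !is.null(points[["points_B"]])
  mode <- config$scoring_mode
  if (mode == "auto") {
    mode <- if (has_printed) {
      detect_scoring_mode(points$winner, points$points_T, points$points_B)$mode
    } else "advantage"
  }
  replay <- score_automaton(points$winner, mode)
  if (has_printed) {
    bad <- which(replay$score_T != points[["points_T"]] |
                   replay$score_B != points[["points_B"]])
    if (length(bad)) {
      msg <- paste0("printed scores diverge from the ", mode,
                    " replay first at point ", bad[1], " (printed ",
                    points[["points_T"]][bad[1]], "-", points[["points_B"]][bad[1]],
                    ", replay ", replay$score_T[bad[1]], "-",
                    replay$score_B[bad[1]], ")")
      if (config$lenient) warning(msg, call. = FALSE) else
        stop(msg, call. = FALSE)
    }
  }

  # ---- frames table in player coordinates -----------------------------------
  frames <- dplyr::arrange(frames, .data$frame_number)
  pt_of_frame <- findInterval(frames$frame_number, points$start)
  inside <- pt_of_frame >= 1 &
    frames$frame_number < points$end[pmax(pt_of_frame, 1L)] &
    frames$frame_number >= points$start[pmax(pt_of_frame, 1L)]
  n_out <- sum(!inside)
  if (n_out > 0) {
    warning(n_out, " frame row(s) fall outside every point span and were ",
            "dropped", call. = FALSE)
  }
  frames <- frames[inside, , drop = FALSE]
  pt_of_frame <- pt_of_frame[inside]
  ftbl <- tibble::tibble(frame_number = frames$frame_number)
  for (pid in ids) for (ax in c("x", "y", "i", "j")) {
    ftbl[[paste0(pid, "_", ax)]] <- rep(NA_real_, nrow(frames))
  }
  if (nrow(frames)) {
    for (crn in CORNERS) for (ax in c("x", "y", "i", "j")) {
      src <- frames[[paste0(crn, "_", ax)]]
      if (is.null(src)) next
      pid_per_row <- vapply(pt_of_frame, function(i) corner_maps[[i]][[crn]],
                            character(1))
      for (pid in unique(pid_per_row)) {
        sel <- pid_per_row == pid
        col <- paste0(pid, "_", ax)
        ftbl[[col]][sel] <- src[sel]
      }
    }
  }
  mt$frames_tbl <- ftbl

  # ---- hierarchy ------------------------------------------------------------
  sets <- list()
  for (si in unique(replay$set)) {
    set_rows <- which(replay$set == si)
    set_env <- new_unit_env("set", list(parent = mt, number = si))
    games <- list()
    for (gi in unique(replay$game[set_rows])) {
      g_rows <- which(replay$game == gi)
      game_env <- new_unit_env("game", list(
        parent = set_env,
        number = base::match(gi, unique(replay$game[set_rows]))
      ))
      pts <- list()
      for (k in seq_along(g_rows)) {
        i <- g_rows[k]
        winner <- point_team(i, points$winner[i])
        loser <- point_team(i, setdiff(c("T", "B"), points$winner[i]))
        pt_env <- new_unit_env("point", list(
          parent = game_env, number = k,
          start_frame = points$start[i], end_frame = points$end[i],
          winner = winner, loser = loser,
          valid = if (!is.null(points[["valid"]])) points[["valid"]][i] else TRUE,
          score_after = c(replay$score_T[i], replay$score_B[i]),
          corner_map = corner_maps[[i]],
          frame_rows = which(pt_of_frame == i),
          row = i
        ))
        pts[[k]] <- pt_env
      }
      game_env$points <- pts
      game_env$start_frame <- points$start[g_rows[1]]
      game_env$end_frame <- points$end[g_rows[length(g_rows)]]
      last <- replay[g_rows[length(g_rows)], ]
      if (last$game_over) {
        game_env$winner <- point_team(g_rows[length(g_rows)], last$winner)
        game_env$loser <- point_team(g_rows[length(g_rows)],
                                     setdiff(c("T", "B"), last$winner))
        game_env$score <- paste0(last$games_T, "-", last$games_B)
      }
      games[[length(games) + 1L]] <- game_env
    }
    set_env$games <- games
    set_env$start_frame <- ufield(games[[1]], "start_frame")
    set_env$end_frame <- ufield(games[[length(games)]], "end_frame")
    last <- replay[set_rows[length(set_rows)], ]
    if (last$set_over) {
      w_lbl <- if (last$games_T > last$games_B) "T" else "B"
      set_env$winner <- mt$teams[[w_lbl]]
      set_env$loser <- mt$teams[[setdiff(c("T", "B"), w_lbl)]]
      set_env$score <- paste0(last$games_T, "-", last$games_B)
    }
    sets[[si]] <- set_env
  }
  mt$sets <- sets
  fin <- replay[nrow(replay), ]
  if (fin$sets_T != fin$sets_B) {
    w_lbl <- if (fin$sets_T > fin$sets_B) "T" else "B"
    mt$winner <- mt$teams[[w_lbl]]
    mt$score <- paste0(fin$sets_T, "-", fin$sets_B)
  }
  mt$scoring_mode <- mode

  attach_shots(mt, points, shots, corner_maps, pt_of_frame)
  assign_forehand(mt)
  auto_tags(mt)
  mt
}

# distribute shot records to points (clamping approximate frame numbers into
# the enclosing span) and carve each point's frames into half-open shot spans
attach_shots <- function(mt, points, shots, corner_maps, pt_of_frame) {
  cfg <- match_config(mt)
  all_points <- collect_units(mt, "point")
  pt_rows <- vapply(all_points, function(p) ufield(p, "row"), integer(1))
  per_point <- vector("list", length(all_points))
  if (nrow(shots)) {
    shots <- dplyr::arrange(shots, .data$frame)
    for (r in seq_len(nrow(shots))) {
      f <- shots$frame[r]
      i <- findInterval(f, points$start)
      hit <- NA_integer_
      if (i >= 1 && f < points$end[i]) hit <- i
      if (is.na(hit)) {
        # approximate annotation: clamp into the nearest point if close
        d_next <- if (i < nrow(points)) points$start[i + 1L] - f else Inf
        d_prev <- if (i >= 1) f - points$end[i] + 1L else Inf
        if (min(d_next, d_prev) > cfg$clamp_tolerance_frames) {
          stop("shot at frame ", f, " lies inside no point and beyond the ",
               "clamping tolerance (", cfg$clamp_tolerance_frames, " frames)",
               call. = FALSE)
        }
        hit <- if (d_next <= d_prev) i + 1L else i
        clamped <- max(points$start[hit], min(f, points$end[hit] - 1L))
        warning("shot at frame ", f, " clamped to frame ", clamped,
                " inside point ", hit, " (approximate annotation)",
                call. = FALSE)
        f <- clamped
      }
      per_point[[hit]] <- c(per_point[[hit]], list(list(frame = f, row = r)))
    }
  }
  for (k in seq_along(all_points)) {
    pt_env <- all_points[[k]]
    i <- pt_rows[k]
    recs <- per_point[[i]]
    sh_list <- list()
    if (length(recs)) {
      ord <- order(vapply(recs, function(z) z$frame, numeric(1)))
      recs <- recs[ord]
      starts <- vapply(recs, function(z) z$frame, numeric(1))
      ends <- c(starts[-1], ufield(pt_env, "end_frame"))
      prows <- ufield(pt_env, "frame_rows")
      pfn <- ufield(mt, "frames_tbl")$frame_number[prows]
      for (s in seq_along(recs)) {
        r <- recs[[s]]$row
        crn <- shots$corner[r]
        sh <- new_unit_env("shot", list(
          parent = pt_env, number = s,
          start_frame = as.integer(starts[s]),
          end_frame = as.integer(ends[s]),
          hitter_id = unname(ufield(pt_env, "corner_map")[[crn]]),
          corner = crn,
          shot_code = shots$shot_code[r],
          lob = shots$lob[r],
          frame_rows = prows[pfn >= starts[s] & pfn < ends[s]]
        ))
        # the serve owns any point-initial frames preceding its own
        # (clamped) start frame
        if (s == 1L) {
          sh$frame_rows <- prows[pfn < ends[1]]
        }
        sh_list[[s]] <- sh
      }
    }
    pt_env$shots <- sh_list
  }
  invisible(mt)
}

# forehand = the player covering the right side (facing the net) of the
# team's half, from mean x over tracked frames; override via config$forehand
assign_forehand <- function(mt) {
  cfg <- match_config(mt)
  tbl <- ufield(mt, "frames_tbl")
  geom <- ufield(mt, "geometry")
  for (lbl in c("T", "B")) {
    team <- ufield(mt, "teams")[[lbl]]
    pl <- ufield(team, "players")
    ov <- cfg$forehand[[lbl]]
    if (!is.null(ov)) {
      fid <- player_id_from_name(ov)
      fh <- Filter(function(p) identical(p[["id"]], fid), pl)
      if (!length(fh)) stop("forehand override '", ov, "' matches no player ",
                            "of team ", lbl, call. = FALSE)
      team$forehand_player <- fh[[1]]
      team$backhand_player <- Filter(function(p) !identical(p[["id"]], fid),
                                     pl)[[1]]
      next
    }
    mean_x <- vapply(pl, function(p) {
      x <- tbl[[paste0(p[["id"]], "_x")]]
      y <- tbl[[paste0(p[["id"]], "_y")]]
      own <- if (lbl == "B") y < geom$net_y else y > geom$net_y
      mean(x[own], na.rm = TRUE)
    }, numeric(1))
    # facing the net: right side is large x on the bottom half, small x on top
    fh_i <- if (all(is.finite(mean_x))) {
      if (lbl == "B") which.max(mean_x) else which.min(mean_x)
    } else if (lbl == "T") 1L else 2L  # no tracking: TL / BR convention
    team$forehand_player <- pl[[fh_i]]
    team$backhand_player <- pl[[setdiff(1:2, fh_i)]]
  }
  invisible(mt)
}
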