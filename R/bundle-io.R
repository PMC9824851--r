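# On-disk match bundles: three canonical CSVs + a JSON manifest.

#' Write a match bundle to a directory
#'
#' Canonical layout: `points.csv`, `shots.csv`, `frames.csv` (the ingest
#' schemas with canonical headers), `roster.csv`, `manifest.json` (title,
#' fps, scoring mode) and, when present, `ground_truth.json`. Writing and
#' re-reading a bundle is the identity on the three tables.
#'
#' @param bundle a `padel_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_match_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "padel_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(bundle$points, file.path(dir, "points.csv"), progress = FALSE)
  readr::write_csv(bundle$shots, file.path(dir, "shots.csv"), progress = FALSE)
  readr::write_csv(bundle$frames, file.path(dir, "frames.csv"), progress = FALSE)
  if (!is.null(bundle$roster)) {
    readr::write_csv(bundle$roster, file.path(dir, "roster.csv"),
                     progress = FALSE)
  }
  manifest <- list(
    title = bundle$config$title %||% "match",
    fps = bundle$config$fps %||% NA,
    scoring_mode = bundle$config$scoring_mode %||% "auto"
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(bundle$ground_truth)) {
    jsonlite::write_json(bundle$ground_truth,
                         file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, dataframe = "columns")
  }
  invisible(dir)
}

#' Read a match bundle from a directory
#'
#' @param dir a directory written by [write_match_bundle()] (or assembled by
#'   hand with the three CSVs).
#' @return a `padel_bundle`.
#' @export
read_match_bundle <- function(dir) {
  manifest <- if (file.exists(file.path(dir, "manifest.json"))) {
    jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  } else list()
  structure(list(
    points = read_points(file.path(dir, "points.csv")),
    shots = if (file.exists(file.path(dir, "shots.csv"))) {
      read_shots(file.path(dir, "shots.csv"))
    },
    frames = if (file.exists(file.path(dir, "frames.csv"))) {
      read_frames(file.path(dir, "frames.csv"))
    },
    roster = if (file.exists(file.path(dir, "roster.csv"))) {
      readr::read_csv(file.path(dir, "roster.csv"), show_col_types = FALSE,
                      progress = FALSE)
    },
    ground_truth = if (file.exists(file.path(dir, "ground_truth.json"))) {
      jsonlite::read_json(file.path(dir, "ground_truth.json"),
                          simplifyVector = TRUE)
    },
    config = list(title = manifest$title %||% basename(dir),
                  fps = manifest$fps %||% NULL,
                  scoring_mode = manifest$scoring_mode %||% "auto")
  ), class = "padel_bundle")
}

#' Flatten a match into a tidy table of play units
#'
#' @param x a `padel_match`.
#' @param level which units to tabulate.
#' @param ... unused.
#' @return a tibble with one row per unit: ids, spans, times and
#'   level-specific columns (winner for scored units, hitter and shot code
#'   for shots).
#' @method tidy padel_match
#' @export
tidy.padel_match <- function(x, level = c("point", "shot", "game", "set"),
                             ...) {
  level <- match.arg(level)
  units <- collect_units(x, level)
  fps <- match_fps(x)
  base <- tibble::tibble(
    id = vapply(units, function(u) as.character(get_prop(u, "id")), character(1)),
    number = vapply(units, function(u) as.integer(ufield(u, "number")), integer(1)),
    start_frame = vapply(units, function(u) ufield(u, "start_frame"), numeric(1)),
    end_frame = vapply(units, function(u) ufield(u, "end_frame"), numeric(1))
  )
  base$duration <- (base$end_frame - base$start_frame) / fps
  if (level %in% c("point", "game", "set")) {
    base$winner <- vapply(units, function(u) {
      wn <- ufield(u, "winner")
      if (is.null(wn) || is_absent(wn)) NA_character_ else ufield(wn, "label")
    }, character(1))
  }
  if (level == "shot") {
    base$hitter <- vapply(units, function(u) {
      p <- match_player(x, ufield(u, "hitter_id"))
      if (is.null(p)) NA_character_ else p[["last_name"]]
    }, character(1))
    base$shot_code <- vapply(units, function(u) ufield(u, "shot_code"),
                             character(1))
    base$lob <- vapply(units, function(u) isTRUE(ufield(u, "lob")), logical(1))
  }
  base
}

#' One-row summary of a match
#'
#' @param x a `padel_match`.
#' @param ... unused.
#' @return a tibble: title, fps, scoring mode, unit counts, winner label.
#' @method glance padel_match
#' @export
glance.padel_match <- function(x, ...) {
  w <- ufield(x, "winner")
  tibble::tibble(
    title = ufield(x, "title") %||% NA_character_,
    fps = match_fps(x),
    scoring_mode = ufield(x, "scoring_mode") %||% NA_character_,
    sets = length(ufield(x, "sets")),
    games = length(collect_units(x, "game")),
    points = length(collect_units(x, "point")),
    shots = length(collect_units(x, "shot")),
    frames = nrow(ufield(x, "frames_tbl")),
    winner = if (is.null(w) || is_absent(w)) NA_character_ else
      ufield(w, "label")
  )
}
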