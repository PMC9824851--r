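# Reading the three tabular schemas.
#
# A match arrives as three delimited text files: a *points* table (frame
# spans, winner, within-game scores, the four players by court corner), a
# *shots* table (hit frame, hitter corner, shot-type code, lob flag) and a
# *frames* table (per-frame image-space and court-space positions of the four
# players). Delimiters (comma or tab) are sniffed, column names are matched
# through a normalising alias table, and frame numbers may carry thousands
# separators as in printed tables ("13,606").

CORNERS <- c("tl", "tr", "bl", "br")

norm_header <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[^a-z0-9]+", "_", x)
  gsub("^_|_$", "", x)
}

POINTS_ALIASES <- list(
  start = c("start_f", "start", "start_frame"),
  end = c("end_f", "end", "end_frame"),
  duration_frames = c("duration_f", "duration_frames"),
  duration_seconds = c("duration_s", "duration_seconds", "duration_sec"),
  winner = "winner",
  points_T = c("points_a", "points_t", "score_a", "points_top"),
  points_B = c("points_b", "score_b", "points_bottom"),
  tl = c("top_left", "tl"),
  tr = c("top_right", "tr"),
  bl = c("bottom_left", "bl"),
  br = c("bottom_right", "br"),
  valid = "valid"
)

SHOTS_ALIASES <- list(
  frame = c("frame", "frame_number", "start_f"),
  corner = c("player", "corner", "hitter"),
  shot_code = c("shot_type", "shot_code", "type", "code"),
  lob = "lob"
)

sniff_delim <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\t", first)) "\t" else ","
}

read_raw_table <- function(path, delim = NULL) {
  if (is.null(delim)) delim <- sniff_delim(path)
  tbl <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), trim_ws = TRUE, progress = FALSE, show_col_types = FALSE)
  names(tbl) <- norm_header(names(tbl))
  tbl
}

pick_columns <- function(tbl, aliases, required, what, path) {
  out <- list()
  for (nm in names(aliases)) {
    hit <- intersect(aliases[[nm]], names(tbl))
    if (length(hit)) out[[nm]] <- tbl[[hit[1]]]
  }
  missing <- setdiff(required, names(out))
  if (length(missing)) {
    stop("file '", path, "' is missing required ", what, " column(s): ",
         paste(missing, collapse = ", "),
         "\nexpected schema (any alias): ",
         paste(vapply(aliases[required], paste, "", collapse = "/"),
               collapse = " | "),
         call. = FALSE)
  }
  tibble::as_tibble(out)
}

# "13,606" -> 13606; decimal points survive, thousands separators do not
parse_num <- function(x, what, integerish = FALSE) {
  raw <- gsub("[ ,](?=\\d{3}\\b)", "", x, perl = TRUE)
  raw <- gsub(",", "", raw)  # defensive: any remaining separator
  out <- suppressWarnings(as.numeric(raw))
  bad <- which(!is.na(x) & nzchar(x) & is.na(out))
  if (length(bad)) {
    stop("cannot parse ", what, " value '", x[bad[1]], "' at row ", bad[1],
         call. = FALSE)
  }
  if (integerish) as.integer(round(out)) else out
}

parse_flag <- function(x) {
  up <- toupper(trimws(x))
  up %in% c("T", "TRUE", "1", "Y", "YES")
}

#' Read a points table
#'
#' One row per point: frame span, durations, winner (`T`/`B` for the
#' top/bottom team as seen in the video), within-game score labels after the
#' point, and the four players' names by court corner.
#'
#' @param path a delimited text file (comma or tab, sniffed).
#' @param delim optional explicit delimiter.
#' @return a tibble with columns `start`, `end`, `duration_frames`,
#'   `duration_seconds`, `winner`, `points_T`, `points_B`, `tl`, `tr`, `bl`,
#'   `br` and (if present) `valid`.
#' @export
read_points <- function(path, delim = NULL) {
  tbl <- read_raw_table(path, delim)
  out <- pick_columns(tbl, POINTS_ALIASES,
                      required = c("start", "end", "winner"),
                      what = "points", path = path)
  out$start <- parse_num(out$start, "start frame", integerish = TRUE)
  out$end <- parse_num(out$end, "end frame", integerish = TRUE)
  if (!is.null(out[["duration_frames"]])) {
    out$duration_frames <- parse_num(out[["duration_frames"]], "frame duration",
                                     integerish = TRUE)
  } else {
    out$duration_frames <- out$end - out$start
  }
  if (!is.null(out[["duration_seconds"]])) {
    out$duration_seconds <- parse_num(out[["duration_seconds"]],
                                      "second duration")
  }
  out$winner <- toupper(trimws(out$winner))
  if (nrow(out) && !all(out$winner %in% c("T", "B"))) {
    stop("winner column must contain only 'T' or 'B'", call. = FALSE)
  }
  if (nrow(out) && any(out$duration_frames != out$end - out$start)) {
    warning("duration_frames differs from end - start in the points table",
            call. = FALSE)
  }
  if (!is.null(out[["valid"]])) out$valid <- parse_flag(out[["valid"]])
  out
}

#' Read a shots table
#'
#' One row per shot: the hit frame, the hitter's corner code (TL/TR/BL/BR),
#' the shot-type code (resolved case-insensitively against the registry,
#' aliases allowed -- "Serve" resolves to code "s"), and the lob flag.
#'
#' @inheritParams read_points
#' @return a tibble with columns `frame`, `corner`, `shot_code`, `lob`.
#' @export
read_shots <- function(path, delim = NULL) {
  tbl <- read_raw_table(path, delim)
  out <- pick_columns(tbl, SHOTS_ALIASES,
                      required = c("frame", "corner", "shot_code"),
                      what = "shots", path = path)
  out$frame <- parse_num(out$frame, "shot frame", integerish = TRUE)
  out$corner <- tolower(trimws(out$corner))
  if (nrow(out) && !all(out$corner %in% CORNERS)) {
    stop("shot corner codes must be one of TL/TR/BL/BR", call. = FALSE)
  }
  registry <- shot_type_registry()
  codes <- vapply(norm_token(out$shot_code), alias_to_code, character(1),
                  registry = registry)
  if (anyNA(codes)) {
    bad <- which(is.na(codes))[1]
    stop("unknown shot type '", out$shot_code[bad], "' at row ", bad,
         "; see shot_type_registry()", call. = FALSE)
  }
  out$shot_code <- unname(codes)
  out$lob <- if (is.null(out[["lob"]])) rep(FALSE, nrow(out)) else
    parse_flag(out[["lob"]])
  out
}

#' Read a frames table
#'
#' One row per video frame with the four players' positions by corner:
#' court-space `x`/`y` in meters (used throughout) and optional image-space
#' `i`/`j` in pixels (carried as opaque metadata).
#'
#' @inheritParams read_points
#' @return a tibble with `frame_number` and per-corner columns `tl_x`,
#'   `tl_y`, ..., plus `tl_i`, `tl_j`, ... when present.
#' @export
read_frames <- function(path, delim = NULL) {
  tbl <- read_raw_table(path, delim)
  if (!"frame" %in% names(tbl) && !"frame_number" %in% names(tbl)) {
    stop("file '", path, "' is missing the frame-number column ",
         "('Frame' or 'frame_number')", call. = FALSE)
  }
  out <- tibble::tibble(
    frame_number = parse_num(tbl[["frame"]] %||% tbl[["frame_number"]],
                             "frame number", integerish = TRUE)
  )
  needed <- paste0(rep(CORNERS, each = 2), "_", c("x", "y"))
  canonical <- paste0(rep(CORNERS, each = 4), "_", c("i", "j", "x", "y"))
  have <- intersect(canonical, names(tbl))
  miss <- setdiff(needed, names(tbl))
  if (length(miss)) {
    stop("file '", path, "' is missing court-space position column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (cn in have) out[[cn]] <- parse_num(tbl[[cn]], cn)
  out
}

#' Infer the video frame rate from a points table
#'
#' Finds the integer fps that best reconciles the frame-count and
#' second-duration columns, minimising the total absolute discrepancy.
#'
#' @param points a points tibble from [read_points()] with both duration
#'   columns.
#' @param candidates integer fps values to search.
#' @return the integer fps, with the total residual (seconds) attached as
#'   attribute `"residual"`.
#' @examples
#' pts <- tibble::tibble(duration_frames = 300, duration_seconds = 10)
#' infer_fps(pts)  # 30
#' @export
infer_fps <- function(points, candidates = 1:120) {
  ds_col <- points[["duration_seconds"]]
  ok <- !is.na(points$duration_frames) &
    !is.na(ds_col %||% rep(NA_real_, nrow(points)))
  if (is.null(ds_col) || !any(ok)) {
    stop("no row has both frame and second durations; set the fps ",
         "explicitly in padel_config(fps = ...)", call. = FALSE)
  }
  df <- points$duration_frames[ok]
  ds <- ds_col[ok]
  resid <- vapply(candidates, function(f) sum(abs(df / f - ds)), numeric(1))
  best <- which.min(resid)
  structure(as.integer(candidates[best]), residual = resid[best])
}
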