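# Structural validation of an assembled match.

#' Validate an assembled match
#'
#' Runs structural checks over the hierarchy and the positions table and
#' returns a report rather than raising: span containment, sibling numbering,
#' monotone frame numbers, court-bounds violations beyond the configured
#' tolerance, non-alternating team hitters within a rally (a warning --
#' annotation noise is common), zero-shot points, and rallies that do not
#' open with a serve.
#'
#' @param match a `padel_match`.
#' @return a tibble with columns `severity` (`"error"`/`"warning"`), `code`,
#'   `where`, `message`; zero `error` rows means the match validates clean.
#' @export
validate_match <- function(match) {
  stopifnot(inherits(match, "padel_match"))
  rep <- list()
  note <- function(severity, code, where, message) {
    rep[[length(rep) + 1L]] <<- tibble::tibble(
      severity = severity, code = code, where = where, message = message)
  }

  # containment + numbering
  check_children <- function(parent) {
    lvl <- unit_level(parent)
    if (lvl == "shot") return(invisible())
    kids <- nav_children(parent)
    ps <- ufield(parent, "start_frame"); pe <- ufield(parent, "end_frame")
    nums <- vapply(kids, function(k) as.integer(ufield(k, "number")), integer(1))
    if (length(kids) && !identical(nums, seq_along(kids))) {
      note("error", "sibling_numbering", unit_id(parent),
           "child numbers are not 1..n in temporal order")
    }
    last_end <- -Inf
    for (k in kids) {
      ks <- ufield(k, "start_frame"); ke <- ufield(k, "end_frame")
      if (ks < ps || ke > pe) {
        note("error", "containment", unit_id(k),
             sprintf("%s span [%d,%d) outside parent %s [%d,%d)",
                     unit_level(k), ks, ke, lvl, ps, pe))
      }
      if (ks < last_end) {
        note("error", "overlap", unit_id(k),
             sprintf("%s starts before the previous sibling ends",
                     unit_level(k)))
      }
      last_end <- ke
      check_children(k)
    }
    invisible()
  }
  check_children(match)

  # frame numbers monotone
  fn <- ufield(match, "frames_tbl")$frame_number
  if (is.unsorted(fn, strictly = FALSE)) {
    note("error", "frame_order", "frames", "frame numbers are not monotone")
  }
  if (anyDuplicated(fn)) {
    note("warning", "frame_duplicates", "frames",
         sprintf("%d duplicated frame number(s)", sum(duplicated(fn))))
  }

  # court bounds
  geom <- ufield(match, "geometry")
  tol <- match_config(match)$bounds_tolerance
  tbl <- ufield(match, "frames_tbl")
  for (p in ufield(match, "players")) {
    x <- tbl[[paste0(p[["id"]], "_x")]]; y <- tbl[[paste0(p[["id"]], "_y")]]
    bad <- sum(x < -tol | x > geom$width + tol |
                 y < -tol | y > geom$length + tol, na.rm = TRUE)
    if (bad > 0) {
      note("error", "court_bounds", p[["last_name"]],
           sprintf("%d position(s) beyond the court bounds tolerance (%.1f m)",
                   bad, tol))
    }
  }

  # rally structure
  for (pt in collect_units(match, "point")) {
    sh <- ufield(pt, "shots")
    if (!length(sh)) {
      note("warning", "empty_point", unit_id(pt), "point has no shots")
      next
    }
    if (!identical(ufield(sh[[1]], "shot_code"), "s")) {
      note("warning", "no_serve", unit_id(pt),
           "first shot of the rally is not a serve")
    }
    labels <- vapply(sh, function(s) {
      p <- match_player(match, ufield(s, "hitter_id"))
      if (is.null(p)) NA_character_ else p[["team_label"]]
    }, character(1))
    if (any(labels[-1] == labels[-length(labels)], na.rm = TRUE)) {
      note("warning", "non_alternating", unit_id(pt),
           "consecutive shots by the same team (annotation noise?)")
    }
  }

  out <- if (length(rep)) dplyr::bind_rows(rep) else tibble::tibble(
    severity = character(), code = character(),
    where = character(), message = character())
  class(out) <- c("padel_validation", class(out))
  out
}

#' @export
print.padel_validation <- function(x, ...) {
  ne <- sum(x$severity == "error"); nw <- sum(x$severity == "warning")
  cat(sprintf("<validation: %d error(s), %d warning(s)>\n", ne, nw))
  if (nrow(x)) NextMethod()
  invisible(x)
}
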