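# Query results.
#
# A query result is a tibble (one row per retrieved item, one column per
# attribute) plus provenance: each row remembers its match, its start frame
# and a deep link into the source video at that moment. Provenance travels
# in dot-prefixed columns (`.match`, `.start_frame`, `.video`) so results
# survive ordinary dplyr manipulation.

PROVENANCE_COLS <- c(".match", ".start_frame", ".video")

new_padel_result <- function(tbl, title = NULL, kind = NULL, query = NULL) {
  structure(
    tbl,
    class = c("padel_result", class(tibble::as_tibble(tbl))),
    title = title, kind = kind, query = query
  )
}

result_columns <- function(result) setdiff(names(result), PROVENANCE_COLS)

#' @export
print.padel_result <- function(x, ...) {
  ttl <- attr(x, "title")
  if (!is.null(ttl)) cat(ttl, "\n")
  cat(sprintf("<query result: %d row(s) of %s-level data>\n",
              nrow(x), attr(x, "kind") %||% "item"))
  print(tibble::as_tibble(x)[result_columns(x)], ...)
  invisible(x)
}

#' Summary statistics of a query result
#'
#' For every numeric column: count, mean, standard deviation, min, max; for
#' every text column: count and the number of distinct values. Provenance
#' columns are ignored.
#'
#' @param result a query result.
#' @return a tibble with one row per column.
#' @export
analyze <- function(result) {
  stopifnot(inherits(result, "padel_result"))
  cols <- result_columns(result)
  if (nrow(result) == 0L || !length(cols)) {
    warning("empty result; nothing to analyze", call. = FALSE)
    return(tibble::tibble(column = character(), type = character(),
                          count = integer(), mean = numeric(), sd = numeric(),
                          min = numeric(), max = numeric(),
                          distinct = integer()))
  }
  purrr::map_dfr(cols, function(cn) {
    v <- result[[cn]]
    if (is.numeric(v)) {
      ok <- v[!is.na(v)]
      tibble::tibble(column = cn, type = "numeric", count = length(ok),
                     mean = mean(ok), sd = if (length(ok) > 1) stats::sd(ok) else 0,
                     min = suppressWarnings(min(ok)),
                     max = suppressWarnings(max(ok)),
                     distinct = NA_integer_)
    } else {
      ok <- v[!is.na(v)]
      tibble::tibble(column = cn, type = "text", count = length(ok),
                     mean = NA_real_, sd = NA_real_,
                     min = NA_real_, max = NA_real_,
                     distinct = length(unique(ok)))
    }
  })
}

#' Group a result by a key column and sum its numeric columns
#'
#' The workhorse of per-point accumulations: a frame-level result carrying a
#' `duration` attribute, summed by `point`, yields time-in-zone per point.
#' Non-numeric columns other than the key are dropped with a warning.
#' Per-group provenance keeps the group's first match and earliest start
#' frame so deep links still work.
#'
#' @param result a query result.
#' @param key name of the grouping column.
#' @return a new query result with one row per distinct key.
#' @export
sum_by <- function(result, key) {
  stopifnot(inherits(result, "padel_result"))
  cols <- result_columns(result)
  if (!key %in% cols) {
    stop("key column '", key, "' is not in the result (columns: ",
         paste(cols, collapse = ", "), ")", call. = FALSE)
  }
  num <- cols[vapply(result[cols], is.numeric, logical(1))]
  num <- setdiff(num, key)
  dropped <- setdiff(cols, c(num, key))
  if (length(dropped)) {
    warning("dropping non-numeric column(s): ", paste(dropped, collapse = ", "),
            call. = FALSE)
  }
  has_prov <- all(PROVENANCE_COLS %in% names(result))
  grouped <- dplyr::group_by(tibble::as_tibble(result), .data[[key]])
  sums <- dplyr::summarise(
    grouped,
    dplyr::across(dplyr::all_of(num), ~ sum(.x, na.rm = TRUE)),
    .groups = "drop")
  if (has_prov) {
    prov <- dplyr::summarise(
      grouped,
      .match = dplyr::first(.data$.match),
      .start_frame = suppressWarnings(min(.data$.start_frame, na.rm = TRUE)),
      .video = dplyr::first(.data$.video),
      .groups = "drop")
    sums <- dplyr::left_join(sums, prov, by = key)
  }
  new_padel_result(sums, title = attr(result, "title"),
                   kind = attr(result, "kind"), query = attr(result, "query"))
}

#' Append a constant column to a result
#'
#' Used to discriminate results before [concat()]: tag one pipeline "Point
#' Winner" and the other "Point Loser", then stack them for a grouped plot.
#'
#' @param result a query result.
#' @param name new column name.
#' @param value the constant value.
#' @return the result with the extra column.
#' @export
add_column <- function(result, name, value) {
  stopifnot(inherits(result, "padel_result"))
  tbl <- tibble::as_tibble(result)
  tbl[[name]] <- rep(value, length.out = nrow(tbl))
  # keep provenance columns last
  tbl <- tbl[c(setdiff(names(tbl), PROVENANCE_COLS),
               intersect(PROVENANCE_COLS, names(tbl)))]
  new_padel_result(tbl, title = attr(result, "title"),
                   kind = attr(result, "kind"), query = attr(result, "query"))
}

#' Row-concatenate query results
#'
#' Inputs must share the same (non-provenance) column set; row order follows
#' the input list.
#'
#' @param results a list of query results.
#' @param title optional title for the combined result.
#' @return a query result.
#' @export
concat <- function(results, title = NULL) {
  stopifnot(is.list(results), length(results) >= 1L)
  ref <- sort(result_columns(results[[1]]))
  for (i in seq_along(results)) {
    cur <- sort(result_columns(results[[i]]))
    if (!identical(ref, cur)) {
      stop("result ", i, " has a different column set; difference: ",
           paste(union(setdiff(ref, cur), setdiff(cur, ref)), collapse = ", "),
           call. = FALSE)
    }
  }
  tbl <- dplyr::bind_rows(lapply(results, tibble::as_tibble))
  new_padel_result(tbl, title = title %||% attr(results[[1]], "title"),
                   kind = attr(results[[1]], "kind"),
                   query = attr(results[[1]], "query"))
}

#' Per-row video deep links
#'
#' Each result row links to the source video at the second its item starts
#' (`floor(start_frame / fps)`), so any retrieved situation can be reviewed
#' in full detail.
#'
#' @param result a query result.
#' @return a character vector of URLs (`NA` where no video is configured).
#' @export
video_links <- function(result) {
  stopifnot(inherits(result, "padel_result"))
  if (!".video" %in% names(result)) return(rep(NA_character_, nrow(result)))
  result$.video
}

video_link_url <- function(url, fps, start_frame) {
  if (is.null(url) || is.na(url)) return(NA_character_)
  offset <- floor(start_frame / fps)
  sep <- if (grepl("?", url, fixed = TRUE)) "&" else "?"
  paste0(url, sep, "t=", offset, "s")
}

#' Export a result to CSV
#'
#' Deterministic column order (attributes, then provenance); the same match
#' bundle and query always produce byte-identical output.
#'
#' @param result a query result.
#' @param path output file.
#' @param links include provenance/link columns.
#' @export
write_result_csv <- function(result, path, links = TRUE) {
  tbl <- tibble::as_tibble(result)
  if (!links) tbl <- tbl[result_columns(result)]
  readr::write_csv(tbl, path, progress = FALSE)
  invisible(path)
}

# ---- broom-style methods ----------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a query result
#'
#' @param x a query result.
#' @param ... unused.
#' @return the result rows as a plain tibble without provenance columns.
#' @method tidy padel_result
#' @export
tidy.padel_result <- function(x, ...) {
  tibble::as_tibble(x)[result_columns(x)]
}

#' One-row summary of a query result
#'
#' @param x a query result.
#' @param ... unused.
#' @return a tibble with the query name, item level, and row/column counts.
#' @method glance padel_result
#' @export
glance.padel_result <- function(x, ...) {
  tibble::tibble(
    query = attr(x, "query") %||% NA_character_,
    kind = attr(x, "kind") %||% NA_character_,
    rows = nrow(x),
    columns = length(result_columns(x)),
    matches = if (".match" %in% names(x)) length(unique(x[[".match"]])) else 0L
  )
}
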