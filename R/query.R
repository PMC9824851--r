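# Query definition and execution.

#' Define a query
#'
#' A query names a Boolean predicate over one level of the hierarchy. The
#' predicate can be an R function of one item, or a string in the expression
#' grammar -- the two are interchangeable everywhere.
#'
#' @param name query name (used in result provenance).
#' @param kind item level: one of match, set, game, point, shot, frame.
#' @param predicate function of one item, or a grammar expression string.
#' @param attribs optional default attribute set (see [run_query()]).
#' @return a `padel_query` object.
#' @examples
#' volleys <- query_def("volleys", "shot", 'shot.one_of("vd,vr")')
#' @export
query_def <- function(name, kind, predicate, attribs = NULL) {
  kind <- match.arg(tolower(kind), PADEL_LEVELS)
  structure(list(name = name, kind = kind, predicate = predicate,
                 attribs = attribs),
            class = "padel_query")
}

#' @export
print.padel_query <- function(x, ...) {
  ptxt <- if (is.character(x$predicate)) x$predicate else "<function>"
  cat(sprintf("<query '%s' on %ss: %s>\n", x$name, x$kind, ptxt))
  invisible(x)
}

normalize_attribs <- function(attribs, kind) {
  if (is.null(attribs) || !length(attribs)) {
    attribs <- c(id = "id")
  }
  # accept list(c("expr", "alias"), "expr", ...) as well as named vectors
  if (is.list(attribs)) {
    alias <- vapply(attribs, function(a) if (length(a) >= 2) a[[2]] else a[[1]],
                    character(1))
    expr <- vapply(attribs, function(a) a[[1]], character(1))
    nm0 <- names(attribs)
    if (!is.null(nm0)) alias[nzchar(nm0)] <- nm0[nzchar(nm0)]
    attribs <- stats::setNames(expr, alias)
  } else {
    nm <- names(attribs)
    if (is.null(nm)) nm <- rep("", length(attribs))
    nm[!nzchar(nm)] <- attribs[!nzchar(nm)]
    attribs <- stats::setNames(as.character(attribs), nm)
  }
  attribs
}

#' Execute a query over a scope
#'
#' Walks every item of the query's level in the scope (a match or list of
#' matches, in order), keeps the items whose predicate is true under the
#' absent contract (absent-valued predicates drop the row; absent-valued
#' *attributes* become explicit `NA`s -- the predicate decides membership,
#' attributes never do), and returns one row per kept item.
#'
#' @param scope a `padel_match` or list of them.
#' @param query a [query_def()], or the name of a catalog query (see
#'   [builtin_catalog()]).
#' @param attribs attribute expressions for the output columns: a character
#'   vector of grammar expressions, optionally named to set column aliases
#'   (the default alias is the expression text), or a list of
#'   `c(expression, alias)` pairs. Defaults to the query's own attribute set.
#' @param helpers named list of extra root bindings available to expressions.
#' @return a `padel_result` tibble with per-row provenance (`.match`,
#'   `.start_frame`, `.video`).
#' @examples
#' \dontrun{
#' m <- demo_match()
#' run_query(m, "q4")                       # catalog query: serves
#' run_query(m, query_def("net", "shot",
#'   "hitter.distance_to_net < 4"), attribs = c("id", "hitter.last_name"))
#' }
#' @export
run_query <- function(scope, query, attribs = NULL, helpers = NULL) {
  if (is.character(query) && length(query) == 1L) {
    cat_q <- builtin_catalog()[[tolower(query)]]
    if (is.null(cat_q)) {
      stop("unknown catalog query '", query, "'; available: ",
           paste(names(builtin_catalog()), collapse = ", "), call. = FALSE)
    }
    query <- cat_q
  }
  stopifnot(inherits(query, "padel_query"))
  kind <- query$kind
  attribs <- normalize_attribs(attribs %||% query$attribs, kind)
  pred <- as_predicate(query$predicate, kind, helpers)
  attr_fns <- lapply(unname(attribs), compile_expr, kind = kind,
                     helpers = helpers)

  items <- collect_units(scope, kind)
  keep <- logical(length(items))
  for (i in seq_along(items)) {
    keep[i] <- tryCatch(truthy(pred(items[[i]])), error = function(e) {
      stop("query '", query$name, "' failed on ", kind, " ",
           format(get_prop(items[[i]], "id")), ": ", conditionMessage(e),
           call. = FALSE)
    })
  }
  items <- items[keep]

  cells <- lapply(attr_fns, function(f) {
    lapply(items, function(it) format_cell(f(it)))
  })
  cols <- lapply(cells, collapse_column)
  names(cols) <- names(attribs)

  prov_match <- character(length(items))
  prov_start <- numeric(length(items))
  prov_video <- character(length(items))
  for (i in seq_along(items)) {
    it <- items[[i]]
    mt <- frame_match(it)
    prov_match[i] <- ufield(mt, "title") %||% "match"
    prov_start[i] <- ufield(it, "start_frame") %||% it[["frame_number"]]
    vid <- ufield(mt, "video")
    prov_video[i] <- video_link_url(vid$url %||% NA_character_, vid$fps,
                                    prov_start[i])
  }
  tbl <- tibble::as_tibble(cols)
  if (!nrow(tbl) && length(items) == 0L) {
    tbl <- tbl[0, , drop = FALSE]
  }
  tbl$.match <- prov_match
  tbl$.start_frame <- prov_start
  tbl$.video <- prov_video
  new_padel_result(tbl, title = query$name, kind = kind, query = query$name)
}

# scalar cell coercion: domain objects render as their natural labels
format_cell <- function(v) {
  if (is_absent(v)) return(NA)
  if (inherits(v, "padel_player")) return(v[["last_name"]])
  if (inherits(v, "padel_team")) return(ufield(v, "label"))
  if (inherits(v, "padel_unit")) return(get_prop(v, "id"))
  if (inherits(v, c("court_point", "court_vec"))) return(format(v))
  if (is.character(v) && length(v) > 1L) return(paste(v, collapse = " "))
  if (length(v) != 1L) return(paste(format(v), collapse = " "))
  v
}

collapse_column <- function(vals) {
  if (!length(vals)) return(logical(0))
  is_num <- vapply(vals, function(v) is.numeric(v) ||
                     (length(v) == 1 && is.na(v)), logical(1))
  if (all(is_num)) {
    return(vapply(vals, function(v) if (is.na(v[1])) NA_real_ else
      as.numeric(v), numeric(1)))
  }
  is_lgl <- vapply(vals, function(v) is.logical(v), logical(1))
  if (all(is_lgl)) return(vapply(vals, function(v) v[1], logical(1)))
  vapply(vals, function(v) if (length(v) == 1 && is.na(v)) NA_character_ else
    as.character(v), character(1))
}
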