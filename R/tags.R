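# Tags and the shot-type taxonomy.
#
# Every play unit carries a dynamic set of string tags. A shot's type is
# itself a tag token with *aliases*: the packaged registry holds 27 shot
# types (code, Spanish expansion, English equivalents), and a membership test
# accepts any of them -- `like(shot, "forehand volley")` is true for a shot
# whose type code is "vd". Matching is case-insensitive; whole-query alias
# lookup takes precedence over whitespace token-splitting, which is what
# makes both "forehand volley" (one alias) and "cross-court volley" (two
# independent tags) behave as expected.

.padel_cache <- new.env(parent = emptyenv())

#' The shot-type registry
#'
#' Twenty-seven shot types with code, Spanish expansion and English aliases,
#' shipped as package data. Spanish names are loaded but only used for
#' matching when `spanish = TRUE` (to avoid accidental token collisions).
#'
#' @param extra optional tibble/data.frame with columns `code`,
#'   `spanish_name`, `aliases` (pipe-separated) appended to the registry.
#' @return a tibble with columns `code`, `spanish_name`, `aliases`
#'   (list-column of character vectors).
#' @export
shot_type_registry <- function(extra = NULL) {
  reg <- get0("registry", envir = .padel_cache)
  if (is.null(reg)) {
    path <- system.file("extdata", "shot_types.csv", package = "padelquery")
    raw <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
    reg <- tibble::tibble(
      code = tolower(raw$code),
      spanish_name = tolower(raw$spanish_name),
      aliases = strsplit(tolower(raw$aliases), "|", fixed = TRUE)
    )
    assign("registry", reg, envir = .padel_cache)
  }
  if (!is.null(extra)) {
    extra <- tibble::tibble(
      code = tolower(extra$code),
      spanish_name = tolower(extra$spanish_name %||% NA_character_),
      aliases = strsplit(tolower(extra$aliases), "|", fixed = TRUE)
    )
    reg <- dplyr::bind_rows(reg, extra)
  }
  reg
}

norm_token <- function(x) tolower(trimws(x))

# map a (normalized) token to a shot-type code, or NA if it is not one
alias_to_code <- function(token, registry = shot_type_registry(),
                          spanish = FALSE) {
  if (token %in% registry$code) return(token)
  for (i in seq_len(nrow(registry))) {
    if (token %in% registry$aliases[[i]]) return(registry$code[i])
    if (spanish && identical(token, registry$spanish_name[i])) {
      return(registry$code[i])
    }
  }
  NA_character_
}

unit_tags <- function(item) {
  if (inherits(item, "padel_frame")) frame_tags_get(item) else ufield(item, "tags")
}

add_tag <- function(item, tag) {
  tag <- norm_token(tag)
  if (inherits(item, "padel_frame")) {
    frame_tags_add(item, tag)
  } else {
    assign("tags", union(ufield(item, "tags"), tag), envir = item)
  }
  invisible(item)
}

item_spanish_flag <- function(item) {
  mt <- tryCatch(frame_match(item), error = function(e) NULL)
  if (is.null(mt)) return(FALSE)
  isTRUE(match_config(mt)$spanish_aliases)
}

# one token against a tag set, honoring shot-type aliasing
token_matches <- function(tags, token, registry, spanish) {
  if (token %in% tags) return(TRUE)
  code <- alias_to_code(token, registry, spanish)
  !is.na(code) && code %in% tags
}

#' Tag membership with AND semantics
#'
#' `like(shot, "volley")` tests whether "volley" is among the shot's tags
#' (resolving shot-type aliases). A multi-word query first tries a
#' whole-string alias match (`"forehand volley"` is an alias of code "vd");
#' failing that it splits on whitespace and requires *every* token to match.
#'
#' @param item a play unit.
#' @param query a non-empty tag query string.
#' @return `TRUE`/`FALSE`; [absent] items yield `FALSE`.
#' @export
like <- function(item, query) {
  if (!is.character(query) || length(query) != 1L || !nzchar(trimws(query))) {
    stop("like() requires a non-empty query string", call. = FALSE)
  }
  if (is_absent(item)) return(FALSE)
  registry <- shot_type_registry()
  spanish <- item_spanish_flag(item)
  tags <- unit_tags(item)
  q <- norm_token(query)
  if (token_matches(tags, q, registry, spanish)) return(TRUE)
  tokens <- strsplit(q, "\\s+")[[1]]
  if (length(tokens) <= 1L) return(FALSE)
  all(vapply(tokens, token_matches, logical(1),
             tags = tags, registry = registry, spanish = spanish))
}

#' Tag membership with OR semantics
#'
#' `one_of(shot, "vd,vr")` is true when any of the comma-separated tokens
#' matches one of the item's tags (shot-type aliases included).
#'
#' @param item a play unit.
#' @param codes_csv comma-separated token list.
#' @return `TRUE`/`FALSE`; [absent] items yield `FALSE`.
#' @export
one_of <- function(item, codes_csv) {
  if (!is.character(codes_csv) || length(codes_csv) != 1L ||
      !nzchar(trimws(codes_csv))) {
    stop("one_of() requires a non-empty comma-separated token list",
         call. = FALSE)
  }
  tokens <- norm_token(strsplit(codes_csv, ",", fixed = TRUE)[[1]])
  tokens <- tokens[nzchar(tokens)]
  if (!length(tokens)) {
    stop("one_of() requires a non-empty comma-separated token list",
         call. = FALSE)
  }
  if (is_absent(item)) return(FALSE)
  registry <- shot_type_registry()
  spanish <- item_spanish_flag(item)
  tags <- unit_tags(item)
  any(vapply(tokens, token_matches, logical(1),
             tags = tags, registry = registry, spanish = spanish))
}

# ---- user tag rules ---------------------------------------------------------

#' Define a tag rule
#'
#' A tag rule names a Boolean predicate over one level of the hierarchy;
#' applying it inserts the rule's name into the tag set of every matching
#' item, after which queries can use the new concept through [like()].
#'
#' @param name tag to insert.
#' @param kind level the predicate runs on: one of match, set, game, point,
#'   shot, frame.
#' @param predicate a function of one item returning a Boolean, or a string
#'   in the query expression grammar (e.g.
#'   `'shot.one_of("vd,vr") and shot.hitter.distance_to_net < 1.5'`).
#' @return a `tag_rule` object.
#' @examples
#' volley <- tag_rule("volley", "shot", 'shot.one_of("vd,vr")')
#' @export
tag_rule <- function(name, kind, predicate) {
  kind <- match.arg(tolower(kind), PADEL_LEVELS)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(list(name = norm_token(name), kind = kind,
                 predicate = as_predicate(predicate, kind)),
            class = "tag_rule")
}

#' Apply a tag rule over a scope
#'
#' Traverses every item of the rule's level in the scope and inserts the tag
#' where the predicate holds (under the absent contract). Applying a rule
#' twice is a no-op: tag sets only grow and insertion is idempotent.
#'
#' @param scope a match or list of matches.
#' @param rule a [tag_rule()].
#' @return the number of items tagged, invisibly tagging in place.
#' @export
apply_tags <- function(scope, rule) {
  stopifnot(inherits(rule, "tag_rule"))
  items <- collect_units(scope, rule$kind)
  n <- 0L
  for (item in items) {
    ok <- tryCatch(truthy(rule$predicate(item)), error = function(e) {
      stop("tag rule '", rule$name, "' failed on ", rule$kind, " ",
           format(get_prop(item, "id")), ": ", conditionMessage(e),
           call. = FALSE)
    })
    if (ok) {
      add_tag(item, rule$name)
      n <- n + 1L
    }
  }
  n
}

# built-in tags inserted at assembly time: the shot-type code, "serve",
# "lob" where flagged, "by-<lastname>", and "winning" for shots whose
# hitter's team took the point
auto_tags <- function(match) {
  for (shot in collect_units(match, "shot")) {
    code <- ufield(shot, "shot_code")
    if (!is.na(code)) {
      add_tag(shot, code)
      if (identical(code, "s")) add_tag(shot, "serve")
    }
    if (isTRUE(ufield(shot, "lob"))) add_tag(shot, "lob")
    hitter_id <- ufield(shot, "hitter_id")
    if (!is.na(hitter_id)) {
      add_tag(shot, paste0("by-", hitter_id))
      pt <- nav_parent(shot, "point")
      w <- ufield(pt, "winner")
      if (!is_absent(w) && !is.null(w) &&
          hitter_id %in% vapply(ufield(w, "players"), function(p) p[["id"]],
                                character(1))) {
        add_tag(shot, "winning")
      }
    }
  }
  invisible(match)
}

#' @export
print.tag_rule <- function(x, ...) {
  cat(sprintf("<tag rule '%s' on %ss>\n", x$name, x$kind))
  invisible(x)
}
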