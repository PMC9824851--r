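#' The absent sentinel
#'
#' Navigation past the edges of the play-unit hierarchy (the shot before a
#' serve, the shot after the last shot of a rally) does not raise an error:
#' it yields the `absent` sentinel. Any member access on `absent` yields
#' `absent` again, so long chained paths such as
#' `shot.next.next.next.hitter.distance_to_side_wall` degrade gracefully on
#' short rallies. In predicates `absent` is falsy, and any comparison that
#' involves `absent` is `FALSE` -- with the single exception that
#' `absent == absent` is `TRUE`.
#'
#' @format `absent` is a singleton object of class `padel_absent`.
#' @examples
#' is_absent(absent$anything$at$all)   # TRUE: member access propagates
#' absent == 3                         # FALSE
#' absent == absent                    # TRUE
#' @export
absent <- structure(new.env(parent = emptyenv()), class = "padel_absent")

#' Test for the absent sentinel
#'
#' @param x any object.
#' @return `TRUE` if `x` is the [absent] sentinel (or `NULL`).
#' @export
is_absent <- function(x) is.null(x) || inherits(x, "padel_absent")

#' @export
`$.padel_absent` <- function(x, name) absent

#' @export
`[[.padel_absent` <- function(x, ...) absent

#' @export
print.padel_absent <- function(x, ...) {
  cat("<absent>\n")
  invisible(x)
}

#' @export
format.padel_absent <- function(x, ...) "<absent>"

#' @export
Ops.padel_absent <- function(e1, e2) {
  if (missing(e2)) {
    # unary operators: !absent is TRUE (absent is falsy), -absent is absent
    if (.Generic == "!") return(TRUE)
    return(absent)
  }
  both <- is_absent(e1) && is_absent(e2)
  switch(.Generic,
    "==" = both,
    "!=" = FALSE,
    "<" = , ">" = , "<=" = , ">=" = FALSE,
    # arithmetic with absent propagates absent
    absent
  )
}

# Truthiness under the predicate contract: absent/NULL/NA are false, empty
# collections are false, domain objects are true, scalars follow R semantics.
truthy <- function(x) {
  if (is_absent(x)) return(FALSE)
  if (is.logical(x)) return(length(x) == 1L && !is.na(x) && x)
  if (is.numeric(x)) return(length(x) == 1L && !is.na(x) && x != 0)
  if (is.character(x)) return(length(x) == 1L && !is.na(x) && nzchar(x))
  if (inherits(x, c("padel_unit", "padel_player", "padel_team"))) return(TRUE)
  if (is.list(x)) return(length(x) > 0L)
  length(x) > 0L
}
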