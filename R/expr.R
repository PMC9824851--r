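# The query expression grammar.
#
# Predicates and attributes can be written as plain strings in a small,
# side-effect-free expression language: dotted member paths
# (`shot.next.hitter.distance_to_net`), numeric/text/Boolean literals,
# arithmetic, comparisons, `and`/`or`/`not` (or `&`/`|`/`!`), parentheses,
# and method calls (`shot.like("serve")`, `shot.one_of("vd,vr")`,
# `frame.distance_to_net(frame.point.winner.forehand_player)`).
#
# R parses a dotted path as a single name, so the grammar rides on the R
# parser: the Python-style keywords are rewritten to R operators and the
# resulting syntax tree is walked by a dedicated evaluator that enforces the
# absent contract (comparisons with absent are FALSE, member access on absent
# stays absent, predicates never raise past the edge of a rally).
#
# Root names resolve in order: (1) the item's own level name or a property
# of the item, (2) a match player by lowercase last name, bound to the
# current frame context, (3) a registered helper.

EXPR_FUNS <- list(
  abs = abs, min = min, max = max, floor = floor, ceiling = ceiling,
  round = round, sqrt = sqrt
)

translate_expr_text <- function(text) {
  text <- gsub("\\band\\b", "&", text)
  text <- gsub("\\bor\\b", "|", text)
  text <- gsub("\\bnot\\b", "!", text)
  text <- gsub("\\bTrue\\b", "TRUE", text)
  text <- gsub("\\bFalse\\b", "FALSE", text)
  text <- gsub("\\bNone\\b", "absent", text)
  # typographic quotes from copy-pasted sources
  text <- gsub("[“”]", '"', text)
  text <- gsub("[‘’]", "'", text)
  text
}

parse_expr <- function(text) {
  lang <- tryCatch(str2lang(translate_expr_text(text)), error = function(e) {
    stop("cannot parse expression '", text, "': ", conditionMessage(e),
         call. = FALSE)
  })
  lang
}

#' Compile a grammar expression
#'
#' Turns an expression string into a function of one play unit. Used for
#' string predicates and for query attributes.
#'
#' @param text the expression.
#' @param kind the level of the item the expression is evaluated on.
#' @param helpers optional named list of extra root bindings.
#' @return a function `f(item)`.
#' @export
compile_expr <- function(text, kind, helpers = NULL) {
  node <- parse_expr(text)
  force(kind)
  f <- function(item) {
    ctx <- list(item = item, kind = kind, helpers = helpers,
                match = frame_match(item), text = text)
    eval_node(node, ctx)
  }
  attr(f, "expr_text") <- text
  f
}

as_predicate <- function(predicate, kind, helpers = NULL) {
  if (is.function(predicate)) return(predicate)
  if (is.character(predicate) && length(predicate) == 1L) {
    return(compile_expr(predicate, kind, helpers))
  }
  stop("a predicate must be a function or an expression string", call. = FALSE)
}

eval_node <- function(node, ctx) {
  if (is.numeric(node) || is.character(node) || is.logical(node)) return(node)
  if (is.symbol(node)) {
    name <- as.character(node)
    if (name == "absent") return(absent)
    return(eval_path(strsplit(name, ".", fixed = TRUE)[[1]], ctx))
  }
  if (is.call(node)) return(eval_call(node, ctx))
  stop("unsupported construct in expression: ", deparse(node), call. = FALSE)
}

eval_call <- function(node, ctx) {
  head <- node[[1]]
  if (!is.symbol(head)) {
    stop("unsupported call in expression: ", deparse(node), call. = FALSE)
  }
  op <- as.character(head)

  if (op == "(") return(eval_node(node[[2]], ctx))

  if (op == "!") return(!truthy(eval_node(node[[2]], ctx)))

  if (op %in% c("&", "&&")) {
    if (!truthy(eval_node(node[[2]], ctx))) return(FALSE)
    return(truthy(eval_node(node[[3]], ctx)))
  }
  if (op %in% c("|", "||")) {
    if (truthy(eval_node(node[[2]], ctx))) return(TRUE)
    return(truthy(eval_node(node[[3]], ctx)))
  }

  if (op %in% c("<", ">", "<=", ">=", "==", "!=")) {
    l <- eval_node(node[[2]], ctx)
    r <- eval_node(node[[3]], ctx)
    return(compare_values(op, l, r))
  }

  if (op %in% c("+", "-", "*", "/", "^", "%%")) {
    l <- eval_node(node[[2]], ctx)
    if (length(node) == 2L) {  # unary +/-
      if (is_absent(l)) return(absent)
      return(do.call(op, list(l)))
    }
    r <- eval_node(node[[3]], ctx)
    if (is_absent(l) || is_absent(r)) return(absent)
    return(do.call(op, list(l, r)))
  }

  # method call through a dotted path: shot.like("serve"),
  # frame.distance_to_net(p), shot.next.next.one_of("vd,vr")
  if (grepl(".", op, fixed = TRUE)) {
    parts <- strsplit(op, ".", fixed = TRUE)[[1]]
    method <- parts[length(parts)]
    obj <- eval_path(parts[-length(parts)], ctx)
    args <- lapply(as.list(node)[-1], eval_node, ctx = ctx)
    return(call_method(method, obj, args, ctx))
  }

  # bare function call: a whitelisted numeric helper, or a method applied
  # to the current item (e.g. like("serve") inside a shot expression)
  if (op %in% names(EXPR_FUNS)) {
    args <- lapply(as.list(node)[-1], eval_node, ctx = ctx)
    if (any(vapply(args, is_absent, logical(1)))) return(absent)
    return(do.call(EXPR_FUNS[[op]], args))
  }
  if (op %in% c("like", "one_of")) {
    args <- lapply(as.list(node)[-1], eval_node, ctx = ctx)
    return(call_method(op, ctx$item, args, ctx))
  }
  if (op %in% c("bind", "distance_to_net")) {
    args <- lapply(as.list(node)[-1], eval_node, ctx = ctx)
    if (any(vapply(args, is_absent, logical(1)))) return(absent)
    return(do.call(op, args))
  }

  stop("unknown function '", op, "' in expression '", ctx$text, "'",
       call. = FALSE)
}

call_method <- function(method, obj, args, ctx) {
  switch(method,
    like = like(obj, args[[1]]),
    one_of = one_of(obj, args[[1]]),
    distance_to_net = {
      if (is_absent(obj)) return(absent)
      do.call(distance_to_net, c(list(obj), args))
    },
    bind = {
      if (is_absent(obj)) return(absent)
      bind(obj, args[[1]])
    },
    stop("unknown method '", method, "' in expression '", ctx$text, "'",
         call. = FALSE)
  )
}

compare_values <- function(op, l, r) {
  la <- is_absent(l); ra <- is_absent(r)
  if (la || ra) {
    if (op == "==") return(la && ra)
    return(FALSE)
  }
  res <- do.call(op, list(l, r))
  if (is.logical(res)) res else truthy(res)
}

eval_path <- function(tokens, ctx) {
  obj <- resolve_root(tokens[1], ctx)
  for (tok in tokens[-1]) {
    if (is_absent(obj)) return(absent)
    obj <- step_prop(obj, tok, ctx)
  }
  obj
}

step_prop <- function(obj, tok, ctx) {
  res <- get_prop(obj, tok)
  if (is_prop_missing(res)) {
    stop("unknown property '", tok, "' in expression '", ctx$text,
         "' (on a ", class(obj)[1], ")", call. = FALSE)
  }
  # in a frame query the item *is* the frame context: players reached along
  # a path are rebound to it, so "point.serve.hitter.x" tracks the server
  # at the current frame rather than at the serve
  if (ctx$kind == "frame" && inherits(res, "padel_player")) {
    res[["frame"]] <- ctx$item
  }
  res
}

resolve_root <- function(name, ctx) {
  item <- ctx$item
  # (1) the item's own level name, or one of its properties
  if (identical(name, ctx$kind)) return(item)
  res <- get_prop(item, name)
  if (!is_prop_missing(res)) return(res)
  # (2) a match player by lowercase last name, bound to the frame context
  p <- match_player(ctx$match, norm_token(name))
  if (!is.null(p)) {
    fr <- current_frame(item, ctx$kind)
    if (!is_absent(fr)) p[["frame"]] <- fr
    return(p)
  }
  # (3) registered helpers
  if (!is.null(ctx$helpers) && name %in% names(ctx$helpers)) {
    return(ctx$helpers[[name]])
  }
  stop("cannot resolve '", name, "' from a ", ctx$kind,
       " (expression '", ctx$text, "')", call. = FALSE)
}

# the frame context an item naturally carries: itself for a frame, the
# first tracked frame for a shot, absent otherwise
current_frame <- function(item, kind) {
  if (kind == "frame") return(item)
  if (kind == "shot") return(get_prop(item, "frame"))
  absent
}
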