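# Tennis-style scoring automaton.
#
# Padel scores exactly like tennis: points accumulate 0 -> 15 -> 30 -> 40
# within a game; at 40-40 either the advantage rule applies (two clear
# points, through "Ad") or, in golden-point mode, the next point takes the
# game. Games accumulate into sets (first to 6, two clear, with 6-6 resolved
# by a single deciding game standing in for the tie-break), sets into the
# match. The automaton replays a winner sequence and emits the within-game
# score labels *after* each point, which is how the points table prints them.

SCORE_LADDER <- c("0", "15", "30", "40")

#' Replay a point-winner sequence through the scoring automaton
#'
#' @param winners character vector of `"T"`/`"B"` (top/bottom team), one per
#'   point, in match order.
#' @param mode `"advantage"` (two clear points at deuce) or `"golden_point"`
#'   (next point at 40-40 wins the game).
#' @param from optional starting within-game score, a character pair such as
#'   `c("30", "30")`, for replaying fragments.
#' @return a tibble with one row per point: `point` (index), `winner`,
#'   `score_T`, `score_B` (labels after the point), `game`, `set` (1-based
#'   indices of the game/set the point belongs to), `games_T`, `games_B`,
#'   `sets_T`, `sets_B` (cumulative tallies after the point), and logical
#'   `game_over`, `set_over` flags.
#' @examples
#' score_automaton(c("B", "T", "T", "B", "B"))
#' @export
score_automaton <- function(winners, mode = c("advantage", "golden_point"),
                            from = c("0", "0")) {
  mode <- match.arg(mode)
  winners <- toupper(as.character(winners))
  if (!length(winners)) stop("winners must be nonempty", call. = FALSE)
  if (!all(winners %in% c("T", "B"))) {
    stop("winners must be 'T' or 'B'", call. = FALSE)
  }
  st <- list(T = from[1], B = from[2])
  games <- c(T = 0L, B = 0L)
  sets <- c(T = 0L, B = 0L)
  game_i <- 1L; set_i <- 1L
  n <- length(winners)
  o_score_T <- character(n); o_score_B <- character(n)
  o_game <- integer(n); o_set <- integer(n)
  o_games_T <- integer(n); o_games_B <- integer(n)
  o_sets_T <- integer(n); o_sets_B <- integer(n)
  o_game_over <- logical(n); o_set_over <- logical(n)
  for (i in seq_len(n)) {
    w <- winners[i]; l <- setdiff(c("T", "B"), w)
    game_over <- FALSE
    if (st[[w]] == "40" && st[[l]] == "40") {
      if (mode == "golden_point") game_over <- TRUE else st[[w]] <- "Ad"
    } else if (st[[w]] == "Ad") {
      game_over <- TRUE
    } else if (st[[l]] == "Ad") {
      st[[l]] <- "40"
    } else if (st[[w]] == "40") {
      game_over <- TRUE
    } else {
      st[[w]] <- SCORE_LADDER[base::match(st[[w]], SCORE_LADDER) + 1L]
    }
    set_over <- FALSE
    if (game_over) {
      st <- list(T = "0", B = "0")
      games[w] <- games[w] + 1L
      lead <- games[w] - games[l]
      if ((games[w] >= 6L && lead >= 2L) || games[w] == 7L) {
        # 7 games means the 6-6 deciding game was just taken
        set_over <- TRUE
        sets[w] <- sets[w] + 1L
      }
    }
    o_score_T[i] <- st$T; o_score_B[i] <- st$B
    o_game[i] <- game_i; o_set[i] <- set_i
    o_games_T[i] <- games[["T"]]; o_games_B[i] <- games[["B"]]
    o_sets_T[i] <- sets[["T"]]; o_sets_B[i] <- sets[["B"]]
    o_game_over[i] <- game_over; o_set_over[i] <- set_over
    if (game_over) game_i <- game_i + 1L
    if (set_over) {
      set_i <- set_i + 1L
      games <- c(T = 0L, B = 0L)
    }
  }
  tibble::tibble(
    point = seq_len(n), winner = winners,
    score_T = o_score_T, score_B = o_score_B,
    game = o_game, set = o_set,
    games_T = o_games_T, games_B = o_games_B,
    sets_T = o_sets_T, sets_B = o_sets_B,
    game_over = o_game_over, set_over = o_set_over
  )
}

# pick the scoring mode whose replay best agrees with the printed score
# columns; ties fall back to "advantage"
detect_scoring_mode <- function(winners, printed_T, printed_B) {
  agree <- function(mode) {
    rep <- score_automaton(winners, mode)
    sum(rep$score_T == printed_T & rep$score_B == printed_B)
  }
  a <- agree("advantage"); g <- agree("golden_point")
  list(mode = if (g > a) "golden_point" else "advantage",
       agreement = max(a, g), n = length(winners))
}
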