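# Seeded generator of padel-consistent match bundles.
#
# Emits the three tabular schemas (points / shots / frames) plus ground
# truth, so the whole package is testable without any real annotations. The
# simulation is intentionally simple but structurally faithful: rallies open
# with a serve, hitters alternate teams (the team-mate nearer the incoming
# ball hits), shot types follow a serve -> return -> volley/smash transition
# table over the registry codes, players chase waypoints under a strict
# per-frame speed cap, and the score columns are produced by the same
# scoring automaton the ingest module replays, so the round trip is exact by
# construction.

#' Generator configuration
#'
#' Defaults describe a plausible professional-level match at 30 fps: mean
#' rally length 6 shots (geometric), mean shot interval 1.3 s (lognormal --
#' observed padel tempo is close to a second and a half), serve struck deep
#' in the server's half with the partner waiting about 2 m from the net, and
#' player movement capped at 7 m/s.
#'
#' @param seed integer seed; the same seed yields a byte-identical bundle.
#' @param fps frames per second.
#' @param scoring_mode `"golden_point"` (modern professional rule) or
#'   `"advantage"`.
#' @param sets sets needed to win the match (1 = single-set bundle).
#' @param rally_mean mean shots per rally (geometric, minimum 1).
#' @param shot_interval_mean mean seconds between shots (lognormal).
#' @param shot_interval_sdlog lognormal shape of the shot interval.
#' @param max_speed player speed cap, m/s.
#' @param waypoint_noise sd (m) of the jitter applied to movement targets.
#' @param serve_depth distance (m) of the server from their back wall.
#' @param partner_net_distance distance (m) of the server's partner from the
#'   net.
#' @param net_approach_prob probability that the serving team advances to
#'   the net after the serve.
#' @param lob_prob probability that a groundstroke is flagged as a lob.
#' @param rally_end_margin seconds between the last shot and the point end.
#' @param inter_point_gap range (s) of dead time between points.
#' @param max_points hard cap on simulated points (truncates the match;
#'   useful to keep test sweeps small).
#' @param title match title.
#' @return a `synth_config` list.
#' @export
synth_config <- function(seed = 1L, fps = 30, scoring_mode = "golden_point",
                         sets = 1L, rally_mean = 6,
                         shot_interval_mean = 1.3, shot_interval_sdlog = 0.35,
                         max_speed = 7, waypoint_noise = 0.3,
                         serve_depth = 1.5, partner_net_distance = 2,
                         net_approach_prob = 0.8, lob_prob = 0.15,
                         rally_end_margin = 1.0, inter_point_gap = c(10, 20),
                         max_points = 400L, title = NULL) {
  stopifnot(fps >= 1, rally_mean >= 1, shot_interval_mean > 0,
            max_speed > 0, sets >= 1)
  structure(list(
    seed = as.integer(seed), fps = fps,
    scoring_mode = match.arg(scoring_mode, c("golden_point", "advantage")),
    sets = as.integer(sets), rally_mean = rally_mean,
    shot_interval_mean = shot_interval_mean,
    shot_interval_sdlog = shot_interval_sdlog,
    max_speed = max_speed, waypoint_noise = waypoint_noise,
    serve_depth = serve_depth, partner_net_distance = partner_net_distance,
    net_approach_prob = net_approach_prob, lob_prob = lob_prob,
    rally_end_margin = rally_end_margin, inter_point_gap = inter_point_gap,
    max_points = max_points,
    title = title %||% paste0("synthetic-match-seed", seed)
  ), class = "synth_config")
}

# run code under a fixed seed without disturbing the caller's RNG
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv()) else
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

SYNTH_ROSTER <- tibble::tibble(
  name = c("A Alba", "B Bosch", "C Castro", "D Duran"),
  team = c("T", "T", "B", "B")
)

#' Generate a synthetic match bundle
#'
#' Simulates a match under [synth_config()] and returns the three tables in
#' the ingest schemas together with the generator's ground truth.
#'
#' @param config a [synth_config()].
#' @return a `padel_bundle` list with elements `points`, `shots`, `frames`
#'   (tibbles matching [read_points()]/[read_shots()]/[read_frames()]
#'   output), `roster`, `ground_truth` and `config`.
#' @examples
#' b <- generate_match(synth_config(seed = 7, max_points = 6))
#' b$points
#' @export
generate_match <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  with_local_seed(config$seed, generate_match_impl(config))
}

generate_match_impl <- function(cfg) {
  fps <- cfg$fps
  geom <- court_geometry()
  w <- geom$width; l <- geom$length; net <- geom$net_y
  max_step <- cfg$max_speed / fps  # strict per-frame displacement cap

  # fixed halves: T on y > net, B on y < net (side switches are a property
  # of broadcast data the corner labels absorb anyway)
  home_y <- c(T1 = l - 3, T2 = l - 3, B1 = 3, B2 = 3)
  ids <- c("T1", "T2", "B1", "B2")
  team_of <- c(T1 = "T", T2 = "T", B1 = "B", B2 = "B")

  winners <- character(0)
  pts_rows <- list(); shot_rows <- list(); frame_rows <- list()
  truth_shots <- list()
  frame_cursor <- 1000L
  serving_team_first <- "B"
  point_i <- 0L
  repeat {
    point_i <- point_i + 1L
    if (point_i > cfg$max_points) break
    # serving team alternates by game; replay the automaton to locate games
    if (length(winners)) {
      rep_now <- score_automaton(winners, cfg$scoring_mode)
      game_now <- rep_now$game[length(winners)] +
        as.integer(rep_now$game_over[length(winners)])
      done_T <- rep_now$sets_T[length(winners)]
      done_B <- rep_now$sets_B[length(winners)]
      if (max(done_T, done_B) >= cfg$sets) break
    } else {
      game_now <- 1L
    }
    srv_team <- if (game_now %% 2L == 1L) serving_team_first else
      setdiff(c("T", "B"), serving_team_first)
    rcv_team <- setdiff(c("T", "B"), srv_team)
    srv_id <- paste0(srv_team, 1L + (game_now %% 2L))
    prt_id <- setdiff(ids[team_of == srv_team], srv_id)

    own_y <- function(id, depth) if (team_of[[id]] == "T") l - depth else depth
    # initial placement: server deep, partner at the net, receivers split
    pos <- rbind(
      T1 = c(stats::runif(1, 2, 8), home_y[["T1"]]),
      T2 = c(stats::runif(1, 2, 8), home_y[["T2"]]),
      B1 = c(stats::runif(1, 2, 8), home_y[["B1"]]),
      B2 = c(stats::runif(1, 2, 8), home_y[["B2"]])
    )
    srv_x <- stats::runif(1, 1.5, w - 1.5)
    pos[srv_id, ] <- c(srv_x, own_y(srv_id, cfg$serve_depth))
    pos[prt_id, ] <- c(w - srv_x, own_y(prt_id, net - cfg$partner_net_distance))

    # rally skeleton: shot count, times, hitters, codes, targets
    n_shots <- 1L + stats::rgeom(1, prob = 1 / cfg$rally_mean)
    meanlog <- log(cfg$shot_interval_mean) - cfg$shot_interval_sdlog^2 / 2
    gaps <- stats::rlnorm(n_shots - 1L, meanlog, cfg$shot_interval_sdlog)
    shot_t <- cumsum(c(0, gaps))
    shot_f <- frame_cursor + as.integer(round(shot_t * fps))
    if (n_shots > 1L) {
      for (s in 2:n_shots) shot_f[s] <- max(shot_f[s], shot_f[s - 1L] + 1L)
    }
    start_f <- frame_cursor
    end_f <- shot_f[n_shots] + as.integer(round(cfg$rally_end_margin * fps))

    hit_team <- rep(c(srv_team, rcv_team), length.out = n_shots)
    net_rush <- stats::runif(1) < cfg$net_approach_prob

    # ball targets: where each shot is aimed (next hitter moves there)
    targets <- matrix(NA_real_, n_shots + 1L, 2)
    targets[1, ] <- pos[srv_id, ]
    for (s in seq_len(n_shots)) {
      rec_team <- setdiff(c("T", "B"), hit_team[s])
      ty_half <- if (rec_team == "T") c(net + 1, l - 0.8) else c(0.8, net - 1)
      targets[s + 1L, ] <- c(stats::runif(1, 0.8, w - 0.8),
                             stats::runif(1, ty_half[1], ty_half[2]))
    }

    # frame-by-frame movement with waypoints and a hard speed cap
    n_frames <- end_f - start_f
    fr_x <- matrix(NA_real_, n_frames, 4, dimnames = list(NULL, ids))
    fr_y <- matrix(NA_real_, n_frames, 4, dimnames = list(NULL, ids))
    way <- pos  # per-player waypoint
    hitters <- character(n_shots)
    shot_pos <- matrix(NA_real_, n_shots, 2)
    next_shot <- 1L
    for (k in seq_len(n_frames)) {
      f <- start_f + k - 1L
      if (next_shot <= n_shots && f == shot_f[next_shot]) {
        s <- next_shot
        cand <- ids[team_of == hit_team[s]]
        if (s == 1L) {
          hitters[s] <- srv_id
        } else {
          d2 <- (pos[cand, 1] - targets[s, 1])^2 + (pos[cand, 2] - targets[s, 2])^2
          hitters[s] <- cand[which.min(d2)]
        }
        shot_pos[s, ] <- pos[hitters[s], ]
        # retarget: the receiving side chases the next ball, the hitting
        # side advances to the net (serving team, if rushing) or recovers
        nxt_rec <- ids[team_of != hit_team[s]]
        d2n <- (pos[nxt_rec, 1] - targets[s + 1L, 1])^2 +
          (pos[nxt_rec, 2] - targets[s + 1L, 2])^2
        chaser <- nxt_rec[which.min(d2n)]
        way[chaser, ] <- targets[s + 1L, ]
        for (id in ids) {
          if (id == chaser) next
          rush <- team_of[[id]] == srv_team && net_rush
          depth <- if (rush) net - cfg$partner_net_distance else 3
          way[id, ] <- c(pos[id, 1] + stats::rnorm(1, 0, cfg$waypoint_noise),
                         own_y(id, depth))
        }
        next_shot <- next_shot + 1L
      }
      # move every player toward their waypoint, capped
      for (id in ids) {
        dvec <- way[id, ] - pos[id, ]
        dd <- sqrt(sum(dvec^2))
        if (dd > 1e-9) {
          step <- min(0.9 * max_step, dd)
          pos[id, ] <- pos[id, ] + dvec / dd * step
        }
        pos[id, 1] <- min(max(pos[id, 1], 0.1), w - 0.1)
        pos[id, 2] <- min(max(pos[id, 2], 0.1), l - 0.1)
      }
      fr_x[k, ] <- pos[, 1]; fr_y[k, ] <- pos[, 2]
    }

    # the point winner: usually the team that struck last
    last_team <- hit_team[n_shots]
    win <- if (stats::runif(1) < 0.65) last_team else
      setdiff(c("T", "B"), last_team)
    winners <- c(winners, win)

    # corner labels from positions at the point's first frame
    corner_by_id <- corners_from_positions(fr_x[1, ], fr_y[1, ], net)
    id_by_corner <- stats::setNames(names(corner_by_id), corner_by_id)
    name_of <- stats::setNames(SYNTH_ROSTER$name, ids)

    shot_codes <- sample_shot_codes(n_shots, shot_pos, net)
    lobs <- shot_codes %in% c("d", "r", "pld", "plr") &
      stats::runif(n_shots) < cfg$lob_prob

    pts_rows[[point_i]] <- tibble::tibble(
      start = start_f, end = end_f,
      duration_frames = end_f - start_f,
      duration_seconds = round((end_f - start_f) / fps, 1),
      winner = win,
      tl = name_of[[id_by_corner[["tl"]]]],
      tr = name_of[[id_by_corner[["tr"]]]],
      bl = name_of[[id_by_corner[["bl"]]]],
      br = name_of[[id_by_corner[["br"]]]]
    )
    shot_rows[[point_i]] <- tibble::tibble(
      frame = shot_f,
      corner = unname(corner_by_id[hitters]),
      shot_code = shot_codes,
      lob = lobs
    )
    frame_rows[[point_i]] <- synth_frame_block(start_f, n_frames, fr_x, fr_y,
                                               id_by_corner, l)
    truth_shots[[point_i]] <- tibble::tibble(
      point = point_i, shot = seq_len(n_shots),
      frame = shot_f, hitter = unname(name_of[hitters]),
      hitter_slot = hitters, code = shot_codes, lob = lobs
    )

    frame_cursor <- end_f +
      as.integer(round(stats::runif(1, cfg$inter_point_gap[1],
                                    cfg$inter_point_gap[2]) * fps))
  }

  points <- dplyr::bind_rows(pts_rows)
  replay <- score_automaton(points$winner, cfg$scoring_mode)
  points$points_T <- replay$score_T
  points$points_B <- replay$score_B
  points <- points[, c("start", "end", "duration_frames", "duration_seconds",
                       "winner", "points_T", "points_B",
                       "tl", "tr", "bl", "br")]

  structure(list(
    points = points,
    shots = dplyr::bind_rows(shot_rows),
    frames = dplyr::bind_rows(frame_rows),
    roster = SYNTH_ROSTER,
    ground_truth = list(
      winners = points$winner,
      score_T = replay$score_T, score_B = replay$score_B,
      game = replay$game, set = replay$set,
      shots = dplyr::bind_rows(truth_shots)
    ),
    config = cfg
  ), class = "padel_bundle")
}

corners_from_positions <- function(x, y, net) {
  top <- names(x)[y > net]; bot <- names(x)[y <= net]
  out <- character(4)
  names(out) <- c(top[order(x[top])], bot[order(x[bot])])
  out[] <- c("tl", "tr", "bl", "br")
  out
}

# serve -> return family -> volleys/smashes near the net, groundstrokes deep
sample_shot_codes <- function(n, shot_pos, net) {
  codes <- character(n)
  for (s in seq_len(n)) {
    if (s == 1L) { codes[s] <- "s"; next }
    near_net <- abs(shot_pos[s, 2] - net) < 4
    codes[s] <- if (s == 2L) {
      sample(c("d", "r", "pld", "plr"), 1, prob = c(0.4, 0.4, 0.1, 0.1))
    } else if (near_net) {
      sample(c("vd", "vr", "b", "r1", "djd"), 1,
             prob = c(0.3, 0.25, 0.25, 0.15, 0.05))
    } else {
      sample(c("d", "r", "spd", "spr", "cp"), 1,
             prob = c(0.35, 0.35, 0.12, 0.12, 0.06))
    }
  }
  codes
}

# emit per-frame corner-format rows, with a fixed synthetic camera mapping
# for the image-space columns (populates the schema; carries no information)
synth_frame_block <- function(start_f, n_frames, fr_x, fr_y, id_by_corner, l) {
  out <- tibble::tibble(frame_number = start_f + seq_len(n_frames) - 1L)
  for (crn in CORNERS) {
    id <- id_by_corner[[crn]]
    x <- fr_x[, id]; y <- fr_y[, id]
    out[[paste0(crn, "_i")]] <- round(100 + 80 * x * (1 + 0.005 * (l - y)))
    out[[paste0(crn, "_j")]] <- round(40 + 28 * (l - y))
    out[[paste0(crn, "_x")]] <- round(x, 2)
    out[[paste0(crn, "_y")]] <- round(y, 2)
  }
  out
}

#' @export
print.padel_bundle <- function(x, ...) {
  cat(sprintf("<match bundle '%s': %d point(s), %d shot(s), %d frame row(s)>\n",
              x$config$title %||% "bundle", nrow(x$points), nrow(x$shots),
              nrow(x$frames)))
  invisible(x)
}

#' Assemble a generated bundle into a match
#'
#' @param bundle a `padel_bundle` from [generate_match()].
#' @param config optional [padel_config()]; defaults to the generator's fps
#'   and scoring mode.
#' @return a `padel_match`.
#' @export
assemble_bundle <- function(bundle, config = NULL) {
  stopifnot(inherits(bundle, "padel_bundle"))
  cfg <- config %||% padel_config(fps = bundle$config$fps,
                                  scoring_mode = bundle$config$scoring_mode)
  assemble_match(bundle$points, bundle$shots, bundle$frames, config = cfg,
                 title = bundle$config$title)
}

#' Perturb a bundle's court positions
#'
#' Adds Gaussian noise (sd `sigma` meters) to every court-space coordinate,
#' clipped to the court rectangle plus `clip` meters -- a stand-in for
#' tracking error when testing validator tolerances and smoothing.
#'
#' @param bundle a `padel_bundle`.
#' @param sigma noise sd in meters (0 is the identity).
#' @param clip clipping envelope outside the court, meters.
#' @return the perturbed bundle.
#' @export
perturb_bundle <- function(bundle, sigma, clip = 2) {
  stopifnot(inherits(bundle, "padel_bundle"), sigma >= 0)
  if (sigma == 0) return(bundle)
  geom <- court_geometry()
  fr <- bundle$frames
  with_local_seed(bundle$config$seed + 999L, {
    for (crn in CORNERS) {
      cx <- paste0(crn, "_x"); cy <- paste0(crn, "_y")
      fr[[cx]] <- pmin(pmax(fr[[cx]] + stats::rnorm(nrow(fr), 0, sigma),
                            -clip), geom$width + clip)
      fr[[cy]] <- pmin(pmax(fr[[cy]] + stats::rnorm(nrow(fr), 0, sigma),
                            -clip), geom$length + clip)
    }
  })
  bundle$frames <- fr
  bundle
}

#' The printed example tables
#'
#' A five-point fragment of a real annotated match in the three raw schemas
#' (the shapes every ingest function understands), packaged as plain-text
#' fixtures: five points of a women's professional match, the five shots of
#' its first rally and five frames of tracking data.
#'
#' @return a list with tibbles `points`, `shots`, `frames`.
#' @examples
#' fx <- make_fixture_tables()
#' fx$points$start[1]  # 13606
#' @export
make_fixture_tables <- function() {
  dir <- system.file("extdata", package = "padelquery")
  list(
    points = read_points(file.path(dir, "fixture_points.tsv")),
    shots = read_shots(file.path(dir, "fixture_shots.tsv")),
    frames = read_frames(file.path(dir, "fixture_frames.tsv"))
  )
}
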