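# Brute-force flat-table oracles.
#
# Everything here recomputes query answers directly from a bundle's three
# raw tables with vectorized dplyr, sharing no code with the hierarchy /
# navigation / expression-evaluation path it checks. Items are identified
# by their start frame (shots by the annotated hit frame, frames by the
# frame number), which is what query results carry in `.start_frame`.

suppressPackageStartupMessages(library(dplyr))

# bind the verbs locally so the oracles resolve them regardless of how the
# test environment is parented (installed package vs pkgload)
for (.f in c("arrange", "mutate", "row_number", "left_join", "select",
             "group_by", "ungroup", "lead", "first", "summarise", "filter",
             "count", "pull", "n")) {
  assign(.f, getExportedValue("dplyr", .f))
}

NET_Y <- 10; COURT_W <- 10; COURT_L <- 20
ALL_CORNERS <- c("tl", "tr", "bl", "br")
DEF_CODES <- strsplit(
  "d,r,ad,ar,pld,plr,spd,spr,bpd,bpr,dpa,dpc,dpag,cp,cpld,cplr", ",")[[1]]

# one row per shot with every derived quantity the predicates need
oracle_shot_table <- function(bundle) {
  fps <- bundle$config$fps
  pts <- bundle$points |> arrange(start) |> mutate(point_idx = row_number())
  sh <- bundle$shots |> arrange(frame)
  sh$point_idx <- findInterval(sh$frame, pts$start)
  stopifnot(all(sh$frame < pts$end[sh$point_idx]))  # synthetic data: no clamping
  sh <- sh |>
    left_join(pts |> select(point_idx, p_start = start, p_end = end,
                            winner, tl, tr, bl, br),
              by = "point_idx") |>
    group_by(point_idx) |>
    mutate(idx = row_number(), n_shots = n()) |>
    ungroup()
  sh$team <- ifelse(sh$corner %in% c("tl", "tr"), "T", "B")
  sh$hitter_name <- vapply(seq_len(nrow(sh)),
                           function(i) sh[[sh$corner[i]]][i], character(1))
  sh$hitter <- tolower(vapply(strsplit(sh$hitter_name, "\\s+"),
                              function(p) p[length(p)], character(1)))

  fr <- bundle$frames
  j <- match(sh$frame, fr$frame_number)
  sh$x <- NA_real_; sh$y <- NA_real_
  sh$partner_y <- NA_real_
  partner_of <- c(tl = "tr", tr = "tl", bl = "br", br = "bl")
  for (crn in ALL_CORNERS) {
    sel <- sh$corner == crn
    sh$x[sel] <- fr[[paste0(crn, "_x")]][j[sel]]
    sh$y[sel] <- fr[[paste0(crn, "_y")]][j[sel]]
    sh$partner_y[sel] <- fr[[paste0(partner_of[[crn]], "_y")]][j[sel]]
  }
  sh <- sh |>
    group_by(point_idx) |>
    mutate(
      nxt_frame = lead(frame), nxt_x = lead(x), nxt_y = lead(y),
      nxt_hitter = lead(hitter),
      nxt2_code = lead(shot_code, 2),
      nxt3_hitter = lead(hitter, 3),
      nxt_code = lead(shot_code),
      nxt2_exists = idx <= n_shots - 2,
      nxt3_side = lead(pmin(x, COURT_W - x), 3)
    ) |>
    ungroup() |>
    mutate(
      dist_net = abs(y - NET_Y),
      dist_side = pmin(x, COURT_W - x),
      dist_back = ifelse(team == "B", y, COURT_L - y),
      partner_dist_net = abs(partner_y - NET_Y),
      nxt_side = pmin(nxt_x, COURT_W - nxt_x),
      duration = (nxt_frame - frame) / fps,
      dx = nxt_x - x, dy = nxt_y - y,
      angle = ifelse(y < NET_Y, atan2(dx, dy), atan2(-dx, -dy)) * 180 / pi,
      abs_angle = abs(angle),
      won = team == winner
    )
  sh
}

# one row per frame of every point that has at least one shot (only those
# frames belong to a rally and are reachable by frame queries)
oracle_frame_table <- function(bundle) {
  fps <- bundle$config$fps
  pts <- bundle$points |> arrange(start) |> mutate(point_idx = row_number())
  sh <- bundle$shots |> arrange(frame)
  serve_corner <- sh |>
    mutate(point_idx = findInterval(frame, pts$start)) |>
    group_by(point_idx) |>
    summarise(serve_corner = first(corner), .groups = "drop")
  fr <- bundle$frames
  fr$point_idx <- findInterval(fr$frame_number, pts$start)
  fr <- fr |>
    left_join(pts |> select(point_idx, p_start = start, p_end = end, winner),
              by = "point_idx") |>
    left_join(serve_corner, by = "point_idx") |>
    filter(!is.na(serve_corner),
           frame_number >= p_start, frame_number < p_end)
  fr$serve_y <- vapply(seq_len(nrow(fr)), function(i)
    fr[[paste0(fr$serve_corner[i], "_y")]][i], numeric(1))
  fr |>
    mutate(
      since_start = (frame_number - p_start) / fps,
      top_both_net = abs(tl_y - NET_Y) < 4 & abs(tr_y - NET_Y) < 4,
      bot_both_net = abs(bl_y - NET_Y) < 4 & abs(br_y - NET_Y) < 4,
      q7a = ifelse(winner == "T", top_both_net, bot_both_net),
      serve_dist_net = abs(serve_y - NET_Y)
    )
}

# expected .start_frame sets for every built-in query
oracle_rowsets <- function(bundle) {
  st <- oracle_shot_table(bundle)
  ft <- oracle_frame_table(bundle)
  list(
    q1 = st$frame[st$shot_code %in% c("vd", "vr")],
    q2 = st$frame[st$shot_code %in% c("vd", "vr") &
                    !is.na(st$duration) & st$duration < 1 &
                    !is.na(st$abs_angle) & st$abs_angle < 8],
    q3 = st$frame[st$idx < st$n_shots],
    q4 = st$frame[st$shot_code == "s" & st$idx < st$n_shots],
    q5 = st$frame[st$shot_code == "s" & st$idx < st$n_shots],
    q6 = ft$frame_number[ft$since_start < 1],
    q7a = ft$frame_number[ft$q7a],
    q7b = st$frame[st$won & st$idx >= st$n_shots - 1],
    q8 = ft$frame_number,
    q9 = st$frame[st$lob & !is.na(st$nxt_code) & st$nxt_code %in% DEF_CODES],
    q10 = st$frame[st$shot_code == "s" &
                     !is.na(st$nxt_side) & st$nxt_side > 2.5 &
                     !is.na(st$nxt2_code) & st$nxt2_code %in% c("vd", "vr") &
                     !is.na(st$nxt3_side) & st$nxt3_side < 2.5 &
                     !is.na(st$nxt3_hitter) & st$nxt_hitter == st$nxt3_hitter]
  )
}

# extra predicate corpus: grammar text + independent oracle over the tables
predicate_corpus <- function() {
  list(
    list(kind = "shot", expr = "shot.hitter.distance_to_net < 4",
         oracle = function(st, ft) st$frame[st$dist_net < 4]),
    list(kind = "shot", expr = "shot.duration < 1.2",
         oracle = function(st, ft)
           st$frame[!is.na(st$duration) & st$duration < 1.2]),
    list(kind = "shot", expr = "shot.number == 1",
         oracle = function(st, ft) st$frame[st$idx == 1]),
    list(kind = "shot", expr = "shot.next.next",
         oracle = function(st, ft) st$frame[st$nxt2_exists]),
    list(kind = "shot", expr = 'shot.prev.like("serve")',
         oracle = function(st, ft) st$frame[st$idx == 2]),
    list(kind = "shot", expr = "shot.abs_angle < 15",
         oracle = function(st, ft)
           st$frame[!is.na(st$abs_angle) & st$abs_angle < 15]),
    list(kind = "shot", expr = "shot.hitter == shot.next.next.hitter",
         oracle = function(st, ft) {
           nxt2_hitter <- st |> group_by(point_idx) |>
             mutate(h2 = lead(hitter, 2)) |> ungroup() |> pull(h2)
           st$frame[!is.na(nxt2_hitter) & st$hitter == nxt2_hitter]
         }),
    list(kind = "shot", expr = "shot.hitter.partner.distance_to_net < 3",
         oracle = function(st, ft) st$frame[st$partner_dist_net < 3]),
    list(kind = "shot", expr = 'shot.one_of("b,r1") or shot.lob',
         oracle = function(st, ft)
           st$frame[st$shot_code %in% c("b", "r1") | st$lob]),
    list(kind = "shot",
         expr = "not shot.next and shot.hitter.from_point_winning_team",
         oracle = function(st, ft) st$frame[st$idx == st$n_shots & st$won]),
    list(kind = "frame", expr = "frame.time - frame.point.start_time < 0.5",
         oracle = function(st, ft) ft$frame_number[ft$since_start < 0.5]),
    list(kind = "frame",
         expr = "frame.distance_to_net(frame.point.serve.hitter) < 6",
         oracle = function(st, ft) ft$frame_number[ft$serve_dist_net < 6])
  )
}

# ---- shared bundles (memoised across test files) ----------------------------

.padel_test_cache <- new.env(parent = emptyenv())

sweep_bundle <- function(seed, max_points = 6) {
  key <- paste0("b", seed, "_", max_points)
  got <- get0(key, envir = .padel_test_cache)
  if (is.null(got)) {
    b <- generate_match(synth_config(seed = seed, max_points = max_points))
    m <- assemble_bundle(b)
    got <- list(bundle = b, match = m)
    assign(key, got, envir = .padel_test_cache)
  }
  got
}

result_frames <- function(result) sort(result$.start_frame)
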