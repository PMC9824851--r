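# Navigation, the play-unit hierarchy and the absent sentinel.

test_that("fixture hierarchy navigates down, up (skip-level) and sideways", {
  fx <- make_fixture_tables()
  m <- suppressWarnings(assemble_match(fx$points, fx$shots, fx$frames))

  games <- nav_children(nav_children(m)[[1]])
  pts <- nav_children(games[[1]])
  expect_length(pts, 5)
  p1 <- pts[[1]]
  shots <- nav_children(p1)
  expect_length(shots, 5)
  # the serve annotated two frames before the printed point start is clamped
  # into the point span and still leads the rally
  expect_equal(shots[[1]]$start_frame, 13606)
  expect_equal(shots[[1]]$shot_code, "s")

  # skip-level ancestor equals the fully chained path
  fr <- nav_children(shots[[1]], "frame")[[1]]
  expect_identical(nav_parent(fr, "match"),
                   fr$shot$point$game$set$match)
  expect_identical(nav_parent(fr, "point"), p1)

  # the serve's point was won by the bottom team (winner column row 1)
  expect_equal(shots[[1]]$point$winner$label, "B")

  # siblings: next of the serve is the BR shot at frame 13,633
  expect_equal(nav_next(shots[[1]])$start_frame, 13633)
  expect_equal(nav_next(shots[[1]])$hitter$last_name, "Salazar")
  expect_true(is_absent(nav_prev(shots[[1]])))
  expect_true(is_absent(nav_next(shots[[5]])))

  # unknown child level errors, naming the valid one
  expect_error(nav_children(p1, "frame"), "child")
  expect_error(nav_parent(p1, "shot"), "ancestor")
})

test_that("an empty match level yields an empty list, not an error", {
  b <- degenerate_bundle()
  m <- suppressWarnings(assemble_test_bundle(b))
  p2 <- nav_children(nav_children(nav_children(m)[[1]])[[1]])[[2]]
  expect_length(nav_children(p2), 0)
})

test_that("shot frame-lists tile each point's tracked frame range", {
  for (seed in 1:5) {
    tb <- sweep_bundle(seed)
    for (pt in padelquery:::collect_units(tb$match, "point")) {
      shots <- nav_children(pt)
      got <- sort(unlist(lapply(shots, function(s)
        vapply(nav_children(s, "frame"), function(f) f$frame_number, numeric(1)))))
      expect_equal(got, seq(pt$start_frame, pt$end_frame - 1))
    }
  }
})

test_that("nav_parent agrees with an interval scan of the points table", {
  for (seed in 1:5) {
    tb <- sweep_bundle(seed)
    pts <- dplyr::arrange(tb$bundle$points, start)
    frames <- padelquery:::collect_units(tb$match, "frame")
    idx <- sample.int(length(frames), min(40, length(frames)))
    for (fr in frames[idx]) {
      expected <- which(pts$start <= fr$frame_number & fr$frame_number < pts$end)
      got <- nav_parent(fr, "point")
      expect_equal(got$start_frame, pts$start[expected])
    }
  }
})

test_that("nav_next and nav_prev invert each other on interior siblings", {
  tb <- sweep_bundle(1)
  for (level in c("game", "point", "shot")) {
    units <- padelquery:::collect_units(tb$match, level)
    for (u in units) {
      nx <- nav_next(u)
      if (!is_absent(nx)) expect_identical(nav_prev(nx), u)
      pv <- nav_prev(u)
      if (!is_absent(pv)) expect_identical(nav_next(pv), u)
    }
  }
})

test_that("sibling numbers are 1..n ordered by start frame", {
  tb <- sweep_bundle(2)
  walk <- function(parent) {
    kids <- nav_children(parent)
    if (length(kids)) {
      expect_equal(vapply(kids, function(k) k$number, numeric(1)),
                   seq_along(kids))
      starts <- vapply(kids, function(k) k$start_frame, numeric(1))
      expect_false(is.unsorted(starts))
      if (padelquery:::unit_level(kids[[1]]) != "frame") {
        for (k in kids) walk(k)
      }
    }
  }
  walk(tb$match)
})

test_that("absent propagates through access and is false in comparisons", {
  expect_true(is_absent(absent$foo$bar$baz))
  expect_false(absent == 3)
  expect_false(absent < 3)
  expect_false(absent > 3)
  expect_false(absent != 3)
  expect_true(absent == absent)
  expect_true(is_absent(absent + 1))
  expect_true(!absent)

  # the Q10-style chain never raises on a short rally
  b <- degenerate_bundle()
  m <- suppressWarnings(assemble_test_bundle(b))
  serve <- nav_children(nav_children(nav_children(nav_children(m)[[1]])[[1]])[[1]])[[1]]
  expect_true(is_absent(serve$nxt))
  expect_no_error(val <- serve$nxt$hitter$distance_to_side_wall > 2.5)
  expect_false(val)
})

test_that("absent-safe comparison holds for arbitrary property paths", {
  paths <- c("nxt", "prev", "nxt$hitter", "nxt$hitter$position",
             "nxt$nxt$nxt$hitter$distance_to_net")
  tb <- sweep_bundle(1)
  shots <- padelquery:::collect_units(tb$match, "shot")
  last_shots <- Filter(function(s) is_absent(nav_next(s)), shots)
  s <- last_shots[[1]]
  for (p in paths) {
    v <- eval(str2lang(paste0("s$", p)))
    expect_no_error(cmp <- v == 1)
    if (is_absent(v)) expect_false(isTRUE(cmp))
  }
})

test_that("bound players compare by identity, ignoring the bound frame", {
  fx <- make_fixture_tables()
  m <- suppressWarnings(assemble_match(fx$points, fx$shots, fx$frames))
  shots <- padelquery:::collect_units(m, "shot")
  # Sainz hits shots 1, 3 and 5 of the rally: same person, different frames
  expect_true(shots[[1]]$hitter == shots[[3]]$hitter)
  expect_false(shots[[1]]$hitter == shots[[2]]$hitter)
  p <- m$players[[1]]
  fr <- nav_children(shots[[1]], "frame")[[1]]
  expect_equal(bind(p, fr)$last_name, p$last_name)
  expect_true(bind(p, fr) == p)

  # bind() checks membership and the frames-table lookup matches the source
  stranger <- padelquery:::new_player("X", "Nobody")
  expect_error(bind(stranger, fr), "not part of this match")
  bp <- bind(m$players[[3]], fr)  # Sanchez, BL corner
  row <- fx$frames[fx$frames$frame_number == fr$frame_number, ]
  expect_equal(bp$position$x, row$bl_x)
  expect_equal(bp$position$y, row$bl_y)
})
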