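# Readers, fps inference, the scoring automaton and match assembly.

test_that("the printed points table parses with thousands separators", {
  fx <- make_fixture_tables()
  expect_equal(nrow(fx$points), 5)
  expect_equal(fx$points$start[1], 13606)
  expect_equal(fx$points$end[1], 13820)
  expect_equal(fx$points$duration_frames[1], 214)
  expect_equal(fx$points$winner[1], "B")
  expect_equal(fx$points$points_B, c("15", "15", "15", "30", "40"))
  # shot codes resolve through the alias table ("Serve" -> "s", "VD" -> "vd")
  expect_equal(fx$shots$shot_code, c("s", "d", "b", "d", "vd"))
  expect_equal(fx$shots$lob, c(FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(fx$frames$bl_x[1], 2.50)
  expect_equal(fx$frames$bl_y[1], 1.60)
})

test_that("reader errors name the missing schema and the offending row", {
  bad <- tempfile(fileext = ".csv")
  writeLines("start,winner\n1,T", bad)
  expect_error(read_points(bad), "missing required points column")
  writeLines("Start (f),End (f),Winner\nxx,20,T", bad)
  expect_error(read_points(bad), "row 1")
  # empty file with header parses to an empty record list
  writeLines("Frame,Player,Shot Type,Lob", bad)
  expect_equal(nrow(read_shots(bad)), 0)
})

test_that("write/read of a bundle round-trips the three tables", {
  b <- sweep_bundle(1)$bundle
  dir <- tempfile()
  write_match_bundle(b, dir)
  b2 <- read_match_bundle(dir)
  expect_equal(as.data.frame(b2$points), as.data.frame(b$points))
  expect_equal(as.data.frame(b2$shots), as.data.frame(b$shots))
  expect_equal(as.data.frame(b2$frames), as.data.frame(b$frames))
})

test_that("fps inference reconciles frame counts with printed seconds", {
  fx <- make_fixture_tables()
  expect_equal(as.integer(infer_fps(fx$points)), 30L)
  # single record
  one <- tibble::tibble(duration_frames = 300, duration_seconds = 10)
  expect_equal(as.integer(infer_fps(one)), 30L)
  # optimality: the residual at the returned fps is the global minimum
  fps <- infer_fps(fx$points)
  res <- vapply(1:120, function(f)
    sum(abs(fx$points$duration_frames / f - fx$points$duration_seconds)),
    numeric(1))
  expect_equal(attr(fps, "residual"), min(res))
  expect_equal(which.min(res), 30L)
  # scale consistency: multiplying the frame column by k scales the fps by k
  doubled <- fx$points
  doubled$duration_frames <- doubled$duration_frames * 2L
  expect_equal(as.integer(infer_fps(doubled, candidates = 1:240)), 60L)
  # no usable rows -> instructive error
  expect_error(infer_fps(tibble::tibble(duration_frames = 10)), "fps")
})

test_that("the scoring automaton reproduces the printed progression", {
  # the five printed points: B,T,T,B,B from 0-0
  rep <- score_automaton(c("B", "T", "T", "B", "B"))
  expect_equal(rep$score_T, c("0", "15", "30", "30", "30"))
  expect_equal(rep$score_B, c("15", "15", "15", "30", "40"))
  expect_true(all(rep$game == 1))

  # four straight points take the game and reset the labels
  rep <- score_automaton(rep("T", 4))
  expect_equal(rep$score_T[4], "0")
  expect_equal(rep$score_B[4], "0")
  expect_true(rep$game_over[4])
  expect_equal(rep$games_T[4], 1L)
})

test_that("advantage play from 30-30 follows the hand-traced state table", {
  # T,B,T,B,T,B,T,T: 40-30, 40-40, Ad-40, 40-40, Ad-40, 40-40, Ad-40, game
  rep <- score_automaton(c("T", "B", "T", "B", "T", "B", "T", "T"),
                         mode = "advantage", from = c("30", "30"))
  expect_equal(rep$score_T, c("40", "40", "Ad", "40", "Ad", "40", "Ad", "0"))
  expect_equal(rep$score_B, c("30", "40", "40", "40", "40", "40", "40", "0"))
  expect_equal(rep$game_over, c(rep(FALSE, 7), TRUE))

  # golden point: the deciding point at 40-40 ends the game at once
  gp <- score_automaton(c("T", "B", "T"), mode = "golden_point",
                        from = c("30", "30"))
  expect_equal(gp$score_T, c("40", "40", "0"))
  expect_true(gp$game_over[3])
})

test_that("games accumulate into sets with the 6-6 deciding game", {
  # 5-5, then 6-5, then the 6-6 deciding game
  w <- c(rep(c(rep("T", 4), rep("B", 4)), 5), rep("T", 4), rep("B", 4),
         rep("B", 4))
  rep <- score_automaton(w, mode = "golden_point")
  last <- rep[nrow(rep), ]
  expect_equal(last$games_B, 7L)
  expect_true(last$set_over)
  expect_equal(last$sets_B, 1L)
})

test_that("the fixture assembles into the expected hierarchy", {
  fx <- make_fixture_tables()
  expect_warning(
    m <- assemble_match(fx$points, fx$shots, fx$frames),
    "clamped")
  g <- glance(m)
  expect_equal(g$sets, 1L)
  expect_equal(g$games, 1L)
  expect_equal(g$points, 5L)
  expect_equal(g$shots, 5L)
  expect_equal(g$fps, 30)
  pts <- padelquery:::collect_units(m, "point")
  expect_equal(pts[[1]]$score_after, c("0", "15"))
  expect_equal(pts[[5]]$score_after, c("30", "40"))
  # empty shots table: points with zero shots still assemble
  m2 <- assemble_match(fx$points, NULL, fx$frames)
  expect_equal(glance(m2)$shots, 0L)
  expect_gt(sum(validate_match(m2)$code == "empty_point"), 0)
})

test_that("shots far outside any point are an error, near ones clamp", {
  fx <- make_fixture_tables()
  stray <- fx$shots
  stray$frame[2] <- 12000L
  expect_error(
    suppressWarnings(assemble_match(fx$points, stray, fx$frames)),
    "clamping tolerance")
})

test_that("printed scores inconsistent with the replay are flagged", {
  fx <- make_fixture_tables()
  wrong <- fx$points
  wrong$points_B[1] <- "30"
  w <- testthat::capture_warnings(assemble_match(wrong, fx$shots, fx$frames))
  expect_true(any(grepl("diverge", w)))
  expect_error(
    suppressWarnings(assemble_match(wrong, fx$shots, fx$frames,
                                    config = padel_config(lenient = FALSE))),
    "point 1")
})

test_that("validation reports constructed violations precisely", {
  fx <- make_fixture_tables()
  m <- suppressWarnings(assemble_match(fx$points, fx$shots, fx$frames))
  expect_equal(sum(validate_match(m)$severity == "error"), 0)

  # move a point outside its parent's span: exactly one containment error
  pt <- padelquery:::collect_units(m, "point")[[1]]
  assign("start_frame", 13000L, envir = pt)
  rep <- validate_match(m)
  expect_equal(sum(rep$code == "containment"), 1)

  # positions beyond the court-bounds tolerance
  b <- degenerate_bundle()
  b$frames$tl_x[1] <- 15
  m2 <- suppressWarnings(assemble_test_bundle(b))
  expect_gt(sum(validate_match(m2)$code == "court_bounds"), 0)
})

test_that("score reconstruction replays exactly on ingested matches", {
  for (seed in 1:5) {
    tb <- sweep_bundle(seed)
    pts <- padelquery:::collect_units(tb$match, "point")
    got <- t(vapply(pts, function(p) p$score_after, character(2)))
    expect_equal(got[, 1], tb$bundle$ground_truth$score_T)
    expect_equal(got[, 2], tb$bundle$ground_truth$score_B)
  }
})
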