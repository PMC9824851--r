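# Query execution, result operations, links and plot-data contracts.

test_that("q4 on the printed fixture retrieves exactly the serve", {
  fx <- make_fixture_tables()
  m <- suppressWarnings(assemble_match(
    fx$points, fx$shots, fx$frames,
    config = padel_config(video_url = "https://example.org/match")))
  r <- run_query(m, "q4")
  expect_equal(nrow(r), 1)
  expect_equal(r$hitter.last_name, "Sainz")
  expect_equal(r$.start_frame, 13606)
  # deep link: floor(13606 / 30) = 453 s into the video
  expect_equal(video_links(r), "https://example.org/match?t=453s")
})

test_that("constant-false predicates yield zero rows with columns intact", {
  tb <- sweep_bundle(1)
  r <- run_query(tb$match, query_def("none", "shot", "False",
                                     attribs = c("id", "duration")))
  expect_equal(nrow(r), 0)
  expect_true(all(c("id", "duration") %in% names(r)))
})

test_that("execution equals the flat-table oracle per query and per match", {
  for (seed in 1:3) {
    tb <- sweep_bundle(seed)
    expected <- oracle_rowsets(tb$bundle)
    for (q in names(expected)) {
      r <- run_query(tb$match, q)
      expect_equal(result_frames(r), sort(expected[[q]]),
                   info = paste("seed", seed, q))
    }
  }
})

test_that("function predicates and grammar strings retrieve the same rows", {
  tb <- sweep_bundle(2)
  fn <- query_def("volleys_fn", "shot", function(s) one_of(s, "vd,vr"))
  gr <- query_def("volleys_gr", "shot", 'shot.one_of("vd,vr")')
  expect_equal(result_frames(run_query(tb$match, fn)),
               result_frames(run_query(tb$match, gr)))
  # R-function predicate with fluent navigation and the absent contract
  fn2 <- query_def("drop_last2", "shot",
                   function(s) !is_absent(s$nxt) && !is_absent(s$nxt$nxt))
  gr2 <- query_def("drop_last2g", "shot", "shot.next.next")
  expect_equal(result_frames(run_query(tb$match, fn2)),
               result_frames(run_query(tb$match, gr2)))
})

test_that("attribute errors are loud but absent attributes are silent NA", {
  tb <- sweep_bundle(1)
  expect_error(run_query(tb$match, "q3", attribs = c("no.such.path")),
               "cannot resolve 'no'")
  expect_error(run_query(tb$match, "q3", attribs = c("hitter.bogus")),
               "unknown property 'bogus'")
  # duration of last shots is absent -> NA cell, row kept
  r <- run_query(tb$match, query_def("all", "shot", "True",
                                     attribs = c("id", "duration")))
  st <- oracle_shot_table(tb$bundle)
  expect_equal(sum(is.na(r$duration)), sum(st$idx == st$n_shots))
})

test_that("scope additivity: a two-match scope concatenates row-wise", {
  a <- sweep_bundle(1); b <- sweep_bundle(2)
  r_both <- run_query(list(a$match, b$match), "q3")
  r_sep <- concat(list(run_query(a$match, "q3"), run_query(b$match, "q3")))
  expect_equal(tidy(r_both), tidy(r_sep))
  expect_equal(r_both$.match, r_sep$.match)
})

test_that("analyze summarises numeric and text columns", {
  tb <- sweep_bundle(1)
  r <- run_query(tb$match, "q3")
  a <- analyze(r)
  expect_setequal(a$column, c("hitter.position.x", "hitter.position.y",
                              "id", "duration"))
  st <- oracle_shot_table(tb$bundle)
  dur <- a[a$column == "duration", ]
  expect_equal(dur$mean, mean(st$duration, na.rm = TRUE))
  expect_equal(dur$count, sum(!is.na(st$duration)))
  expect_equal(a$distinct[a$column == "id"], nrow(r))
  # single row: sd degenerates to 0; empty result warns
  one <- run_query(tb$match, query_def("one", "shot", "shot.number == 99"))
  expect_warning(analyze(one), "empty")
  single <- r[1, ]
  class(single) <- class(r)
  expect_equal(analyze(single)$sd[1], 0)
})

test_that("sum_by groups, sums and conserves point durations", {
  tb <- sweep_bundle(3)
  r <- run_query(tb$match, "q8")
  s <- sum_by(r, "point")
  pts <- tidy(tb$match, "point")
  expect_equal(nrow(s), nrow(pts))
  m <- match(s$point, pts$id)
  # one frame-duration of slack
  expect_true(all(abs(s$duration - pts$duration[m]) <= 1 / 30 + 1e-9))

  # q7a pipeline equals brute-force per-point accumulation
  r7 <- sum_by(run_query(tb$match, "q7a"), "point")
  ft <- oracle_frame_table(tb$bundle)
  brute <- ft |>
    dplyr::filter(q7a) |>
    dplyr::count(point_idx) |>
    dplyr::mutate(secs = n / 30)
  expect_equal(sort(r7$duration), sort(brute$secs))

  # small worked example and the error contract
  toy <- padelquery:::new_padel_result(
    tibble::tibble(point = c("p1", "p1", "p2"), v = c(1, 2, 4)))
  out <- sum_by(toy, "point")
  expect_equal(out$v, c(3, 4))
  expect_error(sum_by(toy, "missing"), "key column")
  expect_warning(sum_by(padelquery:::new_padel_result(
    tibble::tibble(point = "p1", txt = "a", v = 1)), "point"), "dropping")
})

test_that("add_column + concat build labelled comparison pipelines", {
  tb <- sweep_bundle(1)
  q1 <- sum_by(run_query(tb$match, "q7a"), "point")
  q2 <- sum_by(run_query(tb$match, "q8"), "point")
  q2 <- q2[, c("point", "duration", ".match", ".start_frame", ".video")]
  class(q2) <- class(q1)
  r1 <- add_column(q1, "Team", "Point Winner")
  r2 <- add_column(q2, "Team", "Point Loser")
  both <- concat(list(r1, r2), "Time on the net")
  expect_equal(nrow(both), nrow(r1) + nrow(r2))
  expect_equal(attr(both, "title"), "Time on the net")
  expect_setequal(unique(both$Team), c("Point Winner", "Point Loser"))
  # concat of a single result is that result
  expect_equal(tidy(concat(list(r1))), tidy(r1))
  # column-set mismatch names the difference
  expect_error(concat(list(r1, q2)), "Team")
})

test_that("video links are offsets in whole seconds, nondecreasing", {
  tb <- sweep_bundle(2)
  b <- tb$bundle
  m <- assemble_match(b$points, b$shots, b$frames,
                      config = padel_config(fps = 30,
                                            video_url = "https://v.example/x"),
                      title = "linked")
  r <- run_query(m, "q3")
  links <- video_links(r)
  offs <- as.integer(sub(".*t=(\\d+)s$", "\\1", links))
  expect_equal(offs, floor(r$.start_frame / 30))
  expect_false(is.unsorted(offs))
  # no video configured -> NA links
  expect_true(all(is.na(video_links(run_query(tb$match, "q3")))))
})

test_that("deterministic export: same bundle and query, identical bytes", {
  tb <- sweep_bundle(1)
  f1 <- tempfile(); f2 <- tempfile()
  write_result_csv(run_query(tb$match, "q1"), f1)
  m2 <- assemble_bundle(generate_match(synth_config(seed = 1, max_points = 6)))
  write_result_csv(run_query(m2, "q1"), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("plot_data contracts: mappings, conservation, court overlay", {
  tb <- sweep_bundle(1)
  r1 <- run_query(tb$match, "q1")
  st <- oracle_shot_table(tb$bundle)

  pd <- plot_data(r1, "directions")
  # one row per volley with a finite destination (non-last shots)
  expect_equal(nrow(pd$data),
               sum(st$shot_code %in% c("vd", "vr") & !is.na(st$nxt_x)))
  expect_true(all(c("outline", "net") %in% pd$court$part))

  pos <- plot_data(r1[1, ], "positions")
  expect_equal(nrow(pos$data), 1)
  expect_equal(pos$data$x, r1$hitter.position.x[1])

  r3 <- run_query(tb$match, "q3")
  h <- plot_data(r3, "histogram", value = "duration", bins = 7)
  expect_equal(sum(h$data$count), sum(!is.na(r3$duration)))

  expect_error(plot_data(r3, "bar_chart", x = "id", y = "nope"), "'y'")

  # renderers return ggplot objects over exactly these tables
  expect_s3_class(plot_positions(r1), "ggplot")
  expect_s3_class(plot_histogram(r3, value = "duration"), "ggplot")
  expect_s3_class(plot_directions(r1, color = "angle"), "ggplot")
})

test_that("tidy and glance methods expose results the broom way", {
  tb <- sweep_bundle(1)
  r <- run_query(tb$match, "q3")
  td <- tidy(r)
  expect_false(any(startsWith(names(td), ".")))
  g <- glance(r)
  expect_equal(g$rows, nrow(r))
  expect_equal(g$kind, "shot")
  expect_equal(g$matches, 1L)
})
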