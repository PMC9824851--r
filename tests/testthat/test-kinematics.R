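# Wall/net distances, finite-difference kinematics, shot angles.

fixture_match <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      fx <- make_fixture_tables()
      m <<- suppressWarnings(assemble_match(fx$points, fx$shots, fx$frames))
    }
    m
  }
})

frame_at <- function(m, n) {
  frames <- padelquery:::collect_units(m, "frame")
  frames[[which(vapply(frames, function(f) f$frame_number, numeric(1)) == n)]]
}

test_that("net distance is |y - net_y| on the printed positions", {
  m <- fixture_match()
  fr <- frame_at(m, 13614)
  bl <- bind(m$players[[3]], fr)  # Sanchez at (2.50, 1.60)
  expect_equal(distance_to_net(bl), 8.40)
  # the frame-method form binds and agrees
  expect_equal(distance_to_net(fr, m$players[[3]]), 8.40)
  # a player exactly on the net line
  b <- degenerate_bundle()
  b$frames$tl_y[] <- 10
  m2 <- suppressWarnings(assemble_test_bundle(b))
  fr2 <- padelquery:::collect_units(m2, "frame")[[1]]
  expect_equal(suppressWarnings(distance_to_net(bind(m2$players[[1]], fr2))), 0)
  # unbound players have no frame context
  expect_error(distance_to_net(m$players[[1]]), "frame context")
})

test_that("oriented wall distances follow the facing-the-net convention", {
  m <- fixture_match()
  fr <- frame_at(m, 13614)
  # BR (bottom) at (7.87, 1.66): right wall is x = 10
  br <- oriented_wall_distances(bind(m$players[[4]], fr))
  expect_equal(unname(br["right"]), 10 - 7.87)
  expect_equal(unname(br["back"]), 1.66)
  expect_equal(unname(br["side"]), 2.13)
  # TL (top) at (1.89, 18.53): right wall is x = 0
  tl <- oriented_wall_distances(bind(m$players[[1]], fr))
  expect_equal(unname(tl["right"]), 1.89)
  expect_equal(unname(tl["back"]), 20 - 18.53)
})

test_that("wall-distance invariants hold across synthetic frames", {
  tb <- sweep_bundle(1)
  frames <- padelquery:::collect_units(tb$match, "frame")
  idx <- seq(1, length(frames), by = 17)
  for (fr in frames[idx]) {
    for (p in tb$match$players) {
      d <- oriented_wall_distances(bind(p, fr))
      expect_true(all(d >= 0))
      expect_equal(unname(d["left"] + d["right"]), 10)
      expect_equal(unname(d["side"]), min(d["left"], d["right"]))
      # back + distance to the far back wall = court length
      expect_equal(unname(d["back"] + (20 - d["back"])), 20)
    }
  }
})

test_that("speed recovers a constructed constant-velocity trajectory", {
  b <- constant_velocity_bundle(v = 2)
  m <- suppressWarnings(assemble_test_bundle(b))
  frames <- padelquery:::collect_units(m, "frame")
  castro <- m$players[[3]]  # the moving BL player
  v <- player_speed(bind(castro, frames[[30]]))
  expect_equal(v$x, 0, tolerance = 1e-9)
  expect_equal(v$y, 2, tolerance = 1e-9)
  # one-sided truncation at the point boundary still sees the same slope
  v1 <- player_speed(bind(castro, frames[[1]]))
  expect_equal(v1$y, 2, tolerance = 1e-9)
  # constant velocity means zero acceleration
  a <- player_acceleration(bind(castro, frames[[30]]))
  expect_equal(a$magnitude, 0, tolerance = 1e-9)
  # a stationary player
  alba <- m$players[[1]]
  expect_equal(player_speed(bind(alba, frames[[30]]))$magnitude, 0)
})

test_that("per-frame steps sum to the path length and respect the cap", {
  tb <- sweep_bundle(3)
  m <- tb$match
  pt <- padelquery:::collect_units(m, "point")[[1]]
  frames <- unlist(lapply(nav_children(pt), nav_children, "frame"),
                   recursive = FALSE)
  p <- m$players[[1]]
  steps <- vapply(frames, function(f)
    padelquery:::bound_kinematic(bind(p, f), "distance_from_prev_frame"),
    numeric(1))
  expect_equal(steps[1], 0)  # point-initial frame
  # brute-force path length over the point
  xs <- vapply(frames, function(f) bind(p, f)$position$x, numeric(1))
  ys <- vapply(frames, function(f) bind(p, f)$position$y, numeric(1))
  expect_equal(sum(steps), sum(sqrt(diff(xs)^2 + diff(ys)^2)))
  # generator speed cap holds frame by frame
  cap <- tb$bundle$config$max_speed / tb$bundle$config$fps
  expect_true(all(steps <= cap + 1e-9))
})

test_that("a 0.01 m step on the printed positions is recovered", {
  m <- fixture_match()
  fr <- frame_at(m, 13615)  # BL moved (2.50,1.60) -> (2.50,1.59)
  bp <- bind(m$players[[3]], fr)
  expect_equal(padelquery:::bound_kinematic(bp, "distance_from_prev_frame"),
               0.01)
})

test_that("shot angles follow the down-the-line = 0 convention", {
  # straight down the line
  b0 <- angle_bundle(origin = c(2.5, 1.6), dest = c(2.5, 18.5))
  m0 <- suppressWarnings(assemble_test_bundle(b0))
  serve <- padelquery:::collect_units(m0, "shot")[[1]]
  expect_equal(serve$angle, 0)
  # hand trigonometry: atan(6/12) = 26.565 degrees
  b1 <- angle_bundle(origin = c(2, 2), dest = c(8, 14))
  m1 <- suppressWarnings(assemble_test_bundle(b1))
  s1 <- padelquery:::collect_units(m1, "shot")[[1]]
  expect_equal(s1$abs_angle, atan(6 / 12) * 180 / pi, tolerance = 1e-9)
  sd <- shot_direction(s1)
  expect_equal(sd$origin$x, 2)
  expect_equal(sd$destination$y, 14)
  expect_equal(sd$abs_angle, abs(sd$angle))
  # last shot of the rally has no direction
  s2 <- padelquery:::collect_units(m1, "shot")[[2]]
  expect_true(is_absent(shot_direction(s2)))
})

test_that("mirroring x about the court midline negates every angle", {
  tb <- sweep_bundle(2)
  b <- tb$bundle
  mirrored <- b
  for (crn in c("tl", "tr", "bl", "br")) {
    cx <- paste0(crn, "_x")
    mirrored$frames[[cx]] <- 10 - mirrored$frames[[cx]]
  }
  # corner labels flip left/right when x is mirrored; rename to keep the
  # per-point corner maps consistent with the mirrored positions
  swap <- c(tl = "tr", tr = "tl", bl = "br", br = "bl")
  names(mirrored$frames) <- ifelse(
    grepl("^(tl|tr|bl|br)_", names(mirrored$frames)),
    paste0(swap[substr(names(mirrored$frames), 1, 2)],
           substring(names(mirrored$frames), 3)),
    names(mirrored$frames))
  mirrored$shots$corner <- unname(swap[mirrored$shots$corner])
  pts <- mirrored$points
  pts[, c("tl", "tr")] <- pts[, c("tr", "tl")]
  pts[, c("bl", "br")] <- pts[, c("br", "bl")]
  mirrored$points <- pts

  m1 <- tb$match
  m2 <- assemble_bundle(mirrored)
  a1 <- run_query(m1, "q3", attribs = c("angle"))
  a2 <- run_query(m2, "q3", attribs = c("angle"))
  expect_equal(a2$angle, -a1$angle, tolerance = 1e-9)
})
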