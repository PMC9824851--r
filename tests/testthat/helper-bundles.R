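# Hand-built bundles for edge cases: degenerate rallies and constructed
# trajectories, in the same tibble schemas the readers emit.

test_roster <- function() {
  c(tl = "A Alba", tr = "B Bosch", bl = "C Castro", br = "D Duran")
}

# constant four-player frame block over [start, end)
const_frames <- function(start, end,
                         tl = c(2, 18), tr = c(8, 18),
                         bl = c(2, 2), br = c(8, 2)) {
  n <- end - start
  tibble::tibble(
    frame_number = start + seq_len(n) - 1L,
    tl_x = tl[1], tl_y = tl[2], tr_x = tr[1], tr_y = tr[2],
    bl_x = bl[1], bl_y = bl[2], br_x = br[1], br_y = br[2]
  )
}

as_bundle <- function(points, shots, frames, fps = 30,
                      mode = "golden_point", title = "handmade") {
  structure(list(points = points, shots = shots, frames = frames,
                 roster = NULL, ground_truth = NULL,
                 config = list(fps = fps, scoring_mode = mode, title = title,
                               seed = 0L)),
            class = "padel_bundle")
}

points_row <- function(start, end, winner) {
  r <- test_roster()
  tibble::tibble(start = start, end = end,
                 duration_frames = end - start,
                 duration_seconds = round((end - start) / 30, 1),
                 winner = winner,
                 tl = r[["tl"]], tr = r[["tr"]], bl = r[["bl"]], br = r[["br"]])
}

# 0-shot point, 1-shot rally, 3-shot rally, and a single-frame point
degenerate_bundle <- function() {
  points <- dplyr::bind_rows(
    points_row(100L, 200L, "B"),   # serve only
    points_row(300L, 400L, "T"),   # no shots at all
    points_row(500L, 600L, "B"),   # 3-shot rally
    points_row(700L, 701L, "T")    # single-frame point
  )
  shots <- tibble::tibble(
    frame = c(100L, 500L, 530L, 560L, 700L),
    corner = c("bl", "bl", "tl", "br", "tl"),
    shot_code = c("s", "s", "d", "vd", "s"),
    lob = c(FALSE, FALSE, TRUE, FALSE, FALSE)
  )
  frames <- dplyr::bind_rows(
    const_frames(100L, 200L),
    const_frames(300L, 400L),
    const_frames(500L, 600L),
    const_frames(700L, 701L)
  )
  as_bundle(points, shots, frames, title = "degenerate")
}

assemble_test_bundle <- function(bundle, ...) {
  assemble_match(bundle$points, bundle$shots, bundle$frames,
                 config = padel_config(fps = bundle$config$fps, ...),
                 title = bundle$config$title)
}

# one rally, one player moving straight up the court at a constant speed
constant_velocity_bundle <- function(v = 2, fps = 30) {
  start <- 100L; end <- 160L
  n <- end - start
  k <- seq_len(n) - 1L
  frames <- tibble::tibble(
    frame_number = start + k,
    tl_x = 2, tl_y = 18, tr_x = 8, tr_y = 18,
    bl_x = 2.5, bl_y = 1 + v * k / fps,
    br_x = 8, br_y = 2
  )
  points <- points_row(start, end, "B")
  shots <- tibble::tibble(frame = start, corner = "bl",
                          shot_code = "s", lob = FALSE)
  as_bundle(points, shots, frames, fps = fps, title = "constant-velocity")
}

# two-shot rallies with prescribed hitter positions, for angle checks
angle_bundle <- function(origin = c(2, 2), dest = c(8, 14)) {
  start <- 100L; end <- 200L; hit2 <- 150L
  frames <- const_frames(start, end, bl = origin, tl = dest)
  points <- points_row(start, end, "T")
  shots <- tibble::tibble(frame = c(start, hit2), corner = c("bl", "tl"),
                          shot_code = c("s", "d"), lob = FALSE)
  as_bundle(points, shots, frames, title = "angles")
}
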