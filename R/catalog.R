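# The built-in query catalog.
#
# Ten ready-made tactical queries covering the common analysis questions on
# padel tracking data: volley direction, rally tempo, serve placement, net
# pressure, winning shots, distance covered, lob effectiveness and the
# serve-return-volley pattern. Each entry is an ordinary query_def written
# in the expression grammar, with a default attribute set sized for its
# natural plots; all of them are total under the absent contract (they never
# raise on 0-shot points or 1-3-shot rallies).

DEFENSIVE_CODES <- "d,r,ad,ar,pld,plr,spd,spr,bpd,bpr,dpa,dpc,dpag,cp,cpld,cplr"

#' The built-in query catalog
#'
#' Returns the named list of ready-made queries `q1`..`q10` (with `q7a` and
#' `q7b` for the two net-pressure variants). Use the names with
#' [run_query()], e.g. `run_query(match, "q4")`.
#'
#' Queries:
#' * `q1` all volleys (forehand or backhand), with origin, receiver position
#'   and direction angle -- is the volley generally played cross-court?
#' * `q2` fast down-the-line volleys: duration under 1 s and absolute
#'   direction angle under 8 degrees.
#' * `q3` all non-last shots with their duration (time to the next shot) --
#'   the rally tempo.
#' * `q4` serves (with a following shot), with serve direction.
#' * `q5` serves with the server's partner position -- is the partner
#'   waiting in the net zone?
#' * `q6` frames within 1 s of the point start, tracking the server.
#' * `q7a` frames where both players of the point-winning team are inside
#'   the net zone (less than 4 m from the net); summed by point this gives
#'   time-on-net for the winning team.
#' * `q7b` winning shots: hitter on the point-winning team and at most one
#'   shot follows.
#' * `q8` all frames (distance-covered analyses; combine with per-player
#'   step attributes and [sum_by()]).
#' * `q9` lobs followed by a defensive shot.
#' * `q10` serve-return-volley: a serve, any return played from mid-court
#'   (more than 2.5 m from the side wall), then a volley answered by the
#'   same player who returned the serve from within 2.5 m of the side wall.
#'
#' @return named list of `padel_query` objects.
#' @export
builtin_catalog <- function() {
  list(
    q1 = query_def(
      "q1_volleys", "shot",
      'shot.one_of("vd,vr")',
      attribs = c("frame.frame_number",
                  "hitter.position.x", "hitter.position.y",
                  "hitter.last_name",
                  "next.hitter.position.x", "next.hitter.position.y",
                  "angle", "abs_angle")),
    q2 = query_def(
      "q2_fast_down_the_line_volleys", "shot",
      'shot.one_of("vd,vr") and shot.duration < 1 and shot.abs_angle < 8',
      attribs = c("frame.frame_number",
                  "hitter.position.x", "hitter.position.y",
                  "next.hitter.position.x", "next.hitter.position.y",
                  "duration", "angle")),
    q3 = query_def(
      "q3_all_non_last_shots", "shot",
      "shot.next",
      attribs = c("hitter.position.x", "hitter.position.y", "id", "duration")),
    q4 = query_def(
      "q4_serves", "shot",
      'shot.like("serve") and shot.next',
      attribs = c("hitter.last_name",
                  "hitter.position.x", "hitter.position.y",
                  "next.hitter.position.x", "next.hitter.position.y",
                  "angle")),
    q5 = query_def(
      "q5_serves_with_partner", "shot",
      'shot.like("serve") and shot.next',
      attribs = c("hitter.last_name",
                  "hitter.position.x", "hitter.position.y",
                  "hitter.partner.last_name",
                  "hitter.partner.position.x", "hitter.partner.position.y")),
    q6 = query_def(
      "q6_frames_after_serve", "frame",
      "(frame.time - frame.point.start_time) < 1",
      attribs = c("frame.frame_number", "time",
                  point = "point.id",
                  server = "point.serve.hitter.last_name",
                  server_x = "point.serve.hitter.x",
                  server_y = "point.serve.hitter.y")),
    q7a = query_def(
      "q7a_net_zone_winning_team", "frame",
      paste("frame.point.winner and",
            "frame.distance_to_net(frame.point.winner.forehand_player) < 4 and",
            "frame.distance_to_net(frame.point.winner.backhand_player) < 4"),
      attribs = c("duration", point = "point.id")),
    q7b = query_def(
      "q7b_winning_shots", "shot",
      "shot.hitter.from_point_winning_team and (not shot.next or not shot.next.next)",
      attribs = c("hitter.last_name",
                  "hitter.position.x", "hitter.position.y",
                  "frame.frame_number",
                  distance = "hitter.distance_to_net")),
    q8 = query_def(
      "q8_all_frames", "frame",
      "True",
      attribs = c("frame.frame_number", "time", "duration",
                  point = "point.id")),
    q9 = query_def(
      "q9_lobs_then_defensive", "shot",
      sprintf('shot.like("lob") and shot.next.one_of("%s")', DEFENSIVE_CODES),
      attribs = c("hitter.last_name", "frame.frame_number", "id",
                  "next.hitter.distance_to_backwall")),
    q10 = query_def(
      "q10_serve_return_volley", "shot",
      paste('shot.like("serve")',
            "and shot.next.hitter.distance_to_side_wall > 2.5",
            'and shot.next.next.one_of("vd,vr")',
            "and shot.next.next.next.hitter.distance_to_side_wall < 2.5",
            "and shot.next.hitter == shot.next.next.next.hitter"),
      attribs = c("id", "hitter.last_name", "frame.frame_number"))
  )
}
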