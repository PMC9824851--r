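---
title: "Querying padel tracking data with padelquery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Querying padel tracking data with padelquery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(padelquery)
```

## The problem

Modern video tracking produces per-frame annotations of padel matches:
court-space positions of the four players, the frame of every shot with its
type, and the frame span and winner of every point. These arrive as three
flat tables, and the questions analysts ask of them are awkward to answer
with spreadsheet filters or raw data-frame joins: *"serves to the T followed
by any return and then a volley toward the returner's side wall"* is a
statement about a **sequence** of events across three tables.

padelquery turns the three tables into a navigable hierarchy of temporal
play units — match, set, game, point, shot, frame — and layers a compact
predicate language over it, so the question above is a four-line expression
rather than a page of index arithmetic. Every retrieved row keeps a deep
link into the source video so the analyst can inspect the footage behind
any data point.

## The data model

A padel match decomposes by scoring rules: a **match** is won by sets, a
**set** by games (first to six, two clear; six-all here is resolved by a
single deciding game standing in for the tie-break), a **game** by points on
the tennis ladder 0 → 15 → 30 → 40. Below the scoring units sit the
**shots** that partition each rally and the video **frames** that carry the
four player positions. Every unit has a `[start_frame, end_frame)` span, a
1-based ordinal among its siblings, and a dynamic tag set.

The court frame is fixed: `x` across the 10 m width, `y` along the 20 m
length, the net at `y = 10`. The team on the `y < 10` half as seen in the
video is the *bottom* (B) team, the other the *top* (T) team; players are
labeled in the raw tables by their video corner at serve time (TL/TR/BL/BR)
and resolved to persons through each point's corner-name columns, so the
model never assumes teams keep their half between points.

Three tables feed the model:

* **points** — frame span, durations, winner (T/B), within-game score
  labels *after* the point, and the four player names by corner. The score
  columns are read as top team / bottom team, the only reading consistent
  with a row whose winner is B advancing the second column from 0 to 15.
* **shots** — hit frame, hitter corner, shot-type code, and a lob flag.
* **frames** — per-frame court positions (meters) and optional image-space
  pixels, which are carried as opaque metadata (the camera homography is out
  of scope).

### Assembly choices

* **Frame rate.** If not supplied, the integer fps minimising
  $\sum_i |f_i/\mathrm{fps} - s_i|$ over the points table's frame and
  second duration columns is used (`infer_fps()`); a five-row professional
  match fragment pins this to 30 fps with residual 0.13 s.
* **Scoring mode.** Games may be decided at deuce by the advantage rule or
  by a golden point. The printed score columns are replayed under both and
  the better-agreeing mode wins; ties (fragments that never reach deuce)
  fall back to advantage, and `padel_config(scoring_mode=)` overrides.
  In lenient mode (default) score divergence degrades to a warning, so
  tables with points removed still parse; strict mode errors at the first
  divergent point.
* **Shot attachment.** Frame numbers in these datasets are approximate, so
  a shot annotated slightly outside its point (the example serve sits two
  frames before the printed point start) is clamped into the enclosing
  span, with a warning, up to a tolerance (default 30 frames); beyond it
  ingest refuses. A shot owns the frames in the half-open interval from its
  start to the next shot's start; the serve additionally owns any
  point-initial frames that precede its clamped start, and the last shot
  runs to the point end — so the shot frame lists tile the point exactly.
* **Forehand/backhand player.** The team member covering the right side
  facing the net (large `x` for the bottom half, small `x` for the top) by
  mean tracked position during play is the forehand player; a config
  override exists because annotation conventions vary.
* **Point validity** is stored and exposed (`point$valid`, default `TRUE`
  when the column is absent) but never interpreted.

## Navigation and the absent sentinel

Units chain with `$`: `shot$point$winner`, `frame_unit$match$gender`
(skip-level ancestors are allowed), `shot$nxt` / `shot$prev` for siblings
(`next` is reserved in R; the string grammar below keeps the `shot.next`
spelling). Navigating past an edge yields the `absent` sentinel rather than
an error: any member access on `absent` is `absent`, it is falsy, and every
comparison involving it is `FALSE` (except `absent == absent`). This is what
lets a predicate dereference `shot.next.next.next` without guarding: on a
three-shot rally the chain quietly evaluates to false.

Players are identities; kinematics exist only for a player **bound** to a
frame (`bind(player, frame)`, or implicitly: `shot$hitter` comes bound to
the shot's start frame). Equality between players ignores the binding —
`shot.next.hitter == shot.next.next.next.hitter` asks "same person?".
On the fluent path, kinematic access on an *unbound* player follows the
absent contract (so catalog queries stay total on shots without tracked
frames); the strict function forms (`distance_to_net()`,
`oriented_wall_distances()`, `player_speed()`) error instead, naming the
missing frame context.

## Kinematics

All derived quantities are pure functions of the frames table:

* `distance_to_net` is $|y - 10|$; wall distances follow the player's
  orientation (a player faces the net, so the right wall is `x = 10` on the
  bottom half and `x = 0` on the top; `side = min(left, right)`). A player
  exactly on the net line takes facing from their team's half, with a
  warning.
* Speed and acceleration are central finite differences over ±5 frames
  (~0.33 s at 30 fps, configurable via `padel_config(speed_window=)`),
  truncated one-sided at point boundaries; no additional smoothing is
  applied before differencing. Single-frame points return a zero vector
  with a warning.
* Shot direction is proxied by the receiver: origin is the hitter's
  position at the shot, destination the next hitter's position at the next
  shot (there is no ball track). The angle is measured against the court
  long axis oriented away from the hitter; 0° is straight down the line and
  positive angles point to the hitter's right. Mirroring the court in `x`
  negates every angle — the sign convention is arbitrary but consistent,
  and absolute angles (the down-the-line filter `abs_angle < 8`) do not
  depend on it.

## Tags and the shot taxonomy

The registry ships 27 shot types (code, Spanish expansion, English
aliases); matching is case-insensitive. `like()` first tries the whole
query as one alias ("forehand volley" is an alias of `vd`), then splits on
whitespace and requires **every** token to match (AND); `one_of()` is OR
over a comma-separated code list. Spanish expansions are loaded but only
matched when `padel_config(spanish_aliases = TRUE)`, to avoid accidental
token collisions. Assembly inserts built-in tags: the type code, `serve`,
`lob` (from the flag column), `by-<lastname>`, and `winning` for shots whose
hitter's team took the point. `tag_rule()` + `apply_tags()` add user
concepts ("attack_volley": a volley within 1.5 m of the net) by traversal;
application is idempotent and tag sets only grow.

## Queries

A query is a level plus a Boolean predicate, written either as an R
function of one item or as a string in a small expression grammar: dotted
paths, literals, arithmetic, comparisons, `and`/`or`/`not`, parentheses,
method calls (`shot.like("serve")`,
`frame.distance_to_net(frame.point.winner.forehand_player)`). Root names
resolve as the item's own level name or property, then as a match player by
lowercase last name bound to the frame context, then as a caller-supplied
helper. In a frame-level query, players reached along a path are re-bound
to the current frame, so `point.serve.hitter.x` tracks the server through
the second after the serve.

`run_query()` returns one row per item whose predicate is truthy; the
predicate alone decides membership — an attribute that evaluates to absent
becomes an explicit `NA`, never a dropped row. Rows carry provenance
(`.match`, `.start_frame`, `.video` with a `?t=<seconds>` offset). Results
are tibbles: `analyze()` summarises columns, `sum_by()` aggregates (the
time-on-net and distance-covered pipelines), `add_column()`/`concat()`
stack labelled pipelines, `plot_*()` render via ggplot2 with the court
overlay, and `plot_data()` exposes the exact table behind any plot.
`tidy()`/`glance()` follow broom conventions.

Ten tactical queries ship in `builtin_catalog()` (`q1`..`q10`, with `q7a`
and `q7b`). Where the original notebook style first registers `volley` or
`defensive` tags and then uses `like()`, the catalog entries inline the
equivalent `one_of()` code lists so each entry is self-contained; the tag
route is exercised by the tag rules above.

```{r example}
b <- generate_match(synth_config(seed = 42, max_points = 8))
m <- assemble_bundle(b)
glance(m)
run_query(m, "q4")          # serves, with placement and direction
analyze(run_query(m, "q3")) # rally tempo: duration between shots
```

## The synthetic generator

No public padel dataset ships the three annotated tables, so the package
generates them. `generate_match()` simulates a match under a seeded
configuration and emits the exact schemas plus ground truth. It is a
*stated world*, not a claim about professional padel:

* rallies open with a serve and hitters alternate teams, the team-mate
  nearer the incoming ball taking the shot;
* shot codes follow a serve → return family → volleys/smashes-near-the-net
  transition table over the registry codes; lob flags attach to
  groundstrokes with probability 0.15;
* shot intervals are lognormal with mean 1.3 s (the observed tempo of the
  women's professional game is close to a second and a half), rally length
  geometric with mean 6 shots;
* the server stands 1.5 m from their back wall with the partner 2 m from
  the net; players chase waypoints under a hard 7 m/s speed cap (the
  per-frame step keeps 10% headroom under the cap so that rounding emitted
  coordinates to centimeters can never violate it);
* halves are fixed (corner labels per point absorb side information); the
  serving team alternates by game; the last-hitting team wins the point
  with probability 0.65;
* score columns are produced by the same `score_automaton()` ingest
  replays, which makes the generate → assemble round trip exact by
  construction — that is deliberate for the score path, while positions,
  kinematics and query semantics are checked against independent
  brute-force oracles instead.

What a green test on synthetic data does **not** establish: realistic
biomechanics, realistic shot-type frequencies, tracking noise (use
`perturb_bundle()` to inject Gaussian position error), camera effects, or
any empirical claim about padel tactics. The generator's image-space
columns come from a fixed synthetic projection and carry no information.

Test suites scale the simulation down (`max_points` caps a match at a
handful of points) to keep sweeps of 50 seeded matches inside a CPU budget;
the defaults above are unchanged by tests.

## Numerical and degenerate-input choices

* Court-bounds tolerance is 0.5 m (players step through the net-side
  openings; tracking error is ~0.3 m); `perturb_bundle()` clips to a wider
  2 m envelope precisely so that large injected noise still trips the
  validator.
* Frames that fall outside every point span are dropped with a warning;
  frames of a point with no shots are retained in the table but belong to
  no rally action and are therefore invisible to frame queries.
* Zero-shot points, one-to-three-shot rallies and single-frame points are
  legal inputs: every catalog query runs on them without raising, returning
  fewer (possibly zero) rows.
* `validate_match()` reports rather than raises: containment violations,
  non-monotone frame numbers and out-of-bounds positions are errors;
  non-alternating team hitters, missing serves and empty points are
  warnings, since real annotations contain noise.

## Limitations

The ball is not modelled: shot direction is a receiver-position proxy and
shot depth ("to the feet", "to the glass") cannot be expressed. Positions
are feet-on-floor planar coordinates; jumps and 3-D kinematics are out of
scope. The expression grammar is deliberately small — it has no
quantifiers or aggregation; those live in R around `run_query()`.
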