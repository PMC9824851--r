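# Tag semantics: the alias registry, like/one_of, rules and built-in tags.

shot_with_tags <- function(...) {
  padelquery:::new_unit_env("shot", list(tags = c(...)))
}

test_that("the registry ships 27 shot types and matches all their aliases", {
  reg <- shot_type_registry()
  expect_equal(nrow(reg), 27)
  expect_equal(anyDuplicated(reg$code), 0)
  # alias closure: the code and every English alias agree under like()
  for (i in seq_len(nrow(reg))) {
    sh <- shot_with_tags(reg$code[i])
    expect_true(like(sh, reg$code[i]))
    expect_true(like(sh, toupper(reg$code[i])))  # case-insensitive
    for (al in reg$aliases[[i]]) {
      expect_true(like(sh, al), info = paste(reg$code[i], "~", al))
    }
    # spanish names only match when enabled (standalone units: disabled)
    if (!reg$spanish_name[i] %in% unlist(reg$aliases) &&
        !reg$spanish_name[i] %in% reg$code) {
      expect_false(like(sh, reg$spanish_name[i]),
                   info = paste("spanish off:", reg$spanish_name[i]))
    }
  }
})

test_that("like is whole-alias first, then token-AND; one_of is token-OR", {
  vd <- shot_with_tags("vd")
  expect_true(like(vd, "forehand volley"))   # whole-alias precedence
  expect_true(like(vd, "drive volley"))
  expect_false(like(vd, "volley"))           # bare token is not an alias
  expect_false(like(vd, "backhand volley"))

  # token-AND over a mixed tag set
  x <- shot_with_tags("cross-court", "vd")
  expect_false(like(x, "cross-court volley"))    # "volley" matches nothing
  padelquery:::add_tag(x, "volley")
  expect_true(like(x, "cross-court volley"))     # now both tokens match
  expect_true(like(x, "volley cross-court"))     # token order irrelevant
  # "forehand" alone aliases the drive code, which is not among the tags
  expect_false(like(x, "cross-court forehand volley"))
  expect_false(like(x, "cross-court smash"))

  # one_of: any token suffices, whitespace ignored
  vr <- shot_with_tags("vr")
  expect_true(one_of(vr, "vd,vr"))
  expect_true(one_of(vr, " vd , vr "))
  expect_false(one_of(vr, "d,r"))
  cp <- shot_with_tags("cp")
  expect_true(one_of(cp, "d,r,ad,ar,pld,plr,spd,spr,bpd,bpr,dpa,dpc,dpag,cp,cpld,cplr"))

  # like(x, a b) == like(x, a) AND like(x, b) when "a b" is not an alias
  for (pair in list(c("vd", "lob"), c("serve", "winning"), c("d", "vr"))) {
    y <- shot_with_tags(sample(c("vd", "lob", "serve", "d"), 2))
    q <- paste(pair, collapse = " ")
    expect_equal(like(y, q), like(y, pair[1]) && like(y, pair[2]), info = q)
  }

  # degenerate queries error; absent items are simply false
  expect_error(like(vd, ""), "non-empty")
  expect_error(one_of(vd, "  "), "non-empty")
  expect_false(like(absent, "serve"))
  expect_false(one_of(absent, "vd,vr"))
})

test_that("auto tags cover type, serve, lob, hitter and winning shots", {
  fx <- make_fixture_tables()
  m <- suppressWarnings(assemble_match(fx$points, fx$shots, fx$frames))
  shots <- padelquery:::collect_units(m, "shot")
  expect_true(like(shots[[1]], "serve"))
  # Table row 2: BR, D, Lob = T
  expect_true(like(shots[[2]], "d"))
  expect_true(like(shots[[2]], "lob"))
  expect_true(like(shots[[2]], "by-salazar"))
  # "winning": the bottom team took this point, so Salazar's shots carry it
  won <- vapply(shots, like, logical(1), query = "winning")
  expect_equal(won, c(FALSE, TRUE, FALSE, TRUE, FALSE))

  # brute-force count over a synthetic match
  tb <- sweep_bundle(1)
  st <- oracle_shot_table(tb$bundle)
  tagged <- sum(vapply(padelquery:::collect_units(tb$match, "shot"),
                       like, logical(1), query = "winning"))
  expect_equal(tagged, sum(st$won))
})

test_that("tag rules apply idempotently and match a scan oracle", {
  tb <- sweep_bundle(2)
  m <- tb$match
  # the attack-volley concept: a volley struck within 1.5 m of the net
  rule <- tag_rule("attack_volley", "shot",
                   'shot.one_of("vd,vr") and shot.hitter.distance_to_net < 1.5')
  n1 <- apply_tags(m, rule)
  st <- oracle_shot_table(tb$bundle)
  expect_equal(n1, sum(st$shot_code %in% c("vd", "vr") & st$dist_net < 1.5))
  tagged <- Filter(function(s) like(s, "attack_volley"),
                   padelquery:::collect_units(m, "shot"))
  expect_equal(sort(vapply(tagged, function(s) s$start_frame, numeric(1))),
               sort(st$frame[st$shot_code %in% c("vd", "vr") &
                               st$dist_net < 1.5]))

  # idempotence: applying twice changes nothing
  before <- lapply(padelquery:::collect_units(m, "shot"), function(s) s$tags)
  n2 <- apply_tags(m, rule)
  after <- lapply(padelquery:::collect_units(m, "shot"), function(s) s$tags)
  expect_equal(n2, n1)
  expect_identical(before, after)

  # constant-false predicate tags nothing; function predicates work too
  expect_equal(apply_tags(m, tag_rule("never", "shot", function(s) FALSE)), 0)
  n3 <- apply_tags(m, tag_rule("volley_fn", "shot",
                               function(s) one_of(s, "vd,vr")))
  expect_equal(n3, sum(st$shot_code %in% c("vd", "vr")))

  # queries can use the new concept at once
  r <- run_query(m, query_def("volleys", "shot", 'shot.like("volley_fn")'))
  expect_equal(nrow(r), n3)

  # a raising predicate names the item
  expect_error(
    apply_tags(m, tag_rule("boom", "shot", function(s) stop("nope"))),
    "boom")
})

test_that("tag sets grow monotonically under rule application", {
  tb <- sweep_bundle(4)
  m <- tb$match
  shots <- padelquery:::collect_units(m, "shot")
  before <- lapply(shots, function(s) s$tags)
  apply_tags(m, tag_rule("deep", "shot", "hitter.distance_to_backwall < 3"))
  after <- lapply(shots, function(s) s$tags)
  for (i in seq_along(shots)) {
    expect_true(all(before[[i]] %in% after[[i]]))
  }
})
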