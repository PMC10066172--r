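test_that("on-spot predicate uses the closed 3 cm disc", {
  rec <- make_rec(c(0, 3.0, 3.01, -2, 10), rep(0, 5))
  expect_equal(on_spot_mask(rec), c(TRUE, TRUE, FALSE, TRUE, FALSE))
})

test_that("stay detection honours threshold, gap bridging and counting", {
  fps <- 30; dt <- 1 / fps
  t150 <- (0:149) * dt
  s <- detect_stays(rep(TRUE, 150), t150)            # exactly 5.0 s
  expect_equal(nrow(s), 1)
  expect_equal(s$duration_s, 5.0)

  t147 <- (0:146) * dt                               # 4.9 s: too short
  s2 <- detect_stays(rep(TRUE, 147), t147)
  expect_equal(nrow(s2), 0)
  expect_equal(attr(s2, "n_short_visits"), 1L)

  mask <- c(rep(TRUE, 100), rep(FALSE, 3), rep(TRUE, 100))
  s3 <- detect_stays(mask, (0:202) * dt)             # 0.1 s gap bridged
  expect_equal(nrow(s3), 1)
  expect_equal(s3$duration_s, 203 * dt, tolerance = 1e-9)

  mask4 <- c(rep(TRUE, 100), rep(FALSE, 30), rep(TRUE, 100))
  s4 <- detect_stays(mask4, (0:229) * dt)            # 1 s gap: two visits
  expect_equal(nrow(s4), 0)
  expect_equal(attr(s4, "n_short_visits"), 2L)
})

test_that("latency is the first on-spot time, censored at trial end", {
  fps <- 30
  on_spot <- make_rec(rep(0, 60), rep(0, 60))
  expect_equal(latency_first_arrival(on_spot)$latency_s, 0)

  x <- c(rep(10, 900), rep(0, 60))
  rec <- make_rec(x, rep(0, length(x)))
  lat <- latency_first_arrival(rec)
  expect_equal(lat$latency_s, 30.0)
  expect_false(lat$censored)

  never <- make_rec(rep(10, 9000), rep(0, 9000))
  lat2 <- latency_first_arrival(never)
  expect_equal(lat2$latency_s, 300)
  expect_true(lat2$censored)
})

test_that("movement metrics match closed-form constructions", {
  fps <- 30
  still <- make_rec(rep(10, 9000), rep(0, 9000))
  m <- movement_metrics(still)
  expect_equal(m$distance_cm, 0)
  expect_equal(m$rest_s, 300)
  expect_equal(m$prop_on_spot, 0)

  # circling 1 cm inside the wall: all wall-following, speed r*omega
  tt <- (0:8999) / fps
  om <- 2 * pi / 60
  circ <- make_rec(14 * cos(om * tt), 14 * sin(om * tt))
  m2 <- movement_metrics(circ)
  expect_equal(m2$wall_follow_s, 300)
  expect_equal(m2$rest_s, 0)
  expect_equal(m2$distance_cm, 14 * om * 300, tolerance = 1e-3)

  # ten 5-cm hops sum to 50 cm of path
  hops <- make_rec(cumsum(c(0, rep(5, 10))), rep(0, 11), fps = 1,
                   trial_s = 300)
  expect_equal(movement_metrics(hops)$distance_cm, 50)
  # path length always >= straight-line displacement
  expect_gte(m2$distance_cm, 0)
})

test_that("metrics invariants hold on generated trials", {
  set.seed(21)
  arena <- build_arena("triangle")
  g <- gen_strategy_path("arch_ventures", arena, 20, 30)
  rec <- trial_recording(g$trajectory, arena, trial_s = 300)
  mask <- on_spot_mask(rec)
  stays <- detect_stays(mask, rec$trajectory$t)
  dt <- frame_interval(rec$trajectory)
  expect_lte(sum(stays$duration_s), sum(mask) * dt + 1e-9)
  if (nrow(stays) > 0) {
    lat <- latency_first_arrival(rec)
    expect_lte(lat$latency_s, stays$start_s[1] + 1e-9)
  }
})

test_that("occupancy maps are normalized, masked and validated", {
  still <- make_rec(rep(5, 100), rep(5, 100))
  occ <- occupancy_map(list(still))
  expect_equal(max(occ$grid, na.rm = TRUE), 1)
  expect_equal(sum(occ$grid, na.rm = TRUE), 1)

  set.seed(14)
  arena <- build_arena("square")
  pts <- runif_in_arena(arena, 20000)
  tr <- trajectory((0:19999) / 100, pts[, 1], pts[, 2], fps = 100)
  rec <- trial_recording(tr, arena, trial_s = 300)
  occ2 <- occupancy_map(list(rec), bin_cm = 9)       # 3 x 3 interior cells
  expect_equal(sum(occ2$grid, na.rm = TRUE), 1, tolerance = 1e-9)
  inner <- occ2$grid[!is.na(occ2$grid) & occ2$grid > 0]
  p0 <- 81 / 729                                     # uniform cell mass
  sigma <- sqrt(p0 * (1 - p0) / 20000)
  expect_true(all(abs(inner - p0) < 4 * sigma | inner < p0))

  expect_error(occupancy_map(list()), "at least one")
  other <- make_rec(rep(0, 10), rep(0, 10), arena = build_arena("triangle"))
  expect_error(occupancy_map(list(still, other)), "share")
})
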