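test_that("trajectory constructor validates its contract", {
  expect_error(trajectory(c(0, 1), c(0, 1, 2), c(0, 1, 2)), "equal lengths")
  expect_error(trajectory(c(0, 1, 1), 1:3, 1:3), "increasing")
  expect_error(trajectory(c(0, 1, 2), c(0, NA, 2), 1:3), "finite")
  tr <- trajectory(0:2 / 30, 1:3, 1:3, fps = 30)
  expect_s3_class(tr, "trajectory")
  expect_equal(frame_interval(tr), 1 / 30)
})

test_that("align_to_spot is a pure translation preserving all distances", {
  set.seed(3)
  tr <- trajectory(0:99 / 30, stats::rnorm(100), stats::rnorm(100))
  al <- align_to_spot(tr, c(5, 5))
  expect_equal(al$x, tr$x - 5)
  # applying with a zero center is the identity
  expect_equal(align_to_spot(tr, c(0, 0)), tr)
  d0 <- stats::dist(cbind(tr$x, tr$y))
  d1 <- stats::dist(cbind(al$x, al$y))
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-12)
})

test_that("speed series matches closed forms", {
  n <- 90
  still <- trajectory((0:(n - 1)) / 30, rep(2, n), rep(-1, n))
  expect_equal(speed_series(still), rep(0, n))
  uni <- trajectory((0:(n - 1)) / 30, 2 * (0:(n - 1)) / 30, rep(0, n))
  expect_equal(speed_series(uni), rep(2, n), tolerance = 1e-9)
  # circular motion: speed ~ r * omega (central differences)
  r <- 5; om <- 1.3
  tt <- (0:(n - 1)) / 30
  circ <- trajectory(tt, r * cos(om * tt), r * sin(om * tt))
  expect_equal(speed_series(circ)[2:(n - 1)], rep(r * om, n - 2),
               tolerance = 1e-3)
  expect_error(speed_series(trajectory(0, 1, 1)), "2 frames")
})

test_that("tracking tables round-trip bit-identically", {
  arena <- build_arena("circle")
  set.seed(9)
  g <- gen_strategy_path("spiral_inward", arena, 3, 30)
  rec <- trial_recording(g$trajectory, arena)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_tracking_table(rec, f1)
  back <- read_tracking_table(f1, arena)
  write_tracking_table(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(back$trajectory$x, rec$trajectory$x, tolerance = 1e-6)
})

test_that("a calibrated file is mapped into the canonical cm frame", {
  arena <- build_arena("square")
  set.seed(10)
  g <- gen_strategy_path("wall_then_direct", arena, 3, 30)
  rec <- trial_recording(g$trajectory, arena)
  cal <- structure(list(scale = 0.1, rotation = 0.2, flip = TRUE,
                        translation = c(-20, -18), rms_residual = 0),
                   class = "calibration")
  f <- tempfile(fileext = ".csv")
  write_tracking_table(rec, f, calibration = cal)
  back <- read_tracking_table(f, arena)   # must auto-calibrate
  expect_equal(back$trajectory$x, rec$trajectory$x, tolerance = 1e-6)
  expect_equal(back$trajectory$y, rec$trajectory$y, tolerance = 1e-6)
})

test_that("the 3-column pre-calibrated dialect is accepted", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("time_s,x_cm,y_cm", "0,1,2", "0.033,1.5,2.5", "0.067,2,3"), f)
  rec <- read_tracking_table(f, build_arena("circle"))
  expect_equal(rec$trajectory$x, c(1, 1.5, 2))
  writeLines(c("bogus,header", "1,2"), f)
  expect_error(read_tracking_table(f, build_arena("circle")), "header")
})

test_that("gap handling follows the 0.5 s interpolation rule", {
  arena <- build_arena("circle")
  n <- 300; fps <- 30
  t <- (0:(n - 1)) / fps
  x <- seq(-10, 10, length.out = n); y <- rep(0, n)
  base <- data.frame(time_s = t, x_cm = x, y_cm = y)
  f <- tempfile(fileext = ".csv")

  short_gap <- base; short_gap$x_cm[100:102] <- NA  # 0.1 s gap
  utils::write.csv(short_gap, f, row.names = FALSE, quote = FALSE)
  rec <- read_tracking_table(f, arena)
  expect_equal(nrow(rec$trajectory), n)
  expect_equal(rec$trajectory$x[101], x[101], tolerance = 1e-9)  # linear fill

  long_gap <- base; long_gap$x_cm[101:160] <- NA    # 2 s > 0.5 s
  utils::write.csv(long_gap, f, row.names = FALSE, quote = FALSE)
  expect_warning(rec2 <- read_tracking_table(f, arena), "longest")
  expect_equal(nrow(rec2$trajectory), n - 160)      # rows 161..300 kept

  bad <- base; bad$x_cm[1:90] <- NA                 # 30% missing
  utils::write.csv(bad, f, row.names = FALSE, quote = FALSE)
  expect_error(read_tracking_table(f, arena), "quality|missing")
})

test_that("trial recordings enforce index and duration bounds", {
  tr <- trajectory(0:89 / 30, rep(0, 90), rep(0, 90))
  expect_error(trial_recording(tr, build_arena("circle"), trial_index = 11),
               "1..10")
  long <- trajectory(seq(0, 330, by = 1 / 30), numeric(9901), numeric(9901))
  expect_error(trial_recording(long, build_arena("circle")), "duration")
})
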