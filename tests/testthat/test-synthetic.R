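test_that("every archetype stays inside every arena", {
  for (shape in c("circle", "square", "triangle", "quadrilateral")) {
    arena <- build_arena(shape)
    for (arch in archetype_names) {
      g <- gen_strategy_path(arch, arena, 3, 30, seed = 5)
      expect_true(all(arena_contains(arena,
                                     cbind(g$trajectory$x, g$trajectory$y))),
                  info = paste(shape, arch))
    }
  }
})

test_that("archetype construction properties hold", {
  arena <- build_arena("circle")
  # wall-then-direct: hugs the wall, then rises to near the center
  g <- gen_strategy_path("wall_then_direct", arena, 3, 30, seed = 2)
  w <- distance_to_perimeter(arena, cbind(g$trajectory$x, g$trajectory$y))
  n <- length(w)
  expect_lt(max(w[1:round(0.6 * n)]), 3)         # wall band early
  expect_gt(w[n], 13)                            # ends near the center
  expect_gt(stats::cor(seq_len(n)[round(0.7 * n):n], w[round(0.7 * n):n]),
            0.95)                                # final rise
  # center-out-return: first and last frames on the spot
  g2 <- gen_strategy_path("center_out_return", arena, 3, 30, seed = 2)
  d <- sqrt(g2$trajectory$x^2 + g2$trajectory$y^2)
  expect_lte(d[1], 3); expect_lte(d[length(d)], 3)
  expect_gt(max(d), 8)                           # genuine excursion
})

test_that("generation is deterministic given the seed", {
  arena <- build_arena("triangle")
  a <- gen_strategy_path("spiral_inward", arena, 3, 30, seed = 42)
  b <- gen_strategy_path("spiral_inward", arena, 3, 30, seed = 42)
  expect_identical(a, b)
  d1 <- tempfile(); d2 <- tempfile()
  cfg <- session_config(n_animals = 2, n_trials = 2, trial_s = 60,
                        fps = 10, seed = 9)
  gen_session(cfg, d1); gen_session(cfg, d2)
  f1 <- list.files(d1, recursive = TRUE, full.names = TRUE)
  f2 <- list.files(d2, recursive = TRUE, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  for (i in seq_along(f1)) expect_identical(readLines(f1[i]),
                                            readLines(f2[i]))
})

test_that("sessions have the configured layout and truth record", {
  dir <- tempfile()
  cfg <- session_config(shape = "square", n_animals = 3, n_trials = 4,
                        trial_s = 90, fps = 10, seed = 3)
  truth <- gen_session(cfg, dir)
  files <- list.files(file.path(dir, "square"), recursive = TRUE,
                      pattern = "^trial_.*csv$")
  expect_equal(length(files), 3 * 4)             # n_animals x n_trials
  expect_equal(length(truth$trials), 12)
  expect_true(file.exists(file.path(dir, "square", "truth.json")))
  expect_equal(truth$seed, 3)
  archs <- unlist(lapply(truth$trials, `[[`, "archetypes"))
  expect_true(all(archs %in% archetype_names))
})

test_that("control sessions without a cool spot yield no successful stays", {
  dir <- tempfile()
  cfg <- session_config(n_animals = 2, n_trials = 2, trial_s = 120,
                        fps = 10, condition = "unheated", seed = 13)
  gen_session(cfg, dir)
  recs <- load_session(dir, fps = 10, trial_s = 120)
  expect_equal(unique(vapply(recs, `[[`, "", "condition")), "unheated")
  stays <- vapply(recs, function(r)
    nrow(detect_stays(on_spot_mask(r), r$trajectory$t)), 0L)
  expect_true(all(stays == 0))
})

test_that("metrics-level sessions carry the configured trends", {
  m <- gen_metrics_session(seed = 1, noise_sd = 1e-6, animal_sd = 0,
                           animal_slope_sd = 0)
  est <- estimate_learning_slope(m, "prop_on_spot", "sqrt", n_boot = 0)
  expect_equal(est$slope, 0.026, tolerance = 1e-3)
  estl <- estimate_learning_slope(m, "latency_s", "log", n_boot = 0)
  expect_equal(estl$slope, -0.185, tolerance = 1e-3)
  expect_equal(nrow(m), 150)
})

test_that("cluster benchmark is balanced and labeled", {
  b <- gen_cluster_benchmark(3, seed = 2)
  expect_equal(length(b$paths), 12)
  expect_equal(as.numeric(table(b$labels)), rep(3, 4))
  expect_s3_class(b$paths[[1]], "approach_path")
})
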