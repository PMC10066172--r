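test_that("the four canonical arenas have the printed geometry", {
  circ <- build_arena("circle")
  expect_equal(circ$boundary$radius, 15)
  expect_equal(arena_area(circ), pi * 15^2)

  sq <- build_arena("square")
  expect_equal(arena_area(sq), 729)
  expect_equal(arena_centroid(sq), c(0, 0))

  tri <- build_arena("triangle")
  expect_equal(arena_area(tri), sqrt(3) / 4 * 40^2)

  quad <- build_arena("quadrilateral")
  expect_equal(arena_area(quad), 709.0, tolerance = 1e-3)
  # all four within the 3% design band around 709 cm^2
  for (s in c("circle", "square", "triangle", "quadrilateral")) {
    a <- arena_area(build_arena(s))
    expect_gte(a, 709 * 0.97)
    expect_lte(a, 709 * 1.03)
  }
})

test_that("quadrilateral walk closes and puts the spot at the area centroid", {
  quad <- build_arena("quadrilateral")
  v <- quad$boundary
  expect_equal(nrow(v), 4)
  # walked edges keep their printed lengths; the closing edge absorbs the
  # sub-centimetre closure residual of the printed (rounded) dimensions
  lens <- sqrt(rowSums((v[c(2, 3, 4, 1), ] - v)^2))
  expect_equal(lens[1:3], c(37, 24, 23), tolerance = 1e-12)
  expect_lt(abs(lens[4] - 26), 1)
  # spot sits at the shoelace area centroid, i.e. the origin after centering
  expect_equal(polygonal_centroid <- arena_centroid(quad, "area"), c(0, 0),
               tolerance = 1e-12)
  # vertex-average centroid differs for this irregular shape
  expect_gt(sqrt(sum(arena_centroid(quad, "vertex")^2)), 0.1)
  # impossible angles fail to close
  expect_error(build_arena(shape_spec("quadrilateral",
                                      angles = c(100, 100, 100, 60))),
               "close")
})

test_that("angle sum and edge positivity are enforced", {
  expect_error(shape_spec("quadrilateral", angles = c(90, 90, 90, 91)),
               "360")
  expect_error(shape_spec("circle", dimensions = -3), "positive")
})

test_that("distance_to_perimeter matches closed forms", {
  circ <- build_arena("circle")
  expect_equal(distance_to_perimeter(circ, c(10, 0)), 5)
  expect_equal(distance_to_perimeter(circ, c(20, 0)), 5)  # exterior magnitude
  expect_equal(distance_to_perimeter(build_arena("square"), c(0, 0)), 13.5)
  expect_equal(distance_to_perimeter(build_arena("triangle"), c(0, 0)),
               40 / (2 * sqrt(3)))
  # boundary point maps to zero
  expect_equal(distance_to_perimeter(circ, c(15, 0)), 0)
  expect_error(distance_to_perimeter(circ, c(NA, 0)), "finite")
})

test_that("circle distance equals |R - r| on random points", {
  set.seed(42)
  circ <- build_arena("circle")
  p <- cbind(stats::runif(1000, -20, 20), stats::runif(1000, -20, 20))
  expect_equal(distance_to_perimeter(circ, p),
               abs(15 - sqrt(rowSums(p^2))), tolerance = 1e-9)
})

test_that("polygon distance agrees with a dense boundary-sampling oracle", {
  set.seed(7)
  for (shape in c("square", "triangle", "quadrilateral")) {
    arena <- build_arena(shape)
    p <- cbind(stats::runif(50, -25, 25), stats::runif(50, -25, 25))
    got <- distance_to_perimeter(arena, p)
    want <- vapply(seq_len(nrow(p)), function(i)
      poly_dist_oracle(arena$boundary, p[i, ]), 0.0)
    expect_equal(got, want, tolerance = 1e-3)
  }
})

test_that("containment is closed and degenerate polygons have zero area", {
  circ <- build_arena("circle")
  expect_true(arena_contains(circ, c(14.9, 0)))
  expect_false(arena_contains(circ, c(15.1, 0)))
  sq <- build_arena("square")
  expect_true(arena_contains(sq, sq$boundary[1, ]))   # vertex counts inside
  degen <- structure(list(shape_kind = "triangle",
                          boundary = rbind(c(0, 0), c(1, 1), c(2, 2)),
                          spot_center = c(0, 0), spot_radius = 1),
                     class = "arena")
  expect_equal(arena_area(degen), 0)
})

test_that("area validation rejects out-of-band constructions", {
  expect_error(build_arena(shape_spec("circle", dimensions = 40)),
               "area")
  expect_silent(build_arena(shape_spec("circle", dimensions = 40),
                            validate_area = FALSE))
})
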