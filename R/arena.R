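#' Arena shape specifications
#'
#' Printed dimensions of the four canonical arenas used in the heated-arena
#' center-finding paradigm. All four enclosures were built to approximately
#' the same floor area (709 cm^2, within 3%): a circle of diameter 30 cm, a
#' square of edge 27 cm, an equilateral triangle of edge 40 cm, and an
#' asymmetric quadrilateral with edges 37, 24, 23, 26 cm and interior angles
#' 67, 80, 100, 113 degrees.
#'
#' @param shape_kind one of `"circle"`, `"square"`, `"triangle"`,
#'   `"quadrilateral"`.
#' @param dimensions optional numeric vector overriding the printed edge
#'   lengths (circle: diameter; square/triangle: edge; quadrilateral: the
#'   four edges in walking order).
#' @param angles interior angles in degrees, quadrilateral only.
#' @return an object of class `shape_spec`.
#' @export
shape_spec <- function(shape_kind = c("circle", "square", "triangle", "quadrilateral"),
                       dimensions = NULL, angles = NULL) {
  shape_kind <- match.arg(shape_kind)
  defaults <- list(
    circle        = list(dimensions = 30, angles = NULL),
    square        = list(dimensions = 27, angles = NULL),
    triangle      = list(dimensions = 40, angles = NULL),
    quadrilateral = list(dimensions = c(37, 24, 23, 26),
                         angles = c(67, 80, 100, 113))
  )[[shape_kind]]
  if (is.null(dimensions)) dimensions <- defaults$dimensions
  if (is.null(angles)) angles <- defaults$angles
  if (any(dimensions <= 0)) stop("all edge lengths must be strictly positive")
  if (shape_kind == "quadrilateral") {
    if (length(dimensions) != 4L || length(angles) != 4L)
      stop("quadrilateral needs 4 edges and 4 interior angles")
    if (abs(sum(angles) - 360) > 1e-9)
      stop("quadrilateral interior angles must sum to 360 degrees")
  }
  structure(list(shape_kind = shape_kind, dimensions = dimensions,
                 angles = angles, design_area = 709, area_tolerance = 0.03),
            class = "shape_spec")
}

#' Construct a canonical arena
#'
#' Builds the arena in canonical coordinates: centimetres, x to the right,
#' y up, with the cool spot at the origin. The cool spot sits at the centre
#' of symmetry for the circle, square and triangle, and at the area centroid
#' for the quadrilateral. Polygon arenas are constructed by walking the
#' printed edge lengths with the printed interior angles, counter-clockwise;
#' the walk must close within `closure_tol` and the resulting area must lie
#' within the spec's 3% band around 709 cm^2.
#'
#' @param spec a [shape_spec()], or a shape name passed through to it.
#' @param spot_radius cool-spot radius in cm (default 3.0, from the 60 mm
#'   diameter cooling block).
#' @param closure_tol polygon closure tolerance in cm; printed dimensions are
#'   rounded to whole cm/degrees so exact closure is not expected.
#' @param validate_area if `TRUE` (default), error when the computed area
#'   falls outside `design_area * (1 +/- area_tolerance)`.
#' @return an object of class `arena`: a list with `shape_kind`, `boundary`
#'   (for the circle a list with `center` and `radius`; otherwise a CCW
#'   vertex matrix), `spot_center = c(0, 0)` and `spot_radius`.
#' @export
build_arena <- function(spec = "circle", spot_radius = 3.0, closure_tol = 1.0,
                        validate_area = TRUE) {
  if (is.character(spec)) spec <- shape_spec(spec)
  stopifnot(inherits(spec, "shape_spec"))
  kind <- spec$shape_kind
  if (kind == "circle") {
    r <- spec$dimensions[1] / 2
    arena <- structure(list(shape_kind = kind,
                            boundary = list(center = c(0, 0), radius = r),
                            spot_center = c(0, 0), spot_radius = spot_radius),
                       class = "arena")
  } else {
    verts <- switch(kind,
      square = {
        a <- spec$dimensions[1]
        rbind(c(0, 0), c(a, 0), c(a, a), c(0, a))
      },
      triangle = {
        a <- spec$dimensions[1]
        rbind(c(0, 0), c(a, 0), c(a / 2, a * sqrt(3) / 2))
      },
      quadrilateral = walk_polygon(spec$dimensions, spec$angles, closure_tol)
    )
    ctr <- if (kind == "quadrilateral") polygon_centroid(verts) else
      colMeans(verts)
    verts <- sweep(verts, 2, ctr)
    arena <- structure(list(shape_kind = kind, boundary = verts,
                            spot_center = c(0, 0), spot_radius = spot_radius),
                       class = "arena")
  }
  if (validate_area) {
    a <- arena_area(arena)
    lim <- spec$design_area * c(1 - spec$area_tolerance, 1 + spec$area_tolerance)
    if (a < lim[1] || a > lim[2])
      stop(sprintf("arena area %.2f cm^2 outside %.1f%% band around %g cm^2",
                   a, 100 * spec$area_tolerance, spec$design_area))
  }
  if (distance_to_perimeter(arena, arena$spot_center) <= arena$spot_radius)
    stop("cool spot does not lie strictly inside the arena boundary")
  arena
}

# Walk edges in printed order with the printed interior angles at successive
# vertices (first angle at the vertex joining the last and first edge).
# CCW: exterior turn at each vertex is 180 - interior angle, to the left.
walk_polygon <- function(edges, angles, closure_tol) {
  n <- length(edges)
  verts <- matrix(0, n, 2)
  heading <- 0
  p <- c(0, 0)
  for (i in seq_len(n)) {
    verts[i, ] <- p
    p <- p + edges[i] * c(cos(heading), sin(heading))
    ang_next <- angles[if (i < n) i + 1L else 1L]
    heading <- heading + (180 - ang_next) * pi / 180
  }
  resid <- sqrt(sum((p - verts[1, ])^2))
  if (resid > closure_tol)
    stop(sprintf("polygon fails to close: residual %.3f cm > %.3f cm tolerance",
                 resid, closure_tol))
  if (polygon_area_signed(verts) < 0) verts <- verts[rev(seq_len(n)), ]
  verts
}

polygon_area_signed <- function(v) {
  j <- c(seq_len(nrow(v))[-1], 1L)
  sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]) / 2
}

polygon_centroid <- function(v) {
  j <- c(seq_len(nrow(v))[-1], 1L)
  cross <- v[, 1] * v[j, 2] - v[j, 1] * v[, 2]
  a <- sum(cross) / 2
  if (abs(a) < 1e-12) return(colMeans(v))
  c(sum((v[, 1] + v[j, 1]) * cross), sum((v[, 2] + v[j, 2]) * cross)) / (6 * a)
}

#' Arena floor area
#'
#' `pi * r^2` for the circle, shoelace sum for polygon arenas.
#' @param arena an [build_arena()] object.
#' @return area in cm^2 (non-negative).
#' @export
arena_area <- function(arena) {
  stopifnot(inherits(arena, "arena"))
  if (arena$shape_kind == "circle") pi * arena$boundary$radius^2
  else abs(polygon_area_signed(arena$boundary))
}

#' Arena centroid
#'
#' Centre of symmetry for circle/square/triangle; shoelace-weighted area
#' centroid for general polygons. `method = "vertex"` returns the plain
#' vertex average instead (the two differ for irregular quadrilaterals).
#' @param arena an arena.
#' @param method `"area"` (default) or `"vertex"`.
#' @return a length-2 point in cm.
#' @export
arena_centroid <- function(arena, method = c("area", "vertex")) {
  method <- match.arg(method)
  if (arena$shape_kind == "circle") return(arena$boundary$center)
  if (method == "vertex") colMeans(arena$boundary)
  else polygon_centroid(arena$boundary)
}

as_point_matrix <- function(p) {
  if (is.matrix(p)) p else matrix(p, ncol = 2, byrow = length(p) > 2)
}

#' Minimum distance to the arena perimeter
#'
#' Per-point minimum Euclidean (Cartesian) distance from a position to the
#' arena boundary curve, the quantity used to featurize approach paths. The
#' magnitude is returned for interior and exterior points alike; points on
#' the boundary map to 0.
#'
#' @param arena an arena.
#' @param p a length-2 point or an n x 2 matrix of points, cm.
#' @return numeric vector of distances, cm.
#' @export
distance_to_perimeter <- function(arena, p) {
  p <- as_point_matrix(p)
  if (any(!is.finite(p))) stop("points must be finite")
  if (arena$shape_kind == "circle") {
    ctr <- arena$boundary$center
    abs(arena$boundary$radius -
          sqrt((p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2))
  } else {
    v <- arena$boundary
    j <- c(seq_len(nrow(v))[-1], 1L)
    d <- rep(Inf, nrow(p))
    for (e in seq_len(nrow(v))) {
      d <- pmin(d, point_segment_distance(p, v[e, ], v[j[e], ]))
    }
    d
  }
}

# Vectorized point-to-segment distance (p: n x 2, a/b: length-2 endpoints).
point_segment_distance <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt((p[, 1] - a[1])^2 + (p[, 2] - a[2])^2))
  t <- ((p[, 1] - a[1]) * ab[1] + (p[, 2] - a[2]) * ab[2]) / len2
  t <- pmin(1, pmax(0, t))
  qx <- a[1] + t * ab[1]
  qy <- a[2] + t * ab[2]
  sqrt((p[, 1] - qx)^2 + (p[, 2] - qy)^2)
}

#' Point-in-arena test
#'
#' Containment is closed: boundary points count as inside (the insects touch
#' the walls constantly, so an open convention would misclassify genuine
#' wall-following frames).
#'
#' @param arena an arena.
#' @param p a length-2 point or an n x 2 matrix.
#' @param tol boundary tolerance in cm.
#' @return logical vector.
#' @export
arena_contains <- function(arena, p, tol = 1e-9) {
  p <- as_point_matrix(p)
  if (any(!is.finite(p))) stop("points must be finite")
  if (arena$shape_kind == "circle") {
    ctr <- arena$boundary$center
    sqrt((p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2) <=
      arena$boundary$radius + tol
  } else {
    inside <- point_in_polygon(p, arena$boundary)
    inside | distance_to_perimeter(arena, p) <= tol
  }
}

# Even-odd ray casting, vectorized over points.
point_in_polygon <- function(p, v) {
  n <- nrow(v)
  j <- c(n, seq_len(n - 1L))
  inside <- rep(FALSE, nrow(p))
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]
    xj <- v[j[i], 1]; yj <- v[j[i], 2]
    crosses <- ((yi > p[, 2]) != (yj > p[, 2])) &
      (p[, 1] < (xj - xi) * (p[, 2] - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
  }
  inside
}

#' Canonical calibration landmarks of an arena
#'
#' The four tracked landmark points in canonical coordinates: the polygon
#' corners, or for the circle the four furthermost perimeter points at the
#' ends of two perpendicular diameters. The quadrilateral's four corners are
#' its vertices; for the triangle only three corners exist, so the triangle
#' uses its vertices plus the midpoint of the first edge as a fourth tracked
#' point.
#'
#' @param arena an arena.
#' @return a 4 x 2 matrix, cm.
#' @export
arena_landmarks <- function(arena) {
  if (arena$shape_kind == "circle") {
    r <- arena$boundary$radius
    ctr <- arena$boundary$center
    sweep(rbind(c(r, 0), c(0, r), c(-r, 0), c(0, -r)), 2, ctr, "+")
  } else if (arena$shape_kind == "triangle") {
    v <- arena$boundary
    rbind(v, (v[1, ] + v[2, ]) / 2)
  } else {
    arena$boundary
  }
}
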