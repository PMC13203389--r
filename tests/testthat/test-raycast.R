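test_that("ray-plane intersection solves the plane equation", {
  r <- ray(c(0, 0, 0), c(0, 0, 1))
  expect_equal(ray_plane_t(r, c(0, 0, 5), c(0, 0, 1)), 5)
  # in-plane direction: no intersection
  expect_true(is.na(ray_plane_t(ray(c(0, 0, 0), c(1, 0, 0)), c(0, 0, 5),
                                c(0, 0, 1))))
  # behind the origin
  expect_true(is.na(ray_plane_t(r, c(0, 0, -5), c(0, 0, 1))))
  # oblique ray vs tilted plane: agree with a bisection oracle on the
  # signed distance along the ray
  set.seed(8)
  for (i in 1:20) {
    o <- rnorm(3); d <- rnorm(3); d <- d / sqrt(sum(d^2))
    n <- rnorm(3); n <- n / sqrt(sum(n^2)); p0 <- rnorm(3, sd = 5)
    t_pkg <- ray_plane_t(ray(o, d), p0, n)
    sdist <- function(t) sum(n * (o + t * d - p0))
    if (!is.na(t_pkg)) {
      lo <- 0; hi <- 2 * t_pkg + 1
      if (sign(sdist(lo)) != sign(sdist(hi))) {
        for (it in 1:80) {
          mid <- (lo + hi) / 2
          if (sign(sdist(mid)) == sign(sdist(lo))) lo <- mid else hi <- mid
        }
        expect_equal(t_pkg, (lo + hi) / 2, tolerance = 1e-9)
      }
    }
  }
})

test_that("same-side point-in-triangle agrees with the barycentric oracle", {
  A <- c(0, 0, 0); B <- c(4, 0, 0); C <- c(0, 3, 0)
  expect_true(point_in_triangle((A + B + C) / 3, A, B, C))
  expect_false(point_in_triangle(c(5, 5, 0), A, B, C))
  expect_true(point_in_triangle(c(2, 0, 0), A, B, C))   # edge contact
  expect_true(point_in_triangle(B, A, B, C))            # vertex contact
  expect_error(point_in_triangle(c(1, 1, 0), c(0, 0, 0), c(1, 1, 0),
                                 c(2, 2, 0)), "degenerate")
  set.seed(9)
  mism <- 0L
  for (i in 1:2000) {
    tri <- matrix(rnorm(9, sd = 3), 3, byrow = TRUE)
    # coplanar query point via random barycentric-ish combination
    w <- rnorm(3); w <- w / sum(w)
    P <- colSums(tri * w)
    got <- point_in_triangle(P, tri[1, ], tri[2, ], tri[3, ])
    want <- bary_inside(P, tri[1, ], tri[2, ], tri[3, ])
    if (got != want) mism <- mism + 1L
  }
  expect_identical(mism, 0L)
})

test_that("ray-mesh intersections match analytic chords and merge edges", {
  sph <- make_ellipsoid_mesh(c(0, 0, 0), c(60, 60, 60), 4)
  r <- ray(c(-200, 0, 0), c(1, 0, 0))
  h <- ray_mesh_intersections(r, sph)
  expect_identical(nrow(h), 2L)
  expect_equal(h$t, c(140, 260), tolerance = 1e-2)
  expect_identical(h$entering, c(1L, 0L))  # alternating crossing flags
  expect_identical(nrow(ray_mesh_intersections(ray(c(-200, 100, 0), c(1, 0, 0)),
                                               sph)), 0L)
  # shared-edge crossing on a two-triangle square: one merged hit
  quad <- surface_mesh(rbind(c(-1, -1, 0), c(1, -1, 0), c(1, 1, 0),
                             c(-1, 1, 0)),
                       rbind(c(1, 2, 3), c(1, 3, 4)))
  hq <- ray_mesh_intersections(ray(c(0, 0, -5), c(0, 0, 1)), quad)
  expect_identical(nrow(hq), 1L)  # the diagonal crossing is merged
})

test_that("beam tracing partitions nested organs by priority", {
  tum <- make_ellipsoid_mesh(c(0, 0, 0), c(15, 15, 15), 3)
  lung <- make_ellipsoid_mesh(c(0, 0, 0), c(60, 60, 60), 3)
  body <- make_ellipsoid_mesh(c(0, 0, 0), c(150, 150, 150), 3)
  organs <- list(list(label = 1L, mesh = body, eta = 1, name = "body"),
                 list(label = 2L, mesh = lung, eta = 0.275, name = "lung"),
                 list(label = 3L, mesh = tum, eta = 1, name = "tumour"))
  r <- ray(c(-400, 0, 0), c(1, 0, 0))
  seg <- trace_beam(r, organs)
  expect_identical(seg$label, c(1L, 2L, 3L, 2L, 1L))
  expect_equal(seg$z, c(90, 45, 30, 45, 90), tolerance = 0.02)
  expect_equal(seg$zeff, seg$z * seg$eta)
  # all eta = 1: effective length equals geometric length
  organs1 <- lapply(organs, function(o) { o$eta <- 1; o })
  seg1 <- trace_beam(r, organs1)
  expect_equal(sum(seg1$zeff), sum(seg1$z))
  # miss: empty segment table
  expect_identical(nrow(trace_beam(ray(c(-400, 200, 0), c(1, 0, 0)), organs)),
                   0L)
  # open mesh (single triangle) raises the odd-crossing error by name
  open_organ <- list(list(label = 9L, name = "flap", eta = 1,
                          mesh = surface_mesh(rbind(c(-1, -1, 1), c(1, -1, 1),
                                                    c(0, 1, 1)),
                                              rbind(c(1, 2, 3)))))
  expect_error(trace_beam(ray(c(0, 0, -5), c(0, 0, 1)), open_organ), "flap")
})

test_that("segment lengths are invariant under joint rigid motion", {
  set.seed(10)
  tum <- make_ellipsoid_mesh(c(10, 0, 5), c(15, 12, 14), 3)
  body <- make_ellipsoid_mesh(c(0, 0, 0), c(80, 70, 90), 3)
  organs <- list(list(label = 1L, mesh = body, eta = 1),
                 list(label = 2L, mesh = tum, eta = 0.5))
  r <- ray(c(-300, 7, -3), c(1, 0.05, 0.02))
  seg0 <- trace_beam(r, organs)
  for (i in 1:3) {
    R <- random_rotation(); tr <- rnorm(3, sd = 50)
    organs_t <- lapply(organs, function(o) {
      o$mesh <- transform_mesh(o$mesh, R, tr); o
    })
    r_t <- ray(as.vector(R %*% r$origin) + tr, as.vector(R %*% r$direction))
    seg_t <- trace_beam(r_t, organs_t)
    expect_equal(seg_t$z, seg0$z, tolerance = 1e-6)
    expect_identical(seg_t$label, seg0$label)
  }
})

test_that("mesh chords converge to analytic circle chords with resolution", {
  R <- 50; b <- 30
  chord <- function(sub) {
    sph <- make_ellipsoid_mesh(c(0, 0, 0), c(R, R, R), sub)
    h <- ray_mesh_intersections(ray(c(-200, b, 0), c(1, 0, 0)), sph)
    diff(h$t)
  }
  truth <- 2 * sqrt(R^2 - b^2)
  errs <- abs(vapply(2:4, chord, numeric(1)) - truth)
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3] / truth, 0.01)
})
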