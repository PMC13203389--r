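test_that("farthest-point sampling matches greedy brute force", {
  # 4 corners of a square plus centre: after a corner start, FPS must pick
  # the remaining corners before the centre
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
               c(0.5, 0.5, 0))
  for (seed in 1:10) {
    idx <- farthest_point_sample(pts, 4, seed = seed)
    if (idx[1] <= 4) expect_setequal(idx, 1:4)
  }
  # m = 1 returns exactly the seeded first pick
  set.seed(5); first <- sample.int(5, 1)
  expect_identical(farthest_point_sample(pts, 1, seed = 5), first)
  # m = N returns every index
  expect_setequal(farthest_point_sample(pts, 5, seed = 2), 1:5)
  # random clouds agree with the brute-force greedy oracle
  set.seed(11)
  cloud <- matrix(rnorm(3 * 200), ncol = 3)
  idx <- farthest_point_sample(cloud, 40, seed = 11)
  expect_identical(idx, as.integer(brute_fps(cloud, 40, idx[1])))
  expect_error(farthest_point_sample(cloud, 201, seed = 1), "between")
})

test_that("label propagation votes among the k nearest sparse points", {
  set.seed(2)
  sparse <- labeled_cloud(matrix(rnorm(60), ncol = 3),
                          labels = rep(1L, 20))
  dense <- matrix(rnorm(30), ncol = 3)
  expect_true(all(propagate_labels(sparse, dense, k = 10) == 1L))
  # k = 1 is nearest-neighbour classification (brute-force distance oracle)
  sp2 <- labeled_cloud(matrix(rnorm(3 * 50, sd = 10), ncol = 3),
                       labels = sample(1:4, 50, replace = TRUE))
  dn2 <- matrix(rnorm(3 * 120, sd = 10), ncol = 3)
  got <- propagate_labels(sp2, dn2, k = 1)
  nn <- brute_knn(dn2, sp2$points, 1)
  expect_identical(got, sp2$labels[nn[, 1]])
  # 6-vs-4 split at equal distance: majority wins
  ring <- function(n, r, z) cbind(r * cos(2 * pi * seq_len(n) / n),
                                  r * sin(2 * pi * seq_len(n) / n), z)
  sp3 <- labeled_cloud(rbind(ring(6, 1, 0.5), ring(4, 1, -0.5)),
                       labels = c(rep(2L, 6), rep(3L, 4)))
  expect_identical(propagate_labels(sp3, rbind(c(0, 0, 0)), k = 10), 2L)
  expect_error(propagate_labels(labeled_cloud(matrix(0, 0, 3)), dn2), "empty")
})

test_that("statistical outlier removal flags isolated points only", {
  set.seed(3)
  blob <- matrix(rnorm(3 * 500), ncol = 3)
  cl <- labeled_cloud(rbind(blob, c(100, 100, 100)), labels = rep(1L, 501))
  res <- remove_outliers(cl, k = 30, sd_factor = 2)
  expect_true(501L %in% res$removed)          # the planted far point goes
  expect_lt(length(res$removed) / 501, 0.1)   # the blob mostly stays
  # infinite threshold removes nothing
  res_inf <- remove_outliers(cl, k = 30, sd_factor = Inf)
  expect_identical(length(res_inf$removed), 0L)
  # order invariance: permuting the cloud permutes the removed set
  perm <- sample(501)
  res_p <- remove_outliers(labeled_cloud(cl$points[perm, ],
                                         labels = cl$labels[perm]), 30, 2)
  expect_setequal(perm[res_p$removed], res$removed)
  expect_error(remove_outliers(labeled_cloud(blob[1:10, ], labels = rep(1L, 10)),
                               k = 30), "more than k")
})

test_that("voxelisation matches brute-force binning", {
  cl <- labeled_cloud(rbind(c(0.2, 0.3, 0.1)), labels = 1L)
  g <- voxelize(cl, 1L, spacing = c(1, 1, 1))
  expect_identical(sum(g$values), 1)
  cl2 <- labeled_cloud(rbind(c(0.2, 0.3, 0.1), c(0.3, 0.2, 0.2)), labels = c(1L, 1L))
  expect_identical(sum(voxelize(cl2, 1L, c(1, 1, 1))$values), 1)
  # 1000 sphere-interior points at 2 mm: occupancy equals independent binning
  set.seed(4)
  u <- matrix(rnorm(3000), ncol = 3); u <- u / sqrt(rowSums(u^2))
  pts <- u * 20 * runif(1000)^(1 / 3)
  cl3 <- labeled_cloud(pts, labels = rep(1L, 1000))
  g3 <- voxelize(cl3, 1L, spacing = c(2, 2, 2))
  key <- unique(floor(sweep(pts, 2, g3$origin) / 2 + 0.5))
  expect_equal(sum(g3$values), nrow(key))
  expect_error(voxelize(cl3, 9L, c(2, 2, 2)), "label")
})

test_that("isosurface extraction recovers analytic volumes and topology", {
  one <- array(0, c(5, 5, 5)); one[3, 3, 3] <- 1
  m1 <- extract_surface(voxel_grid(one))
  expect_identical(euler_characteristic(m1), 2L)
  expect_gt(mesh_volume(m1), 0)
  expect_lt(mesh_volume(m1), 1)  # dual polyhedron of a unit voxel
  # filled 20 mm sphere at 1 mm spacing: volume within 5 percent, genus 0
  g <- seq(-24, 24, by = 1)
  arr <- array(0, c(49, 49, 49))
  for (k in seq_along(g))
    arr[, , k] <- outer(g, g, function(x, y) as.numeric(x^2 + y^2 + g[k]^2 < 400))
  vg <- voxel_grid(arr, origin = c(-24, -24, -24), spacing = c(1, 1, 1))
  ms <- extract_surface(vg)
  vtrue <- 4 * pi / 3 * 20^3
  expect_lt(abs(mesh_volume(ms) - vtrue) / vtrue, 0.05)
  expect_identical(euler_characteristic(ms), 2L)
  # volume error shrinks as spacing shrinks (2 mm grid vs 1 mm grid)
  g2 <- seq(-24, 24, by = 2)
  arr2 <- array(0, c(25, 25, 25))
  for (k in seq_along(g2))
    arr2[, , k] <- outer(g2, g2, function(x, y) as.numeric(x^2 + y^2 + g2[k]^2 < 400))
  m2 <- extract_surface(voxel_grid(arr2, origin = c(-24, -24, -24),
                                   spacing = c(2, 2, 2)))
  expect_lt(abs(mesh_volume(ms) - vtrue), abs(mesh_volume(m2) - vtrue))
  expect_error(extract_surface(voxel_grid(array(1, c(3, 3, 3)))), "uniform")
})

test_that("Laplacian smoothing relaxes toward neighbour means", {
  tet <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                      rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)))
  expect_identical(smooth_mesh(tet, 0)$vertices, tet$vertices)
  # relaxation 1: every vertex lands on the centroid of the other three
  s1 <- smooth_mesh(tet, iterations = 1, relaxation = 1)
  for (i in 1:4)
    expect_equal(s1$vertices[i, ], colMeans(tet$vertices[-i, ]),
                 tolerance = 1e-12)
  # noisy sphere: RMS radial error decreases, topology untouched
  set.seed(6)
  sph <- make_ellipsoid_mesh(c(0, 0, 0), c(30, 30, 30), 4)
  noisy <- sph
  noisy$vertices <- noisy$vertices + matrix(rnorm(length(sph$vertices), sd = 0.8),
                                            ncol = 3)
  sm <- smooth_mesh(noisy, 80, 0.1)
  rms <- function(m) sqrt(mean((sqrt(rowSums(m$vertices^2)) - 30)^2))
  expect_lt(rms(sm), rms(noisy))
  expect_identical(sm$faces, noisy$faces)
  expect_identical(nrow(sm$vertices), nrow(noisy$vertices))
})

test_that("largest component keeps the biggest shell, ties by area", {
  sph <- make_ellipsoid_mesh(c(0, 0, 0), c(10, 10, 10), 2)
  expect_identical(nrow(largest_component(sph)$faces), nrow(sph$faces))
  cube <- surface_mesh(
    as.matrix(expand.grid(0:1, 0:1, 0:1)) + 100,
    rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7), c(1, 2, 5),
          c(2, 6, 5), c(3, 7, 4), c(4, 7, 8), c(1, 5, 3), c(3, 5, 7),
          c(2, 4, 6), c(4, 8, 6)))
  both <- surface_mesh(rbind(sph$vertices, cube$vertices),
                       rbind(sph$faces, cube$faces + nrow(sph$vertices)))
  kept <- largest_component(both)
  expect_identical(nrow(kept$faces), nrow(sph$faces))
  # equal face counts: the larger-area component wins
  tri <- function(scale, shift) surface_mesh(
    rbind(c(0, 0, 0), c(scale, 0, 0), c(0, scale, 0)) + shift,
    rbind(c(1, 2, 3)))
  small <- tri(1, 0); big <- tri(5, 100)
  pair <- surface_mesh(rbind(small$vertices, big$vertices),
                       rbind(small$faces, big$faces + 3L))
  expect_equal(max(largest_component(pair)$vertices), 105)
})

test_that("Dice matches set arithmetic and detects degenerate input", {
  a <- c(rep(1L, 10), rep(0L, 10))
  expect_equal(dice(a, a, 1L), 1)
  expect_equal(dice(c(1L, 1L, 0L), c(0L, 0L, 1L), 1L), 0)
  pred <- c(rep(1L, 10), rep(0L, 10))
  truth <- c(rep(1L, 6), rep(0L, 4), rep(1L, 4), rep(0L, 6))
  expect_equal(dice(pred, truth, 1L), 0.6)   # |A|=10, |B|=10, overlap 6
  expect_equal(dice(pred, truth, 1L), dice(truth, pred, 1L))
  expect_error(dice(c(0L, 0L), c(0L, 0L), 1L), "undefined")
})

test_that("the refinement pipeline is exact for noiseless propagated labels", {
  dense <- grid_ellipsoid_cloud(c(20, 16, 14), c(2, 2, 2))
  mesh <- refine_pipeline(dense, dense, 1L,
                          refine_config(voxel_spacing = c(2, 2, 2),
                                        knn_outlier = 15))
  expect_equal(dice(attr(mesh, "labels"), dense$labels, 1L), 1)
  expect_identical(euler_characteristic(mesh), 2L)
  audit <- attr(mesh, "audit")
  expect_identical(unname(audit["dense_points"]), nrow(dense$points))
})

test_that("planted outliers are removed before surfacing", {
  spec <- phantom_spec(list(list(name = "organ", shape = "ellipsoid",
                                 center = c(0, 0, 0), semi_axes = c(30, 30, 30),
                                 label = 1L, eta = 1,
                                 architecture = "parallel")),
                       tumor_center = c(0, 0, 0), seed = 9)
  cl <- make_labeled_cloud(spec, points_per_organ = 4000, noise_sd = 1,
                           outlier_fraction = 0.05, seed = 9)
  res <- remove_outliers(cl, k = 30, sd_factor = 2)
  planted <- which(cl$outlier)
  recall <- mean(planted %in% res$removed)
  expect_gte(recall, 0.9)
})
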