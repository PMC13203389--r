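#' @useDynLib meshdose, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optimize rnorm runif sd
NULL

# Icosahedron with outward winding; basis for all ellipsoid meshes.
.icosahedron <- function() {
  t <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1,  t,  0), c( 1,  t,  0), c(-1, -t,  0), c( 1, -t,  0),
    c( 0, -1,  t), c( 0,  1,  t), c( 0, -1, -t), c( 0,  1, -t),
    c( t,  0, -1), c( t,  0,  1), c(-t,  0, -1), c(-t,  0,  1))
  V <- V / sqrt(rowSums(V^2))
  F <- rbind(
    c(0, 11, 5), c(0, 5, 1), c(0, 1, 7), c(0, 7, 10), c(0, 10, 11),
    c(1, 5, 9), c(5, 11, 4), c(11, 10, 2), c(10, 7, 6), c(7, 1, 8),
    c(3, 9, 4), c(3, 4, 2), c(3, 2, 6), c(3, 6, 8), c(3, 8, 9),
    c(4, 9, 5), c(2, 4, 11), c(6, 2, 10), c(8, 6, 7), c(9, 8, 1)) + 1L
  list(V = V, F = F)
}

# One 4-to-1 triangle subdivision with midpoint reuse, reprojected to the
# unit sphere. Orientation of the parent triangles is preserved.
.subdivide_sphere <- function(V, F) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  edges <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  k <- key(edges[, 1], edges[, 2])
  uk <- unique(k)
  mid_of <- match(k, uk)
  ue <- edges[!duplicated(k), , drop = FALSE]
  mids <- (V[ue[, 1], , drop = FALSE] + V[ue[, 2], , drop = FALSE]) / 2
  mids <- mids / sqrt(rowSums(mids^2))
  midx <- nrow(V) + seq_len(nrow(mids))
  nf <- nrow(F)
  mab <- midx[mid_of[seq_len(nf)]]
  mbc <- midx[mid_of[nf + seq_len(nf)]]
  mca <- midx[mid_of[2 * nf + seq_len(nf)]]
  newF <- rbind(cbind(F[, 1], mab, mca),
                cbind(F[, 2], mbc, mab),
                cbind(F[, 3], mca, mbc),
                cbind(mab, mbc, mca))
  list(V = rbind(V, mids), F = newF)
}

#' Analytic ellipsoid mesh (subdivided icosphere)
#'
#' Builds a closed, consistently outward-wound triangular mesh of an
#' ellipsoid by subdividing an icosahedron on the unit sphere and scaling by
#' the semi-axes. Vertices lie exactly on the ellipsoid, so the mesh volume
#' converges to the analytic value from below as subdivisions increase.
#'
#' @param center length-3 centre in mm.
#' @param semi_axes length-3 positive semi-axes in mm.
#' @param subdivisions non-negative integer; 0 gives the raw icosahedron
#'   (20 faces), each level multiplies the face count by 4.
#' @return a [surface_mesh()].
#' @export
make_ellipsoid_mesh <- function(center = c(0, 0, 0), semi_axes = c(1, 1, 1),
                                subdivisions = 3L) {
  if (any(semi_axes <= 0)) stop("semi_axes must be positive")
  if (subdivisions < 0) stop("subdivisions must be >= 0")
  m <- .icosahedron()
  for (i in seq_len(subdivisions)) m <- .subdivide_sphere(m$V, m$F)
  V <- sweep(sweep(m$V, 2, semi_axes, `*`), 2, center, `+`)
  surface_mesh(V, m$F)
}

#' Phantom specification
#'
#' Describes a set of nested quadric organs: each organ has a name, an
#' ellipsoidal shape (a sphere is an ellipsoid with equal semi-axes), an
#' integer label, a water-equivalence coefficient eta, and a serial or
#' parallel radiobiological architecture.
#'
#' @param organs list of organ descriptors; each a list with fields `name`,
#'   `center`, `semi_axes`, `label`, `eta`, `architecture`.
#' @param tumor_center length-3 tumour centre in mm.
#' @param seed integer seed recorded with the spec.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(organs, tumor_center, seed = 1L) {
  labels <- vapply(organs, function(o) as.integer(o$label), integer(1))
  if (any(labels <= 0L)) stop("organ labels must be > 0 (0 is background)")
  if (anyDuplicated(labels)) stop("organ labels must be unique")
  for (o in organs) {
    if (any(o$semi_axes <= 0)) stop("semi_axes must be positive")
    if (o$eta <= 0) stop("eta must be positive")
    if (!o$architecture %in% c("serial", "parallel"))
      stop("architecture must be 'serial' or 'parallel'")
  }
  structure(list(organs = organs, tumor_center = as.numeric(tumor_center),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %d organs, tumour at (%g, %g, %g) mm\n",
              length(x$organs), x$tumor_center[1], x$tumor_center[2],
              x$tumor_center[3]))
  invisible(x)
}

#' Thorax phantom: nested ellipsoid organs with a lung tumour
#'
#' A clinically plausible nested-quadric thorax: water-equivalent body
#' ellipsoid (35 x 20 x 40 cm full axes), two lungs at lung density
#' (eta = 0.275), a near-water heart (eta = 1.05), and a 1.5 cm-radius
#' spherical tumour seated in the left lung. All entry/exit points have
#' closed forms, so the phantom doubles as a geometric oracle.
#'
#' @param seed integer; recorded in the spec (the geometry itself is
#'   deterministic).
#' @param subdivisions icosphere subdivision level for the organ meshes.
#' @return list with `spec` (a [phantom_spec()]) and `meshes` (named list of
#'   [surface_mesh()], one per organ).
#' @export
make_thorax_phantom <- function(seed = 1L, subdivisions = 3L) {
  organs <- list(
    list(name = "body", center = c(0, 0, 0), semi_axes = c(175, 100, 200),
         label = 1L, eta = 1, architecture = "parallel"),
    list(name = "lung_left", center = c(72, 0, 0), semi_axes = c(45, 35, 95),
         label = 2L, eta = 0.275, architecture = "parallel"),
    list(name = "lung_right", center = c(-72, 0, 0), semi_axes = c(45, 35, 95),
         label = 3L, eta = 0.275, architecture = "parallel"),
    list(name = "heart", center = c(0, 0, 0), semi_axes = c(25, 25, 35),
         label = 4L, eta = 1.05, architecture = "serial"),
    list(name = "tumor", center = c(80, 0, 20), semi_axes = c(15, 15, 15),
         label = 5L, eta = 1, architecture = "parallel"))
  spec <- phantom_spec(organs, tumor_center = c(80, 0, 20), seed = seed)
  meshes <- lapply(organs, function(o)
    make_ellipsoid_mesh(o$center, o$semi_axes, subdivisions))
  names(meshes) <- vapply(organs, `[[`, character(1), "name")
  list(spec = spec, meshes = meshes)
}

# Uniform samples inside an ellipsoid (direction x radius^(1/3) scaling).
.sample_in_ellipsoid <- function(n, center, semi_axes) {
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  r <- runif(n)^(1 / 3)
  sweep(sweep(u * r, 2, semi_axes, `*`), 2, center, `+`)
}

#' Labeled point cloud sampled from a phantom
#'
#' Draws `points_per_organ` uniform samples inside each organ, perturbs them
#' with isotropic Gaussian noise, and converts a fixed fraction per organ
#' into planted outliers pushed well outside the organ surface (at 5-10
#' noise standard deviations, with a 2 mm floor so outliers exist even for
#' noiseless clouds). The returned cloud records ground truth: `labels`
#' holds the generating organ and `outlier` flags the planted points.
#'
#' @param spec a [phantom_spec()].
#' @param points_per_organ samples per organ (>= 1).
#' @param noise_sd isotropic noise standard deviation in mm.
#' @param outlier_fraction fraction in [0, 1) of each organ's points planted
#'   as outliers.
#' @param seed integer RNG seed; output is reproducible given the seed.
#' @return a [labeled_cloud()] with an extra logical element `outlier`.
#' @export
make_labeled_cloud <- function(spec, points_per_organ = 1000L, noise_sd = 0,
                               outlier_fraction = 0, seed = 1L) {
  if (points_per_organ < 1L) stop("points_per_organ must be >= 1")
  if (outlier_fraction < 0 || outlier_fraction >= 1)
    stop("outlier_fraction must be in [0, 1)")
  set.seed(seed)
  pts <- NULL; labs <- integer(0); outl <- logical(0)
  n_out <- round(outlier_fraction * points_per_organ)
  shell <- max(5 * noise_sd, 2)
  for (o in spec$organs) {
    p <- .sample_in_ellipsoid(points_per_organ, o$center, o$semi_axes)
    if (noise_sd > 0)
      p <- p + matrix(rnorm(3 * points_per_organ, sd = noise_sd), ncol = 3)
    flag <- rep(FALSE, points_per_organ)
    if (n_out > 0) {
      take <- seq_len(n_out)
      u <- matrix(rnorm(3 * n_out), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      surf <- sweep(u, 2, o$semi_axes, `*`)       # point on the surface
      rad <- sqrt(rowSums(surf^2))
      d <- shell * runif(n_out, 1, 2)             # radial push beyond it
      p[take, ] <- sweep(surf * (1 + d / rad), 2, o$center, `+`)
      flag[take] <- TRUE
    }
    pts <- rbind(pts, p)
    labs <- c(labs, rep(o$label, points_per_organ))
    outl <- c(outl, flag)
  }
  cl <- labeled_cloud(pts, labels = labs)
  cl$outlier <- outl
  cl
}

#' Noisy percentage-depth-dose samples
#'
#' Evaluates a buildup-tail PDD model on a depth grid and applies
#' multiplicative Gaussian noise, as a fixture for [fit_pdd()].
#'
#' @param model a [pdd_model()].
#' @param depths depths in cm (>= 0).
#' @param noise_sd multiplicative noise standard deviation (fraction, e.g.
#'   0.01 for 1 percent).
#' @param seed integer RNG seed.
#' @return data.frame with columns `depth_cm` and `pdd_pct`.
#' @export
sample_pdd_curve <- function(model, depths, noise_sd = 0, seed = 1L) {
  if (any(depths < 0)) stop("depths must be >= 0")
  y <- pdd(depths, model)
  if (noise_sd > 0) {
    set.seed(seed)
    y <- y * (1 + rnorm(length(y), sd = noise_sd))
  }
  data.frame(depth_cm = depths, pdd_pct = y)
}
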