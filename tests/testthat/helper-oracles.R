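# Independent oracles used across the suite. These deliberately use
# different algorithms from the package implementations.

# Barycentric point-in-triangle oracle (2-D coordinates in the triangle
# plane), independent of the same-side cross-product test.
bary_inside <- function(P, A, B, C, tol = 1e-12) {
  v0 <- C - A; v1 <- B - A; v2 <- P - A
  d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
  d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
  den <- d00 * d11 - d01 * d01
  u <- (d11 * d20 - d01 * d21) / den
  v <- (d00 * d21 - d01 * d20) / den
  u >= -tol && v >= -tol && (u + v) <= 1 + tol
}

# Brute-force k nearest neighbours via a full distance matrix.
brute_knn <- function(query, ref, k) {
  D <- as.matrix(stats::dist(rbind(query, ref)))
  nq <- nrow(query)
  D <- D[seq_len(nq), nq + seq_len(nrow(ref)), drop = FALSE]
  matrix(t(apply(D, 1, function(d) order(d)[seq_len(k)])), nrow = nq)
}

# Brute-force farthest-point sampling (matrix form), smallest index wins
# ties, matching the documented tie rule.
brute_fps <- function(pts, m, first) {
  picked <- first
  mind <- rep(Inf, nrow(pts))
  for (s in seq_len(m - 1L)) {
    last <- pts[picked[length(picked)], ]
    d <- sqrt(rowSums(sweep(pts, 2, last)^2))
    mind <- pmin(mind, d)
    picked <- c(picked, which.max(mind))
  }
  picked
}

# Analytic chord of a ray through an axis-aligned ellipsoid centred at c:
# returns sorted entry/exit t values or NULL on a miss.
ellipsoid_ray_t <- function(origin, dir, center, semi) {
  o <- (origin - center) / semi
  d <- dir / semi
  A <- sum(d^2); B <- 2 * sum(o * d); C <- sum(o^2) - 1
  disc <- B^2 - 4 * A * C
  if (disc <= 0) return(NULL)
  sort(c((-B - sqrt(disc)) / (2 * A), (-B + sqrt(disc)) / (2 * A)))
}

# Maclaurin-series erf, for checking the NTCP sigmoid against an
# implementation-independent special-function route.
erf_series <- function(x, terms = 60) {
  k <- 0:(terms - 1)
  2 / sqrt(pi) * sum((-1)^k * x^(2 * k + 1) / (factorial(k) * (2 * k + 1)))
}

# Random rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Ellipsoid label volume on a regular grid -> dense labeled cloud fixture,
# mimicking a CT-derived organ cloud (one point per interior voxel).
grid_ellipsoid_cloud <- function(semi, spacing, margin = 5) {
  gx <- seq(-semi[1] - margin, semi[1] + margin, by = spacing[1])
  gy <- seq(-semi[2] - margin, semi[2] + margin, by = spacing[2])
  gz <- seq(-semi[3] - margin, semi[3] + margin, by = spacing[3])
  lab <- array(0L, c(length(gx), length(gy), length(gz)))
  for (k in seq_along(gz))
    lab[, , k] <- outer(gx, gy, function(x, y)
      as.integer((x / semi[1])^2 + (y / semi[2])^2 + (gz[k] / semi[3])^2 < 1))
  volume_to_cloud(lab, origin = c(gx[1], gy[1], gz[1]), spacing = spacing,
                  target_labels = 1L)
}
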