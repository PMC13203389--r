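#' Refinement configuration
#'
#' Parameters of the point-cloud-to-organ-model chain. Defaults follow a
#' CT-resolution workflow: 10-neighbour majority voting, 30-neighbour
#' outlier statistics at 2 standard deviations, 0.97656 mm in-plane /
#' 2.99 mm slice voxel spacing, isosurface at 0.5 on binary occupancy, and
#' Laplacian smoothing with 80 iterations at relaxation 0.1.
#'
#' @param knn_label neighbours for label voting (>= 1).
#' @param knn_outlier neighbours for the outlier statistic (>= 1).
#' @param sd_factor outlier threshold in global standard deviations.
#' @param voxel_spacing length-3 voxel spacing in mm.
#' @param iso_level isosurface level on the occupancy field.
#' @param smooth_iterations Laplacian smoothing iterations.
#' @param relaxation smoothing step in (0, 1].
#' @param close_surface logical; morphologically close the occupancy grid
#'   before surfacing (for surface-only clouds; off by default since organ
#'   clouds are volumetric).
#' @return object of class `refine_config`.
#' @export
refine_config <- function(knn_label = 10L, knn_outlier = 30L, sd_factor = 2,
                          voxel_spacing = c(0.97656, 0.97656, 2.99),
                          iso_level = 0.5, smooth_iterations = 80L,
                          relaxation = 0.1, close_surface = FALSE) {
  if (knn_label < 1L || knn_outlier < 1L) stop("neighbour counts must be >= 1")
  if (relaxation <= 0 || relaxation > 1) stop("relaxation must be in (0, 1]")
  if (any(voxel_spacing <= 0)) stop("voxel_spacing must be positive")
  structure(list(knn_label = as.integer(knn_label),
                 knn_outlier = as.integer(knn_outlier),
                 sd_factor = sd_factor, voxel_spacing = voxel_spacing,
                 iso_level = iso_level,
                 smooth_iterations = as.integer(smooth_iterations),
                 relaxation = relaxation, close_surface = close_surface),
            class = "refine_config")
}

#' Farthest-point sampling
#'
#' Greedy subsampling: after a seeded random first pick, each selected point
#' maximises its minimum distance to the already-selected set (smallest
#' index wins ties), giving uniform spatial coverage.
#'
#' @param cloud a [labeled_cloud()] (or N x 3 matrix).
#' @param m number of samples, 1 <= m <= N.
#' @param seed integer seed for the first pick.
#' @return integer vector of m selected indices.
#' @export
farthest_point_sample <- function(cloud, m, seed = 1L) {
  pts <- if (inherits(cloud, "labeled_cloud")) cloud$points else
    matrix(as.numeric(cloud), ncol = 3)
  n <- nrow(pts)
  if (m < 1L || m > n) stop("m must be between 1 and the cloud size")
  set.seed(seed)
  first <- sample.int(n, 1L)
  .cpp_fps(pts, as.integer(m), first)
}

#' k-nearest-neighbour label propagation
#'
#' Assigns each dense point the modal label among its k nearest sparse
#' points (Euclidean distance in mm); ties are broken by the label of the
#' single nearest neighbour.
#'
#' @param sparse a [labeled_cloud()] carrying the sparse prediction.
#' @param dense_points N x 3 matrix (or [labeled_cloud()]) to label.
#' @param k neighbours to vote (default 10).
#' @return integer vector of N labels.
#' @export
propagate_labels <- function(sparse, dense_points, k = 10L) {
  if (!nrow(sparse$points)) stop("sparse cloud is empty")
  k <- min(as.integer(k), nrow(sparse$points))
  pts <- if (inherits(dense_points, "labeled_cloud")) dense_points$points
         else matrix(as.numeric(dense_points), ncol = 3)
  nn <- .cpp_knn(pts, sparse$points, k, FALSE)
  labs <- matrix(sparse$labels[nn$idx], ncol = k)
  apply_vote <- function(i) {
    tab <- table(labs[i, ])
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1L) as.integer(top) else labs[i, 1L]  # nearest breaks tie
  }
  vapply(seq_len(nrow(pts)), apply_vote, integer(1))
}

#' Statistical outlier removal
#'
#' For each point, the mean distance to its k nearest neighbours is
#' computed; points whose statistic exceeds the global mean by more than
#' `sd_factor` global standard deviations are removed.
#'
#' @param cloud a [labeled_cloud()] with more than k points.
#' @param k neighbours (default 30).
#' @param sd_factor threshold in standard deviations (default 2).
#' @return list with `cloud` (filtered [labeled_cloud()]) and `removed`
#'   (integer indices into the input).
#' @export
remove_outliers <- function(cloud, k = 30L, sd_factor = 2) {
  n <- nrow(cloud$points)
  if (n <= k) stop("cloud must contain more than k points")
  nn <- .cpp_knn(cloud$points, cloud$points, as.integer(k), TRUE)
  stat <- rowMeans(nn$dist)
  thr <- mean(stat) + sd_factor * sd(stat)
  removed <- which(stat > thr)
  keep <- setdiff(seq_len(n), removed)
  out <- labeled_cloud(cloud$points[keep, , drop = FALSE],
                       labels = cloud$labels[keep],
                       hu = if (is.null(cloud$hu)) NULL else cloud$hu[keep],
                       origin = cloud$origin, spacing = cloud$spacing)
  list(cloud = out, removed = removed)
}

#' Voxelise one organ of a labeled cloud
#'
#' Binary occupancy on a grid covering the labeled points' bounding box
#' plus padding. A voxel is occupied iff at least one point with the label
#' falls in it under the voxel-centre convention (voxel (i,j,k) covers
#' `origin + (i,j,k) * spacing` plus/minus half a spacing).
#'
#' @param cloud a [labeled_cloud()].
#' @param label organ label to voxelise.
#' @param spacing length-3 voxel spacing in mm.
#' @param padding empty voxels added around the bounding box (>= 1 keeps
#'   the isosurface closed).
#' @return a [voxel_grid()] with 0/1 values.
#' @export
voxelize <- function(cloud, label, spacing = c(1, 1, 1), padding = 2L) {
  sel <- cloud$labels == label
  if (!any(sel)) stop("no points carry label ", label)
  pts <- cloud$points[sel, , drop = FALSE]
  lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
  origin <- lo - padding * spacing
  dims <- floor((hi - origin) / spacing + 0.5) + padding + 1
  idx <- sweep(sweep(pts, 2, origin, `-`), 2, spacing, `/`)
  idx <- floor(idx + 0.5)  # nearest voxel centre
  lin <- 1 + idx[, 1] + dims[1] * (idx[, 2] + dims[2] * idx[, 3])
  occ <- array(0, dims)
  occ[unique(lin)] <- 1
  voxel_grid(occ, origin = origin, spacing = spacing)
}

#' Isosurface extraction from a voxel grid
#'
#' Extracts the iso-level surface by tetrahedral decomposition of each grid
#' cell (six tetrahedra per cell, consistent across shared faces), with
#' vertices linearly interpolated along cell edges and returned in physical
#' mm. The surface is closed whenever the above-iso region stays off the
#' grid boundary; on binary occupancy a single occupied voxel yields its
#' dual octahedron (volume 1/6 of the voxel), and volumes converge to the
#' truth as spacing shrinks.
#'
#' @param grid a [voxel_grid()] containing values on both sides of the
#'   iso level.
#' @param iso_level surface level (default 0.5).
#' @param step subsampling stride over the grid (default 1 = full
#'   resolution).
#' @return a [surface_mesh()].
#' @export
extract_surface <- function(grid, iso_level = 0.5, step = 1L) {
  vals <- grid$values
  if (step > 1L) {
    ii <- seq(1, dim(vals)[1], by = step)
    jj <- seq(1, dim(vals)[2], by = step)
    kk <- seq(1, dim(vals)[3], by = step)
    vals <- vals[ii, jj, kk, drop = FALSE]
    spacing <- grid$spacing * step
  } else spacing <- grid$spacing
  if (all(vals > iso_level) || all(vals <= iso_level))
    stop("grid is uniform at the iso level; no surface to extract")
  d <- dim(vals)
  gx <- grid$origin[1] + spacing[1] * (seq_len(d[1]) - 1)
  gy <- grid$origin[2] + spacing[2] * (seq_len(d[2]) - 1)
  gz <- grid$origin[3] + spacing[3] * (seq_len(d[3]) - 1)
  res <- .cpp_isosurface(as.numeric(vals), as.integer(d), gx, gy, gz,
                         iso_level)
  surface_mesh(res$vertices, res$faces)
}

#' Laplacian mesh smoothing
#'
#' Per iteration each vertex moves a fraction `relaxation` of the way
#' toward the average position of its 1-ring neighbours (uniform umbrella
#' weights). Topology is untouched; isolated vertices are left in place
#' with a warning.
#'
#' @param mesh a [surface_mesh()].
#' @param iterations number of smoothing passes (default 80).
#' @param relaxation step size in (0, 1] (default 0.1).
#' @return smoothed [surface_mesh()].
#' @export
smooth_mesh <- function(mesh, iterations = 80L, relaxation = 0.1) {
  if (iterations == 0L) return(mesh)
  V <- mesh$vertices; F <- mesh$faces
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  A <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                            x = 1, dims = c(nrow(V), nrow(V)))
  deg <- Matrix::rowSums(A)
  iso <- deg == 0
  if (any(iso)) warning(sum(iso), " isolated vertices left unmoved")
  deg[iso] <- 1
  for (i in seq_len(iterations)) {
    nbr_mean <- as.matrix(A %*% V) / deg
    delta <- relaxation * (nbr_mean - V)
    delta[iso, ] <- 0
    V <- V + delta
  }
  structure(list(vertices = V, faces = F), class = "surface_mesh")
}

#' Largest connected mesh component
#'
#' Retains the vertex-connected component with the most faces; ties are
#' broken by larger total surface area.
#'
#' @param mesh a [surface_mesh()] with at least one face.
#' @return a [surface_mesh()] (re-indexed to its own vertices).
#' @export
largest_component <- function(mesh) {
  F <- mesh$faces
  if (!nrow(F)) stop("mesh has no faces")
  nv <- nrow(mesh$vertices)
  # union-find over vertices joined by faces
  parent <- seq_len(nv)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (i in seq_len(nrow(F))) {
    a <- find(F[i, 1]); b <- find(F[i, 2]); c <- find(F[i, 3])
    parent[b] <- a; parent[find(c)] <- a
  }
  comp <- vapply(seq_len(nv), find, integer(1))
  fcomp <- comp[F[, 1]]
  sizes <- table(fcomp)
  top <- names(sizes)[sizes == max(sizes)]
  if (length(top) > 1L) {   # tie: larger total area wins
    areas <- vapply(top, function(cc)
      sum(face_areas(mesh$vertices, F[fcomp == as.integer(cc), , drop = FALSE])),
      numeric(1))
    top <- top[which.max(areas)]
  }
  keepF <- F[fcomp == as.integer(top), , drop = FALSE]
  used <- sort(unique(as.vector(keepF)))
  remap <- integer(nv); remap[used] <- seq_along(used)
  surface_mesh(mesh$vertices[used, , drop = FALSE],
               matrix(remap[keepF], ncol = 3))
}

#' Dice similarity coefficient for one organ
#'
#' `2|A n B| / (|A| + |B|)` over the index sets carrying the organ label in
#' the predicted and ground-truth labelings of the same points.
#'
#' @param pred_labels,truth_labels equal-length integer vectors.
#' @param organ organ label to score.
#' @return Dice coefficient in [0, 1].
#' @export
dice <- function(pred_labels, truth_labels, organ) {
  if (length(pred_labels) != length(truth_labels))
    stop("label vectors must have equal length")
  A <- pred_labels == organ
  B <- truth_labels == organ
  if (!any(A) && !any(B))
    stop("Dice undefined: organ ", organ, " absent from both labelings")
  2 * sum(A & B) / (sum(A) + sum(B))
}

# 6-connected binary closing (dilate then erode) used for surface-only clouds
.binary_close <- function(occ) {
  shift <- function(a, d, s) {
    out <- array(0, dim(a)); n <- dim(a)[d]
    idx <- lapply(dim(a), seq_len); src <- idx; dst <- idx
    if (s > 0) { dst[[d]] <- (1 + s):n; src[[d]] <- 1:(n - s) }
    else { dst[[d]] <- 1:(n + s); src[[d]] <- (1 - s):n }
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    out
  }
  nb <- function(a) {
    s <- a
    for (d in 1:3) for (sg in c(-1, 1)) s <- pmax(s, shift(a, d, sg))
    s
  }
  dil <- nb(occ)
  ero <- dil
  for (d in 1:3) for (sg in c(-1, 1)) ero <- pmin(ero, shift(dil, d, sg))
  ero
}

#' Sparse-prediction to organ-model pipeline
#'
#' Composition of the post-processing chain: propagate the sparse labels
#' onto the dense cloud, remove statistical outliers from the organ's
#' points, voxelise, extract the isosurface, smooth, and keep the largest
#' connected component. An audit log of point/face counts per stage is
#' attached as attribute `"audit"`.
#'
#' @param sparse_prediction a [labeled_cloud()] with predicted labels.
#' @param dense_cloud a [labeled_cloud()] of the full-resolution points.
#' @param organ organ label to reconstruct.
#' @param config a [refine_config()].
#' @return a [surface_mesh()] with attributes `audit` (named counts) and
#'   `labels` (the propagated dense labels).
#' @export
refine_pipeline <- function(sparse_prediction, dense_cloud, organ,
                            config = refine_config()) {
  labs <- propagate_labels(sparse_prediction, dense_cloud,
                           k = config$knn_label)
  dense <- labeled_cloud(dense_cloud$points, labels = labs,
                         hu = dense_cloud$hu, origin = dense_cloud$origin,
                         spacing = dense_cloud$spacing)
  organ_cloud <- labeled_cloud(
    dense$points[labs == organ, , drop = FALSE],
    labels = labs[labs == organ])
  filt <- remove_outliers(organ_cloud, k = config$knn_outlier,
                          sd_factor = config$sd_factor)
  grid <- voxelize(filt$cloud, organ, spacing = config$voxel_spacing)
  if (config$close_surface) grid$values <- .binary_close(grid$values)
  mesh <- extract_surface(grid, iso_level = config$iso_level)
  mesh <- smooth_mesh(mesh, iterations = config$smooth_iterations,
                      relaxation = config$relaxation)
  mesh <- largest_component(mesh)
  attr(mesh, "labels") <- labs
  attr(mesh, "audit") <- c(
    dense_points = nrow(dense$points),
    organ_points = nrow(organ_cloud$points),
    outliers_removed = length(filt$removed),
    occupied_voxels = sum(grid$values > 0),
    faces_raw = NA_integer_,
    faces_final = nrow(mesh$faces))
  mesh
}
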