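#' Axis-aligned bounding box
#'
#' @param min_corner,max_corner length-3 mm, `min <= max` componentwise.
#' @return object of class `aabb`.
#' @export
aabb <- function(min_corner, max_corner) {
  if (any(min_corner > max_corner)) stop("min corner must be <= max corner")
  structure(list(min = as.numeric(min_corner), max = as.numeric(max_corner)),
            class = "aabb")
}

#' Rigid pose
#'
#' @param rotation 3 x 3 rotation matrix (orthonormal, det +1).
#' @param translation length-3 mm.
#' @return object of class `pose`.
#' @export
pose <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be orthonormal with det +1")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "pose")
}

#' Compose two poses (apply `b` then `a`)
#' @param a,b [pose()] objects.
#' @return the composed [pose()].
#' @export
pose_compose <- function(a, b)
  pose(a$rotation %*% b$rotation,
       as.vector(a$rotation %*% b$translation) + a$translation)

#' Rotation about a coordinate axis
#' @param axis 1, 2 or 3 (x, y, z).
#' @param angle_deg angle in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
axis_rotation <- function(axis, angle_deg) {
  th <- angle_deg * pi / 180
  c2 <- cos(th); s2 <- sin(th)
  R <- diag(3)
  ij <- setdiff(1:3, axis)
  R[ij[1], ij[1]] <- c2; R[ij[2], ij[2]] <- c2
  R[ij[1], ij[2]] <- -s2; R[ij[2], ij[1]] <- s2
  R
}

#' World-frame AABB of posed geometry
#'
#' Transforms the points by the pose, takes componentwise extrema and
#' inflates all sides by the safety margin. Recomputing the box per pose is
#' deliberately conservative: rotated parts get enlarged boxes.
#'
#' @param points N x 3 local geometry in mm.
#' @param pose a [pose()].
#' @param margin safety margin in mm added on every side (default 0).
#' @return an [aabb()].
#' @export
aabb_of <- function(points, pose = NULL, margin = 0) {
  points <- matrix(as.numeric(points), ncol = 3)
  if (!nrow(points)) stop("empty point set has no bounding box")
  if (!is.null(pose)) {
    points <- points %*% t(pose$rotation)
    points <- sweep(points, 2, pose$translation, `+`)
  }
  aabb(apply(points, 2, min) - margin, apply(points, 2, max) + margin)
}

#' Separating-axis overlap test for AABBs
#'
#' For axis-aligned boxes the three coordinate axes are the only candidate
#' separating axes: the boxes overlap iff their intervals overlap on all
#' three. Touching faces count as overlap (safety-conservative).
#'
#' @param a,b [aabb()] objects.
#' @return logical.
#' @export
sat_overlap <- function(a, b)
  all(a$min <= b$max & b$min <= a$max)

#' Build a bounding-volume hierarchy
#'
#' Binary tree over the boxes: median split on the axis with the longest
#' centroid extent.
#'
#' @param boxes list of [aabb()] (>= 1).
#' @return object of class `bvh`.
#' @export
build_bvh <- function(boxes) {
  if (!length(boxes)) stop("at least one box required")
  build <- function(idx) {
    lo <- apply(vapply(boxes[idx], `[[`, numeric(3), "min"), 1, min)
    hi <- apply(vapply(boxes[idx], `[[`, numeric(3), "max"), 1, max)
    node <- list(box = aabb(lo, hi))
    if (length(idx) == 1L) {
      node$leaf <- idx
    } else {
      cen <- t(vapply(boxes[idx], function(b) (b$min + b$max) / 2,
                      numeric(3)))
      ext <- apply(cen, 2, max) - apply(cen, 2, min)
      ax <- which.max(ext)
      ord <- idx[order(cen[, ax])]
      half <- ceiling(length(ord) / 2)
      node$left <- build(ord[seq_len(half)])
      node$right <- build(ord[-seq_len(half)])
    }
    node
  }
  structure(build(seq_along(boxes)), class = "bvh", n = length(boxes),
            boxes = boxes)
}

#' Candidate colliding pairs between two hierarchies
#'
#' Dual traversal pruning disjoint subtrees; the returned pairs are
#' exactly the overlapping box pairs (identical to all-pairs testing).
#'
#' @param bvh_a,bvh_b [build_bvh()] trees.
#' @return 2-column matrix of (index in a, index in b) pairs.
#' @export
query_pairs <- function(bvh_a, bvh_b) {
  out <- list()
  recur <- function(na, nb) {
    if (!sat_overlap(na$box, nb$box)) return(invisible())
    if (!is.null(na$leaf) && !is.null(nb$leaf)) {
      out[[length(out) + 1L]] <<- c(na$leaf, nb$leaf)
    } else if (!is.null(na$leaf)) {
      recur(na, nb$left); recur(na, nb$right)
    } else {
      recur(na$left, nb); recur(na$right, nb)
    }
    invisible()
  }
  recur(bvh_a, bvh_b)
  if (!length(out)) matrix(integer(0), ncol = 2)
  else do.call(rbind, out)
}

#' Schematic LINAC machine components
#'
#' Boxy local geometry for a gantry head, gantry arm, couch and a patient
#' volume on the couch, with the kinematic parent of each part. Dimensions
#' are schematic, in mm, isocenter at the origin (100 cm nominal SAD).
#'
#' @return named list of components, each with `points` (corner points of
#'   the local geometry), `parent` (`"gantry"`, `"couch"` or `"world"`).
#' @export
default_machine <- function() {
  box_pts <- function(lo, hi) as.matrix(expand.grid(
    x = c(lo[1], hi[1]), y = c(lo[2], hi[2]), z = c(lo[3], hi[3])))
  list(
    gantry_head = list(points = box_pts(c(-250, -1300, -250),
                                        c(250, -700, 250)),
                       parent = "gantry"),
    gantry_arm = list(points = box_pts(c(-200, -1800, -400),
                                       c(200, -1250, 400)),
                      parent = "gantry"),
    couch = list(points = box_pts(c(-250, 100, -1000),
                                  c(250, 250, 1200)),
                 parent = "couch"),
    patient = list(points = box_pts(c(-200, -150, -900),
                                    c(200, 100, 900)),
                   parent = "couch"))
}

#' Forward kinematics of the treatment machine
#'
#' Gantry parts rotate about the z (longitudinal) axis through the
#' isocenter by the gantry angle; couch parts translate and yaw about the
#' vertical y axis.
#'
#' @param gantry_angle degrees.
#' @param couch list with `translation` (mm triple) and `yaw` (degrees).
#' @param components component list as from [default_machine()].
#' @return named list of [pose()] objects, one per component.
#' @export
machine_poses <- function(gantry_angle = 0,
                          couch = list(translation = c(0, 0, 0), yaw = 0),
                          components = default_machine()) {
  gpose <- pose(axis_rotation(3, gantry_angle))
  cpose <- pose(axis_rotation(2, couch$yaw), couch$translation)
  lapply(components, function(comp)
    switch(comp$parent,
           gantry = gpose,
           couch = cpose,
           pose()))
}

#' Margin-inflated collision detection
#'
#' Poses every component, recomputes world-frame AABBs inflated by the
#' safety margin, and reports all overlapping pairs, skipping pairs that
#' share a kinematic parent (adjacent in the chain). The BVH-accelerated
#' query is exact: results equal brute-force all-pairs testing.
#'
#' @param components named component list (see [default_machine()]).
#' @param poses named list of [pose()] from [machine_poses()].
#' @param margin safety margin in mm (default 50, i.e. 5 cm).
#' @param use_bvh accelerate with [build_bvh()] (default TRUE).
#' @return character matrix with columns `a`, `b` of colliding component
#'   names.
#' @export
detect_collisions <- function(components, poses, margin = 50,
                              use_bvh = TRUE) {
  nms <- names(components)
  boxes <- lapply(nms, function(nm)
    aabb_of(components[[nm]]$points, poses[[nm]], margin = margin))
  parent <- vapply(components, `[[`, character(1), "parent")
  ok_pair <- function(i, j) parent[i] != parent[j]
  pairs <- NULL
  if (use_bvh && length(boxes) > 1L) {
    bvh <- build_bvh(boxes)
    cand <- query_pairs(bvh, bvh)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; j <- cand[r, 2]
      if (ok_pair(i, j)) pairs <- rbind(pairs, c(nms[i], nms[j]))
    }
  } else {
    for (i in seq_along(boxes)) for (j in seq_len(i - 1L)) {
      if (ok_pair(i, j) && sat_overlap(boxes[[i]], boxes[[j]]))
        pairs <- rbind(pairs, c(nms[j], nms[i]))
    }
  }
  if (is.null(pairs)) pairs <- matrix(character(0), ncol = 2)
  colnames(pairs) <- c("a", "b")
  pairs
}
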