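#' Ray in patient coordinates
#'
#' @param origin length-3 origin in mm.
#' @param direction length-3 direction; normalised to unit length.
#' @return object of class `ray`.
#' @export
ray <- function(origin, direction) {
  direction <- as.numeric(direction)
  nrm <- sqrt(sum(direction^2))
  if (nrm < 1e-12) stop("ray direction must be non-zero")
  structure(list(origin = as.numeric(origin), direction = direction / nrm),
            class = "ray")
}

#' Ray-plane intersection parameter
#'
#' Solves `t = (D - n.r0) / (n.rd)` with `D = n.P`; returns `NA` when the
#' ray is parallel to the plane (|n.rd| < eps) or the hit lies behind the
#' origin (t <= eps).
#'
#' @param r a [ray()].
#' @param plane_point a point on the plane, mm.
#' @param normal unit plane normal.
#' @param eps parallelism/behind-origin tolerance in mm (default 1e-9).
#' @return t in mm, or `NA_real_`.
#' @export
ray_plane_t <- function(r, plane_point, normal, eps = 1e-9) {
  denom <- sum(normal * r$direction)
  if (abs(denom) < eps) return(NA_real_)
  D <- sum(normal * plane_point)
  t <- (D - sum(normal * r$origin)) / denom
  if (t <= eps) NA_real_ else t
}

#' Same-side point-in-triangle test
#'
#' For every vertex index i (cyclic), the cross products of `P - Pi` with
#' the two adjacent edges must not point to the same side:
#' `[(P-Pi) x (P(i-1)-Pi)] . [(P-Pi) x (P(i+1)-Pi)] <= 0`. Edge and vertex
#' contact count as inside. P is assumed coplanar with the triangle.
#'
#' @param P query point (coplanar with the triangle), mm.
#' @param P1,P2,P3 triangle vertices, mm.
#' @return logical.
#' @export
point_in_triangle <- function(P, P1, P2, P3) {
  tri <- rbind(P1, P2, P3)
  e1 <- P2 - P1; e2 <- P3 - P1
  n <- c(e1[2] * e2[3] - e1[3] * e2[2],
         e1[3] * e2[1] - e1[1] * e2[3],
         e1[1] * e2[2] - e1[2] * e2[1])
  if (sqrt(sum(n^2)) < 1e-12) stop("degenerate (collinear) triangle")
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  tol <- 1e-10 * sum(n^2)
  for (i in 1:3) {
    ip <- ((i - 2) %% 3) + 1  # i - 1 cyclic
    in_ <- (i %% 3) + 1       # i + 1 cyclic
    c1 <- cr(P - tri[i, ], tri[ip, ] - tri[i, ])
    c2 <- cr(P - tri[i, ], tri[in_, ] - tri[i, ])
    if (sum(c1 * c2) > tol) return(FALSE)
  }
  TRUE
}

#' All ray-mesh intersections
#'
#' Tests every face by the ray-plane solve followed by the same-side
#' point-in-triangle condition; hits are sorted by t and duplicates within
#' `eps_merge` (shared-edge crossings) are merged.
#'
#' @param r a [ray()].
#' @param mesh a [surface_mesh()].
#' @param eps rejection tolerance for parallel planes / hits at the origin.
#' @param eps_merge merge tolerance along t in mm.
#' @return data.frame with columns `t` (mm), `face`, `entering` (1 when the
#'   ray runs against the face's outward normal), and hit coordinates
#'   `x`, `y`, `z`.
#' @export
ray_mesh_intersections <- function(r, mesh, eps = 1e-9, eps_merge = 1e-6) {
  h <- .cpp_ray_mesh(r$origin, r$direction, mesh$vertices, mesh$faces,
                     eps, eps_merge)
  if (nrow(h)) {
    p <- outer(h$t, r$direction) + rep(r$origin, each = nrow(h))
    h$x <- p[, 1]; h$y <- p[, 2]; h$z <- p[, 3]
  } else {
    h$x <- h$y <- h$z <- numeric(0)
  }
  h
}

# Pair sorted crossings into (entry, exit) intervals. Entering/exiting
# flags from normal orientation are repaired by position parity when the
# mesh's local winding is inconsistent (possible after isosurfacing).
.crossing_intervals <- function(hits, organ_name = "organ") {
  n <- nrow(hits)
  if (n == 0L) return(NULL)
  if (n %% 2L == 1L)
    stop("open-mesh error: odd crossing count (", n, ") for ", organ_name)
  t <- hits$t
  cbind(t_in = t[seq(1, n, by = 2)], t_out = t[seq(2, n, by = 2)])
}

#' Trace a beam axis through a set of organ meshes
#'
#' Intersects the ray with every closed organ mesh, pairs the crossings
#' into traversal intervals, and resolves spatial overlap (e.g. a tumour
#' nested in a lung) by priority: each elementary interval is assigned the
#' highest-priority organ covering it. By default smaller-volume organs
#' take priority, so nested structures carve their hosts.
#'
#' @param r a [ray()].
#' @param organs list of organ descriptors, each a list with `label`
#'   (integer), `mesh` (a [surface_mesh()]), `eta` (water-equivalence
#'   coefficient), and optionally `name`.
#' @param priority integer vector of organ labels, highest priority first;
#'   `NULL` orders by increasing mesh volume.
#' @return data.frame of path segments sorted by entry distance with
#'   columns `label`, `t_in`, `t_out` (mm along the ray), `z` (geometric
#'   length, mm), `eta`, and `zeff = z * eta` (mm).
#' @export
trace_beam <- function(r, organs, priority = NULL) {
  labels <- vapply(organs, function(o) as.integer(o$label), integer(1))
  if (is.null(priority)) {
    vols <- vapply(organs, function(o) mesh_volume(o$mesh), numeric(1))
    priority <- labels[order(vols)]
  }
  rank <- match(labels, priority)
  intervals <- list()
  for (i in seq_along(organs)) {
    o <- organs[[i]]
    nm <- if (!is.null(o$name)) o$name else paste("label", o$label)
    h <- ray_mesh_intersections(r, o$mesh)
    iv <- .crossing_intervals(h, nm)
    if (!is.null(iv))
      intervals[[length(intervals) + 1L]] <-
        data.frame(label = o$label, eta = o$eta, rank = rank[i],
                   t_in = iv[, "t_in"], t_out = iv[, "t_out"])
  }
  if (!length(intervals))
    return(data.frame(label = integer(0), t_in = numeric(0),
                      t_out = numeric(0), z = numeric(0), eta = numeric(0),
                      zeff = numeric(0)))
  iv <- do.call(rbind, intervals)
  # partition into elementary intervals at all boundaries
  cuts <- sort(unique(c(iv$t_in, iv$t_out)))
  lo <- cuts[-length(cuts)]; hi <- cuts[-1]
  mid <- (lo + hi) / 2
  seg_label <- rep(NA_integer_, length(mid))
  seg_eta <- rep(NA_real_, length(mid))
  seg_rank <- rep(Inf, length(mid))
  for (j in seq_len(nrow(iv))) {
    cover <- mid > iv$t_in[j] & mid < iv$t_out[j] & iv$rank[j] < seg_rank
    seg_label[cover] <- iv$label[j]
    seg_eta[cover] <- iv$eta[j]
    seg_rank[cover] <- iv$rank[j]
  }
  keep <- !is.na(seg_label)
  lo <- lo[keep]; hi <- hi[keep]
  seg_label <- seg_label[keep]; seg_eta <- seg_eta[keep]
  if (!length(lo))
    return(data.frame(label = integer(0), t_in = numeric(0),
                      t_out = numeric(0), z = numeric(0), eta = numeric(0),
                      zeff = numeric(0)))
  # merge adjacent elementary intervals with the same label
  brk <- c(TRUE, seg_label[-1] != seg_label[-length(seg_label)] |
             abs(lo[-1] - hi[-length(hi)]) > 1e-9)
  grp <- factor(cumsum(brk), levels = unique(cumsum(brk)))
  out <- data.frame(
    label = seg_label[brk],
    t_in = as.numeric(tapply(lo, grp, min)),
    t_out = as.numeric(tapply(hi, grp, max)),
    eta = seg_eta[brk])
  out$z <- out$t_out - out$t_in
  out$zeff <- out$z * out$eta
  rownames(out) <- NULL
  out[order(out$t_in), c("label", "t_in", "t_out", "z", "eta", "zeff")]
}

#' Export path segments as CSV
#'
#' @param segments data.frame from [trace_beam()].
#' @param path output CSV path.
#' @export
write_segments <- function(segments, path) {
  utils::write.csv(segments, path, row.names = FALSE)
  invisible(path)
}
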