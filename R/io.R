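#' Labeled point cloud
#'
#' Points in physical mm with per-point integer organ labels (0 =
#' background) and optional Hounsfield values, plus the grid origin/spacing
#' metadata the cloud was derived from.
#'
#' @param points N x 3 numeric matrix, mm.
#' @param labels integer vector of length N, >= 0; defaults to 0.
#' @param hu optional numeric vector of length N.
#' @param origin,spacing length-3 grid metadata in mm (spacing > 0).
#' @return object of class `labeled_cloud`.
#' @export
labeled_cloud <- function(points, labels = NULL, hu = NULL,
                          origin = c(0, 0, 0), spacing = c(1, 1, 1)) {
  points <- matrix(as.numeric(points), ncol = 3)
  n <- nrow(points)
  if (is.null(labels)) labels <- integer(n)
  labels <- as.integer(labels)
  if (length(labels) != n) stop("labels length must match point count")
  if (n && any(labels < 0L)) stop("labels must be >= 0")
  if (!is.null(hu)) {
    hu <- as.numeric(hu)
    if (length(hu) != n) stop("hu length must match point count")
  }
  if (any(spacing <= 0)) stop("spacing must be positive")
  structure(list(points = points, labels = labels, hu = hu,
                 origin = as.numeric(origin), spacing = as.numeric(spacing)),
            class = "labeled_cloud")
}

#' @export
print.labeled_cloud <- function(x, ...) {
  cat(sprintf("<labeled_cloud> %d points, labels: %s\n", nrow(x$points),
              paste(sort(unique(x$labels)), collapse = " ")))
  invisible(x)
}

#' Voxel grid
#'
#' A 3-D occupancy or label array with the voxel-centre convention: the
#' physical coordinate of voxel (i, j, k) (0-based) is
#' `origin + (i, j, k) * spacing`.
#'
#' @param values 3-D array (numeric or integer).
#' @param origin,spacing length-3, mm (spacing > 0).
#' @return object of class `voxel_grid`.
#' @export
voxel_grid <- function(values, origin = c(0, 0, 0), spacing = c(1, 1, 1)) {
  if (length(dim(values)) != 3L) stop("values must be a 3-D array")
  if (any(spacing <= 0)) stop("spacing must be positive")
  structure(list(values = values, origin = as.numeric(origin),
                 spacing = as.numeric(spacing)),
            class = "voxel_grid")
}

#' CT label/HU volume to labeled point cloud
#'
#' Dual-condition filtering: a voxel is retained when its label belongs to
#' `target_labels` or its HU value lies in `hu_range`. Voxels retained only
#' by the HU condition are masked to background (label 0). Indices map to
#' physical mm by `origin + index * spacing` with 0-based indices.
#'
#' @param label_volume 3-D integer array of organ labels.
#' @param hu_volume 3-D numeric array of HU values, same shape (or NULL to
#'   disable the HU condition).
#' @param origin,spacing grid metadata, mm.
#' @param target_labels integer vector of organ labels to keep.
#' @param hu_range length-2 numeric `(low, high)`, the HU retention window.
#' @return a [labeled_cloud()].
#' @export
volume_to_cloud <- function(label_volume, hu_volume = NULL,
                            origin = c(0, 0, 0), spacing = c(1, 1, 1),
                            target_labels = integer(0),
                            hu_range = c(-Inf, -Inf)) {
  if (!is.null(hu_volume) && !identical(dim(label_volume), dim(hu_volume)))
    stop("label and HU volumes must share the same shape")
  if (hu_range[1] > hu_range[2]) stop("hu_range low must be <= high")
  keep_label <- array(label_volume %in% target_labels, dim(label_volume))
  keep_hu <- if (is.null(hu_volume)) {
    array(FALSE, dim(label_volume))
  } else {
    hu_volume >= hu_range[1] & hu_volume <= hu_range[2]
  }
  keep <- keep_label | keep_hu
  idx <- which(keep, arr.ind = TRUE)   # 1-based
  pts <- sweep(sweep(idx - 1, 2, spacing, `*`), 2, origin, `+`)
  labs <- ifelse(keep_label[keep], label_volume[keep], 0L)
  hu <- if (is.null(hu_volume)) NULL else hu_volume[keep]
  labeled_cloud(pts, labels = labs, hu = hu, origin = origin,
                spacing = spacing)
}

# ---------------------------------------------------------------------------
# Cloud readers/writers: XYZ ("x y z [hu] [label]", '#' comments) and
# ascii PLY.

#' Write a labeled point cloud to XYZ or PLY
#'
#' Format chosen from the file extension (`.xyz`/`.txt` or `.ply`).
#'
#' @param cloud a [labeled_cloud()].
#' @param path output path.
#' @export
write_cloud <- function(cloud, path) {
  ext <- tolower(tools::file_ext(path))
  n <- nrow(cloud$points)
  hu <- if (is.null(cloud$hu)) rep(0, n) else cloud$hu
  if (ext == "ply") {
    hdr <- c("ply", "format ascii 1.0", paste("element vertex", n),
             "property float x", "property float y", "property float z",
             "property float hu", "property int label", "end_header")
    body <- if (n) sprintf("%.9g %.9g %.9g %.9g %d", cloud$points[, 1],
                           cloud$points[, 2], cloud$points[, 3], hu,
                           cloud$labels) else character(0)
    writeLines(c(hdr, body), path)
  } else {
    hdr <- "# x y z hu label"
    body <- if (n) sprintf("%.9g %.9g %.9g %.9g %d", cloud$points[, 1],
                           cloud$points[, 2], cloud$points[, 3], hu,
                           cloud$labels) else character(0)
    writeLines(c(hdr, body), path)
  }
  invisible(path)
}

#' Read a labeled point cloud from XYZ or PLY
#'
#' XYZ lines are whitespace-separated `x y z [hu] [label]`; `#` starts a
#' comment. PLY must be ascii; missing label properties default to 0 with a
#' warning.
#'
#' @param path input path.
#' @return a [labeled_cloud()].
#' @export
read_cloud <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") .read_cloud_ply(path) else .read_cloud_xyz(path)
}

.read_cloud_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  keep <- which(nzchar(lines))
  if (!length(keep)) return(labeled_cloud(matrix(0, 0, 3)))
  rows <- strsplit(lines[keep], "[[:space:]]+")
  nf <- lengths(rows)
  bad <- which(nf < 3L)
  if (length(bad))
    stop(sprintf("parse error in %s at line %d: fewer than 3 fields",
                 path, keep[bad[1]]))
  vals <- suppressWarnings(lapply(rows, as.numeric))
  if (any(vapply(vals, anyNA, logical(1)))) {
    bad <- which(vapply(vals, anyNA, logical(1)))[1]
    stop(sprintf("parse error in %s at line %d: non-numeric field",
                 path, keep[bad]))
  }
  pts <- t(vapply(vals, function(v) v[1:3], numeric(3)))
  hu <- if (all(nf >= 4L)) vapply(vals, `[`, numeric(1), 4) else NULL
  labs <- if (all(nf >= 5L)) as.integer(vapply(vals, `[`, numeric(1), 5))
          else integer(nrow(pts))
  labeled_cloud(pts, labels = labs, hu = hu)
}

.read_cloud_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  end <- match("end_header", trimws(lines))
  if (is.na(end) || trimws(lines[1]) != "ply")
    stop("parse error in ", path, ": not an ascii PLY file (line 1)")
  hdr <- trimws(lines[seq_len(end)])
  nvert <- as.integer(sub("element vertex\\s+", "",
                          grep("^element vertex", hdr, value = TRUE)[1]))
  props <- sub("^property\\s+\\S+\\s+", "", grep("^property", hdr,
                                                 value = TRUE))
  body <- lines[end + seq_len(nvert)]
  rows <- strsplit(trimws(body), "[[:space:]]+")
  vals <- suppressWarnings(lapply(rows, as.numeric))
  col <- function(name) {
    i <- match(name, props)
    if (is.na(i)) NULL else vapply(vals, `[`, numeric(1), i)
  }
  if (nvert == 0)
    return(labeled_cloud(matrix(0, 0, 3)))
  pts <- cbind(col("x"), col("y"), col("z"))
  labs <- col("label")
  if (is.null(labs)) {
    warning("PLY file has no label property; labels default to 0")
    labs <- integer(nvert)
  }
  labeled_cloud(pts, labels = as.integer(labs), hu = col("hu"))
}

# ---------------------------------------------------------------------------
# Mesh readers/writers: OBJ (1-based indices, quads fan-triangulated with a
# warning), ascii PLY, ascii STL.

#' Write a surface mesh to OBJ, PLY or STL
#'
#' @param mesh a [surface_mesh()].
#' @param path output path; extension selects the format.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  V <- mesh$vertices; F <- mesh$faces
  if (ext == "obj") {
    writeLines(c(sprintf("v %.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]),
                 sprintf("f %d %d %d", F[, 1], F[, 2], F[, 3])), path)
  } else if (ext == "ply") {
    hdr <- c("ply", "format ascii 1.0",
             paste("element vertex", nrow(V)),
             "property float x", "property float y", "property float z",
             paste("element face", nrow(F)),
             "property list uchar int vertex_indices", "end_header")
    writeLines(c(hdr, sprintf("%.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]),
                 sprintf("3 %d %d %d", F[, 1] - 1L, F[, 2] - 1L,
                         F[, 3] - 1L)), path)
  } else if (ext == "stl") {
    n <- face_normals(mesh)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid meshdose", con)
    for (i in seq_len(nrow(F))) {
      writeLines(c(sprintf("facet normal %.9g %.9g %.9g", n[i, 1], n[i, 2],
                           n[i, 3]),
                   " outer loop",
                   sprintf("  vertex %.9g %.9g %.9g", V[F[i, ], 1],
                           V[F[i, ], 2], V[F[i, ], 3]),
                   " endloop", "endfacet"), con)
    }
    writeLines("endsolid meshdose", con)
  } else stop("unsupported mesh format: .", ext)
  invisible(path)
}

#' Read a surface mesh from OBJ, PLY or STL
#'
#' Triangles only; OBJ quad faces are fan-triangulated with a warning.
#'
#' @param path input path; extension selects the format.
#' @return a [surface_mesh()].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         obj = .read_mesh_obj(path),
         ply = .read_mesh_ply(path),
         stl = .read_mesh_stl(path),
         stop("unsupported mesh format: .", ext))
}

.read_mesh_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (!length(vl)) stop("parse error in ", path, ": no vertices (not a mesh?)")
  V <- t(vapply(strsplit(trimws(sub("^v", "", vl)), "[[:space:]]+"),
                function(v) as.numeric(v[1:3]), numeric(3)))
  faces <- list(); quads <- FALSE
  for (f in fl) {
    tok <- strsplit(trimws(sub("^f", "", f)), "[[:space:]]+")[[1]]
    idx <- as.integer(sub("/.*$", "", tok))  # drop texture/normal refs
    if (anyNA(idx)) stop("parse error in ", path, ": bad face line '", f, "'")
    idx <- ifelse(idx < 0, nrow(V) + idx + 1L, idx)  # negative = relative
    if (length(idx) == 3L) {
      faces[[length(faces) + 1L]] <- idx
    } else if (length(idx) > 3L) {
      quads <- TRUE
      for (k in 2:(length(idx) - 1L))  # fan triangulation
        faces[[length(faces) + 1L]] <- idx[c(1L, k, k + 1L)]
    } else stop("parse error in ", path, ": face with <3 vertices")
  }
  if (quads) warning("non-triangular faces triangulated by fanning")
  surface_mesh(V, do.call(rbind, faces))
}

.read_mesh_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  end <- match("end_header", trimws(lines))
  if (is.na(end) || trimws(lines[1]) != "ply")
    stop("parse error in ", path, ": not an ascii PLY file")
  hdr <- trimws(lines[seq_len(end)])
  nv <- as.integer(sub("element vertex\\s+", "",
                       grep("^element vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub("element face\\s+", "",
                       grep("^element face", hdr, value = TRUE)[1]))
  vrows <- strsplit(trimws(lines[end + seq_len(nv)]), "[[:space:]]+")
  V <- t(vapply(vrows, function(v) as.numeric(v[1:3]), numeric(3)))
  frows <- strsplit(trimws(lines[end + nv + seq_len(nf)]), "[[:space:]]+")
  faces <- list(); polys <- FALSE
  for (r in frows) {
    n <- as.integer(r[1])
    idx <- as.integer(r[1 + seq_len(n)]) + 1L
    if (n == 3L) faces[[length(faces) + 1L]] <- idx
    else { polys <- TRUE
           for (k in 2:(n - 1L))
             faces[[length(faces) + 1L]] <- idx[c(1L, k, k + 1L)] }
  }
  if (polys) warning("non-triangular faces triangulated by fanning")
  surface_mesh(V, do.call(rbind, faces))
}

.read_mesh_stl <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  if (!grepl("^solid", lines[1]))
    stop("parse error in ", path, ": not an ascii STL file")
  vl <- grep("^vertex", lines, value = TRUE)
  coords <- t(vapply(strsplit(sub("^vertex\\s+", "", vl), "[[:space:]]+"),
                     function(v) as.numeric(v[1:3]), numeric(3)))
  if (nrow(coords) %% 3L != 0L)
    stop("parse error in ", path, ": vertex count not a multiple of 3")
  # merge duplicated vertices across facets
  key <- apply(coords, 1, paste, collapse = " ")
  uk <- !duplicated(key)
  V <- coords[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  F <- matrix(idx, ncol = 3, byrow = TRUE)
  surface_mesh(V, F)
}

#' Read a NIfTI label volume as a voxel grid
#'
#' Uses the file's origin and spacing; volumes with non-identity direction
#' cosines are rejected rather than silently misread.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a [voxel_grid()].
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  if (is.null(attr(xf, "code")) || isTRUE(attr(xf, "code") == 0)) {
    # no spatial transform recorded: fall back to header pixdim, origin 0
    sp <- RNifti::pixdim(img)[1:3]
    org <- c(0, 0, 0)
  } else {
    R <- xf[1:3, 1:3]
    sp <- sqrt(colSums(R^2))
    if (max(abs(R / rep(sp, each = 3) - diag(3))) > 1e-4)
      stop("NIfTI volume has non-identity direction cosines; ",
           "reorient it before loading")
    org <- xf[1:3, 4]
  }
  voxel_grid(array(as.numeric(img), dim(img)), origin = org, spacing = sp)
}
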