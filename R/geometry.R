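#' Triangle surface mesh
#'
#' Container for a closed outer cerebral-hemisphere surface: an `n x 3`
#' vertex matrix in RAS millimetres (+x subject right, +y anterior,
#' +z superior) and an `m x 3` matrix of 1-based vertex-index triples.
#'
#' The constructor validates face indices, requires at least 4 non-coplanar
#' vertices, and checks (but does not enforce) watertightness: surfaces
#' produced by surface-reconstruction pipelines are closed, while partial or
#' hand-built fixtures need not be, so a violation is a warning only.
#'
#' @param vertices numeric matrix, one row per vertex, columns x, y, z (mm).
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param side which hemisphere the surface represents: `"left"`, `"right"`,
#'   or `"whole"` for an unlabelled / combined surface.
#' @param validate run full validation (set `FALSE` only for meshes derived
#'   from an already-validated mesh by index-preserving transforms).
#' @return An object of class `trimesh`.
#' @export
trimesh <- function(vertices, faces, side = c("whole", "left", "right"),
                    validate = TRUE) {
  side <- match.arg(side)
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns (x, y, z)")
  if (ncol(faces) != 3L) stop("faces must have 3 columns (triangles only)")
  mesh <- structure(list(vertices = vertices, faces = faces, side = side),
                    class = "trimesh")
  if (validate) validate_trimesh(mesh)
  mesh
}

validate_trimesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(v) < 4L) stop("mesh needs at least 4 vertices")
  if (nrow(f) < 1L) stop("mesh has no faces")
  if (anyNA(v) || any(!is.finite(v))) stop("non-finite vertex coordinates")
  if (min(f) < 1L || max(f) > nrow(v)) stop("face index out of range")
  # non-coplanarity: centred vertex cloud must have rank 3
  ctr <- sweep(v, 2L, colMeans(v))
  s <- svd(ctr, nu = 0L, nv = 0L)$d
  if (s[3L] <= max(s[1L], .Machine$double.eps) * 1e-10)
    stop("mesh vertices are coplanar or degenerate")
  if (!is_watertight(mesh))
    warning("mesh is not watertight (open or non-manifold edges)")
  invisible(mesh)
}

#' Watertightness check
#'
#' A mesh is watertight when every edge is shared by exactly two faces with
#' opposite orientation.
#'
#' @param mesh a [trimesh].
#' @return logical scalar.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  he <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- paste(pmin(he[, 1L], he[, 2L]), pmax(he[, 1L], he[, 2L]))
  cnt <- table(key)
  if (any(cnt != 2L)) return(FALSE)
  # opposite orientation: each directed edge must appear exactly once
  dkey <- paste(he[, 1L], he[, 2L])
  !anyDuplicated(dkey)
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("<trimesh> %d vertices, %d faces, side = %s\n",
              nrow(x$vertices), nrow(x$faces), x$side))
  invisible(x)
}

# row-wise cross product of two n x 3 matrices
cross3 <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

# signed volume via divergence theorem; positive for outward-wound closed mesh
signed_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c_ <- v[f[, 3L], , drop = FALSE]
  sum(rowSums(a * cross3(b, c_))) / 6
}

#' Outward per-vertex unit normals
#'
#' Area-weighted average of the incident face normals at every vertex
#' (the unnormalised face cross products are accumulated, so a degenerate
#' zero-area face contributes zero weight). If the global winding of the
#' closed mesh is inward (negative signed volume) all normals are flipped so
#' that they point outward.
#'
#' @param mesh a [trimesh].
#' @return numeric `n x 3` matrix of unit vectors, one row per vertex.
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  e2 <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  fn <- cross3(e1, e2)                       # |fn| = 2 * face area
  idx <- c(f[, 1L], f[, 2L], f[, 3L])
  acc <- rowsum(rbind(fn, fn, fn), group = idx)
  touched <- as.integer(rownames(acc))
  if (length(touched) != nrow(v))
    stop("mesh has isolated vertices (no incident face)")
  n <- matrix(0, nrow(v), 3L)
  n[touched, ] <- acc
  len <- sqrt(rowSums(n * n))
  if (any(len == 0))
    stop("vertex with only degenerate incident faces")
  n <- n / len
  if (signed_volume(mesh) < 0) n <- -n
  n
}

#' Axis-aligned bounding box
#'
#' Smallest axis-aligned rectangular parallelepiped enclosing the surface.
#' Extents are named by the anatomical axes: `length` is the antero-posterior
#' (y) extent, `height` the dorso-ventral (z) extent and `width` the
#' latero-medial (x) extent. A per-subject uniform scale factor (mapping
#' normalized to native space) multiplies all coordinates.
#'
#' @param mesh a [trimesh].
#' @param scale positive uniform scale factor, default 1 (already native mm).
#' @return An object of class `box3` with fields `min`, `max` (scaled
#'   corners) and `length`, `height`, `width` (mm).
#' @export
bounding_box <- function(mesh, scale = 1) {
  stopifnot(is.numeric(scale), length(scale) == 1L, scale > 0)
  v <- mesh$vertices
  if (nrow(v) == 0L) stop("empty mesh")
  mn <- apply(v, 2L, min) * scale
  mx <- apply(v, 2L, max) * scale
  ext <- mx - mn
  structure(list(min = mn, max = mx,
                 width = ext[1L], length = ext[2L], height = ext[3L]),
            class = "box3")
}

#' @export
print.box3 <- function(x, ...) {
  cat(sprintf("<box3> length %.2f, height %.2f, width %.2f mm\n",
              x$length, x$height, x$width))
  invisible(x)
}

#' Frontal or occipital pole of a hemisphere surface
#'
#' The pole is the single mesh vertex with extreme antero-posterior (y)
#' coordinate: maximal y for the anterior (frontal) pole, minimal y for the
#' posterior (occipital) pole. Ties are broken deterministically by the
#' lowest vertex index.
#'
#' @param mesh a [trimesh].
#' @param direction `"anterior"` or `"posterior"`.
#' @return numeric length-3 point (mm), with the vertex index as attribute
#'   `"index"`.
#' @export
extract_pole <- function(mesh, direction = c("anterior", "posterior")) {
  direction <- match.arg(direction)
  y <- mesh$vertices[, 2L]
  i <- if (direction == "anterior") which.max(y) else which.min(y)
  structure(mesh$vertices[i, ], index = i)
}

#' Rigid transform of a mesh
#'
#' Maps every vertex v to `R v + t`. Faces are unchanged (a proper rotation
#' preserves orientation).
#'
#' @param mesh a [trimesh].
#' @param rotation 3 x 3 proper orthonormal matrix (determinant +1).
#' @param translation numeric length-3 vector (mm), default zero.
#' @return the transformed [trimesh].
#' @export
rigid_transform <- function(mesh, rotation = diag(3),
                            translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!isTRUE(all.equal(crossprod(rotation), diag(3), tolerance = 1e-8)) ||
      abs(det(rotation) - 1) > 1e-8)
    stop("rotation must be orthonormal with determinant +1")
  v <- mesh$vertices %*% t(rotation)
  v <- sweep(v, 2L, translation, "+")
  out <- mesh
  out$vertices <- v
  out
}

#' Rotation matrix about an axis
#'
#' Rodrigues rotation by `angle_deg` degrees about `axis` (need not be unit).
#'
#' @param axis numeric length-3 rotation axis.
#' @param angle_deg rotation angle in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_matrix <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3L], -a[2L],
                -a[3L], 0, a[1L],
                a[2L], -a[1L], 0), 3L, 3L)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Mirror a mesh across the mid-sagittal plane x = 0
#'
#' Negates x coordinates, flips the face winding so the surface orientation
#' stays outward, and swaps the hemisphere label. Mirroring twice is the
#' identity. Used for the anti-symmetry properties of all signed torque
#' metrics.
#'
#' @param mesh a [trimesh].
#' @return mirrored [trimesh].
#' @export
mirror_x <- function(mesh) {
  v <- mesh$vertices
  v[, 1L] <- -v[, 1L]
  f <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
  side <- switch(mesh$side, left = "right", right = "left", whole = "whole")
  trimesh(v, f, side = side, validate = FALSE)
}
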