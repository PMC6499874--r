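# Mesh fixtures built in code, plus naive brute-force oracles kept
# deliberately independent of the package's vectorised implementations.

# flip face winding if the closed mesh is wound inward
orient_outward <- function(mesh) {
  if (braintorque:::signed_volume(mesh) < 0)
    mesh$faces <- mesh$faces[, c(1L, 3L, 2L)]
  mesh
}

# watertight UV sphere, poles on the z axis
uv_sphere <- function(n_th = 24L, n_ph = 12L, radius = 1,
                      center = c(0, 0, 0)) {
  th <- 2 * pi * (seq_len(n_th) - 1L) / n_th
  verts <- matrix(c(0, 0, radius), 1L, 3L)
  starts <- integer(n_ph - 1L)
  for (j in seq_len(n_ph - 1L)) {
    phi <- pi * j / n_ph
    starts[j] <- nrow(verts) + 1L
    verts <- rbind(verts, radius * cbind(sin(phi) * cos(th),
                                         sin(phi) * sin(th), cos(phi)))
  }
  bottom <- nrow(verts) + 1L
  verts <- rbind(verts, c(0, 0, -radius))
  i <- 0:(n_th - 1L); ip <- c(1:(n_th - 1L), 0L)
  faces <- cbind(1L, starts[1L] + i, starts[1L] + ip)
  for (j in seq_len(n_ph - 2L))
    faces <- rbind(faces,
                   cbind(starts[j] + i, starts[j + 1L] + i,
                         starts[j + 1L] + ip),
                   cbind(starts[j] + i, starts[j + 1L] + ip,
                         starts[j] + ip))
  last <- starts[n_ph - 1L]
  faces <- rbind(faces, cbind(bottom, last + ip, last + i))
  verts <- sweep(verts, 2L, center, "+")
  orient_outward(trimesh(verts, faces, validate = FALSE))
}

# ellipsoid with semi-axes (a, b, c): scaled uv sphere
ellipsoid_mesh <- function(a, b, c_, n_th = 32L, n_ph = 16L,
                           center = c(0, 0, 0)) {
  m <- uv_sphere(n_th, n_ph)
  m$vertices <- sweep(m$vertices %*% diag(c(a, b, c_)), 2L, center, "+")
  m
}

# axis-aligned unit cube [0,1]^3 with an n x n vertex grid per face, welded
cube_mesh <- function(n = 4L) {
  g <- seq(0, 1, length.out = n + 1L)
  quads <- list()
  face_grid <- function(fixed_axis, fixed_val, flip) {
    pts <- as.matrix(expand.grid(u = g, v = g))
    coords <- matrix(NA_real_, nrow(pts), 3L)
    other <- setdiff(1:3, fixed_axis)
    coords[, fixed_axis] <- fixed_val
    coords[, other[1L]] <- pts[, 1L]
    coords[, other[2L]] <- pts[, 2L]
    idx <- function(iu, iv) (iv - 1L) * (n + 1L) + iu
    f <- list()
    for (iu in seq_len(n)) for (iv in seq_len(n)) {
      q <- c(idx(iu, iv), idx(iu + 1L, iv), idx(iu + 1L, iv + 1L),
             idx(iu, iv + 1L))
      if (flip) q <- rev(q)
      f[[length(f) + 1L]] <- rbind(q[c(1L, 2L, 3L)], q[c(1L, 3L, 4L)])
    }
    list(coords = coords, faces = do.call(rbind, f))
  }
  verts <- NULL; faces <- NULL
  for (spec in list(list(1L, 0, TRUE), list(1L, 1, FALSE),
                    list(2L, 0, FALSE), list(2L, 1, TRUE),
                    list(3L, 0, TRUE), list(3L, 1, FALSE))) {
    fg <- face_grid(spec[[1L]], spec[[2L]], spec[[3L]])
    off <- if (is.null(verts)) 0L else nrow(verts)
    verts <- rbind(verts, fg$coords)
    faces <- rbind(faces, fg$faces + off)
  }
  # weld duplicate vertices along cube edges
  key <- apply(round(verts, 9L), 1L, paste, collapse = ",")
  uniq <- !duplicated(key)
  remap <- match(key, key[uniq])
  verts <- verts[uniq, , drop = FALSE]
  faces <- matrix(remap[faces], ncol = 3L)
  orient_outward(trimesh(verts, faces, validate = FALSE))
}

# brute-force per-vertex normal oracle: plain loops, no shared code
naive_vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  acc <- matrix(0, nrow(v), 3L)
  for (k in seq_len(nrow(f))) {
    p1 <- v[f[k, 1L], ]; p2 <- v[f[k, 2L], ]; p3 <- v[f[k, 3L], ]
    e1 <- p2 - p1; e2 <- p3 - p1
    fn <- c(e1[2L] * e2[3L] - e1[3L] * e2[2L],
            e1[3L] * e2[1L] - e1[1L] * e2[3L],
            e1[1L] * e2[2L] - e1[2L] * e2[1L])
    for (j in 1:3) acc[f[k, j], ] <- acc[f[k, j], ] + fn
  }
  acc / sqrt(rowSums(acc^2))
}

# symmetric synthetic brain at a given mesh resolution
sym_brain <- function(resolution = 32L, subject_id = "sym", ...) {
  r <- make_hemisphere("right", resolution = resolution, ...)
  brain_surface(mirror_x(r), r, subject_id = subject_id)
}

# small watertight tetrahedron with a duplicated max-y coordinate
tie_tetra <- function() {
  v <- rbind(c(0, 1, 0), c(1, 1, 0), c(0.5, 0, 1), c(0.5, 0, -1))
  f <- rbind(c(1L, 2L, 3L), c(2L, 1L, 4L), c(3L, 2L, 4L), c(1L, 3L, 4L))
  orient_outward(trimesh(v, f, validate = FALSE))
}
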