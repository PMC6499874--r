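#' Per-subject pair of hemisphere surfaces
#'
#' The unit of analysis: left and right closed outer hemisphere surfaces in
#' a common RAS-like frame (the left hemisphere predominantly at x < 0),
#' with an optional uniform scale factor mapping normalized coordinates back
#' to native-space millimetres.
#'
#' @param left,right [trimesh] objects; `side` labels must match.
#' @param scale positive uniform scale factor applied to all mm measures.
#' @param subject_id free-text identifier.
#' @param species one of `"human"`, `"chimpanzee"`, `"synthetic"`.
#' @param sex optional `"male"` / `"female"`.
#' @return An object of class `brain_surface` with an `aligned` flag
#'   (initially `FALSE`) recording whether the mid-sagittal plane has been
#'   brought to x = 0.
#' @export
brain_surface <- function(left, right, scale = 1, subject_id = "subject",
                          species = c("synthetic", "human", "chimpanzee"),
                          sex = NULL) {
  species <- match.arg(species)
  stopifnot(inherits(left, "trimesh"), inherits(right, "trimesh"))
  if (left$side != "left") stop("'left' mesh must have side = \"left\"")
  if (right$side != "right") stop("'right' mesh must have side = \"right\"")
  stopifnot(is.numeric(scale), length(scale) == 1L, scale > 0)
  structure(list(left = left, right = right, scale = scale,
                 aligned = FALSE, alignment_angle = NA_real_,
                 subject_id = subject_id, species = species, sex = sex),
            class = "brain_surface")
}

#' @export
print.brain_surface <- function(x, ...) {
  cat(sprintf(
    "<brain_surface> %s (%s)%s, scale %.4g, %s\n  left:  %d vertices\n  right: %d vertices\n",
    x$subject_id, x$species, if (is.null(x$sex)) "" else paste0(", ", x$sex),
    x$scale,
    if (x$aligned) sprintf("aligned (residual %.2g deg)", x$alignment_angle)
    else "not aligned",
    nrow(x$left$vertices), nrow(x$right$vertices)))
  invisible(x)
}

#' Mirror a whole brain across x = 0
#'
#' Swaps the hemispheres (each mirrored with [mirror_x]); every signed
#' torque metric of the result is the negation of the original's.
#'
#' @param brain a [brain_surface].
#' @return the mirrored [brain_surface].
#' @export
mirror_brain <- function(brain) {
  out <- brain
  out$left <- mirror_x(brain$right)
  out$right <- mirror_x(brain$left)
  out
}

# union vertex cloud of both hemispheres
brain_vertices <- function(brain) {
  rbind(brain$left$vertices, brain$right$vertices)
}

# whole-brain y range
brain_y_range <- function(brain) range(brain_vertices(brain)[, 2L])

#' Medial-surface vertex selection
#'
#' Vertices belonging to the medial wall of a hemisphere are identified from
#' their outward normals: the medial wall faces the inter-hemispheric
#' fissure, so its normals are nearly parallel to the left-right axis. For a
#' labelled hemisphere the angle is taken to the *midline-pointing* axis
#' (+x for the left hemisphere, -x for the right), which excludes the
#' lateral convexity (whose normals also align with x but point away from
#' the midline). For an unlabelled (`side = "whole"`) mesh the criterion
#' falls back to the folded angle `arccos(|n . x|)`, which selects both
#' x-facing regions.
#'
#' @param mesh a [trimesh].
#' @param theta_max selection threshold in degrees (default 40): a vertex is
#'   medial when its normal's angle to the reference axis is below it.
#' @param normals optional precomputed [vertex_normals] matrix.
#' @return An object of class `medial_selection`: list with `indices`,
#'   `theta` (angles in degrees for all vertices), `theta_max`, `side`.
#' @export
medial_vertices <- function(mesh, theta_max = 40, normals = NULL) {
  stopifnot(theta_max > 0, theta_max <= 90)
  if (is.null(normals)) normals <- vertex_normals(mesh)
  nx <- switch(mesh$side,
               left  = normals[, 1L],
               right = -normals[, 1L],
               whole = abs(normals[, 1L]))
  theta <- acos(pmin(1, pmax(-1, nx))) * 180 / pi
  # a 90-degree threshold is vacuous for the folded criterion: select all
  idx <- if (theta_max >= 90 && mesh$side == "whole") seq_along(theta)
         else which(theta < theta_max)
  if (length(idx) == 0L)
    stop("no medial vertices selected; increase theta_max (currently ",
         theta_max, " degrees)")
  structure(list(indices = idx, theta = theta, theta_max = theta_max,
                 side = mesh$side),
            class = "medial_selection")
}

#' Total-least-squares plane fit
#'
#' Fits the plane minimising the sum of squared orthogonal distances: it
#' passes through the centroid and its normal is the direction of smallest
#' variance (last right singular vector of the centred point matrix). The
#' normal is canonicalised so its x component is >= 0 (first nonzero
#' component positive when x is numerically zero), removing the sign
#' ambiguity of the fit.
#'
#' @param points numeric `n x 3` matrix, `n >= 3`, not collinear.
#' @return An object of class `plane3`: list with unit `normal`, `point`
#'   (the centroid) and `rms` orthogonal residual.
#' @export
fit_plane <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3L) stop("need at least 3 points to fit a plane")
  ctr <- colMeans(points)
  x <- sweep(points, 2L, ctr)
  s <- svd(x, nu = 0L)
  if (s$d[2L] <= max(s$d[1L], .Machine$double.eps) * 1e-10)
    stop("points are collinear; plane is undetermined")
  n <- s$v[, 3L]
  n <- n / sqrt(sum(n^2))
  # canonical sign: x component >= 0
  flip <- if (abs(n[1L]) > 1e-12) n[1L] < 0
          else if (abs(n[2L]) > 1e-12) n[2L] < 0 else n[3L] < 0
  if (flip) n <- -n
  structure(list(normal = n, point = ctr,
                 rms = s$d[3L] / sqrt(nrow(points))),
            class = "plane3")
}

#' @export
print.plane3 <- function(x, ...) {
  cat(sprintf("<plane3> normal (%.4f, %.4f, %.4f), point (%.2f, %.2f, %.2f)\n",
              x$normal[1L], x$normal[2L], x$normal[3L],
              x$point[1L], x$point[2L], x$point[3L]))
  invisible(x)
}

# angle in degrees between a plane3 normal and the x axis (normal has x >= 0)
plane_angle_to_x <- function(plane) {
  acos(pmin(1, abs(plane$normal[1L]))) * 180 / pi
}

#' Estimate the mid-sagittal plane
#'
#' Fits a total-least-squares plane to the pooled medial-surface vertices of
#' both hemispheres, restricted to the central portion of the brain along
#' the antero-posterior axis (the middle `central_fraction` of the
#' whole-brain y range), where frontal/occipital bending deviates least from
#' a flat midline.
#'
#' @param brain a [brain_surface].
#' @param central_fraction proportion of the whole-brain y range retained,
#'   centred on its midpoint (default 0.5).
#' @param theta_max medial-selection threshold in degrees (default 40).
#' @param min_vertices minimum pooled medial vertices required (default 50).
#' @return a [fit_plane] `plane3`.
#' @export
estimate_msp <- function(brain, central_fraction = 0.5, theta_max = 40,
                         min_vertices = 50L) {
  stopifnot(central_fraction > 0, central_fraction <= 1)
  yr <- brain_y_range(brain)
  half_cut <- (1 - central_fraction) / 2 * diff(yr)
  lo <- yr[1L] + half_cut
  hi <- yr[2L] - half_cut
  pts <- lapply(list(brain$left, brain$right), function(mesh) {
    sel <- medial_vertices(mesh, theta_max = theta_max)
    v <- mesh$vertices[sel$indices, , drop = FALSE]
    v[v[, 2L] >= lo & v[, 2L] <= hi, , drop = FALSE]
  })
  pts <- do.call(rbind, pts)
  if (nrow(pts) < min_vertices)
    stop(sprintf(
      "only %d medial vertices in the central band (need >= %d); increase theta_max or central_fraction",
      nrow(pts), min_vertices))
  fit_plane(pts)
}

#' Align a brain so its mid-sagittal plane is x = 0
#'
#' Rotates both hemispheres about the axis `msp_normal x x_hat` through the
#' fitted plane's point by the angle between the estimated mid-sagittal
#' plane and the plane x = 0, then translates along x so the plane contains
#' the origin. Because the rotation changes the vertex normals and hence the
#' medial selection, the estimate-and-rotate step is repeated until the
#' residual angle falls below `tol` or `max_iter` is reached (small residual
#' misalignments converge in one or two iterations).
#'
#' @param brain a [brain_surface].
#' @param tol convergence tolerance on the residual plane angle, degrees.
#' @param max_iter maximum estimate-and-rotate iterations.
#' @param central_fraction,theta_max passed to [estimate_msp].
#' @return the aligned [brain_surface] (`aligned = TRUE`,
#'   `alignment_angle` = final residual in degrees). Warns and returns the
#'   last iterate if the tolerance is not reached.
#' @export
align_to_msp <- function(brain, tol = 0.01, max_iter = 5L,
                         central_fraction = 0.5, theta_max = 40) {
  xhat <- c(1, 0, 0)
  plane <- estimate_msp(brain, central_fraction, theta_max)
  ang <- plane_angle_to_x(plane)
  iter <- 0L
  while (ang >= tol && iter < max_iter) {
    axis <- c(plane$normal[2L] * xhat[3L] - plane$normal[3L] * xhat[2L],
              plane$normal[3L] * xhat[1L] - plane$normal[1L] * xhat[3L],
              plane$normal[1L] * xhat[2L] - plane$normal[2L] * xhat[1L])
    # axis = n x xhat rotates n towards xhat by +ang
    R <- rotation_matrix(axis, ang)
    p0 <- plane$point
    for (h in c("left", "right")) {
      m <- brain[[h]]
      m$vertices <- sweep(sweep(m$vertices, 2L, p0) %*% t(R), 2L, p0, "+")
      brain[[h]] <- m
    }
    plane <- estimate_msp(brain, central_fraction, theta_max)
    ang <- plane_angle_to_x(plane)
    iter <- iter + 1L
  }
  # translate along x so the MSP contains the origin
  dx <- sum(plane$normal * plane$point) / max(plane$normal[1L], 1e-12)
  brain$left$vertices[, 1L] <- brain$left$vertices[, 1L] - dx
  brain$right$vertices[, 1L] <- brain$right$vertices[, 1L] - dx
  if (ang >= tol)
    warning(sprintf(
      "MSP alignment did not reach %.3g deg after %d iterations (residual %.3g deg)",
      tol, max_iter, ang))
  brain$aligned <- TRUE
  brain$alignment_angle <- ang
  brain
}
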