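# run code with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic hemisphere surface
#'
#' Builds one closed hemisphere as half of a superellipsoid
#' `|x/a|^e + |y/b|^e + |z/c|^e = 1` cut at the mid-sagittal plane, with a
#' flat medial wall offset by half the inter-hemispheric gap, capped and
#' triangulated so the mesh is watertight. The default semi-axes
#' (67, 87, 59) mm give whole-brain bounding-box extents close to the adult
#' human mean (length ~175, height ~118, width ~135 mm); the exponent
#' (default 2.5) makes the surface boxier than an ellipsoid, mimicking a
#' smoothed outer cerebral surface without gyrification (irrelevant here:
#' the pipeline consumes closed outer surfaces).
#'
#' @param side `"left"` or `"right"`.
#' @param semi_axes positive semi-axes (x, y, z) in mm.
#' @param resolution azimuthal divisions (>= 16; rounded up to a multiple
#'   of 4 so the extreme lattice points lie exactly on the axes).
#' @param exponent superellipsoid exponent, >= 2.
#' @param gap full inter-hemispheric gap in mm (wall at x = +/- gap/2).
#' @return a watertight [trimesh].
#' @export
make_hemisphere <- function(side = c("right", "left"),
                            semi_axes = c(67, 87, 59),
                            resolution = 48L, exponent = 2.5, gap = 1) {
  side <- match.arg(side)
  stopifnot(length(semi_axes) == 3L, all(semi_axes > 0), gap >= 0)
  if (resolution < 16L) stop("resolution must be >= 16")
  if (exponent < 2) stop("superellipsoid exponent must be >= 2")
  n_th <- 4L * ceiling(resolution / 4)
  n_ph <- max(8L, n_th %/% 2L)
  n_dk <- max(2L, n_th %/% 4L)
  a <- semi_axes[1L]; b <- semi_axes[2L]; c_ <- semi_axes[3L]
  e <- exponent
  th <- 2 * pi * (seq_len(n_th) - 1L) / n_th
  radial <- function(d) {                 # map unit direction to surface
    r <- (abs(d[, 1L] / a)^e + abs(d[, 2L] / b)^e +
            abs(d[, 3L] / c_)^e)^(-1 / e)
    d * r
  }
  verts <- matrix(c(a, 0, 0), 1L, 3L)     # apex on +x
  ring_start <- integer(n_ph)             # index of first vertex of ring j
  for (j in seq_len(n_ph)) {
    phi <- (pi / 2) * j / n_ph
    d <- cbind(cos(phi), sin(phi) * cos(th), sin(phi) * sin(th))
    ring_start[j] <- nrow(verts) + 1L
    verts <- rbind(verts, radial(d))
  }
  rim <- verts[ring_start[n_ph] + 0:(n_th - 1L), , drop = FALSE]  # x = 0
  disk_start <- integer(n_dk - 1L)        # shrinking wall rings
  if (n_dk > 1L) for (k in (n_dk - 1L):1L) {
    disk_start[k] <- nrow(verts) + 1L
    verts <- rbind(verts, rim * (k / n_dk))
  }
  center <- nrow(verts) + 1L
  verts <- rbind(verts, c(0, 0, 0))

  quad_band <- function(s1, s2) {         # two rings of n_th vertices
    i <- 0:(n_th - 1L)
    ip <- c(1:(n_th - 1L), 0L)
    rbind(cbind(s1 + i, s2 + i, s2 + ip),
          cbind(s1 + i, s2 + ip, s1 + ip))
  }
  faces <- cbind(1L, ring_start[1L] + 0:(n_th - 1L),
                 ring_start[1L] + c(1:(n_th - 1L), 0L))
  for (j in seq_len(n_ph - 1L))
    faces <- rbind(faces, quad_band(ring_start[j], ring_start[j + 1L]))
  wall_rings <- c(ring_start[n_ph], disk_start)
  for (k in seq_len(length(wall_rings) - 1L))
    faces <- rbind(faces, quad_band(wall_rings[k], wall_rings[k + 1L]))
  last <- wall_rings[length(wall_rings)]
  faces <- rbind(faces, cbind(center, last + c(1:(n_th - 1L), 0L),
                              last + 0:(n_th - 1L)))
  verts[, 1L] <- verts[, 1L] + gap / 2
  mesh <- trimesh(verts, faces, side = "right", validate = FALSE)
  if (signed_volume(mesh) < 0)
    mesh$faces <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
  validate_trimesh(mesh)
  if (side == "left") mirror_x(mesh) else mesh
}

#' Ground-truth deformation parameters for a synthetic subject
#'
#' All torque features the generator can inject, in measurement units:
#' petalia/shift in mm (L-R pole differences), bending in degrees
#' (rightward positive), dimensional asymmetries dL/dH/dW in mm (left minus
#' right), a rigid mid-sagittal tilt in degrees, a global size factor, and
#' i.i.d. Gaussian vertex noise in mm.
#'
#' @param petalia_frontal,petalia_occipital,shift_frontal,shift_occipital
#'   target pole asymmetries, mm.
#' @param bend_frontal,bend_occipital target regional bending, degrees.
#' @param dL,dH,dW left-hemisphere dimensional offsets, mm.
#' @param msp_tilt rigid rotation about the vertical axis, degrees.
#' @param global_scale uniform size factor (> 0).
#' @param noise_sd vertex noise standard deviation, mm (>= 0).
#' @param seed optional integer seed for the noise.
#' @return named list of class `torque_params`.
#' @export
torque_params <- function(petalia_frontal = 0, petalia_occipital = 0,
                          shift_frontal = 0, shift_occipital = 0,
                          bend_frontal = 0, bend_occipital = 0,
                          dL = 0, dH = 0, dW = 0,
                          msp_tilt = 0, global_scale = 1, noise_sd = 0,
                          seed = NULL) {
  p <- list(petalia_frontal = petalia_frontal,
            petalia_occipital = petalia_occipital,
            shift_frontal = shift_frontal,
            shift_occipital = shift_occipital,
            bend_frontal = bend_frontal, bend_occipital = bend_occipital,
            dL = dL, dH = dH, dW = dW, msp_tilt = msp_tilt,
            global_scale = global_scale, noise_sd = noise_sd, seed = seed)
  num <- unlist(p[setdiff(names(p), "seed")])
  stopifnot(all(is.finite(num)), global_scale > 0, noise_sd >= 0)
  structure(p, class = "torque_params")
}

# cosine ramp: 0 at y0, 1 at y1 with zero slope at both ends
cos_ramp <- function(y, y0, y1) {
  t <- pmin(1, pmax(0, (y - y0) / (y1 - y0)))
  0.5 * (1 - cos(pi * t))
}

#' Inject torque into a symmetric brain
#'
#' Deforms a (typically symmetric) brain by composing, in order:
#' (1) anisotropic left-hemisphere scaling realising dL/dH/dW (the
#' latero-medial scaling is anchored at the medial wall so the
#' inter-hemispheric gap is preserved); (2) smooth antero-posterior
#' displacement fields, tapering with a cosine ramp over the outer 40% of
#' the y range and split +/- between the hemispheres, realising petalia;
#' (3) the analogous dorso-ventral fields for shift; (4) a y-graded lateral
#' displacement of *both* hemispheres over each outer quarter of the
#' y range, with slope `tan(angle)`, realising the bending angles; (5) a
#' global size factor; (6) a rigid tilt about the vertical axis through the
#' brain centroid; (7) i.i.d. Gaussian vertex noise (seeded).
#'
#' Because the frontal/occipital poles are the extreme-y vertices, the
#' bounding-box length asymmetry is *identically* the difference of the two
#' petalia (dL = petalia_frontal - petalia_occipital for any brain), so dL
#' cannot be injected independently of petalia: the dL scaling also moves
#' the poles. The returned `truth` therefore records the *net* ground-truth
#' values the composed deformation realises (e.g. petalia_frontal + dL/2),
#' which is what the measurement pipeline should recover. One coupling is
#' deliberately *not* folded into the truth: bending moves midline tissue
#' across x = 0, which widens the bent-into hemisphere's bounding box by up
#' to `tan(angle) * quarter length` — a property of bounding-box width on
#' any bent brain, not a generator artefact — so `truth$dW` records only
#' the injected scaling offset.
#'
#' @param brain a [brain_surface], e.g. a mirror-symmetric pair from
#'   [make_hemisphere].
#' @param params a [torque_params].
#' @return the deformed [brain_surface] with a `truth` element: named list
#'   of net ground-truth metric values (mm scaled by `global_scale`, angles
#'   unchanged). Warns if the deformation makes the hemispheres overlap
#'   across the midline.
#' @export
apply_torque <- function(brain, params = torque_params()) {
  p <- params
  L <- brain$left$vertices
  R <- brain$right$vertices

  # (1) left-hemisphere anisotropic scaling
  if (p$dL != 0 || p$dH != 0 || p$dW != 0) {
    bb <- bounding_box(brain$left)
    sy <- (bb$length + p$dL) / bb$length
    sz <- (bb$height + p$dH) / bb$height
    sx <- (bb$width + p$dW) / bb$width
    if (any(c(sx, sy, sz) <= 0)) stop("dimension offsets collapse the mesh")
    wall <- bb$max[1L]                      # medial wall of the left side
    cy <- mean(range(L[, 2L])); cz <- mean(range(L[, 3L]))
    L[, 1L] <- wall + (L[, 1L] - wall) * sx
    L[, 2L] <- cy + (L[, 2L] - cy) * sy
    L[, 3L] <- cz + (L[, 3L] - cz) * sz
  }

  yr <- range(c(L[, 2L], R[, 2L]))
  ramp <- 0.4 * diff(yr)
  wF_L <- cos_ramp(L[, 2L], yr[2L] - ramp, yr[2L])
  wO_L <- cos_ramp(L[, 2L], yr[1L] + ramp, yr[1L])
  wF_R <- cos_ramp(R[, 2L], yr[2L] - ramp, yr[2L])
  wO_R <- cos_ramp(R[, 2L], yr[1L] + ramp, yr[1L])

  # (2) petalia: antero-posterior fields, +half left / -half right
  L[, 2L] <- L[, 2L] + (p$petalia_frontal / 2) * wF_L +
    (p$petalia_occipital / 2) * wO_L
  R[, 2L] <- R[, 2L] - (p$petalia_frontal / 2) * wF_R -
    (p$petalia_occipital / 2) * wO_R

  # (3) shift: dorso-ventral fields on the same ramps
  L[, 3L] <- L[, 3L] + (p$shift_frontal / 2) * wF_L +
    (p$shift_occipital / 2) * wO_L
  R[, 3L] <- R[, 3L] - (p$shift_frontal / 2) * wF_R -
    (p$shift_occipital / 2) * wO_R

  # (4) bending: lateral shear of both hemispheres over the outer quarters
  qb <- 0.25 * diff(yr)
  shear <- function(y) {
    tan(p$bend_frontal * pi / 180) * pmax(0, y - (yr[2L] - qb)) +
      tan(p$bend_occipital * pi / 180) * pmax(0, (yr[1L] + qb) - y)
  }
  L[, 1L] <- L[, 1L] + shear(L[, 2L])
  R[, 1L] <- R[, 1L] + shear(R[, 2L])

  # (5) global size factor
  if (p$global_scale != 1) {
    L <- L * p$global_scale
    R <- R * p$global_scale
  }

  # (6) rigid mid-sagittal tilt about the vertical axis through the centroid
  if (p$msp_tilt != 0) {
    ctr <- colMeans(rbind(L, R))
    Rz <- rotation_matrix(c(0, 0, 1), p$msp_tilt)
    L <- sweep(sweep(L, 2L, ctr) %*% t(Rz), 2L, ctr, "+")
    R <- sweep(sweep(R, 2L, ctr) %*% t(Rz), 2L, ctr, "+")
  }

  # (7) vertex noise
  if (p$noise_sd > 0) {
    noise <- with_seed(p$seed,
      matrix(stats::rnorm((nrow(L) + nrow(R)) * 3L, sd = p$noise_sd),
             ncol = 3L))
    L <- L + noise[seq_len(nrow(L)), , drop = FALSE]
    R <- R + noise[nrow(L) + seq_len(nrow(R)), , drop = FALSE]
  }

  # heuristic self-intersection check: within antero-posterior slabs, the
  # left surface must stay medial of the right (bending shifts both
  # hemispheres together, so only differential displacement can overlap)
  if (p$msp_tilt == 0) {
    yr2 <- range(c(L[, 2L], R[, 2L]))
    bins <- seq(yr2[1L], yr2[2L], length.out = 21L)
    bl <- findInterval(L[, 2L], bins, all.inside = TRUE)
    br <- findInterval(R[, 2L], bins, all.inside = TRUE)
    overlap <- vapply(seq_len(20L), function(k) {
      li <- L[bl == k, 1L]; ri <- R[br == k, 1L]
      if (length(li) == 0L || length(ri) == 0L) return(-Inf)
      max(li) - min(ri)
    }, numeric(1L))
    if (max(overlap) > 4 * p$noise_sd + 1e-9)
      warning("deformation pushed the hemispheres across the midline")
  }

  out <- brain
  out$left$vertices <- L
  out$right$vertices <- R
  out$aligned <- FALSE
  gs <- p$global_scale
  out$truth <- list(
    petalia_frontal = (p$petalia_frontal + p$dL / 2) * gs,
    petalia_occipital = (p$petalia_occipital - p$dL / 2) * gs,
    shift_frontal = p$shift_frontal * gs,
    shift_occipital = p$shift_occipital * gs,
    bending_frontal = p$bend_frontal,
    bending_occipital = p$bend_occipital,
    dL = (p$dL + p$petalia_frontal - p$petalia_occipital) * gs,
    dH = p$dH * gs, dW = p$dW * gs,
    msp_tilt = p$msp_tilt, global_scale = gs, noise_sd = p$noise_sd)
  out
}

# Published cohort asymmetry distributions used as sampling regimes.
# Means are the reported cohort averages; where no SD is printed the SD is
# derived from the reported t statistic as |mean| sqrt(n) / |t|.
regime_distributions <- function(regime) {
  derive_sd <- function(mean, t, n) abs(mean) * sqrt(n) / abs(t)
  switch(regime,
    human_like = list(
      n_ref = 91L,
      mean = c(petalia_frontal = -0.67, petalia_occipital = -1.58,
               shift_frontal = -0.57, shift_occipital = -1.30,
               bend_frontal = 0.04, bend_occipital = 3.63,
               dH = -0.73, dW = 0.45),
      sd = c(petalia_frontal = derive_sd(-0.67, -4.94, 91),
             petalia_occipital = derive_sd(-1.58, -7.69, 91),
             shift_frontal = derive_sd(-0.57, -0.89, 91),
             shift_occipital = derive_sd(-1.30, -2.66, 91),
             bend_frontal = derive_sd(0.04, 0.22, 91),
             bend_occipital = derive_sd(3.63, 6.65, 91),
             dH = 2.11, dW = 2.74),
      global_scale = 1),
    chimp_like = list(
      n_ref = 78L,
      mean = c(petalia_frontal = 0, petalia_occipital = 0,
               shift_frontal = 0, shift_occipital = 0,
               bend_frontal = 0, bend_occipital = 0, dH = 0, dW = 0),
      sd = c(petalia_frontal = derive_sd(-0.18, -1.80, 78),
             petalia_occipital = derive_sd(-0.20, -1.59, 78),
             shift_frontal = derive_sd(-0.77, -1.62, 78),
             shift_occipital = derive_sd(0.25, 0.65, 78),
             bend_frontal = derive_sd(-0.35, -1.76, 78),
             bend_occipital = derive_sd(-0.39, -1.14, 78),
             dH = 1.45, dW = 1.11),
      global_scale = 111.1 / 174.9),
    null = list(
      n_ref = 91L,
      mean = c(petalia_frontal = 0, petalia_occipital = 0,
               shift_frontal = 0, shift_occipital = 0,
               bend_frontal = 0, bend_occipital = 0, dH = 0, dW = 0),
      sd = c(petalia_frontal = 1.29, petalia_occipital = 1.96,
             shift_frontal = 6.11, shift_occipital = 4.66,
             bend_frontal = 1.73, bend_occipital = 5.21,
             dH = 2.11, dW = 2.74),
      global_scale = 1),
    stop("unknown regime: ", regime))
}

#' Sample per-subject ground-truth torque parameters
#'
#' Draws independent normal deviates per subject for every injectable
#' feature under one of three regimes: `"human_like"` (centred on the human
#' cohort means), `"chimp_like"` (centred on zero, chimpanzee-cohort
#' spreads, smaller brains), `"null"` (centred on zero, human-cohort
#' spreads). dL is derived as `petalia_frontal - petalia_occipital` (see
#' [apply_torque]). Deterministic given the seed.
#'
#' @param n number of subjects.
#' @param regime `"human_like"`, `"chimp_like"`, or `"null"`.
#' @param seed integer seed.
#' @param msp_tilt_sd SD of the random rigid tilt, degrees (default 1).
#' @param noise_sd vertex noise SD in mm given to every subject
#'   (default 0.15, of the order of a subvoxel surface-reconstruction
#'   error).
#' @param mean,sd optional named vectors overriding the regime's per-
#'   parameter means / SDs (names as in [torque_params] except `dL`).
#' @return tibble with one row per subject: `subject_id` and all
#'   [torque_params] fields (ground truth before deformation accounting).
#' @export
sample_torque_params <- function(n, regime = c("human_like", "chimp_like",
                                               "null"),
                                 seed = 1L, msp_tilt_sd = 1,
                                 noise_sd = 0.15,
                                 mean = NULL, sd = NULL) {
  regime <- match.arg(regime)
  dist <- regime_distributions(regime)
  if (!is.null(mean)) dist$mean[names(mean)] <- mean
  if (!is.null(sd)) dist$sd[names(sd)] <- sd
  with_seed(seed, {
    draws <- sapply(names(dist$mean), function(k)
      stats::rnorm(n, dist$mean[[k]], dist$sd[[k]]))
    draws <- matrix(draws, nrow = n,
                    dimnames = list(NULL, names(dist$mean)))
    tibble::tibble(
      subject_id = sprintf("%s_%03d", regime, seq_len(n)),
      petalia_frontal = draws[, "petalia_frontal"],
      petalia_occipital = draws[, "petalia_occipital"],
      shift_frontal = draws[, "shift_frontal"],
      shift_occipital = draws[, "shift_occipital"],
      bend_frontal = draws[, "bend_frontal"],
      bend_occipital = draws[, "bend_occipital"],
      dL = draws[, "petalia_frontal"] - draws[, "petalia_occipital"],
      dH = draws[, "dH"], dW = draws[, "dW"],
      msp_tilt = stats::rnorm(n, 0, msp_tilt_sd),
      global_scale = dist$global_scale,
      noise_sd = noise_sd,
      seed = sample.int(.Machine$integer.max, n))
  })
}

#' Simulate a synthetic cohort of brains with known torque
#'
#' Samples per-subject parameters with [sample_torque_params], builds a
#' mirror-symmetric superellipsoid brain per subject and deforms it with
#' [apply_torque]. The ground-truth table records the net injected metric
#' values each deformation realises. Deterministic given the seed.
#'
#' @inheritParams sample_torque_params
#' @param meshes if `FALSE`, return only the parameter/ground-truth tables
#'   (cheap; for statistical calibration studies that do not need surfaces).
#' @param resolution,exponent,semi_axes base-shape parameters for
#'   [make_hemisphere].
#' @param ... passed on to [sample_torque_params].
#' @return list with `params` (sampled parameter tibble), and when
#'   `meshes = TRUE` also `brains` (list of deformed [brain_surface]) and
#'   `truth` (tibble of net ground-truth metric values per subject).
#' @export
simulate_cohort <- function(n, regime = c("human_like", "chimp_like",
                                          "null"),
                            seed = 1L, meshes = TRUE, resolution = 48L,
                            exponent = 2.5, semi_axes = c(67, 87, 59),
                            ...) {
  regime <- match.arg(regime)
  params <- sample_torque_params(n, regime, seed = seed, ...)
  if (!meshes) return(list(params = params))
  right0 <- make_hemisphere("right", semi_axes = semi_axes,
                            resolution = resolution, exponent = exponent)
  left0 <- mirror_x(right0)
  out <- lapply(seq_len(n), function(i) {
    pr <- params[i, ]
    brain <- brain_surface(left0, right0, subject_id = pr$subject_id,
                           species = "synthetic")
    # the petalia fields already realise the length asymmetry (dL is the
    # emergent value petalia_frontal - petalia_occipital), so no extra dL
    # scaling is injected
    tp <- torque_params(
      petalia_frontal = pr$petalia_frontal,
      petalia_occipital = pr$petalia_occipital,
      shift_frontal = pr$shift_frontal,
      shift_occipital = pr$shift_occipital,
      bend_frontal = pr$bend_frontal, bend_occipital = pr$bend_occipital,
      dL = 0, dH = pr$dH, dW = pr$dW, msp_tilt = pr$msp_tilt,
      global_scale = pr$global_scale, noise_sd = pr$noise_sd,
      seed = pr$seed)
    apply_torque(brain, tp)
  })
  truth <- tibble::as_tibble(do.call(rbind, lapply(out, function(b)
    as.data.frame(b$truth))))
  truth <- tibble::add_column(truth, subject_id = params$subject_id,
                              .before = 1L)
  list(params = params, brains = out, truth = truth)
}
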