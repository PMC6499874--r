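test_that("medial selection finds x-facing regions and honours the threshold", {
  cube <- cube_mesh(4L)
  sel <- medial_vertices(cube, theta_max = 40)
  v <- cube$vertices
  on_x_face <- v[, 1L] %in% c(0, 1)
  # selected vertices lie on the x faces, and all x-face interior vertices
  # (normals exactly +/-x) are selected; edge/corner vertices (>= 45 deg)
  # are not
  expect_true(all(on_x_face[sel$indices]))
  interior <- on_x_face & v[, 2L] > 0.1 & v[, 2L] < 0.9 &
    v[, 3L] > 0.1 & v[, 3L] < 0.9
  expect_true(all(which(interior) %in% sel$indices))
  expect_false(any(!interior & seq_len(nrow(v)) %in% sel$indices &
                     (v[, 2L] %in% c(0, 1) | v[, 3L] %in% c(0, 1))))

  # sphere: folded criterion selects the two caps |x| > cos(theta_max)
  sph <- uv_sphere(n_th = 48L, n_ph = 24L)
  sel2 <- medial_vertices(sph, theta_max = 40)
  x <- sph$vertices[sel2$indices, 1L]
  expect_true(all(abs(x) > cos(40 * pi / 180) - 0.05))
  missed <- setdiff(which(abs(sph$vertices[, 1L]) >
                            cos(40 * pi / 180) + 0.05), sel2$indices)
  expect_length(missed, 0L)

  # vacuous threshold selects everything on an unlabelled mesh
  expect_length(medial_vertices(sph, theta_max = 90)$indices,
                nrow(sph$vertices))
})

test_that("side-aware medial selection keeps the wall, drops the lateral cap", {
  r <- make_hemisphere("right", resolution = 32L)
  sel <- medial_vertices(r, theta_max = 40)
  x <- r$vertices[sel$indices, 1L]
  # right hemisphere medial wall sits at x = +gap/2; lateral surface near
  # x ~ 67 must be excluded even though its normals also align with x
  expect_true(all(x < 1))
  expect_gt(length(sel$indices), 50L)
  # a surface with no near-axis normals yields an empty selection
  tilted <- rigid_transform(cube_mesh(3L), rotation_matrix(c(0, 0, 1), 20))
  expect_error(medial_vertices(tilted, theta_max = 5), "medial")
})

test_that("total-least-squares plane fit recovers exact and noisy planes", {
  set.seed(1)
  pts <- cbind(0, rnorm(200, sd = 30), rnorm(200, sd = 20))
  pl <- fit_plane(pts)
  expect_equal(unname(pl$normal), c(1, 0, 0))
  expect_equal(pl$point[1L], 0, ignore_attr = TRUE)

  R5 <- rotation_matrix(c(0, 0, 1), 5)
  pl2 <- fit_plane(pts %*% t(R5))
  expect_equal(unname(pl2$normal), unname(R5[, 1L]), tolerance = 1e-6)

  # Monte-Carlo: isotropic noise sd 0.1 on 1000 points, normal within 0.5 deg
  set.seed(99)
  pts3 <- cbind(0, rnorm(1000, sd = 30), rnorm(1000, sd = 20)) +
    matrix(rnorm(3000, sd = 0.1), ncol = 3L)
  pl3 <- fit_plane(pts3 %*% t(R5))
  ang <- acos(abs(sum(pl3$normal * R5[, 1L]))) * 180 / pi
  expect_lt(ang, 0.5)

  expect_error(fit_plane(cbind(1:5, 1:5, 1:5)), "collinear")
  expect_error(fit_plane(pts[1:2, ]), "at least 3")
})

test_that("MSP estimation recovers the midline of symmetric and rotated pairs", {
  b <- sym_brain(resolution = 32L)
  pl <- estimate_msp(b)
  expect_lt(acos(abs(pl$normal[1L])) * 180 / pi, 0.1)

  R3 <- rotation_matrix(c(0, 1, 0), 3)
  br <- b
  br$left <- rigid_transform(b$left, R3)
  br$right <- rigid_transform(b$right, R3)
  pl3 <- estimate_msp(br)
  expected <- R3[, 1L]
  ang <- acos(abs(sum(pl3$normal * expected))) * 180 / pi
  expect_lt(ang, 0.1)

  expect_error(estimate_msp(b, min_vertices = 1e6), "medial vertices")
})

test_that("widening the central band on a bent brain tilts the MSP fit", {
  b <- sym_brain(resolution = 32L)
  bent <- apply_torque(b, torque_params(bend_occipital = 6))
  narrow <- estimate_msp(bent, central_fraction = 0.5)
  wide <- estimate_msp(bent, central_fraction = 1.0)
  ang <- function(p) acos(abs(p$normal[1L])) * 180 / pi
  # the bent occipital quarter only contaminates the full-range fit
  expect_lt(ang(narrow), 0.05)
  expect_gt(ang(wide), ang(narrow) + 0.1)
})

test_that("alignment converges, is idempotent, and removes pre-rotations", {
  b <- sym_brain(resolution = 32L)
  ba <- align_to_msp(b)
  expect_true(ba$aligned)
  expect_lt(ba$alignment_angle, 0.01)
  # already-aligned symmetric pair: near-identity transform
  expect_equal(ba$left$vertices, b$left$vertices, tolerance = 1e-6)

  R4 <- rotation_matrix(c(0, 0, 1), 4)
  br <- b
  br$left <- rigid_transform(b$left, R4, c(2, 0, 0))
  br$right <- rigid_transform(b$right, R4, c(2, 0, 0))
  bra <- align_to_msp(br)
  expect_lt(plane_residual <- bra$alignment_angle, 0.01)
  pl <- estimate_msp(bra)
  expect_lt(acos(abs(pl$normal[1L])) * 180 / pi, 0.01)
  # MSP brought back to x = 0 (origin on the plane)
  expect_lt(abs(pl$point[1L]), 0.1)

  # idempotence: second alignment moves vertices < 1e-3 mm
  bra2 <- align_to_msp(bra)
  expect_lt(max(abs(bra2$left$vertices - bra$left$vertices)), 1e-3)
  expect_lt(max(abs(bra2$right$vertices - bra$right$vertices)), 1e-3)
})

test_that("MSP of a mirrored brain is the mirror of the MSP", {
  b <- sym_brain(resolution = 24L)
  bd <- apply_torque(b, torque_params(bend_occipital = 3, msp_tilt = 2,
                                      shift_occipital = -1))
  pl <- estimate_msp(bd)
  plm <- estimate_msp(mirror_brain(bd))
  expect_equal(unname(plm$normal), unname(c(pl$normal[1L], -pl$normal[2L],
                                            -pl$normal[3L])),
               tolerance = 1e-9)
  expect_equal(unname(plm$point), unname(c(-pl$point[1L], pl$point[2L],
                                           pl$point[3L])),
               tolerance = 1e-9)
})
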