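aligned_sym <- function(resolution = 32L) align_to_msp(sym_brain(resolution))

test_that("dimension record: symmetric pair is symmetric, invariants hold", {
  ba <- aligned_sym()
  d <- measure_dimensions(ba)
  expect_equal(d$dL, 0, tolerance = 1e-8)
  expect_equal(d$dH, 0, tolerance = 1e-8)
  expect_equal(d$dW, 0, tolerance = 1e-8)
  # whole-surface extents bound the hemispheric ones; ratios positive
  for (f in c("length", "height", "width")) {
    expect_gte(d[[f]][["whole"]], d[[f]][["left"]] - 1e-9)
    expect_gte(d[[f]][["whole"]], d[[f]][["right"]] - 1e-9)
  }
  expect_gt(d$ratio_length_width, 0)
  expect_gt(d$ratio_height_width, 0)
  expect_error(measure_dimensions(sym_brain(24L)), "aligned")
})

test_that("an injected left length stretch appears in dL only", {
  b <- sym_brain(32L)
  bd <- apply_torque(b, torque_params(dL = 2))
  d <- measure_dimensions(align_to_msp(bd))
  expect_equal(d$dL, 2, tolerance = 0.1)
  expect_equal(d$dH, 0, tolerance = 0.1)
  expect_equal(d$dW, 0, tolerance = 0.1)
})

test_that("petalia and shift recover injected pole offsets with correct signs", {
  b <- sym_brain(32L)
  ba <- align_to_msp(b)
  expect_equal(unname(measure_petalia(ba)), c(0, 0), tolerance = 1e-8)
  expect_equal(unname(measure_shift(ba)), c(0, 0), tolerance = 1e-8)

  # pure left-hemisphere y translation: both petalia move together
  bt <- b
  bt$left$vertices[, 2L] <- bt$left$vertices[, 2L] - 1.5
  pet <- measure_petalia(align_to_msp(bt))
  expect_equal(unname(pet), c(-1.5, -1.5), tolerance = 0.1)

  # injected occipital shear drops the left posterior pole
  bs <- align_to_msp(apply_torque(b, torque_params(shift_occipital = -1.3)))
  shf <- measure_shift(bs)
  expect_equal(shf[["occipital"]], -1.3, tolerance = 0.1)
  expect_equal(shf[["frontal"]], 0, tolerance = 0.1)

  expect_error(measure_petalia(b), "aligned")
  expect_error(measure_shift(b), "aligned")
})

test_that("bending recovers an injected occipital bend and stays zero frontally", {
  b <- sym_brain(32L)
  expect_equal(unname(measure_bending(align_to_msp(b))), c(0, 0),
               tolerance = 0.05)
  bb <- align_to_msp(apply_torque(b, torque_params(bend_occipital = 3.6)))
  bend <- measure_bending(bb)
  expect_equal(bend[["occipital"]], 3.6, tolerance = 0.2)
  expect_equal(bend[["frontal"]], 0, tolerance = 0.2)
})

test_that("configuration quadrants map signs to sides with documented tie-breaks", {
  # the four sign combinations of petalia give four distinct labels
  labs <- c(classify_configuration(1, -1, "petalia")$configuration,
            classify_configuration(1, 1, "petalia")$configuration,
            classify_configuration(-1, -1, "petalia")$configuration,
            classify_configuration(-1, 1, "petalia")$configuration)
  expect_setequal(labs, c("LF/LO", "LF/RO", "RF/LO", "RF/RO"))

  # human cohort mean petalia: right-frontal / left-occipital
  expect_identical(classify_configuration(-0.67, -1.58,
                                          "petalia")$configuration,
                   "RF/LO")
  # human cohort mean bending: rightward occipital
  expect_identical(classify_configuration(0.04, 3.63,
                                          "bending")$configuration,
                   "RF/RO")
  # ties resolve toward RF / LO and are flagged
  z <- classify_configuration(0, 0, "petalia")
  expect_identical(z$configuration, "RF/LO")
  expect_true(z$tie)
  zb <- classify_configuration(0, 0, "bending")
  expect_identical(zb$configuration, "RF/LO")
  expect_true(zb$tie)
  expect_false(classify_configuration(1, -1, "shift")$tie)
})

test_that("measure_subject recovers a torqued synthetic subject end to end", {
  b <- sym_brain(32L)
  rec0 <- measure_subject(b)
  for (f in c("petalia_frontal", "petalia_occipital", "shift_frontal",
              "shift_occipital"))
    expect_equal(rec0[[f]], 0, tolerance = 0.01)
  for (f in c("bending_frontal", "bending_occipital"))
    expect_equal(rec0[[f]], 0, tolerance = 0.05)

  tp <- torque_params(petalia_frontal = -0.7, petalia_occipital = -1.6,
                      shift_occipital = -1.3, bend_occipital = 3.6,
                      msp_tilt = 2)
  rec <- measure_subject(apply_torque(b, tp))
  expect_equal(rec$petalia_frontal, -0.7, tolerance = 0.1)
  expect_equal(rec$petalia_occipital, -1.6, tolerance = 0.1)
  expect_equal(rec$shift_occipital, -1.3, tolerance = 0.1)
  expect_equal(rec$bending_occipital, 3.6, tolerance = 0.2)
  expect_identical(rec$config_petalia, "RF/LO")
})

test_that("every signed metric is anti-symmetric under mirroring", {
  b <- sym_brain(32L)
  tp <- torque_params(petalia_frontal = -0.7, petalia_occipital = -1.6,
                      shift_frontal = 0.4, shift_occipital = -1.3,
                      bend_frontal = 1.1, bend_occipital = 3.6,
                      dH = -0.7, dW = 0.5, msp_tilt = 1.5)
  bd <- apply_torque(b, tp)
  rec <- measure_subject(bd)
  recm <- measure_subject(mirror_brain(bd))
  for (f in c("petalia_frontal", "petalia_occipital", "shift_frontal",
              "shift_occipital", "bending_frontal", "bending_occipital"))
    expect_equal(recm[[f]], -rec[[f]], tolerance = 1e-4)
  for (f in c("dL", "dH", "dW"))
    expect_equal(recm$dimensions[[f]], -rec$dimensions[[f]],
                 tolerance = 1e-4)
  # configuration labels swap L and R on both axes
  swap <- function(lab) chartr("LR", "RL", lab)
  expect_identical(recm$config_petalia, swap(rec$config_petalia))
  expect_identical(recm$config_bending, swap(rec$config_bending))
})

test_that("mm metrics scale with the subject scale factor, angles do not", {
  b <- sym_brain(32L)
  bd <- apply_torque(b, torque_params(petalia_occipital = -1.6,
                                      shift_occipital = -1.3,
                                      bend_occipital = 3.6))
  rec1 <- measure_subject(bd)
  bd$scale <- 1.25
  rec2 <- measure_subject(bd)
  expect_equal(rec2$petalia_occipital, 1.25 * rec1$petalia_occipital,
               tolerance = 1e-9)
  expect_equal(rec2$shift_occipital, 1.25 * rec1$shift_occipital,
               tolerance = 1e-9)
  expect_equal(rec2$dimensions$length[["whole"]],
               1.25 * rec1$dimensions$length[["whole"]], tolerance = 1e-9)
  expect_equal(rec2$bending_occipital, rec1$bending_occipital,
               tolerance = 1e-9)
})

test_that("metrics are invariant to uniform brain-size rescaling at zero torque", {
  for (gs in c(0.6, 0.8, 1.0)) {
    rec <- measure_subject(apply_torque(sym_brain(24L),
                                        torque_params(global_scale = gs)))
    for (f in c("petalia_frontal", "petalia_occipital", "shift_frontal",
                "shift_occipital", "bending_frontal", "bending_occipital"))
      expect_lt(abs(rec[[f]]), 0.05)
    expect_lt(abs(rec$dimensions$dL), 0.05)
  }
})
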