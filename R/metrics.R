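#' Pipeline configuration
#'
#' Collects the tunable hyper-parameters of the measurement pipeline with
#' their defaults: the medial-selection angle threshold (40 degrees), the
#' central fraction of the antero-posterior range used for the mid-sagittal
#' fit (0.5), the frontal/occipital quarter fraction used for bending
#' (0.25), the alignment tolerance (0.01 degrees) and iteration cap (5), and
#' the rounding (2 decimals) applied only when records are serialised.
#'
#' @param theta_max medial-selection threshold, degrees, in (0, 90).
#' @param central_fraction central y-band for the MSP fit, in (0, 1].
#' @param quarter_fraction regional y-band for bending planes, in (0, 1].
#' @param align_tol alignment convergence tolerance, degrees.
#' @param align_max_iter maximum alignment iterations.
#' @param rounding decimal places used at the I/O layer.
#' @return a named list of class `torque_config`.
#' @export
torque_config <- function(theta_max = 40, central_fraction = 0.5,
                          quarter_fraction = 0.25, align_tol = 0.01,
                          align_max_iter = 5L, rounding = 2L) {
  stopifnot(theta_max > 0, theta_max < 90,
            central_fraction > 0, central_fraction <= 1,
            quarter_fraction > 0, quarter_fraction <= 1,
            align_tol > 0, align_max_iter >= 1L, rounding >= 0L)
  structure(list(theta_max = theta_max,
                 central_fraction = central_fraction,
                 quarter_fraction = quarter_fraction,
                 align_tol = align_tol,
                 align_max_iter = as.integer(align_max_iter),
                 rounding = as.integer(rounding)),
            class = "torque_config")
}

require_aligned <- function(brain, what) {
  if (!isTRUE(brain$aligned))
    stop(what, " requires an MSP-aligned brain; call align_to_msp() first")
  invisible(brain)
}

#' Hemispheric and whole-brain bounding-box dimensions
#'
#' Three bounding boxes are constructed independently — left hemisphere,
#' right hemisphere, and the whole cerebral surface (union of both) — with
#' the subject's uniform scale factor applied, so the extents are native-
#' space millimetres. Length/width and height/width ratios are computed from
#' the whole-surface box; dimensional asymmetries are left minus right.
#'
#' @param brain an aligned [brain_surface].
#' @return list of class `dimension_record`: per-surface `length`, `height`,
#'   `width` (named vectors `left`, `right`, `whole`), `ratio_length_width`,
#'   `ratio_height_width`, and asymmetries `dL`, `dH`, `dW` (mm).
#' @export
measure_dimensions <- function(brain) {
  require_aligned(brain, "measure_dimensions")
  union <- trimesh(brain_vertices(brain),
                   rbind(brain$left$faces,
                         brain$right$faces + nrow(brain$left$vertices)),
                   side = "whole", validate = FALSE)
  boxes <- list(left = bounding_box(brain$left, brain$scale),
                right = bounding_box(brain$right, brain$scale),
                whole = bounding_box(union, brain$scale))
  g <- function(field) vapply(boxes, `[[`, numeric(1L), field)
  len <- g("length"); hei <- g("height"); wid <- g("width")
  structure(list(
    length = len, height = hei, width = wid,
    ratio_length_width = len[["whole"]] / wid[["whole"]],
    ratio_height_width = hei[["whole"]] / wid[["whole"]],
    dL = len[["left"]] - len[["right"]],
    dH = hei[["left"]] - hei[["right"]],
    dW = wid[["left"]] - wid[["right"]]), class = "dimension_record")
}

# scaled pole coordinates of both hemispheres for one direction
pole_pair <- function(brain, direction) {
  list(left = extract_pole(brain$left, direction) * brain$scale,
       right = extract_pole(brain$right, direction) * brain$scale)
}

#' Petalia: antero-posterior pole asymmetry
#'
#' Left-minus-right difference of the y coordinates of the frontal
#' (anterior) and occipital (posterior) poles. A negative frontal petalia
#' means the right frontal pole protrudes further anteriorly; a negative
#' occipital petalia means the left occipital pole protrudes further
#' posteriorly — the combination typical of the human torque.
#'
#' @param brain an aligned [brain_surface].
#' @return named numeric vector `c(frontal =, occipital =)` in mm.
#' @export
measure_petalia <- function(brain) {
  require_aligned(brain, "measure_petalia")
  ant <- pole_pair(brain, "anterior")
  post <- pole_pair(brain, "posterior")
  c(frontal = ant$left[2L] - ant$right[2L],
    occipital = post$left[2L] - post$right[2L])
}

#' Shift: dorso-ventral pole asymmetry
#'
#' Left-minus-right difference of the z coordinates of the same frontal and
#' occipital pole vertices used by [measure_petalia]. A negative occipital
#' shift means the left occipital pole sits lower than the right.
#'
#' @param brain an aligned [brain_surface].
#' @return named numeric vector `c(frontal =, occipital =)` in mm.
#' @export
measure_shift <- function(brain) {
  require_aligned(brain, "measure_shift")
  ant <- pole_pair(brain, "anterior")
  post <- pole_pair(brain, "posterior")
  c(frontal = ant$left[3L] - ant$right[3L],
    occipital = post$left[3L] - post$right[3L])
}

# signed bending angle of one regional medial plane.
# magnitude: angle between the plane normal (canonical x >= 0) and the x
# axis; sign: from the normal's y component, chosen so that a midline
# deviating toward the subject's right (+x) at the regional extreme is
# positive in both regions. For the occipital region a rightward posterior
# edge tilts the normal anteriorly (ny > 0); the frontal region is the
# opposite.
signed_bending <- function(plane, region) {
  mag <- plane_angle_to_x(plane)
  ny <- plane$normal[2L]
  s <- if (region == "occipital") sign(ny) else -sign(ny)
  if (s == 0) s <- 1
  s * mag
}

#' Bending: regional tilt of the inter-hemispheric midline
#'
#' For each hemisphere, the medial-surface vertices falling in the first
#' (frontal) and last (occipital) `quarter_fraction` of the whole-brain
#' antero-posterior range are fitted with a total-least-squares plane; the
#' bending angle is the signed angle between that plane's normal and the x
#' axis (positive = midline deviates toward the subject's right at the
#' regional extreme), averaged between the two hemispheres per region.
#' Angles are scale-invariant.
#'
#' @param brain an aligned [brain_surface].
#' @param theta_max medial-selection threshold, degrees.
#' @param quarter_fraction fraction of the y range defining each region.
#' @return named numeric vector `c(frontal =, occipital =)` in degrees.
#' @export
measure_bending <- function(brain, theta_max = 40, quarter_fraction = 0.25) {
  require_aligned(brain, "measure_bending")
  yr <- brain_y_range(brain)
  band <- quarter_fraction * diff(yr)
  angles <- sapply(c("frontal", "occipital"), function(region) {
    per_hemi <- vapply(list(brain$left, brain$right), function(mesh) {
      sel <- medial_vertices(mesh, theta_max = theta_max)
      v <- mesh$vertices[sel$indices, , drop = FALSE]
      keep <- if (region == "frontal") v[, 2L] >= yr[2L] - band
              else v[, 2L] <= yr[1L] + band
      pts <- v[keep, , drop = FALSE]
      if (nrow(pts) < 3L)
        stop("empty ", region, " medial selection for ", mesh$side,
             " hemisphere; increase theta_max or quarter_fraction")
      signed_bending(fit_plane(pts), region)
    }, numeric(1L))
    mean(per_hemi)
  })
  angles
}

#' Quadrant configuration of a frontal/occipital feature pair
#'
#' Maps the signs of the frontal and occipital values of one torque feature
#' to one of the four configurations `LF/LO`, `LF/RO`, `RF/LO`, `RF/RO`,
#' where the letter names the hemisphere (or, for bending, the direction)
#' expressing the feature in that region. For petalia and shift, a positive
#' frontal value (left pole leading / higher) is `LF` and a negative
#' occipital value (left pole trailing / lower) is `LO`; for bending,
#' positive (rightward) is `RF` / `RO`. Exact zeros are resolved
#' deterministically toward `RF` (frontal) and `LO` (occipital) and flagged.
#'
#' @param frontal,occipital signed feature values.
#' @param feature `"petalia"`, `"shift"`, or `"bending"`.
#' @return list with `configuration` (e.g. `"RF/LO"`) and logical `tie`.
#' @export
classify_configuration <- function(frontal, occipital,
                                   feature = c("petalia", "shift", "bending")) {
  feature <- match.arg(feature)
  tie <- (frontal == 0) || (occipital == 0)
  if (feature == "bending") {
    f <- if (frontal == 0) "RF" else if (frontal > 0) "RF" else "LF"
    o <- if (occipital == 0) "LO" else if (occipital > 0) "RO" else "LO"
  } else {
    f <- if (frontal > 0) "LF" else "RF"          # 0 -> RF
    o <- if (occipital < 0 || occipital == 0) "LO" else "RO"
  }
  list(configuration = paste(f, o, sep = "/"), tie = tie)
}

#' Measure one subject end to end
#'
#' Aligns the brain to its mid-sagittal plane if necessary, then computes
#' the dimension record, petalia, shift, bending, and the three quadrant
#' configurations. Deterministic for a fixed input mesh pair.
#'
#' @param brain a [brain_surface] (raw or already aligned).
#' @param config a [torque_config].
#' @return list of class `torque_record`; convert with
#'   [as.data.frame.torque_record] or collect cohorts with [measure_cohort].
#' @export
measure_subject <- function(brain, config = torque_config()) {
  if (!isTRUE(brain$aligned))
    brain <- align_to_msp(brain, tol = config$align_tol,
                          max_iter = config$align_max_iter,
                          central_fraction = config$central_fraction,
                          theta_max = config$theta_max)
  dims <- measure_dimensions(brain)
  pet <- measure_petalia(brain)
  shf <- measure_shift(brain)
  bnd <- measure_bending(brain, theta_max = config$theta_max,
                         quarter_fraction = config$quarter_fraction)
  cls <- list(petalia = classify_configuration(pet[1L], pet[2L], "petalia"),
              shift = classify_configuration(shf[1L], shf[2L], "shift"),
              bending = classify_configuration(bnd[1L], bnd[2L], "bending"))
  structure(list(
    subject_id = brain$subject_id, species = brain$species,
    sex = if (is.null(brain$sex)) NA_character_ else brain$sex,
    dimensions = dims,
    petalia_frontal = unname(pet[1L]), petalia_occipital = unname(pet[2L]),
    shift_frontal = unname(shf[1L]), shift_occipital = unname(shf[2L]),
    bending_frontal = unname(bnd[1L]), bending_occipital = unname(bnd[2L]),
    config_petalia = cls$petalia$configuration,
    config_shift = cls$shift$configuration,
    config_bending = cls$bending$configuration,
    config_tie = any(vapply(cls, `[[`, logical(1L), "tie"))),
    class = "torque_record")
}

#' @export
print.torque_record <- function(x, ...) {
  cat(sprintf("<torque_record> %s (%s)\n", x$subject_id, x$species))
  cat(sprintf("  petalia  F %+.2f  O %+.2f mm  [%s]\n",
              x$petalia_frontal, x$petalia_occipital, x$config_petalia))
  cat(sprintf("  shift    F %+.2f  O %+.2f mm  [%s]\n",
              x$shift_frontal, x$shift_occipital, x$config_shift))
  cat(sprintf("  bending  F %+.2f  O %+.2f deg [%s]\n",
              x$bending_frontal, x$bending_occipital, x$config_bending))
  cat(sprintf("  dL %+.2f  dH %+.2f  dW %+.2f mm\n",
              x$dimensions$dL, x$dimensions$dH, x$dimensions$dW))
  invisible(x)
}

#' Flatten a torque record to one data-frame row
#'
#' @param x a `torque_record`.
#' @param ... unused.
#' @return one-row `data.frame` with all scalar fields, full precision.
#' @export
as.data.frame.torque_record <- function(x, ...) {
  d <- x$dimensions
  data.frame(
    subject_id = x$subject_id, species = x$species, sex = x$sex,
    length_left = d$length[["left"]], length_right = d$length[["right"]],
    length_whole = d$length[["whole"]],
    height_left = d$height[["left"]], height_right = d$height[["right"]],
    height_whole = d$height[["whole"]],
    width_left = d$width[["left"]], width_right = d$width[["right"]],
    width_whole = d$width[["whole"]],
    ratio_length_width = d$ratio_length_width,
    ratio_height_width = d$ratio_height_width,
    dL = d$dL, dH = d$dH, dW = d$dW,
    petalia_frontal = x$petalia_frontal,
    petalia_occipital = x$petalia_occipital,
    shift_frontal = x$shift_frontal, shift_occipital = x$shift_occipital,
    bending_frontal = x$bending_frontal,
    bending_occipital = x$bending_occipital,
    config_petalia = x$config_petalia, config_shift = x$config_shift,
    config_bending = x$config_bending, config_tie = x$config_tie,
    stringsAsFactors = FALSE)
}

#' Measure a list of brains into a cohort table
#'
#' @param brains list of [brain_surface] objects.
#' @param config a [torque_config].
#' @return a tibble with one row per subject (see
#'   [as.data.frame.torque_record] for columns).
#' @export
measure_cohort <- function(brains, config = torque_config()) {
  rows <- lapply(brains, function(b)
    as.data.frame(measure_subject(b, config = config)))
  tibble::as_tibble(do.call(rbind, rows))
}
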