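#' Reference cohort dimension summaries
#'
#' Published bounding-box dimension summaries (mean and SD, mm) from a
#' comparative in-vivo MRI study of 91 human and 78 chimpanzee brains:
#' antero-posterior length, dorso-ventral height and latero-medial width of
#' the left hemisphere, right hemisphere, and whole cerebral surface, per
#' species and sex group. These summaries parameterise the synthetic
#' regimes and are the inputs for recomputing the published ratios and size
#' factors.
#'
#' @return tibble with columns `species`, `group`, `surface`
#'   (left/right/whole), `measure` (length/height/width), `mean`, `sd`, `n`.
#' @export
reference_dimensions <- function() {
  row <- function(species, group, n, surface, measure, mean, sd)
    tibble::tibble(species = species, group = group, surface = surface,
                   measure = measure, mean = mean, sd = sd, n = n)
  h <- function(...) row("human", "all", 91L, ...)
  c_ <- function(...) row("chimpanzee", "all", 78L, ...)
  rows <- rbind(
    h("left", "length", 173.8, 7.5), h("left", "height", 116.0, 5.2),
    h("left", "width", 70.3, 3.2),
    h("right", "length", 172.9, 7.4), h("right", "height", 116.8, 5.1),
    h("right", "width", 70.0, 3.5),
    h("whole", "length", 174.9, 7.6), h("whole", "height", 117.7, 5.0),
    h("whole", "width", 134.0, 5.6),
    c_("left", "length", 110.4, 4.2), c_("left", "height", 74.5, 3.6),
    c_("left", "width", 45.1, 2.1),
    c_("right", "length", 110.4, 4.2), c_("right", "height", 74.4, 3.8),
    c_("right", "width", 45.1, 2.1),
    c_("whole", "length", 111.1, 4.1), c_("whole", "height", 75.1, 3.7),
    c_("whole", "width", 87.2, 3.8))
  tibble::as_tibble(rows)
}

#' Reference cohort asymmetry summaries
#'
#' Published left-minus-right asymmetry summaries for the same cohorts:
#' dimensional asymmetries (mean and SD) and the torque features (cohort
#' means with their reported one-sample t statistics; no SDs were printed
#' for the torque features, so `sd` is `NA` there and can be derived as
#' `|mean| sqrt(n) / |t|`).
#'
#' @return tibble with columns `species`, `variable`, `mean`, `sd`, `t`,
#'   `n`.
#' @export
reference_asymmetries <- function() {
  tb <- tibble::tribble(
    ~species, ~variable, ~mean, ~sd, ~t,
    "human", "dL", 0.92, 1.84, 4.77,
    "human", "dH", -0.73, 2.11, -3.30,
    "human", "dW", 0.45, 2.74, 1.56,
    "human", "petalia_frontal", -0.67, NA, -4.94,
    "human", "petalia_occipital", -1.58, NA, -7.69,
    "human", "shift_frontal", -0.57, NA, -0.89,
    "human", "shift_occipital", -1.30, NA, -2.66,
    "human", "bending_frontal", 0.04, NA, 0.22,
    "human", "bending_occipital", 3.63, NA, 6.65,
    "chimpanzee", "dL", 0.02, 1.38, 0.14,
    "chimpanzee", "dH", 0.11, 1.45, 0.69,
    "chimpanzee", "dW", -0.03, 1.11, -0.25,
    "chimpanzee", "petalia_frontal", -0.18, NA, -1.80,
    "chimpanzee", "petalia_occipital", -0.20, NA, -1.59,
    "chimpanzee", "shift_frontal", -0.77, NA, -1.62,
    "chimpanzee", "shift_occipital", 0.25, NA, 0.65,
    "chimpanzee", "bending_frontal", -0.35, NA, -1.76,
    "chimpanzee", "bending_occipital", -0.39, NA, -1.14)
  tb$n <- ifelse(tb$species == "human", 91L, 78L)
  tb
}

#' Reference configuration prevalences
#'
#' Published prevalences (percent of cohort) of the four frontal/occipital
#' configurations of petalia, shift and bending in each species (rows LO /
#' RO by columns LF / RF; cohort sizes 91 and 78).
#'
#' @return tibble with columns `species`, `feature`, `occipital` (LO/RO),
#'   `frontal` (LF/RF), `percent`, `n`.
#' @export
reference_prevalence <- function() {
  g <- expand.grid(occipital = c("LO", "RO"), frontal = c("LF", "RF"),
                   stringsAsFactors = FALSE)
  build <- function(species, n, feature, lo_lf, lo_rf, ro_lf, ro_rf)
    tibble::tibble(species = species, feature = feature,
                   occipital = g$occipital, frontal = g$frontal,
                   percent = c(lo_lf, ro_lf, lo_rf, ro_rf), n = n)
  rbind(
    build("human", 91L, "petalia", 20.88, 60.44, 9.89, 8.79),
    build("human", 91L, "shift", 23.08, 39.56, 20.88, 16.48),
    build("human", 91L, "bending", 14.29, 7.69, 30.77, 47.25),
    build("chimpanzee", 78L, "petalia", 21.79, 30.77, 17.95, 29.49),
    build("chimpanzee", 78L, "shift", 19.23, 24.36, 21.79, 34.62),
    build("chimpanzee", 78L, "bending", 23.08, 34.62, 16.67, 25.64))
}

#' Recompute the published cohort statistics from the printed summaries
#'
#' Recomputes, from the bundled summary tables only (no raw scans are
#' available), every statistic of the published analysis that is
#' recomputable from printed data:
#'
#' * one-sample t statistics of the dimensional asymmetries from the
#'   printed mean, SD and cohort size ([one_sample_t]);
#' * between-species chi-squared tests on the modal petalia configuration
#'   (right-frontal / left-occipital vs rest) and on occipital bending
#'   direction (rightward vs leftward), with counts reconstructed from the
#'   printed prevalences and cohort sizes ([reconstruct_counts],
#'   [chi2_prevalence], no continuity correction);
#' * whole-surface length/width and height/width ratios per species and
#'   between-species size factors from the printed whole-surface means.
#'
#' @return tibble with columns `quantity`, `value`, `df`, `p_value`
#'   (`df`/`p_value` `NA` for ratios and factors).
#' @export
reproduce_reported_statistics <- function() {
  asym <- reference_asymmetries()
  dims <- reference_dimensions()
  prev <- reference_prevalence()

  rows <- list()
  add <- function(quantity, value, df = NA_real_, p = NA_real_)
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      quantity = quantity, value = value, df = df, p_value = p)

  for (sp in c("human", "chimpanzee")) {
    for (v in c("dL", "dH", "dW")) {
      a <- asym[asym$species == sp & asym$variable == v, ]
      tt <- one_sample_t(mean = a$mean, sd = a$sd, n = a$n)
      add(sprintf("t_%s_%s", v, sp), tt$statistic, tt$df, tt$p.value)
    }
  }

  quadrant_counts <- function(sp, feature, frontal, occipital) {
    p <- prev[prev$species == sp & prev$feature == feature, ]
    hit <- p$percent[p$frontal == frontal & p$occipital == occipital]
    reconstruct_counts(c(hit, 100 - hit), p$n[1L])
  }
  margin_counts <- function(sp, feature, occipital) {
    p <- prev[prev$species == sp & prev$feature == feature, ]
    hit <- sum(p$percent[p$occipital == occipital])
    reconstruct_counts(c(hit, 100 - hit), p$n[1L])
  }

  hp <- quadrant_counts("human", "petalia", "RF", "LO")
  cp <- quadrant_counts("chimpanzee", "petalia", "RF", "LO")
  chi_pet <- chi2_prevalence(hp[1L], hp[2L], cp[1L], cp[2L])
  add("chi2_petalia_configuration", chi_pet$statistic, chi_pet$df,
      chi_pet$p.value)

  hb <- margin_counts("human", "bending", "RO")
  cb <- margin_counts("chimpanzee", "bending", "RO")
  chi_bend <- chi2_prevalence(hb[1L], hb[2L], cb[1L], cb[2L])
  add("chi2_occipital_bending", chi_bend$statistic, chi_bend$df,
      chi_bend$p.value)

  whole <- function(sp, measure)
    dims$mean[dims$species == sp & dims$surface == "whole" &
                dims$measure == measure]
  for (sp in c("human", "chimpanzee")) {
    add(sprintf("ratio_length_width_%s", sp),
        whole(sp, "length") / whole(sp, "width"))
    add(sprintf("ratio_height_width_%s", sp),
        whole(sp, "height") / whole(sp, "width"))
  }
  for (m in c("length", "height", "width"))
    add(sprintf("factor_%s_human_chimp", m),
        whole("human", m) / whole("chimpanzee", m))

  do.call(rbind, rows)
}
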