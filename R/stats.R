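new_torque_test <- function(test, statistic, df, p, inputs) {
  structure(list(test = test, statistic = statistic, df = df,
                 p.value = p, inputs = inputs),
            class = "torque_test")
}

#' @export
print.torque_test <- function(x, ...) {
  cat(sprintf("<torque_test> %s: statistic %.4f, df %s, p %.4g\n",
              x$test, x$statistic, format(x$df), x$p.value))
  invisible(x)
}

#' Two-tailed one-sample t test
#'
#' Tests the null hypothesis that the population mean of a left-minus-right
#' asymmetry equals `mu` (default 0). Accepts either raw values or the
#' summary triple (mean, sd, n); the raw-value route computes the mean and
#' the n-1-denominator standard deviation first, so both routes agree
#' exactly. `t = (mean - mu) / (sd / sqrt(n))` on `n - 1` degrees of
#' freedom, two-tailed p from the t distribution.
#'
#' @param x optional numeric vector of raw values.
#' @param mean,sd,n summary statistics (used when `x` is `NULL`).
#' @param mu null-hypothesis mean, default 0.
#' @return a `torque_test` with fields `statistic`, `df`, `p.value`.
#' @export
one_sample_t <- function(x = NULL, mean = NULL, sd = NULL, n = NULL, mu = 0) {
  if (!is.null(x)) {
    n <- length(x)
    mean <- base::mean(x)
    sd <- stats::sd(x)
  }
  stopifnot(is.numeric(mean), is.numeric(sd), is.numeric(n))
  if (n < 2L) stop("need n >= 2")
  if (sd <= 0) stop("need sd > 0")
  t <- (mean - mu) / (sd / sqrt(n))
  df <- n - 1
  new_torque_test("one-sample t", t, df, 2 * stats::pt(-abs(t), df),
                  inputs = list(mean = mean, sd = sd, n = n, mu = mu))
}

#' Pearson chi-squared test on a 2x2 prevalence table
#'
#' Two-sample prevalence comparison on the table `rbind(c(a, b), c(c, d))`
#' (rows = groups, columns = configuration present / absent), *without*
#' continuity correction:
#' `X^2 = n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, df = 1.
#'
#' @param a,b,c,d non-negative cell counts.
#' @return a `torque_test`.
#' @export
chi2_prevalence <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  stopifnot(is.numeric(counts), all(counts >= 0))
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0)
    stop("zero marginal total; chi-squared undefined")
  n <- a + b + c + d
  stat <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  new_torque_test("chi-squared (2x2, uncorrected)", stat, 1,
                  stats::pchisq(stat, df = 1, lower.tail = FALSE),
                  inputs = list(table = matrix(c(a, b, c, d), 2L, 2L,
                                               byrow = TRUE)))
}

#' Pearson correlation with t-based p value
#'
#' Sample correlation of two equal-length vectors; significance from
#' `t = r sqrt((n-2) / (1-r^2))` on `n - 2` degrees of freedom (p = 0 for a
#' perfect correlation).
#'
#' @param x,y numeric vectors, same length >= 3, each with nonzero variance.
#' @return a `torque_test` with the correlation as `statistic` and the
#'   t value under `inputs$t`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("constant input; correlation undefined")
  r <- stats::cor(x, y)
  df <- n - 2
  if (abs(r) >= 1) {
    t <- Inf * sign(r)
    p <- 0
  } else {
    t <- r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), df)
  }
  new_torque_test("Pearson correlation", r, df, p,
                  inputs = list(n = n, t = t))
}

# classification labels for one feature over a cohort table (tibble from
# measure_cohort, or any data frame with the two value columns)
cohort_configurations <- function(cohort, feature) {
  fcol <- paste0(switch(feature, petalia = "petalia", shift = "shift",
                        bending = "bending"), "_frontal")
  ocol <- sub("_frontal", "_occipital", fcol)
  stopifnot(fcol %in% names(cohort), ocol %in% names(cohort))
  vapply(seq_len(nrow(cohort)), function(i)
    classify_configuration(cohort[[fcol]][i], cohort[[ocol]][i],
                           feature)$configuration,
    character(1L))
}

#' Configuration prevalence table for one torque feature
#'
#' Cross-tabulates the four frontal/occipital configurations of one feature
#' over a cohort, as percentages of the cohort size with row (occipital LO /
#' RO) and column (frontal LF / RF) marginals.
#'
#' @param cohort cohort table: a tibble/data.frame with columns
#'   `<feature>_frontal` and `<feature>_occipital` (as from
#'   [measure_cohort]).
#' @param feature `"petalia"`, `"shift"`, or `"bending"`.
#' @return list of class `prevalence_table`: integer `counts` and numeric
#'   `percent` 2x2 matrices (rows LO/RO, columns LF/RF), `row_percent` /
#'   `col_percent` marginals, `n`, `feature`.
#' @export
prevalence_table <- function(cohort, feature = c("petalia", "shift",
                                                 "bending")) {
  feature <- match.arg(feature)
  if (nrow(cohort) == 0L) stop("empty cohort")
  labels <- cohort_configurations(cohort, feature)
  f <- substr(labels, 1L, 2L)
  o <- substr(labels, 4L, 5L)
  counts <- table(factor(o, levels = c("LO", "RO")),
                  factor(f, levels = c("LF", "RF")))
  counts <- matrix(as.integer(counts), 2L, 2L,
                   dimnames = list(c("LO", "RO"), c("LF", "RF")))
  n <- length(labels)
  structure(list(counts = counts, percent = 100 * counts / n,
                 row_percent = 100 * rowSums(counts) / n,
                 col_percent = 100 * colSums(counts) / n,
                 n = n, feature = feature),
            class = "prevalence_table")
}

#' @export
print.prevalence_table <- function(x, ...) {
  cat(sprintf("<prevalence_table> %s, n = %d (%%)\n", x$feature, x$n))
  print(round(x$percent, 2))
  invisible(x)
}

#' Between-species prevalence comparison of one configuration
#'
#' Collapses each cohort to "in the configuration of interest" versus the
#' rest and applies the uncorrected 2x2 chi-squared test
#' ([chi2_prevalence]). The configuration may be a full quadrant
#' (e.g. `"RF/LO"`) or a single margin (`"LO"`, `"RO"`, `"LF"`, `"RF"`),
#' e.g. `"RO"` with `feature = "bending"` compares the prevalence of
#' rightward occipital bending.
#'
#' @param cohort_a,cohort_b cohort tables (see [prevalence_table]).
#' @param feature `"petalia"`, `"shift"`, or `"bending"`.
#' @param configuration quadrant label or margin label of interest.
#' @return a `torque_test`.
#' @export
species_comparison <- function(cohort_a, cohort_b,
                               feature = c("petalia", "shift", "bending"),
                               configuration = "RF/LO") {
  feature <- match.arg(feature)
  count_in <- function(cohort) {
    labels <- cohort_configurations(cohort, feature)
    hit <- if (grepl("/", configuration, fixed = TRUE)) {
      labels == configuration
    } else if (configuration %in% c("LF", "RF")) {
      substr(labels, 1L, 2L) == configuration
    } else if (configuration %in% c("LO", "RO")) {
      substr(labels, 4L, 5L) == configuration
    } else stop("unknown configuration: ", configuration)
    c(sum(hit), sum(!hit))
  }
  ca <- count_in(cohort_a)
  cb <- count_in(cohort_b)
  out <- chi2_prevalence(ca[1L], ca[2L], cb[1L], cb[2L])
  out$inputs$configuration <- configuration
  out$inputs$feature <- feature
  out
}

#' Reconstruct integer counts from printed prevalence percentages
#'
#' Published prevalence tables print percentages of known cohort sizes; the
#' implied integer counts are `round(pct/100 * n)`.
#'
#' @param percent numeric vector of percentages.
#' @param n cohort size.
#' @return integer counts.
#' @export
reconstruct_counts <- function(percent, n) {
  as.integer(round(percent / 100 * n))
}
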