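# Visit-to-visit reproducibility statistics: intraclass correlation
# ICC(1,1) and the within-subject coefficient of variation, with banded
# interpretation scales.

#' Intraclass correlation coefficient, model (1,1)
#'
#' One-way random-effects, single-measure, absolute-agreement ICC
#' (Shrout-Fleiss (1,1)): `(BMS - WMS) / (BMS + (k - 1) * WMS)` from the
#' one-way ANOVA decomposition over subjects with k = 2 visits. The p-value
#' is from the F ratio `BMS / WMS` on (n - 1, n * (k - 1)) degrees of
#' freedom. A two-way mixed-effects consistency variant, ICC(3,1), is
#' available via `model = "twoway"`.
#'
#' @param visit1,visit2 paired measurements (e.g. ARI per subject); pairs
#'   with a missing value are dropped listwise.
#' @param model `"oneway"` (ICC(1,1), primary) or `"twoway"` (ICC(3,1)).
#' @return list with `icc`, `p`, `n`, `model`.
#' @export
icc_1_1 <- function(visit1, visit2, model = c("oneway", "twoway")) {
  model <- match.arg(model)
  stopifnot(length(visit1) == length(visit2))
  ok <- is.finite(visit1) & is.finite(visit2)
  x <- cbind(visit1[ok], visit2[ok])
  n <- nrow(x); k <- 2
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::var(as.vector(x)) <= 0) stop("zero total variance")
  gm <- mean(x)
  sm <- rowMeans(x)  # subject means
  vm <- colMeans(x)  # visit means
  ss_between <- k * sum((sm - gm)^2)
  ss_within <- sum((x - sm)^2)
  bms <- ss_between / (n - 1)
  wms <- ss_within / (n * (k - 1))
  if (model == "oneway") {
    icc <- (bms - wms) / (bms + (k - 1) * wms)
    f <- bms / wms
    p <- stats::pf(f, n - 1, n * (k - 1), lower.tail = FALSE)
  } else {
    # ICC(3,1): remove the visit (rater) effect
    ss_visit <- n * sum((vm - gm)^2)
    ems <- (ss_within - ss_visit) / ((n - 1) * (k - 1))
    icc <- (bms - ems) / (bms + (k - 1) * ems)
    f <- bms / ems
    p <- stats::pf(f, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  }
  list(icc = icc, p = p, n = n, model = model)
}

#' Within-subject coefficient of variation across two visits
#'
#' Per-subject CV = SD of the two repeated measures divided by their mean,
#' averaged over subjects.
#'
#' @param visit1,visit2 paired measurements; incomplete pairs dropped.
#' @return mean CV (dimensionless).
#' @export
cv_within <- function(visit1, visit2) {
  stopifnot(length(visit1) == length(visit2))
  ok <- is.finite(visit1) & is.finite(visit2)
  x <- cbind(visit1[ok], visit2[ok])
  m <- rowMeans(x)
  if (any(m <= 0)) stop("non-positive pair mean; CV undefined")
  cv <- apply(x, 1, stats::sd) / m
  mean(cv)
}

#' Banded interpretation of a reproducibility statistic
#'
#' Half-open binning of a value against sorted cut points: the i-th label
#' applies on `[cut[i-1], cut[i])`.
#'
#' @param value numeric scalar.
#' @param cuts sorted interior cut points.
#' @param labels `length(cuts) + 1` labels, low to high.
#' @return the matching label.
#' @export
band_label <- function(value, cuts, labels) {
  stopifnot(!is.unsorted(cuts), length(labels) == length(cuts) + 1)
  labels[findInterval(value, cuts) + 1L]
}

#' @rdname band_label
#' @details `icc_band()` applies the Cicchetti cuts: poor (< 0.40), fair
#'   (0.40-0.59), good (0.60-0.74), excellent (0.75-1.00). `cv_band()`
#'   applies: very good (< 0.10), good (0.10-0.20), acceptable (0.20-0.30),
#'   not acceptable (> 0.30).
#' @export
icc_band <- function(value) {
  band_label(value, c(0.40, 0.60, 0.75), c("poor", "fair", "good", "excellent"))
}

#' @rdname band_label
#' @export
cv_band <- function(value) {
  band_label(value, c(0.10, 0.20, 0.30),
             c("very good", "good", "acceptable", "not acceptable"))
}

#' Reproducibility summary for one condition
#'
#' ICC(1,1) with its p-value and interpretation band, and mean
#' within-subject CV with its band, for one condition's paired visits.
#'
#' @inheritParams icc_1_1
#' @param condition label carried into the output row.
#' @return one-row data.frame: condition, n_pairs, icc, icc_p, icc_band,
#'   cv_mean, cv_band.
#' @export
repro_stats <- function(visit1, visit2, condition = "") {
  r <- icc_1_1(visit1, visit2)
  cv <- cv_within(visit1, visit2)
  data.frame(condition = condition, n_pairs = r$n, icc = r$icc, icc_p = r$p,
             icc_band = icc_band(r$icc), cv_mean = cv, cv_band = cv_band(cv),
             stringsAsFactors = FALSE)
}
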