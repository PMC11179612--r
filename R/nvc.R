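# Objective responder / non-responder classification of neurovascular
# coupling responses: cross-correlation-peak and variance-ratio criteria
# with null-calibrated thresholds.

#' Coherent average of task-locked response curves
#'
#' Pointwise mean across subjects of percent-change velocity curves
#' time-locked to task onset.
#'
#' @param curves numeric matrix, one column per curve, rows on a common
#'   time grid.
#' @return numeric vector (the average curve).
#' @export
coherent_average <- function(curves) {
  stopifnot(is.matrix(curves), ncol(curves) >= 2)
  rowMeans(curves)
}

#' Peak of the normalized cross-correlation function
#'
#' Maximum over lags in `[-max_lag_s, +max_lag_s]` of the Pearson
#' correlation between an individual response curve and a template (the
#' cohort coherent average), computed over the overlapping support at each
#' lag.
#'
#' @param individual,template numeric vectors on the same time grid.
#' @param rate samples/s of the grid.
#' @param max_lag_s lag search half-range, s.
#' @return list with `peak` (in \[-1, 1\]) and `lag_s` (lag at the peak).
#' @export
ccf_peak <- function(individual, template, rate = 5, max_lag_s = 5) {
  n <- length(individual)
  stopifnot(length(template) == n, max_lag_s >= 0)
  if (stats::sd(individual) == 0 || stats::sd(template) == 0) {
    stop("zero-variance input to cross-correlation")
  }
  K <- round(max_lag_s * rate)
  lags <- (-K):K
  vals <- vapply(lags, function(k) {
    if (k >= 0) {
      a <- individual[(1 + k):n]; b <- template[1:(n - k)]
    } else {
      a <- individual[1:(n + k)]; b <- template[(1 - k):n]
    }
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, numeric(1))
  i <- which.max(vals)
  list(peak = vals[i], lag_s = lags[i] / rate)
}

#' Variance ratio of post- vs pre-stimulation windows
#'
#' Ratio of the velocity-signal variance over a post-onset window to that
#' over a pre-onset window (an F-type statistic of the change in signal
#' power with stimulation).
#'
#' @param curve numeric response curve.
#' @param time_s time axis, s, relative to task onset.
#' @param pre_window_s,post_window_s half-open windows, s.
#' @return scalar variance ratio (>= 0).
#' @export
variance_ratio <- function(curve, time_s, pre_window_s = c(-30, 0),
                           post_window_s = c(0, 30)) {
  ipre <- window_index(time_s, pre_window_s[1], pre_window_s[2])
  ipost <- window_index(time_s, post_window_s[1], post_window_s[2])
  if (length(ipre) < 10 || length(ipost) < 10) {
    stop("each window must contain at least 10 samples")
  }
  vpre <- stats::var(curve[ipre])
  if (vpre <= 0) stop("zero variance in the pre-stimulation window")
  stats::var(curve[ipost]) / vpre
}

#' Classifier thresholds for responder detection
#'
#' The published 90% null-distribution confidence limits
#' (`ccf90 = 0.53`, `vr90 = 2.59`), or thresholds recalibrated from
#' unstimulated data via [recalibrate_thresholds()].
#'
#' @param ccf90 cross-correlation-peak threshold.
#' @param vr90 variance-ratio threshold.
#' @param alpha nominal per-criterion false-positive rate.
#' @param provenance `"published"` or a list describing a recalibration.
#' @return object of class `nvc_thresholds`.
#' @export
nvc_thresholds <- function(ccf90 = 0.53, vr90 = 2.59, alpha = 0.10,
                           provenance = "published") {
  stopifnot(ccf90 > 0, ccf90 < 1, vr90 > 0)
  structure(list(ccf90 = ccf90, vr90 = vr90, alpha = alpha,
                 provenance = provenance),
            class = "nvc_thresholds")
}

#' Responder / non-responder classification
#'
#' A response is labelled responder (`"R"`) if *either* the
#' cross-correlation peak exceeds `ccf90` *or* the variance ratio exceeds
#' `vr90` (strict inequalities); otherwise non-responder (`"NoR"`).
#'
#' @param ccf_peak cross-correlation peak value.
#' @param vr variance ratio.
#' @param thresholds an [nvc_thresholds()] object.
#' @return `"R"` or `"NoR"`.
#' @export
classify_nvc <- function(ccf_peak, vr, thresholds = nvc_thresholds()) {
  stopifnot(is.finite(ccf_peak), is.finite(vr))
  if (ccf_peak > thresholds$ccf90 || vr > thresholds$vr90) "R" else "NoR"
}

#' Recalibrate classifier thresholds from unstimulated data
#'
#' Computes the (1 - alpha) quantiles of the cross-correlation peak and of
#' the variance ratio over a set of unstimulated (null) percent-change
#' velocity curves. The cross-correlation template is the coherent average
#' of the null set itself, leave-one-out by default so that each curve is
#' not correlated against an average containing itself.
#'
#' @param null_curves numeric matrix of null curves (columns), on the grid
#'   `time_s`; at least 50 curves.
#' @param time_s time axis, s, relative to (sham) onset.
#' @param alpha per-criterion false-positive rate (0.10 for 90% limits).
#' @param rate samples/s.
#' @param max_lag_s lag search half-range for the cross-correlation.
#' @param template optional fixed template; overrides the null-set average.
#' @param leave_one_out exclude each curve from its own template.
#' @param pre_window_s,post_window_s variance-ratio windows.
#' @return an [nvc_thresholds()] object with recalibration provenance.
#' @export
recalibrate_thresholds <- function(null_curves, time_s, alpha = 0.10,
                                   rate = 5, max_lag_s = 5, template = NULL,
                                   leave_one_out = TRUE,
                                   pre_window_s = c(-30, 0),
                                   post_window_s = c(0, 30)) {
  stopifnot(is.matrix(null_curves), nrow(null_curves) == length(time_s))
  m <- ncol(null_curves)
  if (m < 50) stop("need at least 50 unstimulated curves for recalibration")
  stats_null <- nvc_metrics_set(null_curves, time_s, rate = rate,
                                max_lag_s = max_lag_s, template = template,
                                leave_one_out = leave_one_out,
                                pre_window_s = pre_window_s,
                                post_window_s = post_window_s)
  nvc_thresholds(
    ccf90 = unname(stats::quantile(stats_null$ccf_peak, 1 - alpha, type = 7)),
    vr90 = unname(stats::quantile(stats_null$vr, 1 - alpha, type = 7)),
    alpha = alpha,
    provenance = list(kind = "recalibrated", n_null = m,
                      leave_one_out = leave_one_out && is.null(template))
  )
}

#' Cross-correlation and variance-ratio metrics for a set of curves
#'
#' Computes, for every curve in a set, the peak cross-correlation against
#' the cohort template (leave-one-out coherent average by default) and the
#' pre/post variance ratio.
#'
#' @inheritParams recalibrate_thresholds
#' @param curves numeric matrix of response curves (columns).
#' @return data.frame with `ccf_peak`, `ccf_lag_s`, `vr`.
#' @export
nvc_metrics_set <- function(curves, time_s, rate = 5, max_lag_s = 5,
                            template = NULL, leave_one_out = TRUE,
                            pre_window_s = c(-30, 0),
                            post_window_s = c(0, 30)) {
  m <- ncol(curves)
  grand <- if (m >= 2) rowMeans(curves) else NULL
  out <- lapply(seq_len(m), function(i) {
    tpl <- if (!is.null(template)) {
      template
    } else if (leave_one_out && m >= 3) {
      (grand * m - curves[, i]) / (m - 1)
    } else {
      grand
    }
    if (is.null(tpl)) stop("no template available: supply one or >= 2 curves")
    cc <- ccf_peak(curves[, i], tpl, rate = rate, max_lag_s = max_lag_s)
    vr <- variance_ratio(curves[, i], time_s, pre_window_s, post_window_s)
    data.frame(ccf_peak = cc$peak, ccf_lag_s = cc$lag_s, vr = vr)
  })
  do.call(rbind, out)
}
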