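# Cohort-level orchestration: ARI estimation per recording and hemisphere,
# responder classification per subject x task, visit-to-visit
# reproducibility statistics.

#' Pipeline run configuration
#'
#' Collects the tunable settings of every pipeline stage with the standard
#' defaults; echoed into the run log.
#'
#' @param crcp_mmHg critical closing pressure for pressure normalization.
#' @param alpha significance of the coherence confidence limit.
#' @param limit_method `"mc"` or `"analytic"` (see [coherence_limit()]).
#' @param limit_seed seed of the surrogate coherence calibration.
#' @param fit_window_s ARI template fit window, s.
#' @param coherence_band coherence acceptance band, Hz.
#' @param thresholds responder thresholds: `"published"` or an
#'   [nvc_thresholds()] object.
#' @param nvc_alpha alpha used when recalibrating thresholds.
#' @param max_lag_s cross-correlation lag search half-range, s.
#' @return list of class `run_config`.
#' @export
run_config <- function(crcp_mmHg = 12, alpha = 0.05,
                       limit_method = c("mc", "analytic"), limit_seed = 1L,
                       fit_window_s = c(0, 10),
                       coherence_band = c(0.15, 0.25),
                       thresholds = "published", nvc_alpha = 0.10,
                       max_lag_s = 5) {
  structure(list(crcp_mmHg = crcp_mmHg, alpha = alpha,
                 limit_method = match.arg(limit_method),
                 limit_seed = limit_seed, fit_window_s = fit_window_s,
                 coherence_band = coherence_band, thresholds = thresholds,
                 nvc_alpha = nvc_alpha, max_lag_s = max_lag_s),
            class = "run_config")
}

# ARI for both hemispheres of one recording (uniform level).
ari_both_hemispheres <- function(rec, config, templates) {
  u <- rec$uniform
  seg_type <- if (rec$type == "task") "task" else "baseline"
  out <- lapply(c(left = "mcav_left", right = "mcav_right"), function(ch) {
    estimate_ari(u$map_mmHg, u[[ch]], rate = attr(u, "rate") %||% 5,
                 segment_type = seg_type, crcp = config$crcp_mmHg,
                 coherence_band = config$coherence_band,
                 alpha = config$alpha, limit_method = config$limit_method,
                 limit_seed = config$limit_seed,
                 fit_window_s = config$fit_window_s, templates = templates)
  })
  out
}

#' Run the full analysis over a synthetic cohort
#'
#' For every subject, visit and recording: estimates the ARI of both
#' hemispheres (baseline recordings with 512-sample segments, task
#' recordings with 256-sample segments) with the coherence and NMSE
#' acceptance gates; classifies each subject x task x hemisphere response
#' as responder or non-responder against the cohort's leave-one-out
#' coherent average; and computes visit-to-visit ICC(1,1) and
#' within-subject CV per condition from accepted ARI estimates
#' (non-accepted estimates are excluded from group statistics but retained,
#' flagged, in the batch table).
#'
#' @param cohort a [gen_cohort()] result.
#' @param config a [run_config()].
#' @return list of class `cohort_results`: `ari` (batch data.frame), `nvc`
#'   (classification data.frame), `repro` (reproducibility data.frame),
#'   `log` (settings, seeds, rejection tallies).
#' @export
run_cohort <- function(cohort, config = run_config()) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  spec <- cohort$spec
  if (!length(cohort$recordings)) stop("no recordings in cohort")
  templates <- make_templates(rate = spec$rate)
  thresholds <- if (inherits(config$thresholds, "nvc_thresholds")) {
    config$thresholds
  } else {
    nvc_thresholds()
  }

  ari_rows <- list()
  failures <- list()
  for (s in seq_along(cohort$recordings)) {
    for (v in seq_along(cohort$recordings[[s]])) {
      entry <- cohort$recordings[[s]][[v]]
      for (cond in names(entry)) {
        est <- tryCatch(
          ari_both_hemispheres(entry[[cond]], config, templates),
          error = function(e) e
        )
        if (inherits(est, "error")) {
          failures[[length(failures) + 1L]] <-
            list(subject = s, visit = v, condition = cond,
                 message = conditionMessage(est))
          next
        }
        for (h in c("left", "right")) {
          e <- est[[h]]
          ari_rows[[length(ari_rows) + 1L]] <- data.frame(
            subject = s, visit = v, condition = cond, hemisphere = h,
            ari = e$ari, nmse = e$nmse, mean_coherence = e$mean_coherence,
            coherence_limit = e$coherence_limit,
            coherence_pass = e$coherence_pass, nmse_pass = e$nmse_pass,
            accepted = e$accepted
          )
        }
      }
    }
  }
  ari <- do.call(rbind, ari_rows)

  # responder classification per task x visit x hemisphere
  nvc_rows <- list()
  rel_grid <- NULL
  for (task in spec$tasks) {
    for (v in seq_len(spec$n_visits)) {
      for (h in c("left", "right")) {
        ch <- paste0("mcav_", h, "_pct")
        curves <- vapply(seq_along(cohort$recordings), function(s) {
          cohort$recordings[[s]][[v]][[task]]$uniform[[ch]]
        }, numeric(nrow(cohort$recordings[[1]][[1]][[task]]$uniform)))
        onset <- cohort$recordings[[1]][[1]][[task]]$onset_s
        rel_grid <- cohort$recordings[[1]][[1]][[task]]$uniform$time_s - onset
        met <- nvc_metrics_set(curves, rel_grid, rate = spec$rate,
                               max_lag_s = config$max_lag_s)
        for (s in seq_len(ncol(curves))) {
          nvc_rows[[length(nvc_rows) + 1L]] <- data.frame(
            subject = s, visit = v, task = task, hemisphere = h,
            ccf_peak = met$ccf_peak[s], vr = met$vr[s],
            label = classify_nvc(met$ccf_peak[s], met$vr[s], thresholds),
            ccf90 = thresholds$ccf90, vr90 = thresholds$vr90
          )
        }
      }
    }
  }
  nvc <- do.call(rbind, nvc_rows)

  # visit-to-visit reproducibility per condition x hemisphere
  repro <- NULL
  if (spec$n_visits >= 2 && !is.null(ari)) {
    acc <- ari
    acc$ari[!acc$accepted] <- NA_real_
    conds <- unique(acc$condition)
    rows <- list()
    for (cond in conds) {
      for (h in c("left", "right")) {
        sub <- acc[acc$condition == cond & acc$hemisphere == h, ]
        v1 <- sub$ari[match(seq_len(spec$n_subjects),
                            ifelse(sub$visit == 1, sub$subject, NA))]
        v2 <- sub$ari[match(seq_len(spec$n_subjects),
                            ifelse(sub$visit == 2, sub$subject, NA))]
        r <- tryCatch(repro_stats(v1, v2,
                                  condition = paste(cond, h, sep = "_")),
                      error = function(e) NULL)
        if (!is.null(r)) rows[[length(rows) + 1L]] <- r
      }
    }
    repro <- if (length(rows)) do.call(rbind, rows) else NULL
  }

  structure(list(
    ari = ari, nvc = nvc, repro = repro,
    log = list(config = unclass(config), spec_seed = spec$seed,
               thresholds = unclass(thresholds),
               n_recording_failures = length(failures),
               failures = failures,
               n_rejected = if (is.null(ari)) 0L else sum(!ari$accepted))
  ), class = "cohort_results")
}

#' Group-mean ARI per condition and hemisphere
#'
#' Means of accepted ARI estimates across subjects and visits, the quantity
#' compared between baseline and task activation.
#'
#' @param results a [run_cohort()] result.
#' @return data.frame: condition, hemisphere, n, mean_ari, sd_ari.
#' @export
group_mean_ari <- function(results) {
  a <- results$ari
  a <- a[a$accepted, ]
  agg <- stats::aggregate(ari ~ condition + hemisphere, data = a,
                          FUN = function(z) c(n = length(z), mean = mean(z),
                                              sd = stats::sd(z)))
  data.frame(condition = agg$condition, hemisphere = agg$hemisphere,
             n = agg$ari[, "n"], mean_ari = agg$ari[, "mean"],
             sd_ari = agg$ari[, "sd"])
}
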