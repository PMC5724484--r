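# Predictor tracks: per-subject piecewise-constant functions psi_i(t) that
# feed the hazard model as time-varying covariates. A track is a tidy
# tibble with one row per constant segment: subject_id, start (segment start
# time) and one or more value columns ("biomarker" for the observed-value
# summaries; "b0"/"b1" for the random-effect plug-ins). Segments run from
# `start` to the next row's start (or the subject's follow-up end), so a
# measurement at time t acts on the hazard just after t (predictability),
# while a prediction made at t_p = t may use it.

new_track <- function(tb, model) {
  attr(tb, "model") <- model
  tb
}

#' Model of a predictor track
#' @param tracks A track tibble.
#' @return The model tag ("bcf", "locf", "ca", "ewma", "orc", "rrc").
#' @export
track_model <- function(tracks) attr(tracks, "model")

track_base <- function(x) {
  long <- dplyr::arrange(x$longitudinal, .data$subject_id, .data$time)
  base <- long[long$time == 0, , drop = FALSE]
  if (!all(x$survival$subject_id %in% base$subject_id))
    abort("every subject needs a baseline (time 0) measurement")
  long
}

#' Baseline-carried-forward predictor track
#'
#' The baseline biomarker value acts on the hazard throughout follow-up:
#' one constant segment per subject.
#'
#' @param x A `longsurv` cohort.
#' @return Track tibble with value column `biomarker`.
#' @export
track_bcf <- function(x) {
  long <- track_base(x)
  base <- long[long$time == 0, , drop = FALSE]
  new_track(tibble::tibble(subject_id = base$subject_id, start = 0,
                           biomarker = base$value), "bcf")
}

#' Last-observation-carried-forward predictor track
#'
#' The most recent measurement acts on the hazard until the next one: the
#' track steps to each new value at its measurement time.
#'
#' @inheritParams track_bcf
#' @return Track tibble with value column `biomarker`.
#' @export
track_locf <- function(x) {
  long <- track_base(x)
  new_track(tibble::tibble(subject_id = long$subject_id, start = long$time,
                           biomarker = long$value), "locf")
}

#' Cumulative-average predictor track
#'
#' Segment k carries the running mean of all measurements up to and
#' including the k-th; averaging damps measurement error, so the track
#' partially corrects regression dilution without any model fitting.
#'
#' @inheritParams track_bcf
#' @return Track tibble with value column `biomarker`.
#' @export
track_ca <- function(x) {
  long <- track_base(x)
  long <- dplyr::group_by(long, .data$subject_id)
  long <- dplyr::mutate(long,
                        biomarker = cumsum(.data$value) / dplyr::row_number())
  long <- dplyr::ungroup(long)
  new_track(tibble::tibble(subject_id = long$subject_id, start = long$time,
                           biomarker = long$biomarker), "ca")
}

#' Exponentially weighted moving-average predictor track
#'
#' A weighted cumulative average discounting older measurements: at segment
#' k the value is `sum_j w_j x_j / sum_j w_j` with `w_j =
#' 2^{-(t_k - t_j)/halflife}`. The limit `halflife -> Inf` recovers the
#' cumulative average; `halflife -> 0` recovers last observation carried
#' forward.
#'
#' @inheritParams track_bcf
#' @param halflife Discounting half-life in years (> 0).
#' @return Track tibble with value column `biomarker`.
#' @export
track_ewma <- function(x, halflife) {
  if (!is.numeric(halflife) || halflife <= 0) abort("halflife must be > 0")
  long <- track_base(x)
  ew <- function(t, v) {
    vapply(seq_along(t), function(k) {
      w <- 2^(-(t[k] - t[seq_len(k)]) / halflife)
      sum(w * v[seq_len(k)]) / sum(w)
    }, numeric(1))
  }
  long <- dplyr::group_by(long, .data$subject_id)
  long <- dplyr::mutate(long, biomarker = ew(.data$time, .data$value))
  long <- dplyr::ungroup(long)
  new_track(tibble::tibble(subject_id = long$subject_id, start = long$time,
                           biomarker = long$biomarker), "ewma")
}

#' Ordinary regression calibration track
#'
#' Stage 1 of the two-stage approach: a single mixed model is fitted to all
#' subjects and all measurements, and each subject's empirical Bayes
#' `(b0, b1)` pair is used as a pair of time-constant predictors (one
#' association parameter per random effect).
#'
#' @inheritParams track_bcf
#' @param fit Optionally a pre-computed `lmm_fit` on `x` (all data).
#' @return Track tibble with value columns `b0`, `b1`; the stage-1 fit is
#'   attached as attribute `"fit"`.
#' @export
track_orc <- function(x, fit = NULL) {
  fit <- fit %||% fit_lmm(x)
  tr <- tibble::tibble(subject_id = fit$blups$subject_id, start = 0,
                       b0 = fit$blups$b0, b1 = fit$blups$b1)
  # subjects without any measurement would be absent; cohort invariants
  # guarantee at least a baseline value, so tr covers everyone.
  out <- new_track(tr, "orc")
  attr(out, "fit") <- fit
  out
}

#' Risk-set regression calibration track
#'
#' The mixed model is refitted at each update time on the subjects still at
#' risk, using only their past measurements ([rrc_refit_schedule()]); a
#' subject's `(b0, b1)` pair is updated at every refit that includes them.
#' Before the first update time every subject carries a baseline-only
#' empirical Bayes estimate under the first refit's parameters, so the
#' stage-2 survival likelihood retains all early risk sets; subjects whose
#' follow-up ends before the first update time never enter any refit and
#' are flagged `out_of_risk_set`. Predictions (as opposed to hazard
#' fitting) are not available before the first update time.
#'
#' @inheritParams track_bcf
#' @param update_times Ascending refit times (> 0); typically the repeat
#'   visit times.
#' @param fits Optionally a pre-computed [rrc_refit_schedule()] result.
#' @return Track tibble with value columns `b0`, `b1` and logical
#'   `out_of_risk_set`; the refit schedule is attached as attribute
#'   `"fits"` and the update times as `"update_times"`.
#' @export
track_rrc <- function(x, update_times, fits = NULL) {
  fits <- fits %||% rrc_refit_schedule(x, update_times)
  surv <- x$survival
  first_fit <- fits[[1]]

  # pre-first-update segment: baseline-only empirical Bayes under fit 1
  seg0 <- blup_at(first_fit, x, time_cutoff = min(x$longitudinal$time))
  seg0 <- tibble::tibble(subject_id = seg0$subject_id, start = 0,
                         b0 = seg0$b0, b1 = seg0$b1)
  in_any <- unique(unlist(lapply(fits, function(f) f$blups$subject_id)))
  seg0$out_of_risk_set <- !(seg0$subject_id %in% in_any)

  segs <- list(seg0)
  for (k in seq_along(fits)) {
    f <- fits[[k]]
    tau <- update_times[k]
    keep <- surv$followup_time[match(f$blups$subject_id,
                                     surv$subject_id)] > tau
    bl <- f$blups[keep, , drop = FALSE]
    if (nrow(bl) > 0)
      segs[[length(segs) + 1]] <- tibble::tibble(
        subject_id = bl$subject_id, start = tau,
        b0 = bl$b0, b1 = bl$b1, out_of_risk_set = FALSE)
  }
  tr <- dplyr::arrange(dplyr::bind_rows(segs), .data$subject_id, .data$start)
  out <- new_track(tr, "rrc")
  attr(out, "fits") <- fits
  attr(out, "update_times") <- update_times
  out
}

#' Evaluate a predictor track at a prediction time
#'
#' Returns the track value usable for a prediction made at `t_p`: the
#' segment with the latest start not exceeding `t_p` (a measurement taken
#' exactly at `t_p` is usable at `t_p`). For risk-set regression
#' calibration tracks, subjects are only predictable from the first update
#' time onwards; earlier `t_p` raises an error.
#'
#' @param tracks A track tibble.
#' @param t_p Prediction time in years.
#' @return Tibble `subject_id` plus the track's value columns, one row per
#'   subject present in the track.
#' @export
psi_at <- function(tracks, t_p) {
  stopifnot(t_p >= 0)
  if (identical(track_model(tracks), "rrc")) {
    ut <- attr(tracks, "update_times")
    if (!is.null(ut) && t_p < min(ut))
      abort(paste0("risk-set regression calibration predictions need at ",
                   "least one repeat measurement: t_p must be >= ", min(ut)))
    tracks <- tracks[!tracks$out_of_risk_set, , drop = FALSE]
  }
  tr <- tracks[tracks$start <= t_p, , drop = FALSE]
  tr <- dplyr::slice_tail(dplyr::group_by(
    dplyr::arrange(tr, .data$subject_id, .data$start), .data$subject_id),
    n = 1)
  tr <- dplyr::ungroup(tr)
  tr[setdiff(names(tr), c("start", "model", "out_of_risk_set"))]
}
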