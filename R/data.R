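#' Bundle longitudinal biomarker records with per-subject survival records
#'
#' A `longsurv` cohort couples a long-format table of intermittent biomarker
#' measurements with a one-row-per-subject survival table. Follow-up time is
#' measured in years from study entry; measurement times must be strictly
#' increasing within subject and strictly before the subject's follow-up time
#' (measurements recorded at or after the event/censoring time carry no
#' information for a predictable hazard and are dropped with a message).
#'
#' @param longitudinal Data frame with columns `subject_id`, `time`, `value`.
#' @param survival Data frame with columns `subject_id`, `followup_time`,
#'   `event` (0/1) plus any baseline covariate columns.
#' @param covariate_names Character vector naming the baseline covariate
#'   columns of `survival`. Defaults to every column beyond the three
#'   required ones.
#' @param require_baseline Should subjects lacking a measurement at time 0 be
#'   rejected (`TRUE`, default) or kept with a warning (`FALSE`)?
#'
#' @return An object of class `longsurv`: a list with tibbles `longitudinal`
#'   and `survival`, plus `covariate_names` and `n_dropped` (count of
#'   measurements removed for falling at/after follow-up).
#' @export
longsurv <- function(longitudinal, survival, covariate_names = NULL,
                     require_baseline = TRUE) {
  longitudinal <- tibble::as_tibble(longitudinal)
  survival <- tibble::as_tibble(survival)
  if ("subject_id" %in% names(longitudinal))
    longitudinal$subject_id <- as.character(longitudinal$subject_id)
  if ("subject_id" %in% names(survival))
    survival$subject_id <- as.character(survival$subject_id)
  need_l <- c("subject_id", "time", "value")
  need_s <- c("subject_id", "followup_time", "event")
  if (!all(need_l %in% names(longitudinal)))
    abort("`longitudinal` needs columns subject_id, time, value")
  if (!all(need_s %in% names(survival)))
    abort("`survival` needs columns subject_id, followup_time, event")
  covariate_names <- covariate_names %||% setdiff(names(survival), need_s)
  if (anyDuplicated(survival$subject_id))
    abort("duplicate subject_id in survival table")
  if (!all(longitudinal$subject_id %in% survival$subject_id))
    abort("longitudinal table contains subject_id absent from survival table")
  for (col in c("time", "value"))
    if (!is.numeric(longitudinal[[col]]))
      abort(paste0("longitudinal column `", col, "` must be numeric"))
  if (!is.numeric(survival$followup_time) || any(survival$followup_time <= 0))
    abort("followup_time must be numeric and > 0")
  if (!all(survival$event %in% c(0, 1)))
    abort("event must be 0/1")
  if (any(longitudinal$time < 0)) abort("measurement times must be >= 0")
  if (anyDuplicated(longitudinal[c("subject_id", "time")]))
    abort("duplicate (subject_id, time) measurement")

  longitudinal <- dplyr::arrange(longitudinal, .data$subject_id, .data$time)
  fu <- setNames(survival$followup_time, survival$subject_id)
  late <- longitudinal$time >= fu[as.character(longitudinal$subject_id)]
  n_dropped <- sum(late)
  if (n_dropped > 0) {
    inform(paste0("Dropped ", n_dropped,
                  " measurement(s) taken at or after follow-up time."))
    longitudinal <- longitudinal[!late, , drop = FALSE]
  }
  has_base <- unique(longitudinal$subject_id[longitudinal$time == 0])
  missing_base <- setdiff(survival$subject_id, has_base)
  if (length(missing_base) > 0) {
    msg <- paste0(length(missing_base),
                  " subject(s) have no baseline (time 0) measurement")
    if (require_baseline) abort(msg) else warn(msg)
  }
  structure(
    list(longitudinal = longitudinal, survival = survival,
         covariate_names = covariate_names, n_dropped = n_dropped),
    class = "longsurv")
}

#' @export
print.longsurv <- function(x, ...) {
  cat("<longsurv> cohort:", nrow(x$survival), "subjects,",
      nrow(x$longitudinal), "measurements,",
      sum(x$survival$event), "events\n")
  if (length(x$covariate_names))
    cat("baseline covariates:", paste(x$covariate_names, collapse = ", "), "\n")
  invisible(x)
}

#' Number of subjects in a cohort
#' @param x A `longsurv` object.
#' @return Integer count.
#' @export
n_subjects <- function(x) nrow(x$survival)

#' Read a cohort from the two standard CSV files
#'
#' The long file has columns `subject_id,time,value`; the survival file has
#' `subject_id,followup_time,event` plus covariate columns. Headers required.
#'
#' @param long_path,surv_path Paths to the two CSV files.
#' @inheritParams longsurv
#' @return A [longsurv] object.
#' @export
read_longsurv <- function(long_path, surv_path, require_baseline = TRUE) {
  # base read.csv parses doubles via strtod, which is exact to the last bit
  # (a written cohort reads back bitwise identical)
  long <- utils::read.csv(long_path)
  surv <- utils::read.csv(surv_path)
  long$time <- as.double(long$time)
  long$value <- as.double(long$value)
  surv$followup_time <- as.double(surv$followup_time)
  longsurv(long, surv, require_baseline = require_baseline)
}

#' Write a cohort to the two standard CSV files
#' @param x A `longsurv` object.
#' @inheritParams read_longsurv
#' @return `x`, invisibly.
#' @export
write_longsurv <- function(x, long_path, surv_path) {
  stopifnot(inherits(x, "longsurv"))
  # full %.17g precision so a write/read cycle reproduces doubles bitwise
  fmt <- function(tb) {
    for (nm in names(tb))
      if (is.double(tb[[nm]])) tb[[nm]] <- sprintf("%.17g", tb[[nm]])
    tb
  }
  readr::write_csv(fmt(x$longitudinal), long_path)
  readr::write_csv(fmt(x$survival), surv_path)
  invisible(x)
}

#' Subjects still at risk at a time point
#'
#' Two conventions are needed. At a prediction time the risk set is
#' `followup > t` (a subject whose follow-up ends exactly at `t` cannot
#' receive a prediction). At an event time inside the C-index sum the failing
#' subject belongs to its own risk set, so `followup >= t` is used.
#'
#' @param x A `longsurv` object.
#' @param t Time in years (>= 0).
#' @param convention `"prediction"` (strict `>`) or `"event"` (`>=`).
#' @return Vector of subject ids.
#' @export
risk_set <- function(x, t, convention = c("prediction", "event")) {
  convention <- match.arg(convention)
  stopifnot(t >= 0)
  fu <- x$survival$followup_time
  keep <- if (convention == "prediction") fu > t else fu >= t
  x$survival$subject_id[keep]
}

#' Split follow-up into counting-process episodes along a predictor track
#'
#' Each subject's follow-up `(0, T*]` is partitioned at the track's
#' change-points; within an episode the time-varying predictor is constant,
#' and the event indicator is placed in the final episode. Baseline
#' covariates named in `x$covariate_names` are carried onto every episode.
#'
#' @param x A `longsurv` object.
#' @param tracks A predictor-track tibble as returned by the `track_*()`
#'   builders: columns `subject_id`, `start` and one or more predictor value
#'   columns; rows are segment starts.
#' @return Tibble with columns `subject_id`, `start`, `stop`, `event` and the
#'   predictor/covariate columns, one row per episode.
#' @export
episode_split <- function(x, tracks) {
  stopifnot(inherits(x, "longsurv"))
  tracks <- tibble::as_tibble(tracks)
  if (nrow(tracks) == 0) abort("empty predictor track")
  val_cols <- setdiff(names(tracks), c("subject_id", "start", "model"))
  surv <- x$survival[c("subject_id", "followup_time", "event",
                       x$covariate_names)]
  ep <- dplyr::inner_join(tracks, surv, by = "subject_id")
  if (nrow(ep) < nrow(tracks))
    abort("track contains subject_id absent from the cohort")
  if (any(ep$start >= ep$followup_time))
    abort("track change-point at or beyond follow-up time")
  ep <- dplyr::arrange(ep, .data$subject_id, .data$start)
  chk <- dplyr::summarise(
    dplyr::group_by(ep, .data$subject_id),
    ok = dplyr::first(.data$start) == 0 &&
      !is.unsorted(.data$start, strictly = TRUE))
  if (!all(chk$ok))
    abort("track segments must start at 0 and have strictly increasing starts")
  ep <- dplyr::group_by(ep, .data$subject_id)
  ep <- dplyr::mutate(
    ep,
    stop = dplyr::lead(.data$start, default = dplyr::first(.data$followup_time)),
    last = dplyr::row_number() == dplyr::n())
  ep <- dplyr::ungroup(ep)
  ep$event <- as.integer(ep$last & ep$event == 1)
  ep[c("subject_id", "start", "stop", "event", val_cols, x$covariate_names)]
}
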