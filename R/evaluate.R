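# Dynamic risk prediction and its evaluation layer. All implemented
# predictor constructions give a linear predictor that is constant over the
# prediction window, so the L-year risk from t_p is
#   P_iL(t_p) = 1 - [S0(t_p + L) / S0(t_p)]^exp(lp_i).

#' L-year risk predictions from a fitted survival model
#'
#' @param fit A `ph_fit` or `joint_fit`.
#' @param newdata Tibble with `subject_id` plus one column per fitted
#'   covariate, holding each subject's predictor values usable at `t_p`
#'   (e.g. from [psi_at()] or [eb_random_effects()], joined with baseline
#'   covariates where the model has any).
#' @param t_p Prediction time (years); subjects handed in are assumed to be
#'   at risk at `t_p`.
#' @param L Prediction horizon (years, >= 0).
#' @return Tibble `subject_id`, `t_p`, `L`, `lp`, `risk`.
#' @export
predict_risk <- function(fit, newdata, t_p, L) {
  stopifnot(t_p >= 0, L >= 0)
  newdata <- tibble::as_tibble(newdata)
  if (inherits(fit, "joint_fit")) {
    covs <- c("b0", "b1", fit$covariates_surv)
    cf <- c(fit$alpha,
            if (length(fit$covariates_surv))
              fit$coef[paste0("surv_", fit$covariates_surv)] else numeric(0))
    s0 <- function(t) joint_baseline_survival(fit, t)
  } else if (inherits(fit, "ph_fit")) {
    covs <- fit$covariates
    cf <- fit$coef[covs]
    s0 <- function(t) baseline_survival(fit, t)
  } else abort("fit must be a ph_fit or joint_fit")
  miss <- setdiff(covs, names(newdata))
  if (length(miss))
    abort(paste("newdata lacks predictor column(s):",
                paste(miss, collapse = ", ")))
  lp <- if (length(covs))
    as.vector(as.matrix(newdata[covs]) %*% cf) else
      rep(0, nrow(newdata))
  risk <- 1 - (s0(t_p + L) / s0(t_p))^exp(lp)
  tibble::tibble(subject_id = newdata$subject_id, t_p = t_p, L = L,
                 lp = lp, risk = risk)
}

check_pred_truth <- function(predictions, truth, t_p) {
  predictions <- tibble::as_tibble(predictions)
  truth <- tibble::as_tibble(truth)
  stopifnot(all(c("subject_id", "risk") %in% names(predictions)),
            all(c("subject_id", "followup_time", "event") %in% names(truth)))
  truth$subject_id <- as.character(truth$subject_id)
  predictions$subject_id <- as.character(predictions$subject_id)
  if (anyDuplicated(predictions$subject_id))
    abort("duplicate subject in predictions")
  j <- dplyr::inner_join(predictions[c("subject_id", "risk")],
                         truth[c("subject_id", "followup_time", "event")],
                         by = "subject_id")
  if (nrow(j) < nrow(predictions))
    abort("truth lacks outcomes for some predicted subjects")
  j[j$followup_time > t_p, , drop = FALSE]
}

# raw concordance sums: per-event numerator terms and risk-set sizes
cindex_terms <- function(tb, t_p, L) {
  ev <- which(tb$event == 1 & tb$followup_time >= t_p &
                tb$followup_time <= t_p + L)
  if (length(ev) == 0) return(NULL)
  num <- numeric(length(ev)); ym1 <- numeric(length(ev))
  for (kk in seq_along(ev)) {
    i <- ev[kk]
    r <- tb$followup_time >= tb$followup_time[i]
    r[i] <- FALSE
    num[kk] <- sum(tb$risk[r] < tb$risk[i]) +
      0.5 * sum(tb$risk[r] == tb$risk[i])
    ym1[kk] <- sum(r)
  }
  list(ev = ev, num = num, ym1 = ym1)
}

# leave-one-out C values via increment bookkeeping (no re-enumeration)
cindex_loo <- function(tb, terms) {
  n <- nrow(tb)
  N <- sum(terms$num); D <- sum(terms$ym1)
  dN <- numeric(n); dD <- numeric(n)
  # removing subject k removes (a) its own event term, (b) its presence in
  # other events' risk sets
  dN[terms$ev] <- dN[terms$ev] + terms$num
  dD[terms$ev] <- dD[terms$ev] + terms$ym1
  for (kk in seq_along(terms$ev)) {
    i <- terms$ev[kk]
    r <- which(tb$followup_time >= tb$followup_time[i])
    r <- setdiff(r, i)
    contrib <- (tb$risk[r] < tb$risk[i]) + 0.5 * (tb$risk[r] == tb$risk[i])
    dN[r] <- dN[r] + contrib
    dD[r] <- dD[r] + 1
  }
  # note: when k is itself an event, its own-term removal and risk-set
  # removals are disjoint, so the increments add correctly
  (N - dN) / (D - dD)
}

#' Dynamic (windowed) Harrell C-index
#'
#' Concordance of `L`-year risk predictions made at `t_p`, computed among
#' the predicted subjects still at risk at `t_p`. Each event time in
#' `[t_p, t_p + L]` contributes the number of at-risk subjects with a
#' strictly lower prediction (ties count one half) against a denominator of
#' risk-set size minus one; the failing subject belongs to its own risk set
#' (`>=` convention). The standard error is a leave-one-subject-out
#' jackknife.
#'
#' @param predictions Tibble `subject_id`, `risk` (one prediction per
#'   subject, all sharing `t_p` and `L`).
#' @param truth Tibble `subject_id`, `followup_time`, `event` giving the
#'   outcomes the predictions are judged against.
#' @param t_p,L Window start and length (years).
#' @return Tibble of class `dynamic_metric`: `metric`, `t_p`, `L`, `value`,
#'   `se`, `n_at_risk`, `n_events_in_window`.
#' @export
dynamic_cindex <- function(predictions, truth, t_p, L) {
  tb <- check_pred_truth(predictions, truth, t_p)
  terms <- cindex_terms(tb, t_p, L)
  if (is.null(terms)) {
    warn("no events inside the prediction window: C-index undefined")
    return(tibble::tibble(metric = "cindex", t_p = t_p, L = L,
                          value = NA_real_, se = NA_real_,
                          n_at_risk = nrow(tb), n_events_in_window = 0L))
  }
  C <- sum(terms$num) / sum(terms$ym1)
  loo <- cindex_loo(tb, terms)
  ok <- is.finite(loo)
  n <- sum(ok)
  se <- sqrt((n - 1) / n * sum((loo[ok] - mean(loo[ok]))^2))
  tibble::tibble(metric = "cindex", t_p = t_p, L = L, value = C, se = se,
                 n_at_risk = nrow(tb),
                 n_events_in_window = length(terms$ev))
}

#' Difference in dynamic C-index between two prediction sets
#'
#' `C_B - C_A` for two models evaluated on the same subjects, with a paired
#' leave-one-subject-out jackknife standard error that accounts for the
#' correlation between the two estimates.
#'
#' @param predictions_a,predictions_b Prediction tibbles over identical
#'   subjects (A is the reference).
#' @inheritParams dynamic_cindex
#' @return Tibble as in [dynamic_cindex()] with `metric = "delta_cindex"`.
#' @export
delta_cindex <- function(predictions_a, predictions_b, truth, t_p, L) {
  pa <- tibble::as_tibble(predictions_a)
  pb <- tibble::as_tibble(predictions_b)
  if (!setequal(pa$subject_id, pb$subject_id))
    abort("the two prediction sets must cover the same subjects")
  pb <- pb[match(pa$subject_id, pb$subject_id), , drop = FALSE]
  ta <- check_pred_truth(pa, truth, t_p)
  tb <- check_pred_truth(pb, truth, t_p)
  terms_a <- cindex_terms(ta, t_p, L)
  terms_b <- cindex_terms(tb, t_p, L)
  if (is.null(terms_a) || is.null(terms_b))
    return(tibble::tibble(metric = "delta_cindex", t_p = t_p, L = L,
                          value = NA_real_, se = NA_real_,
                          n_at_risk = nrow(ta), n_events_in_window = 0L))
  dC <- sum(terms_b$num) / sum(terms_b$ym1) -
    sum(terms_a$num) / sum(terms_a$ym1)
  loo <- cindex_loo(tb, terms_b) - cindex_loo(ta, terms_a)
  ok <- is.finite(loo)
  n <- sum(ok)
  se <- sqrt((n - 1) / n * sum((loo[ok] - mean(loo[ok]))^2))
  tibble::tibble(metric = "delta_cindex", t_p = t_p, L = L, value = dC,
                 se = se, n_at_risk = nrow(ta),
                 n_events_in_window = length(terms_a$ev))
}

# Kaplan-Meier of the censoring distribution on the at-risk subset,
# evaluated as a right-continuous step function (1 before the first step).
censoring_km <- function(time, event) {
  cf <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  stats::stepfun(cf$time, c(1, cf$surv), right = FALSE)
}

#' Dynamic Brier score with inverse-probability-of-censoring weights
#'
#' Mean squared difference between predicted `L`-year risk and the observed
#' window outcome among subjects at risk at `t_p`. Subjects censored inside
#' the window get weight zero; events inside the window are weighted by
#' `1/G(T_i)` and survivors beyond the window by `1/G(t_p + L)`, where `G`
#' is the Kaplan-Meier estimate of the censoring distribution on the
#' at-risk subset. The standard error treats the weights as fixed
#' (empirical SE of the weighted per-subject terms).
#'
#' @inheritParams dynamic_cindex
#' @return Tibble as in [dynamic_cindex()] with `metric = "brier"`.
#' @export
dynamic_brier <- function(predictions, truth, t_p, L) {
  tb <- check_pred_truth(predictions, truth, t_p)
  G <- censoring_km(tb$followup_time, tb$event)
  horizon <- t_p + L
  in_window <- tb$followup_time <= horizon
  w <- numeric(nrow(tb))
  w[in_window & tb$event == 1] <-
    1 / G(tb$followup_time[in_window & tb$event == 1])
  w[!in_window] <- 1 / G(horizon)
  if (any(!is.finite(w)))
    abort("censoring survival estimate is zero at a needed time")
  terms <- (tb$risk - as.numeric(in_window & tb$event == 1))^2 * w
  bs <- mean(terms)
  tibble::tibble(metric = "brier", t_p = t_p, L = L, value = bs,
                 se = sd(terms) / sqrt(length(terms)),
                 n_at_risk = nrow(tb),
                 n_events_in_window = sum(in_window & tb$event == 1))
}

#' Decile calibration table for dynamic risk predictions
#'
#' Groups at-risk subjects by quantiles of predicted risk and compares the
#' group mean predicted risk with the observed risk `1 - KM(t_p + L)` from
#' a Kaplan-Meier estimate within the group, administratively censoring
#' subjects still at risk at the window end.
#'
#' @inheritParams dynamic_cindex
#' @param n_groups Number of quantile groups (default 10).
#' @return Tibble of class `calibration_table`: per group, `group`,
#'   `risk_lo`, `risk_hi`, `n`, `mean_predicted`, `observed`, `km_se`.
#' @export
calibration_table <- function(predictions, truth, t_p, L, n_groups = 10) {
  tb <- check_pred_truth(predictions, truth, t_p)
  if (nrow(tb) < n_groups)
    abort("fewer at-risk subjects than requested groups")
  brks <- unique(quantile(tb$risk, probs = seq(0, 1, length.out =
                                                 n_groups + 1)))
  if (length(brks) - 1 < n_groups)
    warn("tied predictions: fewer calibration groups than requested")
  grp <- cut(tb$risk, breaks = brks, include.lowest = TRUE)
  horizon <- t_p + L
  time2 <- pmin(tb$followup_time, horizon) - t_p
  status <- as.integer(tb$event == 1 & tb$followup_time <= horizon)
  keep_lvls <- levels(grp)[tabulate(grp, nbins = nlevels(grp)) > 0]
  out <- lapply(keep_lvls, function(g) {
    ix <- grp == g
    km <- survival::survfit(survival::Surv(time2[ix], status[ix]) ~ 1)
    sm <- summary(km, times = L, extend = TRUE)
    tibble::tibble(group = g,
                   risk_lo = min(tb$risk[ix]), risk_hi = max(tb$risk[ix]),
                   n = sum(ix), mean_predicted = mean(tb$risk[ix]),
                   observed = 1 - sm$surv, km_se = sm$std.err)
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("calibration_table", class(out))
  out
}
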