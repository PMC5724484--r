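#' Data-generating parameters for the simulation scenarios
#'
#' The generator couples a random-intercept random-slope biomarker trajectory
#' (in mmHg, visits every three years) with an exponential hazard whose
#' log-linear predictor loads on the two random effects:
#' `x_ij = (beta0 + b0i) + (beta1 + b1i) t_ij + eps_ij`,
#' `h_i(t) = lam * exp(alpha0 * b0i + alpha1 * b1i)`, administrative
#' censoring at `admin_censor` years. Four stock scenarios vary the slope
#' heterogeneity, event rate and intercept-slope correlation.
#'
#' @param scenario Integer 1-4 selecting a stock scenario.
#' @return A `scenario_parameters` list with elements `beta0`, `beta1`
#'   (mmHg, mmHg/year), `sigma_e` (within-person SD, mmHg), `sigma0`,
#'   `sigma1` (random-effect SDs), `rho` (intercept-slope correlation),
#'   `lam` (baseline rate, events/person-year), `alpha0`, `alpha1` (log-HR
#'   per unit random effect), `visit_times` (years) and `admin_censor`
#'   (years).
#' @export
scenario_parameters <- function(scenario) {
  if (!scenario %in% 1:4) abort("scenario must be 1, 2, 3 or 4")
  base <- list(beta0 = 120, beta1 = 0.3, sigma_e = 10, sigma0 = 15,
               sigma1 = 1, rho = -0.2, lam = 0.005,
               alpha0 = 0.035, alpha1 = 0.15,
               visit_times = c(0, 3, 6, 9), admin_censor = 15)
  mod <- switch(scenario,
                `1` = list(),
                `2` = list(sigma1 = 5),
                `3` = list(sigma1 = 5, lam = 0.06),
                `4` = list(sigma1 = 5, rho = 0))
  out <- utils::modifyList(base, mod)
  out$scenario <- scenario
  validate_scenario_parameters(out)
}

#' Build a custom set of generator parameters
#'
#' @param ... Named overrides of any scenario-1 value (see
#'   [scenario_parameters()] for names and units).
#' @return A validated `scenario_parameters` list.
#' @export
custom_parameters <- function(...) {
  out <- utils::modifyList(scenario_parameters(1), list(...))
  out$scenario <- NA_integer_
  validate_scenario_parameters(out)
}

validate_scenario_parameters <- function(p) {
  stopifnot(p$sigma_e > 0, p$sigma0 > 0, p$sigma1 > 0, p$lam > 0,
            p$rho > -1, p$rho < 1,
            p$visit_times[1] == 0,
            !is.unsorted(p$visit_times, strictly = TRUE),
            p$admin_censor > max(p$visit_times))
  structure(p, class = "scenario_parameters")
}

#' @export
print.scenario_parameters <- function(x, ...) {
  cat("<scenario_parameters>",
      if (!is.na(x$scenario)) paste0("scenario ", x$scenario) else "custom",
      "\n")
  flds <- c("beta0", "beta1", "sigma_e", "sigma0", "sigma1", "rho", "lam",
            "alpha0", "alpha1")
  cat(paste0(flds, " = ", unlist(x[flds]), collapse = ", "), "\n")
  cat("visits:", paste(x$visit_times, collapse = ", "),
      " admin censoring:", x$admin_censor, "years\n")
  invisible(x)
}

#' Simulate a cohort from the joint data-generating model
#'
#' Random effects are bivariate normal; measurement error is iid Gaussian;
#' event times are exponential given the random effects; follow-up is the
#' minimum of event time and administrative censoring; visits falling at or
#' after the follow-up time are not observed. The random-number stream is
#' drawn in a fixed order (random effects, then measurement errors visit by
#' visit, then the event-time uniforms) so that extending the visit schedule
#' leaves earlier draws unchanged.
#'
#' @param params A `scenario_parameters` object.
#' @param n Number of subjects.
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return List with `data` (a [longsurv] cohort) and `truth` (tibble
#'   `subject_id`, `b0`, `b1`, `event_time` with the latent effects and the
#'   uncensored event time).
#' @export
simulate_cohort <- function(params, n, seed) {
  stopifnot(inherits(params, "scenario_parameters"), n >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  # (b0, b1) via Cholesky of the 2x2 covariance
  cov01 <- params$rho * params$sigma0 * params$sigma1
  l11 <- params$sigma0
  l21 <- cov01 / l11
  l22 <- sqrt(params$sigma1^2 - l21^2)
  z1 <- rnorm(n); z2 <- rnorm(n)
  b0 <- l11 * z1
  b1 <- l21 * z1 + l22 * z2

  visits <- params$visit_times
  eps <- matrix(NA_real_, n, length(visits))
  for (j in seq_along(visits)) eps[, j] <- rnorm(n, sd = params$sigma_e)

  rate <- params$lam * exp(params$alpha0 * b0 + params$alpha1 * b1)
  event_time <- -log(runif(n)) / rate
  followup <- pmin(event_time, params$admin_censor)
  event <- as.integer(event_time <= params$admin_censor)

  ids <- seq_len(n)
  xmat <- outer(b0 + params$beta0, rep(1, length(visits))) +
    outer(b1 + params$beta1, visits) + eps
  long <- tibble::tibble(
    subject_id = rep(ids, each = length(visits)),
    time = rep(visits, times = n),
    value = as.vector(t(xmat)))
  keep <- long$time < rep(followup, each = length(visits))
  long <- long[keep, , drop = FALSE]

  surv <- tibble::tibble(subject_id = ids, followup_time = followup,
                         event = event)
  data <- longsurv(long, surv, covariate_names = character(0))
  truth <- tibble::tibble(subject_id = as.character(ids), b0 = b0, b1 = b1,
                          event_time = event_time)
  list(data = data, truth = truth)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Censor a random subsample just after a prediction time
#'
#' Implements the validation-by-censoring protocol: `m` subjects are sampled
#' without replacement; each sampled subject still at risk at `t_p` has
#' their follow-up administratively censored at `t_p + offset` with the
#' event indicator cleared, and their measurements after `t_p` discarded
#' (the visit at `t_p` itself is kept). Sampled subjects whose follow-up
#' already ended by `t_p` are left unchanged and are not part of the
#' held-out truth. Models refitted on the returned cohort therefore never
#' see the held-out subjects' post-`t_p` information, while `truth` retains
#' their real outcomes for honest evaluation.
#'
#' @param x A `longsurv` cohort.
#' @param m Number of subjects to sample.
#' @param t_p Prediction time (years).
#' @param seed Integer seed for the subsample draw.
#' @param offset Small positive time added so held-out subjects remain in
#'   every risk set at `t_p` under the strict convention (default 1e-6
#'   years).
#' @return List with `data` (the censored cohort) and `truth` (tibble
#'   `subject_id`, `followup_time`, `event`: the withheld true outcomes of
#'   sampled subjects at risk at `t_p`).
#' @export
make_validation_copy <- function(x, m, t_p, seed, offset = 1e-6) {
  stopifnot(inherits(x, "longsurv"), t_p >= 0)
  n <- n_subjects(x)
  if (m > n) abort("m exceeds the number of subjects")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sampled <- sample(x$survival$subject_id, m)
  at_risk <- x$survival$subject_id[x$survival$followup_time > t_p]
  held <- intersect(sampled, at_risk)

  surv <- x$survival
  idx <- surv$subject_id %in% held
  truth <- surv[idx, c("subject_id", "followup_time", "event")]
  surv$followup_time[idx] <- t_p + offset
  surv$event[idx] <- 0L
  long <- x$longitudinal
  drop <- long$subject_id %in% held & long$time > t_p
  long <- long[!drop, , drop = FALSE]
  data <- longsurv(long, surv, covariate_names = x$covariate_names)
  list(data = data, truth = tibble::as_tibble(truth))
}
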