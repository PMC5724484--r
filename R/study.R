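# End-to-end simulation study: replicate loop over simulated cohorts, the
# seven fitted models (true random effects reference, BCF, LOCF, CA, ORC,
# RRC, joint), bias/coverage aggregation, dynamic C-index and Brier curves
# on estimation and validation samples via the validation-by-censoring
# protocol.

STUDY_MODELS <- c("true", "bcf", "locf", "ca", "orc", "rrc", "joint")

#' Hazard ratio per unit and per SD of a predictor
#'
#' Converts a log-hazard ratio per unit into the hazard ratio for a 1-SD
#' increase of the predictor, the scale on which effect sizes are usually
#' quoted.
#'
#' @param alpha Log-hazard ratio per unit.
#' @param sd Population SD of the predictor (> 0).
#' @return Tibble `alpha`, `sd`, `hr_per_unit`, `hr_per_sd`.
#' @export
hr_per_sd <- function(alpha, sd) {
  stopifnot(all(sd > 0))
  tibble::tibble(alpha = alpha, sd = sd, hr_per_unit = exp(alpha),
                 hr_per_sd = exp(alpha * sd))
}

#' Configure a simulation study
#'
#' Defaults are a reduced-scale version of the full design (which uses
#' n = 5000, 200 replicates, 2000 validation subjects): reduced runs keep
#' Monte-Carlo error manageable on a single CPU while preserving every
#' structural feature.
#'
#' @param scenarios Scenario ids (subset of 1:4).
#' @param n Cohort size per replicate.
#' @param replicates Number of replicates.
#' @param m_validation Subjects sampled into each validation copy (0
#'   disables the validation protocol).
#' @param prediction_times Prediction times (years); must be a subset of
#'   the visit schedule.
#' @param horizon Prediction window length L (years).
#' @param models Models to fit each replicate (subset of
#'   `c("true","bcf","locf","ca","orc","rrc","joint")`).
#' @param eval_estimation Compute estimation-sample dynamic C-indices?
#' @param eval_validation Run the validation-by-censoring protocol?
#' @param quad_points Gauss-Hermite points per dimension for joint fits.
#' @param seed Master seed; per-replicate seeds are derived by a
#'   counter-based scheme so each replicate is individually reproducible.
#' @param output_dir Optional directory for CSV/JSON outputs of
#'   [run_study()].
#' @return A `study_config` list.
#' @export
study_config <- function(scenarios = 1, n = 2000, replicates = 50,
                         m_validation = round(0.4 * n),
                         prediction_times = c(0, 3, 6, 9), horizon = 5,
                         models = STUDY_MODELS,
                         eval_estimation = FALSE, eval_validation = FALSE,
                         quad_points = 9, seed = 1, output_dir = NULL) {
  stopifnot(all(scenarios %in% 1:4), replicates >= 1, horizon > 0,
            all(models %in% STUDY_MODELS), n >= 10)
  structure(list(scenarios = scenarios, n = n, replicates = replicates,
                 m_validation = m_validation,
                 prediction_times = prediction_times, horizon = horizon,
                 models = models, eval_estimation = eval_estimation,
                 eval_validation = eval_validation,
                 quad_points = quad_points, seed = seed,
                 output_dir = output_dir),
            class = "study_config")
}

#' Read a study configuration from a YAML file
#' @param path YAML file whose keys match [study_config()] arguments.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  # YAML 1.1 would read the bare key `n` as a boolean; keep y/n as strings
  keep_yn <- function(x) {
    if (tolower(x) %in% c("true", "yes", "on")) TRUE
    else if (tolower(x) %in% c("false", "no", "off")) FALSE
    else x
  }
  cfg <- yaml::read_yaml(path, handlers = list("bool#yes" = keep_yn,
                                               "bool#no" = keep_yn))
  do.call(study_config, cfg)
}

# deterministic per-replicate seed, independent of evaluation order
replicate_seed <- function(master, scenario, r) {
  as.integer((as.double(master %% 1000000L) * 1009 + scenario * 101459 +
                r * 7919) %% 2147483587 + 1)
}

# fit one model on a cohort; returns list(fit, track, lmm) as applicable
fit_study_model <- function(model, data, truth, params, quad_points) {
  switch(model,
    true = {
      tr <- tibble::tibble(subject_id = truth$subject_id, start = 0,
                           b0 = truth$b0, b1 = truth$b1)
      tr <- tr[tr$subject_id %in% data$survival$subject_id, ]
      eps <- episode_split(data, tr)
      list(fit = fit_ph(eps, covariates = c("b0", "b1")), track = tr)
    },
    bcf = {
      tr <- track_bcf(data)
      list(fit = fit_ph(episode_split(data, tr),
                        covariates = "biomarker"), track = tr)
    },
    locf = {
      tr <- track_locf(data)
      list(fit = fit_ph(episode_split(data, tr),
                        covariates = "biomarker"), track = tr)
    },
    ca = {
      tr <- track_ca(data)
      list(fit = fit_ph(episode_split(data, tr),
                        covariates = "biomarker"), track = tr)
    },
    orc = {
      tr <- track_orc(data)
      list(fit = fit_ph(episode_split(data, tr),
                        covariates = c("b0", "b1")), track = tr)
    },
    rrc = {
      ut <- params$visit_times[-1]
      ut <- ut[vapply(ut, function(tau)
        any(abs(data$longitudinal$time - tau) < 1e-8), logical(1))]
      tr <- track_rrc(data, update_times = ut)
      list(fit = fit_ph(episode_split(data, tr),
                        covariates = c("b0", "b1")), track = tr)
    },
    joint = list(fit = fit_joint(data,
                                 quad = quadrature_spec(quad_points)),
                 track = NULL),
    abort(paste("unknown model", model)))
}

# alpha estimates + Wald intervals from a fitted study model
extract_alpha <- function(model, fitted, params) {
  fit <- fitted$fit
  z <- qnorm(0.975)
  if (model %in% c("bcf", "locf", "ca")) {
    est <- fit$coef[["biomarker"]]
    se <- sqrt(fit$vcov["biomarker", "biomarker"])
    tibble::tibble(model = model, term = "alpha0", estimate = est, se = se,
                   lower = est - z * se, upper = est + z * se,
                   true = params$alpha0,
                   covered = (est - z * se) <= params$alpha0 &
                     params$alpha0 <= (est + z * se))
  } else {
    cn <- if (model == "joint") c("alpha0", "alpha1") else c("b0", "b1")
    est <- unname(fit$coef[cn])
    se <- sqrt(diag(fit$vcov)[cn])
    truev <- c(params$alpha0, params$alpha1)
    tibble::tibble(model = model, term = c("alpha0", "alpha1"),
                   estimate = est, se = unname(se),
                   lower = est - z * se, upper = est + z * se,
                   true = truev,
                   covered = (est - z * se) <= truev &
                     truev <= (est + z * se))
  }
}

# predictions at t_p for the subjects in `ids` from a fitted study model
study_predictions <- function(model, fitted, data, truth, t_p, L, ids) {
  newdata <- switch(model,
    true = {
      tr <- fitted$track
      tr[tr$subject_id %in% ids, c("subject_id", "b0", "b1")]
    },
    joint = eb_random_effects(fitted$fit, data, subject_ids = ids),
    rrc = ,
    orc = ,
    bcf = ,
    locf = ,
    ca = {
      ps <- psi_at(fitted$track, t_p)
      ps[ps$subject_id %in% ids, , drop = FALSE]
    })
  predict_risk(fitted$fit, newdata, t_p, L)
}

#' Run one replicate of the simulation study
#'
#' Simulates a cohort, fits the configured models, extracts association
#' estimates with Wald intervals, and (optionally) computes
#' estimation-sample dynamic C-indices and the validation-by-censoring
#' C-index/Brier evaluation. Per-model failures are recorded, not fatal.
#'
#' @param params A `scenario_parameters` object.
#' @param config A [study_config()].
#' @param rep_seed Integer seed for this replicate.
#' @return List with tibbles `estimates`, `cindex`, `brier`, `failures`
#'   and the `rep_seed`.
#' @export
run_replicate <- function(params, config, rep_seed) {
  sim <- simulate_cohort(params, config$n, seed = rep_seed)
  data <- sim$data; truth <- sim$truth
  L <- config$horizon
  fits <- list(); failures <- list()
  for (mname in config$models) {
    fits[[mname]] <- tryCatch(
      fit_study_model(mname, data, truth, params, config$quad_points),
      error = function(e) {
        failures[[length(failures) + 1]] <<- tibble::tibble(
          model = mname, stage = "fit", message = conditionMessage(e))
        NULL
      })
  }
  estimates <- dplyr::bind_rows(lapply(names(fits), function(mname) {
    if (is.null(fits[[mname]])) return(NULL)
    tryCatch(extract_alpha(mname, fits[[mname]], params),
             error = function(e) NULL)
  }))

  cindex <- list(); brier <- list()
  if (config$eval_estimation) {
    for (t_p in config$prediction_times) {
      ids <- risk_set(data, t_p)
      for (mname in names(fits)) {
        if (is.null(fits[[mname]])) next
        res <- tryCatch({
          pr <- study_predictions(mname, fits[[mname]], data, truth,
                                  t_p, L, ids)
          ci <- dynamic_cindex(pr, data$survival, t_p, L)
          ci$model <- mname; ci$sample <- "estimation"
          ci
        }, error = function(e) NULL)
        if (!is.null(res)) cindex[[length(cindex) + 1]] <- res
      }
    }
  }
  if (config$eval_validation && config$m_validation > 0) {
    for (t_p in config$prediction_times) {
      vc <- make_validation_copy(data, config$m_validation, t_p,
                                 seed = rep_seed + round(1000 * t_p) + 17)
      held <- vc$truth$subject_id
      for (mname in names(fits)) {
        if (is.null(fits[[mname]])) next
        res <- tryCatch({
          refit <- fit_study_model(mname, vc$data, truth, params,
                                   config$quad_points)
          pr <- study_predictions(mname, refit, vc$data, truth, t_p, L,
                                  held)
          ci <- dynamic_cindex(pr, vc$truth, t_p, L)
          ci$model <- mname; ci$sample <- "validation"
          bs <- dynamic_brier(pr, vc$truth, t_p, L)
          bs$model <- mname; bs$sample <- "validation"
          list(ci = ci, bs = bs)
        }, error = function(e) {
          failures[[length(failures) + 1]] <<- tibble::tibble(
            model = mname, stage = paste0("validation_t", t_p),
            message = conditionMessage(e))
          NULL
        })
        if (!is.null(res)) {
          cindex[[length(cindex) + 1]] <- res$ci
          brier[[length(brier) + 1]] <- res$bs
        }
      }
    }
  }
  list(estimates = estimates,
       cindex = dplyr::bind_rows(cindex),
       brier = dplyr::bind_rows(brier),
       failures = dplyr::bind_rows(failures),
       rep_seed = rep_seed)
}

#' Aggregate replicate estimates into bias and coverage summaries
#'
#' @param estimates Row-bound `estimates` tibbles from replicates (must
#'   carry `model`, `term`, `estimate`, `se`, `covered`, `true`).
#' @return Tibble per (model, term): `n_reps`, `bias`, `empirical_se`,
#'   `mean_model_se`, `coverage` (percent).
#' @export
summarize_bias_coverage <- function(estimates) {
  grp <- dplyr::group_by(estimates, dplyr::across(dplyr::any_of(
    c("scenario", "model", "term"))))
  dplyr::summarise(grp,
                   n_reps = dplyr::n(),
                   bias = mean(.data$estimate) - .data$true[1],
                   empirical_se = sd(.data$estimate),
                   mean_model_se = mean(.data$se),
                   coverage = 100 * mean(.data$covered),
                   .groups = "drop")
}

#' Run the full simulation study
#'
#' @param config A [study_config()].
#' @param progress Print one line per replicate?
#' @return Object of class `study_results`: tibbles `bias_coverage`,
#'   `cindex` (per-replicate), `cindex_summary`, `brier`, `brier_summary`,
#'   `estimates` (replicate-level, for audit), `failures`, and the config.
#'   If `config$output_dir` is set, writes `bias_coverage.csv`,
#'   `cindex_dynamic.csv`, `brier_dynamic.csv` and `provenance.json` there.
#' @export
run_study <- function(config, progress = interactive()) {
  all_est <- list(); all_ci <- list(); all_bs <- list(); all_fail <- list()
  for (s in config$scenarios) {
    params <- scenario_parameters(s)
    for (r in seq_len(config$replicates)) {
      rs <- replicate_seed(config$seed, s, r)
      t0 <- Sys.time()
      rep <- run_replicate(params, config, rs)
      if (progress)
        message(sprintf("scenario %d replicate %d/%d (%.1fs)", s, r,
                        config$replicates,
                        as.numeric(Sys.time() - t0, units = "secs")))
      lab <- function(tb) {
        if (nrow(tb) == 0) return(tb)
        tb$scenario <- s; tb$replicate <- r; tb
      }
      all_est[[length(all_est) + 1]] <- lab(rep$estimates)
      all_ci[[length(all_ci) + 1]] <- lab(rep$cindex)
      all_bs[[length(all_bs) + 1]] <- lab(rep$brier)
      all_fail[[length(all_fail) + 1]] <- lab(rep$failures)
    }
  }
  estimates <- dplyr::bind_rows(all_est)
  cindex <- dplyr::bind_rows(all_ci)
  brier <- dplyr::bind_rows(all_bs)
  failures <- dplyr::bind_rows(all_fail)
  bias_coverage <- summarize_bias_coverage(estimates)
  summarise_metric <- function(tb) {
    if (nrow(tb) == 0) return(tb)
    dplyr::summarise(
      dplyr::group_by(tb, .data$scenario, .data$model, .data$sample,
                      .data$t_p),
      mean_value = mean(.data$value, na.rm = TRUE),
      mean_se = mean(.data$se, na.rm = TRUE),
      n_reps = sum(!is.na(.data$value)), .groups = "drop")
  }
  out <- structure(list(
    bias_coverage = bias_coverage,
    cindex = cindex, cindex_summary = summarise_metric(cindex),
    brier = brier, brier_summary = summarise_metric(brier),
    estimates = estimates, failures = failures, config = config),
    class = "study_results")
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(bias_coverage,
                     file.path(config$output_dir, "bias_coverage.csv"))
    if (nrow(cindex))
      readr::write_csv(out$cindex_summary,
                       file.path(config$output_dir, "cindex_dynamic.csv"))
    if (nrow(brier))
      readr::write_csv(out$brier_summary,
                       file.path(config$output_dir, "brier_dynamic.csv"))
    prov <- c(unclass(config)[setdiff(names(config), "output_dir")],
              list(package_version =
                     as.character(utils::packageVersion("repeatrisk")),
                   timestamp = format(Sys.time(), tz = "UTC")))
    jsonlite::write_json(prov,
                         file.path(config$output_dir, "provenance.json"),
                         auto_unbox = TRUE, null = "null")
  }
  out
}

#' @export
print.study_results <- function(x, ...) {
  cat("<study_results>", length(unique(x$estimates$replicate)),
      "replicates, scenarios:",
      paste(unique(x$estimates$scenario), collapse = ", "), "\n")
  cat("\nBias / coverage:\n")
  print(x$bias_coverage, n = 50)
  if (nrow(x$cindex)) {
    cat("\nDynamic C-index summary:\n")
    print(x$cindex_summary, n = 50)
  }
  if (nrow(x$failures)) cat("\n", nrow(x$failures), "model failures recorded\n")
  invisible(x)
}
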