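# Tidiers for the fitted-object classes.

#' @rdname tidy.ph_fit
#' @method tidy lmm_fit
#' @export
tidy.lmm_fit <- function(x, ...) {
  tibble::tibble(
    term = c(names(x$beta), "sd_b0", "sd_b1", "corr_b0_b1", "sigma_e"),
    estimate = c(unname(x$beta), sqrt(x$Sigma[1, 1]), sqrt(x$Sigma[2, 2]),
                 stats::cov2cor(x$Sigma)[1, 2], x$sigma_e))
}

#' @rdname glance.ph_fit
#' @method glance lmm_fit
#' @export
glance.lmm_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, n_subjects = x$n_subjects,
                 n_obs = x$n_obs, converged = x$converged,
                 boundary = x$boundary)
}

#' Tidy a fitted proportional-hazards or joint model
#'
#' @param x A fitted object (`ph_fit`, `joint_fit` or `lmm_fit`).
#' @param conf_level Confidence level for Wald intervals.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `std_error`, `conf_low`, `conf_high` (where a covariance is
#'   available).
#' @method tidy ph_fit
#' @export
tidy.ph_fit <- function(x, conf_level = 0.95, ...) {
  se <- sqrt(diag(x$vcov))
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(term = names(x$coef), estimate = unname(x$coef),
                 std_error = unname(se),
                 conf_low = unname(x$coef - z * se),
                 conf_high = unname(x$coef + z * se))
}

#' @rdname tidy.ph_fit
#' @method tidy joint_fit
#' @export
tidy.joint_fit <- tidy.ph_fit

#' Glance at a fitted proportional-hazards or joint model
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @return One-row tibble of fit-level summaries.
#' @method glance ph_fit
#' @export
glance.ph_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, n_events = x$n_events,
                 person_time = x$person_time, n_subjects = x$n_subjects,
                 baseline = x$baseline$family, converged = x$converged)
}

#' @rdname glance.ph_fit
#' @method glance joint_fit
#' @export
glance.joint_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, n_events = x$n_events,
                 n_subjects = x$n_subjects, baseline = x$baseline$family,
                 quad_points = x$quad$points_per_dim,
                 converged = x$converged)
}

#' Export a fitted model as JSON
#'
#' Parameters, covariance and convergence metadata in a plain JSON object,
#' for audit trails and language-agnostic downstream use.
#'
#' @param x A `ph_fit`, `joint_fit` or `lmm_fit`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_fit_json <- function(x, path) {
  obj <- list(class = class(x)[1], tidy = tidy(x), glance = glance(x))
  if (!is.null(x$vcov)) obj$vcov <- unname(as.matrix(x$vcov))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
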