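# Random-intercept random-slope Gaussian mixed model, fitted by maximum
# likelihood (not REML) so that two-stage plug-ins and the joint model
# maximise comparable likelihoods. The marginal likelihood is profiled over
# the fixed effects: for variance parameters theta, V_i = Q_i Sigma Q_i' +
# sigma_e^2 I, beta(theta) is the GLS solution, and the optimiser works on
# the 4 unconstrained parameters (log sd0, log sd1, atanh rho, log sigma_e).
# Subjects sharing a measurement-time pattern share one Cholesky factor,
# which keeps repeated refits (risk-set regression calibration) cheap.

# Assemble per-pattern blocks: times, value matrix (m x n_g), Z matrix.
lmm_blocks <- function(x, covariates, time_cutoff = NULL,
                       subject_ids = NULL) {
  long <- x$longitudinal
  if (!is.null(subject_ids))
    long <- long[long$subject_id %in% subject_ids, , drop = FALSE]
  if (!is.null(time_cutoff))
    long <- long[long$time <= time_cutoff, , drop = FALSE]
  if (nrow(long) == 0) abort("no usable measurements after filtering")
  long <- dplyr::arrange(long, .data$subject_id, .data$time)
  sp <- split(long[c("time", "value")], long$subject_id)
  ids <- names(sp)
  keys <- vapply(sp, function(d) paste(signif(d$time, 12), collapse = ","),
                 character(1))
  surv <- x$survival
  zmat <- as.matrix(surv[match(ids, as.character(surv$subject_id)),
                         covariates, drop = FALSE])
  blocks <- lapply(split(seq_along(ids), keys), function(ix) {
    tms <- sp[[ix[1]]]$time
    list(times = tms,
         ids = ids[ix],
         X = vapply(sp[ix], function(d) d$value, numeric(length(tms))),
         Z = zmat[ix, , drop = FALSE])
  })
  blocks <- lapply(blocks, function(b) {
    b$X <- matrix(b$X, nrow = length(b$times)); b
  })
  list(blocks = blocks, ids = ids, n_obs = nrow(long))
}

theta_to_pars <- function(theta) {
  sd0 <- exp(theta[1]); sd1 <- exp(theta[2]); rho <- tanh(theta[3])
  se <- exp(theta[4])
  Sigma <- matrix(c(sd0^2, rho * sd0 * sd1, rho * sd0 * sd1, sd1^2), 2, 2)
  list(Sigma = Sigma, sigma_e = se)
}

# Profile log-likelihood pieces for one theta; returns beta, loglik, and the
# per-pattern whitening needed downstream.
lmm_profile <- function(blocks, theta, q) {
  pr <- theta_to_pars(theta)
  XtX <- matrix(0, q, q); Xty <- numeric(q)
  yy <- 0; logdet <- 0; n_tot <- 0
  pieces <- vector("list", length(blocks))
  for (g in seq_along(blocks)) {
    b <- blocks[[g]]
    m <- length(b$times); ng <- ncol(b$X)
    Q <- cbind(1, b$times)
    V <- Q %*% pr$Sigma %*% t(Q) + diag(pr$sigma_e^2, m)
    R <- chol(V)
    a <- backsolve(R, rep(1, m), transpose = TRUE)
    tv <- backsolve(R, b$times, transpose = TRUE)
    WX <- backsolve(R, b$X, transpose = TRUE)
    s11 <- sum(a * a); s12 <- sum(a * tv); s22 <- sum(tv * tv)
    aX <- colSums(a * WX); bX <- colSums(tv * WX)
    XtX[1, 1] <- XtX[1, 1] + ng * s11
    XtX[1, 2] <- XtX[1, 2] + ng * s12
    XtX[2, 2] <- XtX[2, 2] + ng * s22
    Xty[1] <- Xty[1] + sum(aX)
    Xty[2] <- Xty[2] + sum(bX)
    if (q > 2) {
      Z <- b$Z
      zs <- colSums(Z)
      XtX[1, 3:q] <- XtX[1, 3:q] + s11 * zs
      XtX[2, 3:q] <- XtX[2, 3:q] + s12 * zs
      XtX[3:q, 3:q] <- XtX[3:q, 3:q] + s11 * crossprod(Z)
      Xty[3:q] <- Xty[3:q] + as.vector(crossprod(Z, aX))
    }
    yy <- yy + sum(WX * WX)
    logdet <- logdet + ng * 2 * sum(log(diag(R)))
    n_tot <- n_tot + m * ng
    pieces[[g]] <- list(R = R)
  }
  XtX[lower.tri(XtX)] <- t(XtX)[lower.tri(XtX)]
  beta <- solve(XtX, Xty)
  quad <- yy - 2 * sum(beta * Xty) + sum(beta * (XtX %*% beta))
  loglik <- -0.5 * (n_tot * log(2 * pi) + logdet + quad)
  list(beta = beta, loglik = loglik, pieces = pieces, pr = pr)
}

#' Fit the random-intercept random-slope mixed model by maximum likelihood
#'
#' The biomarker model is `X_i(t) = beta0 + beta1 t + Z_i' beta_Z + b0i +
#' b1i t + eps`, with `(b0i, b1i) ~ N(0, Sigma)` and iid Gaussian
#' measurement error. Estimation maximises the marginal Gaussian likelihood
#' over an unconstrained parameterisation of `Sigma` (log-SDs and
#' atanh-correlation); fixed effects are profiled out in closed form.
#' Per-subject empirical Bayes effects (BLUPs) are the closed-form
#' conditional means `Sigma Q_i' V_i^{-1} (X_i - P_i beta)`.
#'
#' @param x A `longsurv` cohort.
#' @param covariates Baseline covariate columns to include in the fixed
#'   design (default: the cohort's covariate names).
#' @param time_cutoff Use only measurements with `time <= time_cutoff`
#'   (inclusive, so the visit defining a refit time contributes to that
#'   refit). `NULL` uses everything.
#' @param subject_ids Restrict to these subjects (`NULL` = all).
#' @param init Optional starting values `c(log sd0, log sd1, atanh rho,
#'   log sigma_e)`.
#' @return An object of class `lmm_fit`: `beta` (named fixed effects),
#'   `Sigma` (2x2), `sigma_e`, `loglik`, `blups` (tibble `subject_id`,
#'   `b0`, `b1` for fitted subjects), `n_subjects`, `n_obs`, `converged`,
#'   `boundary`, plus the filter settings used.
#' @export
fit_lmm <- function(x, covariates = x$covariate_names, time_cutoff = NULL,
                    subject_ids = NULL, init = NULL) {
  stopifnot(inherits(x, "longsurv"))
  bl <- lmm_blocks(x, covariates, time_cutoff, subject_ids)
  if (length(bl$ids) < 2) abort("need at least 2 subjects to fit the model")
  q <- 2 + length(covariates)

  if (is.null(init)) {
    long <- x$longitudinal
    if (!is.null(subject_ids))
      long <- long[long$subject_id %in% subject_ids, , drop = FALSE]
    if (!is.null(time_cutoff))
      long <- long[long$time <= time_cutoff, , drop = FALSE]
    v <- long$value
    sub_means <- tapply(v, long$subject_id, mean)
    s0 <- max(sd(sub_means), sd(v) / 4, 1e-3)
    trange <- max(diff(range(long$time)), 1)
    wvar <- tapply(seq_along(v), long$subject_id, function(ix) {
      if (length(ix) >= 2) var(v[ix]) else NA_real_
    })
    se0 <- sqrt(max(mean(unlist(wvar), na.rm = TRUE), 1e-6))
    if (!is.finite(se0)) se0 <- sd(v) / 2
    init <- c(log(s0), log(max(s0 / trange, 1e-2)), 0, log(se0))
  }

  negll <- function(theta) {
    if (any(!is.finite(theta)) || any(abs(theta) > 20)) return(1e10)
    ll <- tryCatch(lmm_profile(bl$blocks, theta, q)$loglik,
                   error = function(e) NA_real_)
    if (!is.finite(ll)) 1e10 else -ll
  }
  opt <- optim(init, negll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  prof <- lmm_profile(bl$blocks, opt$par, q)
  pr <- prof$pr
  beta <- setNames(prof$beta, c("(Intercept)", "time", covariates))

  # closed-form BLUPs on the fitting data
  blups <- matrix(0, length(bl$ids), 2,
                  dimnames = list(NULL, c("b0", "b1")))
  pos <- 1L
  ord_ids <- character(length(bl$ids))
  for (g in seq_along(bl$blocks)) {
    b <- bl$blocks[[g]]
    m <- length(b$times); ng <- ncol(b$X)
    Q <- cbind(1, b$times)
    R <- prof$pieces[[g]]$R
    fix <- beta[1] + beta[2] * b$times
    r <- b$X - fix
    if (q > 2) r <- r - tcrossprod(rep(1, m), as.vector(b$Z %*% beta[3:q]))
    Vinv_r <- backsolve(R, backsolve(R, r, transpose = TRUE))
    qtv <- rbind(colSums(Vinv_r), colSums(b$times * Vinv_r))
    bb <- t(pr$Sigma %*% qtv)
    ix <- pos:(pos + ng - 1)
    blups[ix, ] <- bb
    ord_ids[ix] <- b$ids
    pos <- pos + ng
  }

  sds <- c(sqrt(pr$Sigma[1, 1]), sqrt(pr$Sigma[2, 2]), pr$sigma_e)
  structure(list(
    beta = beta, Sigma = pr$Sigma, sigma_e = pr$sigma_e,
    loglik = -opt$value,
    blups = tibble::tibble(subject_id = ord_ids,
                           b0 = blups[, 1], b1 = blups[, 2]),
    n_subjects = length(bl$ids), n_obs = bl$n_obs,
    converged = opt$convergence == 0, boundary = any(sds < 1e-6),
    theta = opt$par, covariates = covariates,
    time_cutoff = time_cutoff, subject_ids = subject_ids),
    class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("<lmm_fit> ML mixed model:", x$n_subjects, "subjects,",
      x$n_obs, "observations, logLik", format(x$loglik, digits = 8), "\n")
  print(round(x$beta, 4))
  cat("SD(b0) =", signif(sqrt(x$Sigma[1, 1]), 5),
      " SD(b1) =", signif(sqrt(x$Sigma[2, 2]), 5),
      " corr =", signif(stats::cov2cor(x$Sigma)[1, 2], 4),
      " sigma_e =", signif(x$sigma_e, 5), "\n")
  if (!x$converged) cat("WARNING: optimiser did not report convergence\n")
  if (x$boundary) cat("NOTE: variance component at/near boundary\n")
  invisible(x)
}

# Marginal log-likelihood of the same model at arbitrary parameter values
# (used for optimality checks and joint-model initialisation diagnostics).
lmm_marginal_loglik <- function(x, beta, Sigma, sigma_e,
                                covariates = x$covariate_names,
                                time_cutoff = NULL, subject_ids = NULL) {
  bl <- lmm_blocks(x, covariates, time_cutoff, subject_ids)
  ll <- 0
  for (b in bl$blocks) {
    m <- length(b$times)
    Q <- cbind(1, b$times)
    V <- Q %*% Sigma %*% t(Q) + diag(sigma_e^2, m)
    R <- chol(V)
    fix <- beta[1] + beta[2] * b$times
    r <- b$X - fix
    if (length(covariates) > 0)
      r <- r - tcrossprod(rep(1, m),
                          as.vector(b$Z %*% beta[2 + seq_along(covariates)]))
    W <- backsolve(R, r, transpose = TRUE)
    ll <- ll - 0.5 * (ncol(b$X) * (m * log(2 * pi) +
                                     2 * sum(log(diag(R)))) + sum(W * W))
  }
  ll
}

#' Empirical Bayes random effects at a time cutoff
#'
#' Evaluates the closed-form conditional mean of `(b0, b1)` for each subject
#' using only measurements taken at or before `time_cutoff`, under the
#' parameters of an existing fit. A subject with no usable measurement gets
#' the prior mean `(0, 0)`.
#'
#' @param fit An `lmm_fit`.
#' @param x The cohort supplying subject data (may differ from the fitting
#'   cohort, e.g. a validation copy).
#' @param time_cutoff Upper bound (inclusive) on usable measurement times;
#'   `Inf` uses all.
#' @param subject_ids Subjects to evaluate (default: all in `x`).
#' @return Tibble `subject_id`, `b0`, `b1`, `n_meas`.
#' @export
blup_at <- function(fit, x, time_cutoff = Inf,
                    subject_ids = NULL) {
  stopifnot(inherits(fit, "lmm_fit"), inherits(x, "longsurv"))
  ids <- subject_ids %||% x$survival$subject_id
  ids <- as.character(ids)
  long <- x$longitudinal[x$longitudinal$subject_id %in% ids &
                           x$longitudinal$time <= time_cutoff, , drop = FALSE]
  out <- tibble::tibble(subject_id = ids, b0 = 0, b1 = 0, n_meas = 0L)
  if (nrow(long) > 0) {
    covs <- fit$covariates
    bl <- lmm_blocks(x, covs, time_cutoff, ids)
    beta <- fit$beta; Sigma <- fit$Sigma; se <- fit$sigma_e
    res <- list()
    for (b in bl$blocks) {
      m <- length(b$times)
      Q <- cbind(1, b$times)
      V <- Q %*% Sigma %*% t(Q) + diag(se^2, m)
      R <- chol(V)
      fix <- beta[1] + beta[2] * b$times
      r <- b$X - fix
      if (length(covs) > 0)
        r <- r - tcrossprod(rep(1, m),
                            as.vector(b$Z %*% beta[2 + seq_along(covs)]))
      Vinv_r <- backsolve(R, backsolve(R, r, transpose = TRUE))
      qtv <- rbind(colSums(Vinv_r), colSums(b$times * Vinv_r))
      bb <- t(Sigma %*% qtv)
      res[[length(res) + 1]] <- tibble::tibble(
        subject_id = b$ids, b0 = bb[, 1], b1 = bb[, 2], n_meas = m)
    }
    res <- dplyr::bind_rows(res)
    hit <- match(res$subject_id, out$subject_id)
    out[hit, c("b0", "b1", "n_meas")] <- res[c("b0", "b1", "n_meas")]
  }
  out
}

#' Risk-set regression calibration refit schedule
#'
#' At each update time `tau` the mixed model is refitted using only subjects
#' still at risk (`followup > tau`) who attended the visit defining `tau`,
#' and only their measurements taken at or before `tau`.
#'
#' @param x A `longsurv` cohort.
#' @param update_times Ascending measurement-visit times (> 0) at which to
#'   refit. An update time at baseline is rejected: a refit needs at least
#'   two distinct measurement times.
#' @param covariates Fixed-effect baseline covariates (as in [fit_lmm()]).
#' @param visit_tol Matching tolerance for "has a measurement at `tau`".
#' @return Named list of `lmm_fit` objects keyed by update time.
#' @export
rrc_refit_schedule <- function(x, update_times,
                               covariates = x$covariate_names,
                               visit_tol = 1e-8) {
  stopifnot(inherits(x, "longsurv"), length(update_times) >= 1,
            !is.unsorted(update_times, strictly = TRUE))
  min_t <- min(x$longitudinal$time)
  if (any(update_times <= min_t))
    abort(paste("update time at or before the first visit rejected:",
                "a refit needs at least one repeat measurement"))
  fits <- lapply(update_times, function(tau) {
    at_risk <- risk_set(x, tau, convention = "prediction")
    long <- x$longitudinal
    has_visit <- unique(long$subject_id[abs(long$time - tau) <= visit_tol])
    ids <- intersect(at_risk, has_visit)
    if (length(ids) < 2)
      abort(paste0("risk set at update time ", tau, " is empty or trivial"))
    fit_lmm(x, covariates = covariates, time_cutoff = tau + visit_tol,
            subject_ids = ids)
  })
  names(fits) <- as.character(update_times)
  fits
}
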