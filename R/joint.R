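# Shared random-effects joint model: the random-intercept random-slope
# longitudinal submodel and a parametric proportional-hazards submodel with
# the two random effects entering the log-hazard directly,
#   h_i(t | b) = h0(t) exp(alpha0 b0i + alpha1 b1i + Z_i' gamma).
# Because the survival linear predictor is time-constant given b, the
# cumulative hazard is H0(T) exp(lp) in closed form, and the per-subject
# marginal likelihood is a 2-D integral
#   integral f(X_i | b) f(T*_i, delta_i | b) phi(b; Sigma) db,
# evaluated by adaptive Gauss-Hermite quadrature centred at the per-subject
# posterior mode (found by a vectorised 2-D Newton iteration; the log
# integrand is strictly concave in b for these families).
#
# The longitudinal contribution depends on the data only through per-subject
# sufficient statistics (m, sum t, sum t^2, sum x, sum t x, sum x^2), so a
# likelihood evaluation is a fixed number of vectorised operations over
# subjects -- no per-subject loops.

#' Specify the quadrature rule for joint-model integration
#'
#' @param points_per_dim Gauss-Hermite points per random-effect dimension
#'   (>= 3; default 9 -- 81 nodes on the 2-D grid).
#' @param adaptive Centre and scale the grid at each subject's posterior
#'   mode and curvature (default `TRUE`). The non-adaptive rule centres at
#'   the prior.
#' @return A `quadrature_spec` list.
#' @export
quadrature_spec <- function(points_per_dim = 9, adaptive = TRUE) {
  stopifnot(points_per_dim >= 3)
  structure(list(points_per_dim = as.integer(points_per_dim),
                 adaptive = isTRUE(adaptive)),
            class = "quadrature_spec")
}

# per-subject sufficient statistics + survival data, in a fixed subject order
joint_arrays <- function(x, covariates_long, covariates_surv,
                         time_cutoff = NULL, subject_ids = NULL) {
  long <- x$longitudinal
  if (!is.null(subject_ids))
    long <- long[long$subject_id %in% as.character(subject_ids), ,
                 drop = FALSE]
  if (!is.null(time_cutoff))
    long <- long[long$time <= time_cutoff, , drop = FALSE]
  surv <- x$survival
  ids <- if (is.null(subject_ids)) surv$subject_id else
    intersect(surv$subject_id, as.character(subject_ids))
  f <- factor(long$subject_id, levels = ids)
  tt <- long$time; vv <- long$value
  agg <- function(w) as.vector(tapply(w, f, sum, default = 0))
  m <- agg(rep(1, length(tt)))
  sidx <- match(ids, surv$subject_id)
  list(ids = ids,
       m = m, St = agg(tt), Stt = agg(tt^2),
       Sx = agg(vv), Stx = agg(tt * vv), Sxx = agg(vv^2),
       T = surv$followup_time[sidx], delta = surv$event[sidx],
       Zl = as.matrix(surv[sidx, covariates_long, drop = FALSE]),
       Zs = as.matrix(surv[sidx, covariates_surv, drop = FALSE]))
}

joint_par_names <- function(covariates_long, covariates_surv, family) {
  c("(Intercept)", "time", covariates_long,
    "log_sd0", "log_sd1", "atanh_rho", "log_sigma_e",
    if (family == "exponential") "log_lambda" else
      c("weib_log_cumhaz0", "weib_log_shape"),
    "alpha0", "alpha1",
    if (length(covariates_surv)) paste0("surv_", covariates_surv))
}

# Core marginal log-likelihood. `ar` from joint_arrays; `gh` product grid;
# `mode_env` caches the per-subject modes between evaluations.
joint_loglik <- function(par, ar, pl, ps, family, gh, adaptive, mode_env) {
  n <- length(ar$m)
  beta0 <- par[1]; beta1 <- par[2]
  betaZ <- if (pl) par[2 + seq_len(pl)] else numeric(0)
  th <- par[2 + pl + 1:4]
  sd0 <- exp(th[1]); sd1 <- exp(th[2]); rho <- tanh(th[3]); se <- exp(th[4])
  se2 <- se^2
  nb <- if (family == "exponential") 1 else 2
  bpar <- par[2 + pl + 4 + seq_len(nb)]
  a0 <- par[2 + pl + 4 + nb + 1]; a1 <- par[2 + pl + 4 + nb + 2]
  gam <- if (ps) par[2 + pl + 4 + nb + 2 + seq_len(ps)] else numeric(0)

  det_s <- (1 - rho^2) * sd0^2 * sd1^2
  if (det_s <= 0 || !is.finite(det_s)) return(-Inf)
  s11 <- sd1^2 / det_s; s22 <- sd0^2 / det_s
  s12 <- -rho * sd0 * sd1 / det_s
  logdetS <- log(det_s)

  ci <- beta0 + (if (pl) as.vector(ar$Zl %*% betaZ) else 0)
  u1 <- (ar$Sx - ar$m * ci - beta1 * ar$St) / se2
  u2 <- (ar$Stx - ci * ar$St - beta1 * ar$Stt) / se2
  rss <- ar$Sxx - 2 * ci * ar$Sx - 2 * beta1 * ar$Stx +
    ar$m * ci^2 + 2 * ci * beta1 * ar$St + beta1^2 * ar$Stt
  q11 <- ar$m / se2; q12 <- ar$St / se2; q22 <- ar$Stt / se2

  zg <- if (ps) as.vector(ar$Zs %*% gam) else 0
  if (family == "exponential") {
    Hb <- exp(bpar[1]) * ar$T * exp(zg)
    logh0 <- bpar[1] + zg
  } else {
    shape <- exp(bpar[2])
    Hb <- exp(bpar[1]) * ar$T^shape * exp(zg)
    logh0 <- bpar[1] + bpar[2] + (shape - 1) * log(ar$T) + zg
  }

  # log integrand up to b-independent constants, as a function of (b0, b1)
  gfun <- function(b0, b1) {
    eta <- a0 * b0 + a1 * b1
    u1 * b0 + u2 * b1 -
      0.5 * (q11 * b0^2 + 2 * q12 * b0 * b1 + q22 * b1^2) +
      ar$delta * eta - Hb * exp(eta) -
      0.5 * (s11 * b0^2 + 2 * s12 * b0 * b1 + s22 * b1^2)
  }

  a11 <- q11 + s11; a12 <- q12 + s12; a22 <- q22 + s22
  if (adaptive) {
    if (is.null(mode_env$b0) || length(mode_env$b0) != n) {
      mode_env$b0 <- numeric(n); mode_env$b1 <- numeric(n)
    }
    b0 <- mode_env$b0; b1 <- mode_env$b1
    for (it in 1:40) {
      eta <- a0 * b0 + a1 * b1
      ce <- Hb * exp(pmin(eta, 50))
      g1 <- u1 - (q11 * b0 + q12 * b1) - (s11 * b0 + s12 * b1) +
        a0 * (ar$delta - ce)
      g2 <- u2 - (q12 * b0 + q22 * b1) - (s12 * b0 + s22 * b1) +
        a1 * (ar$delta - ce)
      h11 <- a11 + ce * a0^2; h12 <- a12 + ce * a0 * a1
      h22 <- a22 + ce * a1^2
      det_h <- h11 * h22 - h12^2
      db0 <- (h22 * g1 - h12 * g2) / det_h
      db1 <- (h11 * g2 - h12 * g1) / det_h
      if (any(!is.finite(db0)) || any(!is.finite(db1))) {
        mode_env$b0 <- NULL
        return(-Inf)
      }
      # damp outsized steps from poor parameter proposals
      db0 <- pmax(pmin(db0, 20), -20); db1 <- pmax(pmin(db1, 20), -20)
      b0 <- b0 + db0; b1 <- b1 + db1
      if (max(abs(db0), abs(db1)) < 1e-9) break
    }
    mode_env$b0 <- b0; mode_env$b1 <- b1
    eta <- a0 * b0 + a1 * b1
    ce <- Hb * exp(pmin(eta, 50))
    h11 <- a11 + ce * a0^2; h12 <- a12 + ce * a0 * a1
    h22 <- a22 + ce * a1^2
  } else {
    b0 <- numeric(n); b1 <- numeric(n)
    h11 <- rep(s11, n); h12 <- rep(s12, n); h22 <- rep(s22, n)
  }
  r11 <- sqrt(h11); r12 <- h12 / r11; r22 <- sqrt(pmax(h22 - r12^2, 1e-300))
  l11 <- 1 / r11; l12 <- -r12 / (r11 * r22); l22 <- 1 / r22

  gmode <- gfun(b0, b1)
  S <- numeric(n)
  sq2 <- sqrt(2)
  for (k in seq_len(nrow(gh$grid))) {
    z1 <- gh$grid[k, 1]; z2 <- gh$grid[k, 2]
    bk0 <- b0 + sq2 * (l11 * z1 + l12 * z2)
    bk1 <- b1 + sq2 * (l22 * z2)
    S <- S + gh$w[k] * exp(pmin(gfun(bk0, bk1) - gmode, 50) +
                             gh$zz[k])
  }
  const <- -0.5 * ar$m * log(2 * pi * se2) - 0.5 * rss / se2 -
    log(2 * pi) - 0.5 * logdetS + ar$delta * logh0
  ll <- sum(const + gmode + log(2 * l11 * l22) + log(S))
  if (!is.finite(ll)) return(-Inf)
  ll
}

gh_grid <- function(points_per_dim) {
  g <- pracma::gaussHermite(points_per_dim)
  grid <- unname(as.matrix(expand.grid(g$x, g$x)))
  w <- as.vector(outer(g$w, g$w))
  list(grid = grid, w = w, zz = rowSums(grid^2))
}

#' Fit the shared random-effects joint longitudinal-survival model
#'
#' Simultaneous maximum-likelihood estimation of the mixed-model and
#' survival parameters, linking the two submodels through the random
#' intercept and slope. The fit is initialised at the two-stage (ordinary
#' regression calibration) estimates unless `init` is supplied. Standard
#' errors come from the numerically differentiated observed information.
#'
#' @param x A `longsurv` cohort.
#' @param baseline A [baseline_spec()]; `"exponential"` or `"weibull"`
#'   (closed-form cumulative hazard given the time-constant linear
#'   predictor).
#' @param quad A [quadrature_spec()].
#' @param covariates_long,covariates_surv Baseline covariates for the fixed
#'   part of the longitudinal submodel and for the survival submodel.
#' @param init Optional full parameter vector on the internal scale.
#' @return Object of class `joint_fit` with `coef`, `vcov`, `loglik`,
#'   `beta`, `Sigma`, `sigma_e`, `alpha`, `lambda`/`shape`, `converged`,
#'   `quad`, and the data arrays needed for empirical Bayes prediction.
#' @export
fit_joint <- function(x, baseline = baseline_spec("exponential"),
                      quad = quadrature_spec(),
                      covariates_long = x$covariate_names,
                      covariates_surv = x$covariate_names,
                      init = NULL) {
  stopifnot(inherits(x, "longsurv"))
  family <- baseline$family
  if (!family %in% c("exponential", "weibull"))
    abort("joint fits support exponential and weibull baselines")
  if (sum(x$survival$event) < 1) abort("no events in the cohort")
  pl <- length(covariates_long); ps <- length(covariates_surv)
  ar <- joint_arrays(x, covariates_long, covariates_surv)
  gh <- gh_grid(quad$points_per_dim)
  nms <- joint_par_names(covariates_long, covariates_surv, family)

  if (is.null(init)) {
    lfit <- fit_lmm(x, covariates = covariates_long)
    tr <- track_orc(x, fit = lfit)
    eps <- episode_split(x, tr)
    sfit <- fit_ph(eps, covariates = c("b0", "b1", covariates_surv),
                   baseline = baseline_spec("exponential"))
    binit <- if (family == "exponential")
      sfit$coef[["log_lambda"]] else c(sfit$coef[["log_lambda"]], 0)
    init <- c(lfit$beta, lfit$theta, binit,
              sfit$coef[["b0"]], sfit$coef[["b1"]],
              if (ps) sfit$coef[covariates_surv] else numeric(0))
  }
  stopifnot(length(init) == length(nms))

  mode_env <- new.env(parent = emptyenv())
  negll <- function(par) {
    if (any(!is.finite(par))) return(1e10)
    ll <- joint_loglik(par, ar, pl, ps, family, gh, quad$adaptive, mode_env)
    if (!is.finite(ll)) 1e10 else -ll
  }
  opt <- optim(init, negll, method = "BFGS",
               control = list(maxit = 400, reltol = 1e-10))
  H <- optimHess(opt$par, negll)
  V <- tryCatch(solve(H), error = function(e)
    matrix(NA_real_, length(nms), length(nms)))
  dimnames(V) <- list(nms, nms)
  est <- setNames(opt$par, nms)

  th <- est[c("log_sd0", "log_sd1", "atanh_rho", "log_sigma_e")]
  sd0 <- exp(th[1]); sd1 <- exp(th[2]); rho <- tanh(th[3])
  Sigma <- matrix(c(sd0^2, rho * sd0 * sd1, rho * sd0 * sd1, sd1^2), 2, 2)
  structure(list(
    coef = est, vcov = V, loglik = -opt$value,
    beta = est[seq_len(2 + pl)], Sigma = Sigma,
    sigma_e = unname(exp(th[4])),
    alpha = unname(est[c("alpha0", "alpha1")]),
    lambda = if (family == "exponential")
      unname(exp(est["log_lambda"])) else NA_real_,
    shape = if (family == "weibull")
      unname(exp(est["weib_log_shape"])) else NA_real_,
    baseline = baseline, quad = quad,
    covariates_long = covariates_long, covariates_surv = covariates_surv,
    n_subjects = length(ar$ids), n_events = sum(ar$delta),
    converged = opt$convergence == 0),
    class = "joint_fit")
}

#' @export
print.joint_fit <- function(x, ...) {
  cat("<joint_fit>", x$baseline$family, "baseline,",
    x$n_subjects, "subjects,", x$n_events, "events, logLik",
    format(x$loglik, digits = 9), "\n")
  cat("alpha0 =", signif(x$alpha[1], 4), " alpha1 =", signif(x$alpha[2], 4),
      "\n")
  cat("beta:", paste(signif(x$beta, 5), collapse = ", "),
      " SDs:", signif(sqrt(diag(x$Sigma)), 5),
      " sigma_e:", signif(x$sigma_e, 5), "\n")
  if (!x$converged) cat("WARNING: optimiser did not report convergence\n")
  invisible(x)
}

# H0(t) of a joint fit (baseline cumulative hazard at covariate zero)
joint_cumhaz <- function(fit, t) {
  if (fit$baseline$family == "exponential") fit$lambda * t
  else exp(fit$coef[["weib_log_cumhaz0"]]) * t^fit$shape
}

#' Baseline survivor function of a joint fit
#' @param fit A `joint_fit`.
#' @param t Times in years.
#' @return `S0(t) = exp(-H0(t))`.
#' @export
joint_baseline_survival <- function(fit, t) exp(-joint_cumhaz(fit, t))

#' Empirical Bayes random effects under a joint fit
#'
#' Posterior means of `(b0, b1)` by the fit's quadrature rule. With
#' `t_p = NULL` each subject's full likelihood contribution is used --
#' all measurements and the observed event/censoring outcome (this is
#' exactly what the estimation-sample predictions of the joint model use,
#' and the source of their over-optimism). With `t_p` set, only
#' measurements at times `<= t_p` and the fact of survival to `t_p` are
#' used, which is the honest information set for a prediction at `t_p`.
#'
#' @param fit A `joint_fit`.
#' @param x Cohort supplying the subject data (e.g. a validation copy).
#' @param t_p Optional truncation time.
#' @param subject_ids Subjects to evaluate (default: all in `x`).
#' @return Tibble `subject_id`, `b0`, `b1`.
#' @export
eb_random_effects <- function(fit, x, t_p = NULL, subject_ids = NULL) {
  stopifnot(inherits(fit, "joint_fit"), inherits(x, "longsurv"))
  ar <- joint_arrays(x, fit$covariates_long, fit$covariates_surv,
                     time_cutoff = t_p, subject_ids = subject_ids)
  if (!is.null(t_p)) {
    ar$T <- rep(t_p, length(ar$T))
    ar$delta <- rep(0L, length(ar$delta))
  }
  pl <- length(fit$covariates_long); ps <- length(fit$covariates_surv)
  est <- fit$coef
  beta0 <- est[[1]]; beta1 <- est[[2]]
  betaZ <- if (pl) est[2 + seq_len(pl)] else numeric(0)
  se2 <- fit$sigma_e^2
  Sinv <- solve(fit$Sigma)
  s11 <- Sinv[1, 1]; s12 <- Sinv[1, 2]; s22 <- Sinv[2, 2]
  a0 <- fit$alpha[1]; a1 <- fit$alpha[2]
  gam <- if (ps) est[paste0("surv_", fit$covariates_surv)] else numeric(0)
  zg <- if (ps) as.vector(ar$Zs %*% gam) else 0
  Hb <- joint_cumhaz(fit, ar$T) * exp(zg)

  ci <- beta0 + (if (pl) as.vector(ar$Zl %*% betaZ) else 0)
  u1 <- (ar$Sx - ar$m * ci - beta1 * ar$St) / se2
  u2 <- (ar$Stx - ci * ar$St - beta1 * ar$Stt) / se2
  q11 <- ar$m / se2; q12 <- ar$St / se2; q22 <- ar$Stt / se2
  a11 <- q11 + s11; a12 <- q12 + s12; a22 <- q22 + s22

  gfun <- function(b0, b1) {
    eta <- a0 * b0 + a1 * b1
    u1 * b0 + u2 * b1 -
      0.5 * (q11 * b0^2 + 2 * q12 * b0 * b1 + q22 * b1^2) +
      ar$delta * eta - Hb * exp(eta) -
      0.5 * (s11 * b0^2 + 2 * s12 * b0 * b1 + s22 * b1^2)
  }
  n <- length(ar$m)
  b0 <- numeric(n); b1 <- numeric(n)
  for (it in 1:60) {
    eta <- a0 * b0 + a1 * b1
    ce <- Hb * exp(pmin(eta, 50))
    g1 <- u1 - (q11 * b0 + q12 * b1) - (s11 * b0 + s12 * b1) +
      a0 * (ar$delta - ce)
    g2 <- u2 - (q12 * b0 + q22 * b1) - (s12 * b0 + s22 * b1) +
      a1 * (ar$delta - ce)
    h11 <- a11 + ce * a0^2; h12 <- a12 + ce * a0 * a1
    h22 <- a22 + ce * a1^2
    det_h <- h11 * h22 - h12^2
    db0 <- (h22 * g1 - h12 * g2) / det_h
    db1 <- (h11 * g2 - h12 * g1) / det_h
    b0 <- b0 + db0; b1 <- b1 + db1
    if (max(abs(db0), abs(db1)) < 1e-10) break
  }
  eta <- a0 * b0 + a1 * b1
  ce <- Hb * exp(pmin(eta, 50))
  h11 <- a11 + ce * a0^2; h12 <- a12 + ce * a0 * a1
  h22 <- a22 + ce * a1^2
  r11 <- sqrt(h11); r12 <- h12 / r11; r22 <- sqrt(pmax(h22 - r12^2, 1e-300))
  l11 <- 1 / r11; l12 <- -r12 / (r11 * r22); l22 <- 1 / r22

  gh <- gh_grid(fit$quad$points_per_dim)
  gmode <- gfun(b0, b1)
  S <- numeric(n); M0 <- numeric(n); M1 <- numeric(n)
  sq2 <- sqrt(2)
  for (k in seq_len(nrow(gh$grid))) {
    z1 <- gh$grid[k, 1]; z2 <- gh$grid[k, 2]
    bk0 <- b0 + sq2 * (l11 * z1 + l12 * z2)
    bk1 <- b1 + sq2 * (l22 * z2)
    wk <- gh$w[k] * exp(pmin(gfun(bk0, bk1) - gmode, 50) + gh$zz[k])
    S <- S + wk; M0 <- M0 + wk * bk0; M1 <- M1 + wk * bk1
  }
  tibble::tibble(subject_id = ar$ids, b0 = M0 / S, b1 = M1 / S)
}
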