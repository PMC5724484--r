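# Full-likelihood proportional-hazards fitting on counting-process episodes
# with piecewise-constant covariates. Because the linear predictor is
# constant within an episode, each episode (s0, s1] contributes
#   d * log h(s1) - [H0(s1) - H0(s0)] * exp(lp)
# to the log-likelihood, and the fitted baseline survivor function S0(t) =
# exp(-H0(t)) is available in closed form -- which the dynamic risk
# prediction formula requires. Three baseline families are supported:
#   exponential  H0(t) = lambda t          (fitted via the Poisson-GLM
#                                           identity for piecewise-constant
#                                           exponential likelihoods)
#   weibull      log H0(t) = g0 + g1 log t
#   rcs          log H0(t) = restricted cubic spline in log t
#                (Royston-Parmar; internal knots at tertiles of uncensored
#                log event times, boundary knots at their extremes)

#' Specify a baseline hazard family
#'
#' @param family `"exponential"`, `"weibull"` or `"rcs"` (restricted cubic
#'   spline on the log cumulative hazard scale, i.e. a Royston-Parmar
#'   flexible parametric baseline).
#' @param n_internal_knots Number of internal spline knots (rcs only;
#'   default 2, placed at tertiles of the uncensored log event times). With
#'   0 internal knots the spline family reduces exactly to the Weibull.
#' @return A `baseline_spec` list.
#' @export
baseline_spec <- function(family = c("exponential", "weibull", "rcs"),
                          n_internal_knots = 2) {
  family <- match.arg(family)
  stopifnot(n_internal_knots >= 0)
  structure(list(family = family, n_internal_knots = n_internal_knots),
            class = "baseline_spec")
}

# Restricted cubic spline basis in x = log t with linearity beyond the
# boundary knots (Royston-Parmar form). Returns basis and derivative wrt x.
rp_basis <- function(x, knots) {
  kmin <- knots[1]; kmax <- knots[length(knots)]
  internal <- knots[-c(1, length(knots))]
  B <- cbind(rep(1, length(x)), x)
  D <- cbind(rep(0, length(x)), rep(1, length(x)))
  pp <- function(u) pmax(u, 0)
  for (kj in internal) {
    lam <- (kmax - kj) / (kmax - kmin)
    v <- pp(x - kj)^3 - lam * pp(x - kmin)^3 - (1 - lam) * pp(x - kmax)^3
    dv <- 3 * (pp(x - kj)^2 - lam * pp(x - kmin)^2 -
                 (1 - lam) * pp(x - kmax)^2)
    B <- cbind(B, v)
    D <- cbind(D, dv)
  }
  list(B = B, D = D)
}

ph_h0 <- function(fit_pars, knots, family, t) {
  # cumulative hazard H0(t); t may contain zeros
  out <- numeric(length(t))
  pos <- t > 0
  if (family == "exponential") return(exp(fit_pars[1]) * t)
  x <- log(t[pos])
  B <- rp_basis(x, knots)$B
  out[pos] <- exp(as.vector(B %*% fit_pars))
  out
}

#' Fit a parametric proportional-hazards model on episodes
#'
#' Maximises the full parametric likelihood over counting-process episodes
#' with episode-constant covariates. Standard errors come from the observed
#' information at the optimum.
#'
#' @param episodes Episode tibble from [episode_split()] (columns
#'   `subject_id`, `start`, `stop`, `event` plus covariates).
#' @param covariates Names of the covariate columns to include. Default:
#'   every numeric non-structural column.
#' @param baseline A [baseline_spec()].
#' @return Object of class `ph_fit`: `coef` (named, covariates first, then
#'   baseline parameters), `vcov`, `loglik`, `baseline` (family, knots),
#'   `n_events`, `person_time`, `converged`, `monotone_ok` (for the spline
#'   family, whether the fitted cumulative hazard is non-decreasing over
#'   the observed event-time range).
#' @export
fit_ph <- function(episodes, covariates = NULL,
                   baseline = baseline_spec("exponential")) {
  episodes <- tibble::as_tibble(episodes)
  need <- c("subject_id", "start", "stop", "event")
  stopifnot(all(need %in% names(episodes)))
  if (any(episodes$stop <= episodes$start))
    abort("episodes must have stop > start")
  covariates <- covariates %||% Filter(function(nm) {
    is.numeric(episodes[[nm]])
  }, setdiff(names(episodes), need))
  d <- episodes$event
  if (sum(d) < 1) abort("no events in the episode data")
  expo <- episodes$stop - episodes$start
  Xc <- if (length(covariates)) as.matrix(episodes[covariates]) else
    matrix(0, nrow(episodes), 0)

  if (baseline$family == "exponential") {
    # piecewise-exponential likelihood == Poisson with log-exposure offset
    df <- data.frame(d = d, Xc, check.names = FALSE)
    fml <- if (length(covariates))
      stats::as.formula(paste("d ~",
                              paste(sprintf("`%s`", covariates),
                                    collapse = " + "))) else d ~ 1
    g <- glm(fml, family = poisson(), data = df, offset = log(expo),
             control = stats::glm.control(epsilon = 1e-12, maxit = 50))
    cf <- coef(g)
    est <- c(cf[-1], log_lambda = unname(cf[1]))
    V <- vcov(g)
    perm <- c(seq_len(length(covariates)) + 1L, 1L)
    V <- V[perm, perm, drop = FALSE]
    dimnames(V) <- list(names(est), names(est))
    lp_all <- cf[1] + (if (length(covariates))
      as.vector(Xc %*% cf[-1]) else 0)
    ll <- sum(d * lp_all) - sum(expo * exp(lp_all))
    fit <- list(coef = est, vcov = V, loglik = ll, knots = NULL,
                converged = g$converged, monotone_ok = TRUE)
  } else {
    n_int <- if (baseline$family == "weibull") 0 else
      baseline$n_internal_knots
    ev_t <- episodes$stop[d == 1]
    lx <- log(ev_t)
    if (n_int > 0) {
      probs <- seq_len(n_int) / (n_int + 1)
      knots <- c(min(lx), quantile(lx, probs, names = FALSE), max(lx))
    } else knots <- range(lx)
    p <- length(covariates); nb <- 2 + n_int
    # init from the exponential fit: g0 = log lambda, slope 1, curvature 0
    e0 <- fit_ph(episodes, covariates, baseline_spec("exponential"))
    init <- c(if (p) e0$coef[seq_len(p)] else numeric(0),
              e0$coef[["log_lambda"]], 1, rep(0, n_int))

    bas_stop <- rp_basis(log(episodes$stop), knots)
    pos_start <- episodes$start > 0
    bas_start <- rp_basis(log(episodes$start[pos_start]), knots)
    negll <- function(par) {
      if (any(!is.finite(par)) || any(abs(par) > 500)) return(1e10)
      bcf <- par[p + seq_len(nb)]
      lp <- if (p) as.vector(Xc %*% par[seq_len(p)]) else 0
      s_stop <- as.vector(bas_stop$B %*% bcf)
      ds_stop <- as.vector(bas_stop$D %*% bcf)
      if (any(!is.finite(ds_stop)) || any(ds_stop[d == 1] <= 0))
        return(1e10)
      H_stop <- exp(s_stop)
      H_start <- numeric(length(s_stop))
      H_start[pos_start] <- exp(as.vector(bas_start$B %*% bcf))
      # h0(t) = H0(t) * ds/dx / t
      ll <- sum(d * (s_stop + log(ds_stop) - log(episodes$stop) + lp)) -
        sum((H_stop - H_start) * exp(lp))
      if (!is.finite(ll)) return(1e10)
      -ll
    }
    opt <- optim(init, negll, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-12))
    H <- optimHess(opt$par, negll)
    V <- tryCatch(solve(H), error = function(e) matrix(NA_real_,
                                                       length(init),
                                                       length(init)))
    nms <- c(covariates, paste0("rcs", seq_len(nb) - 1))
    est <- setNames(opt$par, nms)
    dimnames(V) <- list(nms, nms)
    grid <- exp(seq(min(lx), max(lx), length.out = 201))
    Hg <- ph_h0(opt$par[p + seq_len(nb)], knots, "rcs", grid)
    fit <- list(coef = est, vcov = V, loglik = -opt$value, knots = knots,
                converged = opt$convergence == 0,
                monotone_ok = !is.unsorted(Hg))
    if (!fit$monotone_ok)
      warn("fitted baseline cumulative hazard is non-monotone over the observed range")
  }

  structure(c(fit, list(baseline = baseline, covariates = covariates,
                        n_events = sum(d), person_time = sum(expo),
                        n_subjects = length(unique(episodes$subject_id)))),
            class = "ph_fit")
}

#' @export
print.ph_fit <- function(x, ...) {
  cat("<ph_fit>", x$baseline$family, "baseline:", x$n_events, "events /",
      signif(x$person_time, 6), "person-years, logLik",
      format(x$loglik, digits = 8), "\n")
  print(tidy.ph_fit(x), n = 20)
  invisible(x)
}

ph_baseline_pars <- function(fit) {
  if (fit$baseline$family == "exponential")
    fit$coef[["log_lambda"]]
  else fit$coef[grepl("^rcs", names(fit$coef))]
}

#' Baseline cumulative hazard of a fitted model
#' @param fit A `ph_fit`.
#' @param t Times (years, >= 0).
#' @return `H0(t)` at covariate value zero.
#' @export
baseline_cumhaz <- function(fit, t) {
  stopifnot(inherits(fit, "ph_fit"), all(t >= 0))
  fam <- if (fit$baseline$family == "exponential") "exponential" else "rcs"
  ph_h0(ph_baseline_pars(fit), fit$knots, fam, t)
}

#' Baseline survivor function of a fitted model
#'
#' `S0(t) = exp(-H0(t))` at covariate value zero; this is the quantity the
#' dynamic risk prediction formula divides at the window ends.
#'
#' @inheritParams baseline_cumhaz
#' @return Survival probabilities.
#' @export
baseline_survival <- function(fit, t) exp(-baseline_cumhaz(fit, t))

#' Wald confidence interval for a fitted coefficient
#' @param fit A `ph_fit`, `lmm_fit` or `joint_fit` with `coef`/`vcov`.
#' @param coefficient Coefficient name.
#' @param level Confidence level (default 0.95).
#' @return Tibble `term`, `estimate`, `se`, `lower`, `upper`, `level`.
#' @export
wald_ci <- function(fit, coefficient, level = 0.95) {
  est <- fit$coef
  if (!coefficient %in% names(est))
    abort(paste0("unknown coefficient `", coefficient, "`"))
  se <- sqrt(fit$vcov[coefficient, coefficient])
  z <- qnorm(1 - (1 - level) / 2)
  tibble::tibble(term = coefficient, estimate = unname(est[coefficient]),
                 se = se, lower = unname(est[coefficient]) - z * se,
                 upper = unname(est[coefficient]) + z * se, level = level)
}
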