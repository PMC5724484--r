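toy_episodes <- function() {
  tibble::tibble(
    subject_id = c("a", "a", "b", "c", "d", "e"),
    start = c(0, 2, 0, 0, 0, 0),
    stop = c(2, 5, 3, 4, 6, 2.5),
    event = c(0L, 1L, 1L, 0L, 1L, 0L),
    trt = c(0, 1, 1, 0, 0, 1))
}

test_that("the exponential fit equals its closed form and a brute-force oracle", {
  eps <- toy_episodes()
  f0 <- fit_ph(eps, covariates = character(0))
  lam_hat <- exp(f0$coef[["log_lambda"]])
  expect_equal(lam_hat, sum(eps$event) / sum(eps$stop - eps$start),
               tolerance = 1e-10)

  # with a binary covariate: numeric maximisation of the written likelihood
  f1 <- fit_ph(eps, covariates = "trt")
  loglik <- function(par) {
    lp <- par[1] + par[2] * eps$trt
    sum(eps$event * lp) - sum((eps$stop - eps$start) * exp(lp))
  }
  oracle <- optim(c(-1, 0), function(p) -loglik(p), method = "BFGS",
                  control = list(reltol = 1e-14))
  expect_equal(unname(f1$coef[c("log_lambda", "trt")]), oracle$par,
               tolerance = 1e-6)
  expect_equal(f1$loglik, -oracle$value, tolerance = 1e-8)
})

test_that("baseline survival matches closed forms", {
  # engineer person-time so that lambda-hat is exactly 0.005
  eps <- tibble::tibble(subject_id = as.character(1:5),
                        start = 0, stop = c(49.75, 49.75, 49.75, 49.75, 1),
                        event = c(0L, 0L, 0L, 0L, 1L))
  f <- fit_ph(eps, covariates = character(0))
  expect_equal(exp(f$coef[["log_lambda"]]), 0.005, tolerance = 1e-12)
  expect_equal(baseline_survival(f, 10), exp(-0.05), tolerance = 1e-10)
  expect_equal(baseline_survival(f, 0), 1)
  expect_true(all(diff(baseline_survival(f, seq(0, 30, 0.5))) < 0))
})

test_that("Wald intervals follow the normal arithmetic", {
  fake <- structure(list(coef = c(alpha = 0.035),
                         vcov = matrix(0.002^2, 1, 1,
                                       dimnames = list("alpha", "alpha"))),
                    class = "ph_fit")
  ci <- wald_ci(fake, "alpha")
  expect_equal(ci$lower, 0.035 - qnorm(0.975) * 0.002, tolerance = 1e-12)
  expect_equal(round(c(ci$lower, ci$upper), 4), c(0.0311, 0.0389))
  fake0 <- structure(list(coef = c(a = 1),
                          vcov = matrix(0, 1, 1,
                                        dimnames = list("a", "a"))),
                     class = "ph_fit")
  ci0 <- wald_ci(fake0, "a")
  expect_equal(ci0$lower, ci0$upper)
  expect_error(wald_ci(fake, "nope"), "unknown")
})

weibull_episodes <- function(n = 600, shape = 1.5, seed = 31) {
  set.seed(seed)
  z <- stats::rbinom(n, 1, 0.5)
  u <- runif(n)
  lam <- 0.02 * exp(0.7 * z)
  t_ev <- (-log(u) / lam)^(1 / shape)
  cens <- runif(n, 2, 12)
  tibble::tibble(subject_id = as.character(seq_len(n)), start = 0,
                 stop = pmin(t_ev, cens),
                 event = as.integer(t_ev <= cens), z = z)
}

test_that("Weibull fits agree with an independent parametric fitter", {
  skip_if_not_installed("flexsurv")
  eps <- weibull_episodes()
  f <- fit_ph(eps, covariates = "z", baseline = baseline_spec("weibull"))
  fs <- flexsurv::flexsurvreg(
    survival::Surv(stop, event) ~ z, data = as.data.frame(eps),
    dist = "weibullPH")
  cf <- fs$res[, "est"]
  # our parameterisation: log H0 = g0 + g1 log t -> shape g1, scale exp(g0)
  expect_equal(f$coef[["rcs1"]], unname(cf["shape"]), tolerance = 1e-3)
  expect_equal(exp(f$coef[["rcs0"]]), unname(cf["scale"]), tolerance = 1e-3)
  expect_equal(f$coef[["z"]], unname(cf["z"]), tolerance = 1e-3)
  expect_equal(f$loglik, as.numeric(stats::logLik(fs)), tolerance = 1e-6)
  grid <- seq(0.5, 10, by = 0.5)
  expect_equal(baseline_survival(f, grid),
               exp(-unname(cf["scale"]) * grid^unname(cf["shape"])),
               tolerance = 1e-3)
})

test_that("a spline with no internal knots spans exactly the Weibull family", {
  eps <- weibull_episodes(n = 300, seed = 32)
  fw <- fit_ph(eps, covariates = "z", baseline = baseline_spec("weibull"))
  fr <- fit_ph(eps, covariates = "z",
               baseline = baseline_spec("rcs", n_internal_knots = 0))
  expect_equal(fw$loglik, fr$loglik, tolerance = 1e-8)
  expect_equal(unname(fw$coef), unname(fr$coef), tolerance = 1e-5)
})

test_that("spline baselines fit and stay monotone on realistic data", {
  eps <- weibull_episodes(n = 500, shape = 0.8, seed = 33)
  f <- fit_ph(eps, covariates = "z",
              baseline = baseline_spec("rcs", n_internal_knots = 2))
  expect_true(f$converged)
  expect_true(f$monotone_ok)
  expect_length(f$knots, 4)
  grid <- seq(0.2, 11, by = 0.2)
  expect_true(all(diff(baseline_cumhaz(f, grid)) >= 0))
  # close to the generating Weibull survival despite the extra flexibility
  expect_lt(max(abs(baseline_survival(f, seq(1, 8, 1)) -
                      exp(-0.02 * seq(1, 8, 1)^0.8))), 0.05)
})

test_that("covariate rescaling and episode re-splitting leave fits unchanged", {
  eps <- toy_episodes()
  f1 <- fit_ph(eps, covariates = "trt")
  eps_scaled <- dplyr::mutate(eps, trt = trt * 10)
  f2 <- fit_ph(eps_scaled, covariates = "trt")
  expect_equal(f2$coef[["trt"]], f1$coef[["trt"]] / 10, tolerance = 1e-8)
  expect_equal(f2$loglik, f1$loglik, tolerance = 1e-10)

  # split every episode at its midpoint: likelihood additivity
  halves <- dplyr::bind_rows(
    dplyr::mutate(eps, stop = (start + stop) / 2, event = 0L),
    dplyr::mutate(eps, start = (start + stop) / 2))
  f3 <- fit_ph(halves, covariates = "trt")
  expect_equal(unname(f3$coef), unname(f1$coef), tolerance = 1e-8)
  expect_equal(f3$loglik, f1$loglik, tolerance = 1e-10)

  ew <- weibull_episodes(n = 200, seed = 34)
  fw1 <- fit_ph(ew, covariates = "z", baseline = baseline_spec("weibull"))
  halves_w <- dplyr::bind_rows(
    dplyr::mutate(ew, stop = (start + stop) / 2, event = 0L),
    dplyr::mutate(ew, start = (start + stop) / 2))
  fw2 <- fit_ph(halves_w, covariates = "z",
                baseline = baseline_spec("weibull"))
  expect_equal(unname(fw2$coef), unname(fw1$coef), tolerance = 1e-6)
})

test_that("Weibull shape recovers one on exponential data", {
  set.seed(35)
  n <- 1500
  t_ev <- -log(runif(n)) / 0.03
  eps <- tibble::tibble(subject_id = as.character(1:n), start = 0,
                        stop = pmin(t_ev, 20),
                        event = as.integer(t_ev <= 20))
  f <- fit_ph(eps, covariates = character(0),
              baseline = baseline_spec("weibull"))
  se_shape <- sqrt(f$vcov["rcs1", "rcs1"])
  expect_lt(abs(f$coef[["rcs1"]] - 1), 3 * se_shape)
})
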