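joint_par_vector <- function(beta0, beta1, sd0, sd1, rho, sigma_e, lam,
                             alpha0, alpha1) {
  c(beta0, beta1, log(sd0), log(sd1), atanh(rho), log(sigma_e), log(lam),
    alpha0, alpha1)
}

# hand-assemble a joint_fit object from known parameters
fake_joint_fit <- function(par, quad = quadrature_spec(9)) {
  nms <- repeatrisk:::joint_par_names(character(0), character(0),
                                      "exponential")
  sd0 <- exp(par[3]); sd1 <- exp(par[4]); rho <- tanh(par[5])
  structure(list(
    coef = setNames(par, nms), vcov = NULL, loglik = NA_real_,
    beta = par[1:2],
    Sigma = matrix(c(sd0^2, rho * sd0 * sd1, rho * sd0 * sd1, sd1^2), 2),
    sigma_e = exp(par[6]), alpha = par[8:9], lambda = exp(par[7]),
    shape = NA_real_, baseline = baseline_spec("exponential"),
    quad = quad, covariates_long = character(0),
    covariates_surv = character(0)), class = "joint_fit")
}

test_that("the marginal likelihood matches dense-grid integration", {
  x <- tiny_joint_cohort()$data
  par <- joint_par_vector(10.2, 0.4, 1.8, 0.6, -0.1, 1.1, 0.04, 0.25, 0.7)
  ar <- repeatrisk:::joint_arrays(x, character(0), character(0))
  gh <- repeatrisk:::gh_grid(15)
  ll <- repeatrisk:::joint_loglik(par, ar, 0, 0, "exponential", gh, TRUE,
                                  new.env())
  ll_grid <- grid_joint_loglik(x, par, n_grid = 501)
  expect_equal(ll, ll_grid, tolerance = 1e-6)

  # a second, asymmetric parameter point
  par2 <- joint_par_vector(9.5, 0.6, 2.2, 0.4, 0.3, 0.9, 0.08, -0.2, 1.1)
  ll2 <- repeatrisk:::joint_loglik(par2, ar, 0, 0, "exponential", gh, TRUE,
                                   new.env())
  expect_equal(ll2, grid_joint_loglik(x, par2, n_grid = 501),
               tolerance = 1e-6)
})

test_that("with zero association the likelihood factorises exactly", {
  sim <- scen1_small()
  x <- sim$data
  lfit <- scen1_lmm()
  eps <- episode_split(x, track_bcf(x))
  sfit <- fit_ph(eps[c("subject_id", "start", "stop", "event")],
                 covariates = character(0))
  par <- c(lfit$beta, lfit$theta, sfit$coef[["log_lambda"]], 0, 0)
  ar <- repeatrisk:::joint_arrays(x, character(0), character(0))
  gh <- repeatrisk:::gh_grid(9)
  ll <- repeatrisk:::joint_loglik(unname(par), ar, 0, 0, "exponential",
                                  gh, TRUE, new.env())
  expect_equal(ll, lfit$loglik + sfit$loglik, tolerance = 1e-6)
})

test_that("empirical Bayes effects reduce to the mixed-model conditional mean", {
  sim <- scen1_small()
  x <- sim$data
  lfit <- scen1_lmm()
  par <- c(unname(lfit$beta), lfit$theta, log(0.005), 0, 0)
  jf <- fake_joint_fit(par)
  eb <- eb_random_effects(jf, x, t_p = 6)
  ref <- blup_at(lfit, x, time_cutoff = 6)
  ref <- ref[match(eb$subject_id, ref$subject_id), ]
  expect_equal(eb$b0, ref$b0, tolerance = 1e-8)
  expect_equal(eb$b1, ref$b1, tolerance = 1e-8)

  # no measurements and no survival exposure: the prior mean
  x0 <- longsurv(tibble::tibble(subject_id = "s", time = 0, value = 120),
                 tibble::tibble(subject_id = "s", followup_time = 5,
                                event = 0))
  eb0 <- eb_random_effects(jf, x0, t_p = 0)
  expect_equal(nrow(eb0), 1)
  # a subject with no measurements at all and t_p = 0: the prior mean
  jf_alpha <- fake_joint_fit(joint_par_vector(120, 0.3, 15, 1, -0.2, 10,
                                              0.005, 0, 0))
  expect_warning(x_none <- longsurv(
    tibble::tibble(subject_id = character(0), time = numeric(0),
                   value = numeric(0)),
    tibble::tibble(subject_id = "s", followup_time = 5, event = 0),
    require_baseline = FALSE), "baseline")
  eb_none <- eb_random_effects(jf_alpha, x_none, t_p = 0)
  expect_equal(c(eb_none$b0, eb_none$b1), c(0, 0), tolerance = 1e-12)
})

test_that("posterior means match the dense-grid oracle", {
  x <- tiny_joint_cohort()$data
  par <- joint_par_vector(10.2, 0.4, 1.8, 0.6, -0.1, 1.1, 0.04, 0.25, 0.7)
  jf <- fake_joint_fit(par, quad = quadrature_spec(15))
  eb <- eb_random_effects(jf, x)
  oracle <- grid_joint_loglik(x, par, n_grid = 501,
                              posterior_means = TRUE)$post
  oracle <- oracle[match(eb$subject_id, oracle$subject_id), ]
  expect_equal(eb$b0, oracle$b0, tolerance = 1e-5)
  expect_equal(eb$b1, oracle$b1, tolerance = 1e-5)
})

test_that("the default quadrature order is converged", {
  sim <- simulate_cohort(scenario_parameters(1), 150, seed = 55)
  x <- sim$data
  lfit <- fit_lmm(x)
  par <- c(unname(lfit$beta), lfit$theta, log(0.005), 0.035, 0.15)
  ar <- repeatrisk:::joint_arrays(x, character(0), character(0))
  ll9 <- repeatrisk:::joint_loglik(par, ar, 0, 0, "exponential",
                                   repeatrisk:::gh_grid(9), TRUE, new.env())
  ll15 <- repeatrisk:::joint_loglik(par, ar, 0, 0, "exponential",
                                    repeatrisk:::gh_grid(15), TRUE,
                                    new.env())
  expect_lt(abs(ll9 - ll15) / n_subjects(x), 1e-4)
})

test_that("joint fitting recovers strong-signal parameters on a small cohort", {
  p <- custom_parameters(sigma0 = 10, sigma1 = 2, sigma_e = 4,
                         lam = 0.04, alpha0 = 0.08, alpha1 = 0.3)
  sim <- simulate_cohort(p, 600, seed = 91)
  jf <- fit_joint(sim$data)
  expect_true(jf$converged)
  se <- sqrt(diag(jf$vcov)[c("alpha0", "alpha1")])
  expect_lt(abs(jf$alpha[1] - 0.08), 4 * se[1])
  expect_lt(abs(jf$alpha[2] - 0.3), 4 * se[2])
  expect_lt(abs(jf$beta[[1]] - 120), 2)
  expect_lt(abs(jf$sigma_e - 4), 0.5)
})

test_that("survival information pulls long survivors toward lower risk", {
  par <- joint_par_vector(120, 0.3, 15, 1, -0.2, 10, 0.02, 0.06, 0.3)
  jf <- fake_joint_fit(par)
  # a long survivor with average measurements
  x <- longsurv(tibble::tibble(subject_id = "s", time = c(0, 3, 6, 9),
                               value = 120 + 0.3 * c(0, 3, 6, 9)),
                tibble::tibble(subject_id = "s", followup_time = 15,
                               event = 0))
  eb_full <- eb_random_effects(jf, x)           # includes survival to 15y
  par0 <- par; par0[8:9] <- 0
  jf0 <- fake_joint_fit(par0)
  eb_long <- eb_random_effects(jf0, x)          # longitudinal only
  lp_full <- 0.06 * eb_full$b0 + 0.3 * eb_full$b1
  lp_long <- 0.06 * eb_long$b0 + 0.3 * eb_long$b1
  expect_lt(lp_full, lp_long)
})
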