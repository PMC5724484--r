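fake_exp_fit <- function(log_lambda = log(0.005), coefs = c(psi = 0.1)) {
  est <- c(coefs, log_lambda = log_lambda)
  structure(list(coef = est,
                 vcov = diag(length(est)),
                 baseline = baseline_spec("exponential"),
                 covariates = names(coefs), knots = NULL),
            class = "ph_fit")
}

test_that("the dynamic risk formula matches closed forms and is monotone", {
  fit <- fake_exp_fit()
  nd <- tibble::tibble(subject_id = "s", psi = 0)
  pr <- predict_risk(fit, nd, t_p = 0, L = 10)
  expect_equal(pr$risk, 1 - exp(-0.05), tolerance = 1e-12)
  expect_equal(predict_risk(fit, nd, t_p = 0, L = 0)$risk, 0)
  expect_equal(predict_risk(fit, nd, t_p = 7, L = 0)$risk, 0)

  # exponential baseline: risk depends on L, not t_p
  expect_equal(predict_risk(fit, nd, t_p = 9, L = 10)$risk,
               pr$risk, tolerance = 1e-12)

  grid <- tibble::tibble(subject_id = as.character(1:50),
                         psi = seq(-5, 5, length.out = 50))
  r <- predict_risk(fit, grid, t_p = 0, L = 10)$risk
  expect_true(all(diff(r) > 0))
  expect_true(all(r >= 0 & r <= 1))
})

test_that("the windowed concordance equals exhaustive enumeration", {
  set.seed(77)
  for (rep in 1:25) {
    n <- sample(5:10, 1)
    fu <- round(runif(n, 0.5, 14), 1)
    ev <- stats::rbinom(n, 1, 0.6)
    risk <- round(runif(n), 1)      # rounding forces ties
    t_p <- sample(c(0, 3, 6), 1)
    L <- sample(c(3, 5), 1)
    truth <- tibble::tibble(subject_id = as.character(1:n),
                            followup_time = fu, event = ev)
    preds <- tibble::tibble(subject_id = as.character(1:n), risk = risk)
    oracle <- enumerate_cindex(risk, fu, ev, t_p, L)
    if (is.na(oracle) || !any(fu > t_p)) next
    got <- suppressWarnings(dynamic_cindex(preds, truth, t_p, L))
    expect_equal(got$value, oracle)
  }
})

test_that("concordance handles the degenerate cases from its definition", {
  truth <- tibble::tibble(subject_id = c("a", "b"),
                          followup_time = c(1, 5), event = c(1L, 0L))
  preds <- tibble::tibble(subject_id = c("a", "b"), risk = c(0.8, 0.2))
  expect_equal(dynamic_cindex(preds, truth, 0, 5)$value, 1)
  preds_flat <- tibble::tibble(subject_id = c("a", "b"), risk = c(0.5, 0.5))
  expect_equal(dynamic_cindex(preds_flat, truth, 0, 5)$value, 0.5)

  # invariance under a strictly increasing transform of the predictions
  set.seed(8)
  n <- 40
  truth2 <- tibble::tibble(subject_id = as.character(1:n),
                           followup_time = runif(n, 0.2, 15),
                           event = stats::rbinom(n, 1, 0.5))
  p <- tibble::tibble(subject_id = as.character(1:n), risk = runif(n))
  p2 <- dplyr::mutate(p, risk = stats::qlogis(risk / 1.0001 + 1e-5))
  a <- dynamic_cindex(p, truth2, 0, 10)
  b <- dynamic_cindex(p2, truth2, 0, 10)
  expect_equal(a$value, b$value)

  # no events in the window
  expect_warning(r <- dynamic_cindex(p, dplyr::mutate(truth2, event = 0L),
                                     0, 10), "no events")
  expect_true(is.na(r$value))
})

test_that("concordance differences are internally consistent", {
  set.seed(9)
  n <- 60
  truth <- tibble::tibble(subject_id = as.character(1:n),
                          followup_time = runif(n, 0.2, 15),
                          event = stats::rbinom(n, 1, 0.5))
  pa <- tibble::tibble(subject_id = as.character(1:n), risk = runif(n))
  pb <- tibble::tibble(subject_id = as.character(1:n), risk = runif(n))
  d <- delta_cindex(pa, pb, truth, 0, 10)
  ca <- dynamic_cindex(pa, truth, 0, 10)
  cb <- dynamic_cindex(pb, truth, 0, 10)
  expect_equal(d$value, cb$value - ca$value, tolerance = 1e-12)

  same <- delta_cindex(pa, pa, truth, 0, 10)
  expect_equal(same$value, 0)
  expect_equal(same$se, 0)

  # jackknife SE of a paired comparison is far below the marginal SEs
  expect_lt(d$se, ca$se + cb$se)
  expect_error(delta_cindex(pa, pb[1:10, ], truth, 0, 10), "same subjects")
})

test_that("the weighted Brier score matches hand arithmetic and a product-limit oracle", {
  # no censoring: plain mean squared error
  truth <- tibble::tibble(subject_id = c("a", "b", "c"),
                          followup_time = c(2, 20, 4), event = c(1L, 0L, 1L))
  preds <- tibble::tibble(subject_id = c("a", "b", "c"),
                          risk = c(0.2, 0.5, 0.9))
  bs <- dynamic_brier(preds, truth, 0, 10)
  expect_equal(bs$value, ((0.2 - 1)^2 + 0.5^2 + (0.9 - 1)^2) / 3,
               tolerance = 1e-12)

  # perfect certain predictions, no censoring: zero
  preds2 <- tibble::tibble(subject_id = c("a", "b", "c"), risk = c(1, 0, 1))
  expect_equal(dynamic_brier(preds2, truth, 0, 10)$value, 0)

  # constant prediction at the event proportion: binomial variance
  set.seed(10)
  n <- 200
  tr <- tibble::tibble(subject_id = as.character(1:n),
                       followup_time = runif(n, 0.1, 9),
                       event = stats::rbinom(n, 1, 0.4))
  tr$followup_time[tr$event == 0] <- 20   # no censoring inside the window
  pstar <- mean(tr$event)
  pc <- tibble::tibble(subject_id = tr$subject_id, risk = pstar)
  expect_equal(dynamic_brier(pc, tr, 0, 10)$value, pstar * (1 - pstar),
               tolerance = 1e-12)

  # with censoring: independent product-limit computation of the weights
  set.seed(11)
  n <- 120
  ev_t <- stats::rexp(n, 0.15)
  cn_t <- runif(n, 0.5, 12)
  tr2 <- tibble::tibble(subject_id = as.character(1:n),
                        followup_time = pmin(ev_t, cn_t),
                        event = as.integer(ev_t <= cn_t))
  pr2 <- tibble::tibble(subject_id = tr2$subject_id, risk = runif(n))
  t_p <- 0; L <- 5
  got <- dynamic_brier(pr2, tr2, t_p, L)
  G <- function(t) hand_km(tr2$followup_time, 1 - tr2$event, t)
  terms <- mapply(function(risk, fu, ev) {
    if (fu <= t_p + L && ev == 1) (risk - 1)^2 / G(fu)
    else if (fu > t_p + L) risk^2 / G(t_p + L)
    else 0
  }, pr2$risk, tr2$followup_time, tr2$event)
  expect_equal(got$value, mean(terms), tolerance = 1e-10)
})

test_that("calibration tables partition the risk set and match hand KM values", {
  set.seed(12)
  n <- 20
  fu <- c(stats::rexp(15, 0.2), runif(5, 6, 30))
  ev <- as.integer(seq_len(n) <= 15)
  tr <- tibble::tibble(subject_id = as.character(1:n),
                       followup_time = fu, event = ev)
  pr <- tibble::tibble(subject_id = as.character(1:n),
                       risk = seq(0.05, 0.95, length.out = n))
  tab <- calibration_table(pr, tr, 0, 5, n_groups = 4)
  expect_equal(sum(tab$n), n)
  expect_true(!is.unsorted(tab$mean_predicted))
  # hand product-limit within each group
  grp_id <- split(seq_len(n)[order(pr$risk)],
                  rep(1:4, each = 5))
  for (g in 1:4) {
    ix <- grp_id[[g]]
    t2 <- pmin(fu[ix], 5)
    s2 <- as.integer(ev[ix] == 1 & fu[ix] <= 5)
    expect_equal(tab$observed[g], 1 - hand_km(t2, s2, 5),
                 tolerance = 1e-10)
  }

  # self-consistency: predictions equal to group event proportions
  set.seed(13)
  n2 <- 400
  grp <- rep(1:4, each = 100)
  p_true <- c(0.1, 0.3, 0.5, 0.8)[grp]
  ev2 <- stats::rbinom(n2, 1, p_true)
  tr3 <- tibble::tibble(subject_id = as.character(1:n2),
                        followup_time = ifelse(ev2 == 1, runif(n2, 0.1, 4.9),
                                               30),
                        event = ev2)
  pr3 <- tibble::tibble(subject_id = as.character(1:n2), risk = p_true)
  expect_warning(tab3 <- calibration_table(pr3, tr3, 0, 5, n_groups = 10),
                 "fewer")
  expect_lt(max(abs(tab3$observed - tab3$mean_predicted)), 0.12)
})
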