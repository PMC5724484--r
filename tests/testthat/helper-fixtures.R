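# Shared fixtures, built in code. Heavier simulated objects are memoised so
# several test files can reuse one computation.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# Five-subject handcrafted cohort with a binary baseline covariate.
toy_cohort <- function() {
  long <- tibble::tibble(
    subject_id = c("a", "a", "a", "a", "b", "b", "c", "d", "d", "e"),
    time = c(0, 3, 6, 9, 0, 3, 0, 0, 3, 0),
    value = c(120, 130, 125, 140, 118, 122, 135, 110, 111, 128))
  surv <- tibble::tibble(
    subject_id = c("a", "b", "c", "d", "e"),
    followup_time = c(12, 5.5, 2.5, 9.2, 15),
    event = c(1L, 1L, 0L, 1L, 0L),
    sex = c(0, 1, 0, 1, 1))
  longsurv(long, surv, covariate_names = "sex")
}

# Moderate scenario-1 cohort reused across files.
scen1_small <- function() memo("scen1_small", {
  simulate_cohort(scenario_parameters(1), 400, seed = 101)
})

# Larger scenario-1 cohort for statistical checks.
scen1_mid <- function() memo("scen1_mid", {
  simulate_cohort(scenario_parameters(1), 2000, seed = 202)
})

scen1_lmm <- function() memo("scen1_lmm", fit_lmm(scen1_small()$data))

# Tiny cohort with strong effects for joint-model oracle tests.
tiny_joint_cohort <- function() memo("tiny_joint", {
  p <- custom_parameters(sigma0 = 2, sigma1 = 0.5, sigma_e = 1, beta0 = 10,
                         beta1 = 0.5, lam = 0.05, alpha0 = 0.3,
                         alpha1 = 0.8)
  simulate_cohort(p, 6, seed = 7)
})

# Independent dense-grid evaluation of the joint marginal log-likelihood
# and posterior means (brute force; used only on tiny cohorts).
grid_joint_loglik <- function(x, par, n_grid = 501, width = 7,
                              posterior_means = FALSE) {
  beta0 <- par[1]; beta1 <- par[2]
  sd0 <- exp(par[3]); sd1 <- exp(par[4]); rho <- tanh(par[5])
  se <- exp(par[6]); lam <- exp(par[7]); a0 <- par[8]; a1 <- par[9]
  S <- matrix(c(sd0^2, rho * sd0 * sd1, rho * sd0 * sd1, sd1^2), 2)
  Sinv <- solve(S)
  g0 <- seq(-width * sd0, width * sd0, length.out = n_grid)
  g1 <- seq(-width * sd1, width * sd1, length.out = n_grid)
  d0 <- diff(g0)[1]; d1 <- diff(g1)[1]
  ll <- 0
  post <- NULL
  for (id in x$survival$subject_id) {
    li <- x$longitudinal[x$longitudinal$subject_id == id, ]
    si <- x$survival[x$survival$subject_id == id, ]
    tot <- 0; m0 <- 0; m1 <- 0
    for (i0 in seq_along(g0)) {
      b0 <- g0[i0]
      lx <- rep(0, length(g1))
      for (j in seq_len(nrow(li))) {
        mu <- beta0 + b0 + (beta1 + g1) * li$time[j]
        lx <- lx + stats::dnorm(li$value[j], mu, se, log = TRUE)
      }
      eta <- a0 * b0 + a1 * g1
      lt <- si$event * (log(lam) + eta) -
        lam * si$followup_time * exp(eta)
      qb <- -0.5 * (Sinv[1, 1] * b0^2 + 2 * Sinv[1, 2] * b0 * g1 +
                      Sinv[2, 2] * g1^2)
      dens <- exp(lx + lt - log(2 * pi) - 0.5 * log(det(S)) + qb)
      tot <- tot + sum(dens) * d0 * d1
      m0 <- m0 + sum(dens * b0) * d0 * d1
      m1 <- m1 + sum(dens * g1) * d0 * d1
    }
    ll <- ll + log(tot)
    post <- rbind(post, c(m0 / tot, m1 / tot))
  }
  if (posterior_means)
    list(loglik = ll, post = tibble::tibble(
      subject_id = x$survival$subject_id,
      b0 = post[, 1], b1 = post[, 2]))
  else ll
}

# Exhaustive windowed-concordance enumeration straight from the definition.
enumerate_cindex <- function(risk, fu, ev, t_p, L) {
  keep <- fu > t_p
  risk <- risk[keep]; fu <- fu[keep]; ev <- ev[keep]
  num <- 0; den <- 0
  for (i in seq_along(fu)) {
    if (ev[i] != 1 || fu[i] < t_p || fu[i] > t_p + L) next
    r <- which(fu >= fu[i])
    r <- setdiff(r, i)
    num <- num + sum(risk[r] < risk[i]) + 0.5 * sum(risk[r] == risk[i])
    den <- den + length(r)
  }
  if (den == 0) NA_real_ else num / den
}

# Hand product-limit estimator (survival of the given status indicator).
hand_km <- function(time, status, at) {
  ut <- sort(unique(time[status == 1]))
  s <- 1
  for (tt in ut[ut <= at]) {
    n_risk <- sum(time >= tt)
    d <- sum(time == tt & status == 1)
    s <- s * (1 - d / n_risk)
  }
  s
}
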