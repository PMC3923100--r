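test_that("unadjusted logistic matches the saturated 2x2 closed form", {
  d <- trial_from_2x2(10, 10, 5, 15)
  r <- unadjusted_logistic(d)
  expect_equal(r$log_or, log(3), tolerance = 1e-6)
  expect_equal(r$se, sqrt(1/10 + 1/10 + 1/5 + 1/15), tolerance = 1e-6)
  expect_equal(r$n_included, 40L)
  expect_true(r$converged)
  expect_equal(r$ci_low, exp(r$log_or - 1.96 * r$se), tolerance = 1e-12)
  expect_equal(r$ci_high, exp(r$log_or + 1.96 * r$se), tolerance = 1e-12)
})

test_that("unadjusted logistic flags degenerate outcomes as non-estimable", {
  d <- trial_from_2x2(0, 12, 0, 12)  # no events at all
  r <- unadjusted_logistic(d)
  expect_false(r$converged)
  expect_true(is.na(r$p_value))
})

test_that("unadjusted logistic recovers a null effect at scale", {
  set.seed(71)
  d <- sim_trial(n_total = 20000, n_centres = 10, icc = 0, beta = 0)
  r <- unadjusted_logistic(d)
  expect_lt(abs(r$log_or), 3 * r$se)
})

test_that("convergence rules fire on extreme, dropped, and ordinary fits", {
  expect_false(convergence_check(1001, 0.2)$converged)
  expect_equal(convergence_check(1001, 0.2)$reason, "extreme-estimate")
  expect_false(convergence_check(0.5, 1500)$converged)
  expect_false(convergence_check(0, 0)$converged)
  expect_equal(convergence_check(0, 0)$reason, "dropped")
  cc <- convergence_check(-0.3, 0.2)
  expect_true(cc$converged)
  expect_true(is.na(cc$reason))
  expect_equal(convergence_check(-0.3, 0.2, optimiser_ok = FALSE)$reason,
               "optimiser-failure")
})

test_that("stratum construction cross-classifies and drops empty cells", {
  set.seed(81)
  d <- sim_trial(n_total = 300, n_centres = 10, icc = 0)
  d$b1 <- rbinom(300, 1, 0.5); d$b2 <- rbinom(300, 1, 0.3)
  d$b3 <- rbinom(300, 1, 0.5)
  s <- build_strata(d, c("centre", "b1", "b2", "b3"))
  expect_lte(nlevels(s), 80)
  expect_true(all(table(s) > 0))
  s0 <- build_strata(d, "centre")
  expect_equal(nlevels(s0), 10)
  d$cont <- runif(300, 0, 100)
  expect_error(build_strata(d, c("centre", "cont")),
               class = "centresim_config_error")
  s2 <- build_strata(d, c("centre", "cont"), cut_rules = list(cont = 30))
  expect_lte(nlevels(s2), 20)
})

test_that("Mantel-Haenszel evaluates the weighted odds-ratio formula", {
  # two informative strata, hand evaluation:
  # (4*8/20 + 3*7/20) / (6*2/20 + 7*3/20) = 2.65/1.65
  d <- trial_from_strata(list(c(4, 6, 2, 8), c(3, 7, 3, 7)))
  r <- mantel_haenszel(d)
  expect_equal(exp(r$log_or), 2.65 / 1.65, tolerance = 1e-10)
  expect_equal(r$n_strata_included, 2L)
  expect_equal(r$n_included, 40L)
})

test_that("one-stratum MH equals the crude odds ratio with Woolf variance", {
  set.seed(91)
  for (i in 1:200) {
    cells <- sample(1:12, 4, replace = TRUE)
    d <- trial_from_2x2(cells[1], cells[2], cells[3], cells[4])
    r <- mantel_haenszel(d)
    expect_equal(r$log_or, log(cells[1] * cells[4] / (cells[2] * cells[3])),
                 tolerance = 1e-12)
    expect_equal(r$se, sqrt(sum(1 / cells)), tolerance = 1e-12)
  }
})

test_that("MH ignores non-informative strata and stratum order", {
  base <- list(c(4, 6, 2, 8), c(3, 7, 3, 7))
  r1 <- mantel_haenszel(trial_from_strata(base))
  # appending single-arm and single-outcome strata changes nothing
  r2 <- mantel_haenszel(trial_from_strata(c(base, list(c(3, 5, 0, 0),
                                                       c(2, 0, 4, 0)))))
  expect_equal(r2$log_or, r1$log_or, tolerance = 1e-12)
  expect_equal(r2$se, r1$se, tolerance = 1e-12)
  expect_equal(r2$p_value, r1$p_value, tolerance = 1e-12)
  expect_equal(r2$n_included, r1$n_included)  # their patients are excluded
  r3 <- mantel_haenszel(trial_from_strata(rev(base)))
  expect_equal(r3$log_or, r1$log_or, tolerance = 1e-12)
  expect_equal(r3$se, r1$se, tolerance = 1e-12)
})

test_that("fixed-effects matches a direct likelihood-maximisation oracle", {
  # two informative centres, no covariates: compare against Nelder-Mead on
  # the hand-written conditional-on-centre log-likelihood
  set.seed(101)
  d <- sim_trial(n_total = 120, n_centres = 2, icc = 0.2, beta = -0.6)
  r <- fixed_effects_logistic(d)
  y <- d$outcome; x <- d$arm; c2 <- as.integer(d$centre_id == "C002")
  nll <- function(par) {
    eta <- par[1] + par[2] * x + par[3] * c2
    -sum(y * eta - log1p(exp(eta)))
  }
  o <- optim(c(0, 0, 0), nll, method = "Nelder-Mead",
             control = list(reltol = 1e-14, maxit = 5000))
  expect_equal(r$log_or, o$par[2], tolerance = 1e-4)
  expect_true(r$converged)
})

test_that("fixed-effects excludes uninformative centres before fitting", {
  base <- list(c(4, 6, 2, 8), c(3, 7, 3, 7))
  d_all_events <- trial_from_strata(c(base, list(c(5, 0, 5, 0))))
  r <- fixed_effects_logistic(d_all_events)
  expect_equal(r$n_included, 40L)        # the all-event centre is dropped
  expect_equal(r$n_strata_included, 2L)
  # single-centre data reduce to the unadjusted fit
  d1 <- trial_from_2x2(10, 10, 5, 15)
  rf <- fixed_effects_logistic(d1)
  ru <- unadjusted_logistic(d1)
  expect_equal(rf$log_or, ru$log_or, tolerance = 1e-8)
  expect_equal(rf$se, ru$se, tolerance = 1e-8)
  # no informative centre at all
  r0 <- fixed_effects_logistic(trial_from_strata(list(c(3, 0, 2, 0))))
  expect_false(r0$converged)
})

test_that("random-effects collapses to the unadjusted fit when ICC is zero", {
  set.seed(111)
  d <- sim_trial(n_total = 600, n_centres = 12, icc = 0, beta = -0.4)
  rr <- random_effects_logistic(d)
  ru <- unadjusted_logistic(d)
  expect_lt(rr$sigma, 0.05)
  expect_equal(rr$log_or, ru$log_or, tolerance = 1e-3)
  expect_equal(rr$se, ru$se, tolerance = 1e-3)
})

test_that("adaptive quadrature estimate is invariant to node refinement", {
  set.seed(121)
  d <- sim_trial(n_total = 500, n_centres = 25, icc = 0.15, beta = -0.5)
  r12 <- random_effects_logistic(d, quad_points = 12)
  r30 <- random_effects_logistic(d, quad_points = 30)
  expect_equal(r12$log_or, r30$log_or, tolerance = 1e-4)
  expect_equal(r12$sigma, r30$sigma, tolerance = 1e-4)
})

test_that("random-effects agrees with an independent mixed-model fitter", {
  skip_if_not_installed("lme4")
  set.seed(131)
  d <- sim_trial(n_total = 500, n_centres = 25, icc = 0.15, beta = -0.5)
  r <- random_effects_logistic(d)
  g <- lme4::glmer(outcome ~ arm + (1 | centre_id), data = d,
                   family = binomial, nAGQ = 12)
  expect_equal(r$log_or, unname(lme4::fixef(g)["arm"]), tolerance = 1e-4)
  expect_equal(r$sigma, sqrt(unname(unlist(lme4::VarCorr(g)))),
               tolerance = 1e-3)
  expect_equal(r$se, sqrt(vcov(g)[2, 2]), tolerance = 1e-3)
})

test_that("random-effects recovers the generating ICC and treatment effect", {
  set.seed(141)
  for (icc in c(0.075, 0.25)) {
    d <- sim_trial(n_total = 8000, n_centres = 160, icc = icc, beta = -0.5)
    r <- random_effects_logistic(d)
    expect_true(r$converged)
    expect_lt(abs(r$icc - icc), 0.05)
    expect_lt(abs(r$log_or - (-0.5)), 3 * r$se)
  }
})

test_that("GEE with singleton clusters equals ordinary logistic regression", {
  set.seed(151)
  d <- sim_trial(n_total = 150, n_centres = 150, icc = 0, beta = -0.3)
  gn <- gee_logistic(d, se_type = "naive")
  ru <- unadjusted_logistic(d)
  expect_equal(gn$log_or, ru$log_or, tolerance = 1e-8)
  expect_equal(gn$se, ru$se, tolerance = 1e-8)
})

test_that("GEE sandwich matches a brute-force per-cluster matrix oracle", {
  set.seed(161)
  d <- sim_trial(n_total = 200, n_centres = 10, icc = 0.1, beta = -0.5)
  gn <- gee_logistic(d, se_type = "naive")
  gr <- gee_logistic(d, se_type = "robust")
  # brute force: explicit V_j = A^{1/2} R A^{1/2} per cluster at the
  # fitted coefficients and working correlation
  X <- cbind(1, d$arm); y <- d$outcome
  centres <- unique(d$centre_id)
  cl <- match(d$centre_id, centres)
  p <- 2L
  beta <- coef(glm(y ~ d$arm, family = binomial))
  rho <- 0
  for (it in 1:200) {
    mu <- plogis(drop(X %*% beta)); A <- mu * (1 - mu)
    res <- (y - mu) / sqrt(A)
    num <- 0; den <- -p
    for (j in seq_along(centres)) {
      rj <- res[cl == j]; m <- length(rj)
      num <- num + (sum(rj)^2 - sum(rj^2)) / 2
      den <- den + m * (m - 1) / 2
    }
    rho <- num / den
    U <- numeric(p); B <- matrix(0, p, p)
    for (j in seq_along(centres)) {
      idx <- which(cl == j); m <- length(idx)
      R <- matrix(rho, m, m); diag(R) <- 1
      Aj <- A[idx]
      Vinv <- diag(1 / sqrt(Aj), m) %*% solve(R) %*% diag(1 / sqrt(Aj), m)
      Dj <- Aj * X[idx, , drop = FALSE]
      U <- U + t(Dj) %*% Vinv %*% (y[idx] - plogis(drop(X[idx, ] %*% beta)))
      B <- B + t(Dj) %*% Vinv %*% Dj
    }
    step <- solve(B, U)
    beta <- beta + drop(step)
    if (max(abs(step)) < 1e-12) break
  }
  mu <- plogis(drop(X %*% beta)); A <- mu * (1 - mu)
  B <- matrix(0, p, p); M <- matrix(0, p, p)
  for (j in seq_along(centres)) {
    idx <- which(cl == j); m <- length(idx)
    R <- matrix(rho, m, m); diag(R) <- 1
    Vinv <- diag(1 / sqrt(A[idx]), m) %*% solve(R) %*% diag(1 / sqrt(A[idx]), m)
    Dj <- A[idx] * X[idx, , drop = FALSE]
    gj <- t(Dj) %*% Vinv %*% (y[idx] - mu[idx])
    B <- B + t(Dj) %*% Vinv %*% Dj
    M <- M + gj %*% t(gj)
  }
  v_naive <- solve(B); v_rob <- v_naive %*% M %*% v_naive
  expect_equal(gn$log_or, unname(beta[2]), tolerance = 1e-8)
  expect_equal(gn$se, sqrt(v_naive[2, 2]), tolerance = 1e-10)
  expect_equal(gr$se, sqrt(v_rob[2, 2]), tolerance = 1e-10)
})

test_that("marginal GEE effect is attenuated relative to the conditional one", {
  set.seed(171)
  d <- sim_trial(n_total = 4000, n_centres = 80, icc = 0.25, beta = -1)
  g <- gee_logistic(d)
  r <- random_effects_logistic(d)
  expect_lt(abs(g$log_or), abs(r$log_or))
})

test_that("naive and robust GEE standard errors converge with many clusters", {
  # the sandwich SE is noisy replicate by replicate (CV ~ sqrt(2/J)), so
  # the consistency claim is about the average SE over replicates
  set.seed(181)
  nrep <- 200
  ses <- vapply(seq_len(nrep), function(i) {
    d <- sim_trial(n_total = 5000, n_centres = 100, icc = 0.05, beta = 0)
    c(gee_logistic(d, se_type = "naive")$se,
      gee_logistic(d, se_type = "robust")$se)
  }, numeric(2))
  expect_lt(abs(mean(ses[2, ]) - mean(ses[1, ])) / mean(ses[1, ]), 0.05)
})
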