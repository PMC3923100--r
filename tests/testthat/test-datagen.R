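test_that("ICC and centre-effect SD convert both ways exactly", {
  expect_identical(icc_to_sigma(0), 0)
  expect_equal(icc_to_sigma(0.5), sqrt(pi^2 / 3), tolerance = 1e-12)
  expect_equal(icc_to_sigma(0.025), 0.290440, tolerance = 1e-5)
  grid <- seq(0, 0.99, length.out = 100)
  for (icc in grid) {
    expect_equal(sigma_to_icc(icc_to_sigma(icc)), icc, tolerance = 1e-12)
  }
  expect_error(icc_to_sigma(1), class = "centresim_config_error")
  expect_error(icc_to_sigma(-0.1), class = "centresim_config_error")
})

test_that("intercept calibration is the logit of the control rate", {
  expect_identical(calibrate_alpha(0.5), 0)
  expect_equal(calibrate_alpha(0.2), log(0.25), tolerance = 1e-12)
  expect_equal(calibrate_alpha(0.12), qlogis(0.12), tolerance = 1e-12)
  expect_error(calibrate_alpha(0), class = "centresim_config_error")
  expect_error(calibrate_alpha(1), class = "centresim_config_error")
})

test_that("effect calibration reduces events and shrinks with sample size", {
  b <- calibrate_effect(2000, 0.5)
  expect_lt(b, 0)
  expect_lt(plogis(qlogis(0.5) + b), 0.5)
  expect_lt(abs(calibrate_effect(4000, 0.5)), abs(b))
  expect_lt(abs(calibrate_effect(4000, 0.2)), abs(calibrate_effect(2000, 0.2)))
})

test_that("calibrated effect attains 80% power in a two-proportion simulation", {
  # independent oracle: exact n/2-per-arm binomial draws, Wald z on the 2x2
  b <- calibrate_effect(2000, 0.5, target_power = 0.8)
  p2 <- plogis(qlogis(0.5) + b)
  set.seed(21)
  nrep <- 4000
  ev_t <- rbinom(nrep, 1000, p2)
  ev_c <- rbinom(nrep, 1000, 0.5)
  lo <- log(ev_t / (1000 - ev_t)) - log(ev_c / (1000 - ev_c))
  se <- sqrt(1 / ev_t + 1 / (1000 - ev_t) + 1 / ev_c + 1 / (1000 - ev_c))
  power <- mean(abs(lo / se) > qnorm(0.975))
  expect_lt(abs(power - 0.8), 3 * sqrt(0.8 * 0.2 / nrep))
})

test_that("latent-logistic generation matches closed-form marginal rates", {
  # sigma = 0, alpha = beta = 0: iid Bernoulli(1/2)
  set.seed(31)
  sizes <- allocate_centres(1e5, 10, "even")
  arm <- simple_randomization(1e5)
  d0 <- generate_trial(sizes, arm, generative_params(0, 0, sigma = 0))
  expect_lt(abs(mean(d0$outcome) - 0.5), 3 * sqrt(0.25 / 1e5))
  # sigma = 0, general alpha/beta: per-arm rates are expit(alpha), expit(alpha+beta)
  al <- qlogis(0.2); be <- -0.7
  d1 <- generate_trial(sizes, arm, generative_params(al, be, sigma = 0))
  r0 <- mean(d1$outcome[d1$arm == 0]); r1 <- mean(d1$outcome[d1$arm == 1])
  n0 <- sum(d1$arm == 0); n1 <- sum(d1$arm == 1)
  expect_lt(abs(r0 - plogis(al)), 3 * sqrt(plogis(al) * (1 - plogis(al)) / n0))
  expect_lt(abs(r1 - plogis(al + be)),
            3 * sqrt(plogis(al + be) * (1 - plogis(al + be)) / n1))
})

test_that("latent generation equals direct Bernoulli-expit generation", {
  # same number of patients, same parameters; one dataset via the latent
  # model, one drawn directly as Y ~ Bern(expit(alpha + beta x + u));
  # per-arm event totals must be homogeneous
  al <- qlogis(0.3); be <- -0.5; sg <- icc_to_sigma(0.1)
  J <- 2000L; m <- 50L
  sizes <- rep(m, J)
  arm <- rep_len(c(0L, 1L), J * m)
  set.seed(41)
  d_lat <- generate_trial(sizes, arm, generative_params(al, be, sigma = sg))
  u <- rnorm(J, 0, sg)
  centre <- rep(seq_len(J), each = m)
  y_dir <- rbinom(J * m, 1, plogis(al + be * arm + u[centre]))
  tab <- rbind(
    c(sum(d_lat$outcome[arm == 0]), sum(1 - d_lat$outcome[arm == 0])),
    c(sum(y_dir[arm == 0]), sum(1 - y_dir[arm == 0]))
  )
  expect_gt(chisq.test(tab)$p.value, 0.01)
  tab1 <- rbind(
    c(sum(d_lat$outcome[arm == 1]), sum(1 - d_lat$outcome[arm == 1])),
    c(sum(y_dir[arm == 1]), sum(1 - y_dir[arm == 1]))
  )
  expect_gt(chisq.test(tab1)$p.value, 0.01)
  # and the marginal control rate matches numerical integration over u
  marg <- integrate(function(u) plogis(al + u) * dnorm(u, 0, sg),
                    -Inf, Inf)$value
  rates <- tapply(d_lat$outcome[arm == 0], centre[arm == 0], mean)
  expect_lt(abs(mean(rates) - marg), 4 * sd(rates) / sqrt(J))
})

test_that("generation is exchangeable within centre and seed-reproducible", {
  set.seed(51)
  d1 <- sim_trial(seed = 99)
  d2 <- sim_trial(seed = 99)
  expect_identical(d1, d2)
  expect_error(
    generate_trial(c(2L, 2L), c(0L, 1L, 0L, 1L),
                   generative_params(0, 0, sigma = 0,
                                     covariate_betas = c(zz = 1))),
    class = "centresim_config_error")
})

test_that("MIST2-like generator reproduces the trial's shape and event rate", {
  set.seed(61)
  d <- generate_mist2_like()
  expect_equal(nrow(d), 190)
  sizes <- table(d$centre_id)
  expect_length(sizes, 11)
  expect_equal(median(as.numeric(sizes)), 12)
  expect_equal(range(as.numeric(sizes)), c(1, 87))
  expect_true(all(c("pleural_fluid", "purulence", "hospital_infection")
                  %in% names(d)))
  expect_true(all(d$pleural_fluid >= 0 & d$pleural_fluid <= 100))
  # event rate ~12% over many draws
  set.seed(62)
  rates <- replicate(40, mean(generate_mist2_like()$outcome))
  expect_lt(abs(mean(rates) - 0.12), 3 * sqrt(0.12 * 0.88 / (40 * 190)))
})

test_that("MIST2-like treatment effect is recovered at scale", {
  # at 10x the trial size the adjusted logistic recovers log(0.23)
  set.seed(63)
  nrep <- 60
  covs <- c("pleural_fluid", "purulence", "hospital_infection")
  lo <- replicate(nrep, {
    d <- generate_mist2_like(n_total = 1900, treatment_or = 0.23)
    unadjusted_logistic(d, covariates = covs)$log_or
  })
  expect_lt(abs(mean(lo) - log(0.23)), 3 * sd(lo) / sqrt(nrep))
  # and under the null the two arms have equal rates in expectation
  set.seed(64)
  d0 <- generate_mist2_like(n_total = 9500, treatment_or = 1)
  r <- tapply(d0$outcome, d0$arm, mean)
  expect_lt(abs(r[1] - r[2]), 3 * sqrt(2 * 0.12 * 0.88 / 4750))
})
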