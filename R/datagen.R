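#' Convert an intraclass correlation to a centre-effect SD
#'
#' For a binary outcome modelled on the log-odds scale with a latent logistic
#' error (variance pi^2/3) and normal centre effects with variance sigma^2,
#' the intraclass correlation is ICC = sigma^2 / (sigma^2 + pi^2/3). This
#' inverts that relation.
#'
#' @param icc Intraclass correlation in `[0, 1)`.
#' @return Non-negative centre-effect standard deviation on the log-odds
#'   scale.
#' @examples
#' icc_to_sigma(0)      # 0
#' icc_to_sigma(0.5)    # sqrt(pi^2/3)
#' sigma_to_icc(icc_to_sigma(0.075))
#' @export
icc_to_sigma <- function(icc) {
  if (length(icc) != 1L || !is.finite(icc) || icc < 0 || icc >= 1) {
    stop_config("icc must lie in [0, 1)")
  }
  sqrt(icc * (pi^2 / 3) / (1 - icc))
}

#' @rdname icc_to_sigma
#' @param sigma Non-negative centre-effect SD on the log-odds scale.
#' @export
sigma_to_icc <- function(sigma) {
  if (length(sigma) != 1L || !is.finite(sigma) || sigma < 0) {
    stop_config("sigma must be non-negative")
  }
  sigma^2 / (sigma^2 + pi^2 / 3)
}

#' Calibrate the intercept to a control-arm event rate
#'
#' Returns the log-odds intercept `alpha = logit(rate)` interpreted
#' conditionally on a zero centre effect. At the moderate ICCs used in the
#' scenario grids the gap between this conditional event rate and the
#' marginal rate (averaged over centre effects) is small; see the methods
#' vignette for the rationale.
#'
#' @param control_event_rate Event probability in the control arm, strictly
#'   inside (0, 1).
#' @return Log-odds intercept.
#' @examples
#' calibrate_alpha(0.5)   # 0
#' calibrate_alpha(0.2)   # log(0.25)
#' @export
calibrate_alpha <- function(control_event_rate) {
  r <- control_event_rate
  if (length(r) != 1L || !is.finite(r) || r <= 0 || r >= 1) {
    stop_config("control_event_rate must lie strictly inside (0, 1)")
  }
  stats::qlogis(r)
}

#' Calibrate an event-reducing treatment effect for a target power
#'
#' Solves for the (negative) treatment log odds ratio such that a two-sided
#' two-proportion comparison at `n_total / 2` patients per arm attains the
#' target power under the standard normal approximation
#' `power = Phi(|p1 - p2| / sqrt((p1 q1 + p2 q2) / (n/2)) - z_{1 - alpha/2})`.
#' The effect reduces (rather than increases) the number of events, so the
#' returned value is always below zero. Clustering is ignored in this design
#' calculation, matching conventional trial practice.
#'
#' @param n_total Total trial size (both arms).
#' @param control_event_rate Control-arm event probability.
#' @param target_power Desired power in (0, 1), default 0.8.
#' @param alpha_level Two-sided significance level, default 0.05.
#' @return Negative treatment log odds ratio.
#' @examples
#' b <- calibrate_effect(2000, 0.5)
#' exp(b)  # odds ratio below 1
#' @export
calibrate_effect <- function(n_total, control_event_rate,
                             target_power = 0.8, alpha_level = 0.05) {
  check_count(n_total, "n_total")
  p1 <- control_event_rate
  if (!is.finite(p1) || p1 <= 0 || p1 >= 1) {
    stop_config("control_event_rate must lie strictly inside (0, 1)")
  }
  if (target_power <= 0 || target_power >= 1 ||
      alpha_level <= 0 || alpha_level >= 1) {
    stop_config("target_power and alpha_level must lie strictly inside (0, 1)")
  }
  n_arm <- n_total / 2
  za <- stats::qnorm(1 - alpha_level / 2)
  attained <- function(beta) {
    p2 <- stats::plogis(stats::qlogis(p1) + beta)
    se <- sqrt((p1 * (1 - p1) + p2 * (1 - p2)) / n_arm)
    stats::pnorm(abs(p1 - p2) / se - za)
  }
  lo <- -50
  if (attained(lo) < target_power) {
    stop(errorCondition(
      "no event-reducing log odds ratio reaches the target power",
      class = c("centresim_calibration_error", "error")))
  }
  stats::uniroot(function(b) attained(b) - target_power,
                 lower = lo, upper = -1e-9, tol = 1e-10)$root
}

#' Generative parameters for the latent-outcome trial model
#'
#' Bundles the parameters of the latent-variable outcome model
#' `Y* = alpha + beta_treat X + sum_k beta_k Z_k + u_j + eps`,
#' with `u_j ~ N(0, sigma^2)` per centre and `eps` standard logistic per
#' patient; the observed outcome is `Y = 1` if `Y* > 0`. Supply exactly one
#' of `sigma` or `icc`; the other is derived via
#' `ICC = sigma^2 / (sigma^2 + pi^2/3)`.
#'
#' @param alpha Log-odds intercept (control log-odds at zero centre effect).
#' @param beta_treat Treatment log odds ratio.
#' @param sigma Centre-effect SD (log-odds scale), or `NULL` to derive from
#'   `icc`.
#' @param icc Intraclass correlation, or `NULL` to derive from `sigma`.
#' @param covariate_betas Optional named numeric vector of covariate log-odds
#'   coefficients.
#' @return An object of class `generative_params`.
#' @examples
#' generative_params(alpha = calibrate_alpha(0.2), beta_treat = 0, icc = 0.075)
#' @export
generative_params <- function(alpha, beta_treat, sigma = NULL, icc = NULL,
                              covariate_betas = NULL) {
  if (is.null(sigma) && is.null(icc)) icc <- 0
  if (is.null(sigma)) sigma <- icc_to_sigma(icc)
  icc <- sigma_to_icc(sigma)
  if (!is.null(covariate_betas) &&
      (is.null(names(covariate_betas)) || any(names(covariate_betas) == ""))) {
    stop_config("covariate_betas must be a fully named numeric vector")
  }
  structure(list(alpha = alpha, beta_treat = beta_treat, sigma = sigma,
                 icc = icc, covariate_betas = covariate_betas),
            class = "generative_params")
}

#' Generate a trial dataset from the latent-outcome model
#'
#' Draws centre effects `u_j ~ N(0, sigma^2)` independently per centre and
#' logistic errors independently per patient, forms the latent outcome
#' `Y* = alpha + beta_treat X + sum_k beta_k Z_k + u_j + eps`, and records
#' `Y = 1` when `Y* > 0`. Randomness is consumed from R's global stream, so
#' `set.seed()` before the call makes the dataset reproducible.
#'
#' @param sizes Centre allocation (integer sizes, see [allocate_centres()]).
#' @param arms 0/1 arm assignment of length `sum(sizes)`, ordered by centre.
#' @param params A [generative_params()] object.
#' @param covariates Optional data frame of per-patient covariate values
#'   (numeric; binary covariates coded 0/1), `sum(sizes)` rows.
#' @return A `trial_dataset` data frame with columns `patient_id`,
#'   `centre_id`, `arm`, `outcome`, then one column per covariate.
#' @examples
#' set.seed(42)
#' sizes <- allocate_centres(200, 10, "even")
#' arm <- stratified_permuted_blocks(sizes, 4)
#' pars <- generative_params(alpha = 0, beta_treat = 0, icc = 0.075)
#' head(generate_trial(sizes, arm, pars))
#' @export
generate_trial <- function(sizes, arms, params, covariates = NULL) {
  check_sizes(sizes)
  n <- sum(sizes)
  if (length(arms) != n || !all(arms %in% c(0L, 1L))) {
    stop_config("arms must be a 0/1 vector matching the allocation size")
  }
  stopifnot(inherits(params, "generative_params"))
  centre <- rep.int(seq_along(sizes), sizes)
  eta <- params$alpha + params$beta_treat * arms
  if (!is.null(params$covariate_betas)) {
    nm <- names(params$covariate_betas)
    if (is.null(covariates) || !all(nm %in% names(covariates))) {
      stop_config("covariate_betas refer to covariates absent from the data: ",
                  paste(setdiff(nm, names(covariates)), collapse = ", "))
    }
    eta <- eta + drop(as.matrix(covariates[nm]) %*% params$covariate_betas)
  }
  u <- stats::rnorm(length(sizes), 0, params$sigma)
  ystar <- eta + u[centre] + stats::rlogis(n)
  out <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    centre_id = sprintf("C%03d", centre),
    arm = as.integer(arms),
    outcome = as.integer(ystar > 0),
    stringsAsFactors = FALSE
  )
  if (!is.null(covariates)) out <- cbind(out, covariates)
  class(out) <- c("trial_dataset", "data.frame")
  out
}

# Centre-size profile emulating an 11-centre trial of 190 patients with a
# median centre of 12 patients, a single dominant centre of 87, and a
# smallest centre of 1 (sorted ascending). Synthetic: only the median,
# range, and total of the real trial are published.
mist2_centre_profile <- c(1L, 3L, 5L, 8L, 10L, 12L, 14L, 15L, 16L, 19L, 87L)

#' Generate a MIST2-like pleural-infection trial dataset
#'
#' Emulates a two-arm version of an 11-centre pleural infection trial:
#' 190 patients by default, one dominant centre (size profile 1 to 87 with
#' median 12), an overall event rate of about 12%, and three baseline
#' covariates - pleural fluid volume as a percentage (continuous,
#' right-skewed on `[0, 100]`), purulence (binary), and hospital-acquired
#' infection (binary). Outcomes come from [generate_trial()] with the
#' log-odds coefficients `alpha = -3.3`, `beta_fluid = 0.03` per percentage
#' point, `beta_purulence = -0.2`, and `beta_hospital = 0.4`; patients are
#' assigned by simple randomisation. The covariate distributions themselves
#' are synthetic (the source trial's patient-level data are not public):
#' fluid is `100 * Beta(1.55, 2.45)`, purulence is Bernoulli(0.5),
#' hospital-acquired is Bernoulli(0.2), with mild dependence (Gaussian
#' copula, r = 0.2).
#'
#' @param n_total Total patients, default 190.
#' @param treatment_or Treatment odds ratio (1 = no effect; 0.23 mirrors the
#'   strongest comparison of the source trial).
#' @param icc Intraclass correlation of the centre effects, default 0.
#' @return A `trial_dataset` with covariate columns `pleural_fluid`,
#'   `purulence`, `hospital_infection`.
#' @examples
#' set.seed(7)
#' d <- generate_mist2_like()
#' mean(d$outcome)  # close to 0.12
#' @export
generate_mist2_like <- function(n_total = 190, treatment_or = 1, icc = 0) {
  check_count(n_total, "n_total")
  prof <- mist2_centre_profile
  if (n_total == sum(prof)) {
    sizes <- prof
  } else {
    sizes <- pmax(1L, round(prof * n_total / sum(prof)))
    # repair rounding drift on the dominant centre
    sizes[length(sizes)] <- sizes[length(sizes)] + (n_total - sum(sizes))
  }
  n <- sum(sizes)
  # Gaussian copula for mildly dependent covariates
  r <- 0.2
  cr <- matrix(r, 3, 3); diag(cr) <- 1
  z <- matrix(stats::rnorm(3 * n), n, 3) %*% chol(cr)
  covs <- data.frame(
    pleural_fluid = 100 * stats::qbeta(stats::pnorm(z[, 1]), 1.55, 2.45),
    purulence = as.integer(stats::pnorm(z[, 2]) < 0.5),
    hospital_infection = as.integer(stats::pnorm(z[, 3]) < 0.2)
  )
  arms <- simple_randomization(n)
  params <- generative_params(
    alpha = -3.3, beta_treat = log(treatment_or), icc = icc,
    covariate_betas = c(pleural_fluid = 0.03, purulence = -0.2,
                        hospital_infection = 0.4))
  generate_trial(sizes, arms, params, covariates = covs)
}
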