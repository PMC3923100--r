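#' Declare whether a fit converged
#'
#' Applies the convergence rules used throughout the simulation engine: a
#' fit has failed when (i) the optimiser itself signalled failure, (ii) the
#' absolute treatment log odds ratio or its standard error exceeds 1000
#' (or is non-finite), or (iii) the log odds ratio and its standard error
#' are both exactly zero, indicating the treatment term was dropped from
#' the model.
#'
#' @param log_or Estimated treatment log odds ratio.
#' @param se Its standard error.
#' @param optimiser_ok `FALSE` if the underlying optimiser reported failure.
#' @return List with `converged` (logical) and `reason` (one of
#'   `"optimiser-failure"`, `"extreme-estimate"`, `"dropped"`, or `NA` when
#'   converged).
#' @examples
#' convergence_check(-0.3, 0.2)        # converged
#' convergence_check(1001, 0.2)        # extreme-estimate
#' convergence_check(0, 0)             # dropped
#' @export
convergence_check <- function(log_or, se, optimiser_ok = TRUE) {
  if (!isTRUE(optimiser_ok)) {
    return(list(converged = FALSE, reason = "optimiser-failure"))
  }
  if (!is.finite(log_or) || !is.finite(se) ||
      abs(log_or) > 1000 || se > 1000) {
    return(list(converged = FALSE, reason = "extreme-estimate"))
  }
  if (log_or == 0 && se == 0) {
    return(list(converged = FALSE, reason = "dropped"))
  }
  list(converged = TRUE, reason = NA_character_)
}

# Assemble the uniform result object from a core fit.
as_estimate_result <- function(core, method) {
  conv <- isTRUE(core$converged)
  structure(list(
    method = method,
    log_or = core$log_or,
    se = core$se,
    ci_low = if (conv) exp(core$log_or - 1.96 * core$se) else NA_real_,
    ci_high = if (conv) exp(core$log_or + 1.96 * core$se) else NA_real_,
    p_value = core$p_value,
    n_included = core$n_included,
    n_strata_included = core$n_strata_included,
    converged = conv,
    failure_reason = core$failure_reason,
    sigma = core$sigma,
    icc = core$icc,
    rho = core$rho
  ), class = "estimate_result")
}

#' @export
print.estimate_result <- function(x, ...) {
  cat(sprintf("<%s> ", x$method))
  if (x$converged) {
    cat(sprintf("OR %.3f (95%% CI %.3f to %.3f), p = %.4g, n = %d\n",
                exp(x$log_or), x$ci_low, x$ci_high, x$p_value, x$n_included))
  } else {
    cat(sprintf("did not converge (%s)\n", x$failure_reason))
  }
  invisible(x)
}

#' @export
as.data.frame.estimate_result <- function(x, ...) {
  data.frame(method = x$method, log_or = x$log_or, se = x$se,
             or = exp(x$log_or), ci_low = x$ci_low, ci_high = x$ci_high,
             p_value = x$p_value, n_included = x$n_included,
             n_strata_included = x$n_strata_included,
             converged = x$converged,
             failure_reason = ifelse(is.na(x$failure_reason), "",
                                     x$failure_reason),
             stringsAsFactors = FALSE)
}

# Validate a trial dataset and pull out the vectors the cores consume.
trial_vectors <- function(data, covariates = character()) {
  req <- c("patient_id", "centre_id", "arm", "outcome")
  miss <- setdiff(req, names(data))
  if (length(miss)) {
    stop_data("missing required columns: ", paste(miss, collapse = ", "))
  }
  if (!all(data$arm %in% c(0, 1)) || !all(data$outcome %in% c(0, 1))) {
    stop_data("arm and outcome must be coded 0/1")
  }
  miss_cov <- setdiff(covariates, names(data))
  if (length(miss_cov)) {
    stop_data("covariates not present in data: ",
              paste(miss_cov, collapse = ", "))
  }
  lev <- unique(data$centre_id)
  list(y = as.integer(data$outcome), x = as.integer(data$arm),
       centre = match(data$centre_id, lev), n_centres = length(lev),
       Z = if (length(covariates)) {
         as.matrix(data[covariates])
       } else NULL)
}

#' Logistic regression unadjusted for centre
#'
#' Maximum-likelihood logistic regression of outcome on treatment (plus any
#' listed covariates), with no centre terms; Wald standard error, 95% CI,
#' and p-value for the treatment log odds ratio.
#'
#' @param data A `trial_dataset` (see [generate_trial()] or
#'   [read_trial_csv()]).
#' @param covariates Character vector of covariate column names to adjust
#'   for (default none).
#' @return An `estimate_result`.
#' @export
unadjusted_logistic <- function(data, covariates = character()) {
  v <- trial_vectors(data, covariates)
  as_estimate_result(fit_unadjusted_core(v$y, v$x, v$Z), "unadjusted")
}

#' Fixed-effects (centre-indicator) logistic regression
#'
#' Logistic regression of outcome on treatment plus an indicator for every
#' centre but one. Centres in which all patients share the same outcome, or
#' are all randomised to the same arm, carry no within-centre information
#' about the treatment effect; they are excluded before fitting and their
#' patients do not count towards `n_included`.
#'
#' @inheritParams unadjusted_logistic
#' @return An `estimate_result`; `n_strata_included` holds the number of
#'   informative centres retained.
#' @export
fixed_effects_logistic <- function(data, covariates = character()) {
  v <- trial_vectors(data, covariates)
  as_estimate_result(fit_fixed_core(v$y, v$x, v$centre, v$Z, v$n_centres),
                     "fixed")
}

#' Random-effects (mixed) logistic regression
#'
#' Logistic regression with a normal random intercept per centre,
#' `u_j ~ N(0, sigma^2)`. The marginal likelihood is maximised with the
#' random intercept integrated out by adaptive Gauss-Hermite quadrature.
#' All centres and all patients contribute, including centres with a single
#' arm or a single outcome. The fitted centre-effect SD is returned in
#' `$sigma` (and as an ICC in `$icc`) for intraclass-correlation reporting.
#'
#' @inheritParams unadjusted_logistic
#' @param quad_points Number of quadrature nodes (default 12).
#' @return An `estimate_result` with extra fields `sigma` and `icc`.
#' @export
random_effects_logistic <- function(data, covariates = character(),
                                    quad_points = 12L) {
  v <- trial_vectors(data, covariates)
  ord <- order(v$centre)
  core <- fit_random_core(v$y[ord], v$x[ord], v$centre[ord],
                          if (is.null(v$Z)) NULL else v$Z[ord, , drop = FALSE],
                          quad_points = quad_points, n_centres = v$n_centres)
  as_estimate_result(core, "random")
}

#' GEE logistic regression with exchangeable working correlation
#'
#' Population-averaged logistic regression solved by generalised estimating
#' equations under an exchangeable working correlation (all patients within
#' a centre equally correlated, patients in different centres independent).
#' The common correlation is re-estimated each iteration by the moment
#' estimator from Pearson residual cross-products. Standard errors are
#' either model-based (`"naive"`, valid when the working structure is
#' correct) or the robust sandwich estimator (`"robust"`).
#'
#' @inheritParams unadjusted_logistic
#' @param se_type `"naive"` (model-based) or `"robust"` (sandwich).
#' @return An `estimate_result` with the estimated working correlation in
#'   `$rho`.
#' @export
gee_logistic <- function(data, covariates = character(),
                         se_type = c("naive", "robust")) {
  se_type <- match.arg(se_type)
  v <- trial_vectors(data, covariates)
  fits <- fit_gee_core(v$y, v$x, v$centre, v$Z, v$n_centres)
  as_estimate_result(fits[[se_type]], paste0("gee-", se_type))
}

#' Build analysis strata from centre and categorical covariates
#'
#' Cross-classifies patients by centre and/or covariates for a stratified
#' (Mantel-Haenszel) analysis. Covariates must be categorical: a continuous
#' covariate may only appear in `stratify_on` together with a cut rule that
#' dichotomises or bins it. Empty combinations produce no stratum.
#'
#' @inheritParams unadjusted_logistic
#' @param stratify_on Character vector of stratification variables; use
#'   `"centre"` for the recruiting centre.
#' @param cut_rules Named list mapping a continuous covariate to its numeric
#'   cut point(s); values at or below a cut go to the lower category.
#' @return Factor of stratum labels, one per patient (empty levels dropped).
#' @examples
#' set.seed(3)
#' d <- generate_mist2_like()
#' s <- build_strata(d, c("centre", "pleural_fluid", "purulence"),
#'                   cut_rules = list(pleural_fluid = 30))
#' nlevels(s)
#' @export
build_strata <- function(data, stratify_on = "centre", cut_rules = NULL) {
  if (!length(stratify_on)) stop_config("stratify_on must not be empty")
  cols <- lapply(stratify_on, function(nm) {
    if (nm == "centre") return(data$centre_id)
    if (!nm %in% names(data)) {
      stop_config("stratification variable not in data: ", nm)
    }
    val <- data[[nm]]
    if (is.numeric(val) && length(unique(val)) > 2L) {
      if (is.null(cut_rules[[nm]])) {
        stop_config("continuous covariate '", nm,
                    "' needs a cut rule to be used as a stratum")
      }
      val <- cut(val, breaks = c(-Inf, cut_rules[[nm]], Inf))
    } else if (!is.null(cut_rules[[nm]])) {
      val <- cut(as.numeric(val), breaks = c(-Inf, cut_rules[[nm]], Inf))
    }
    val
  })
  interaction(cols, drop = TRUE, lex.order = TRUE)
}

#' Per-stratum 2x2 tables
#'
#' Tabulates events and non-events by arm within each stratum: `a` / `b`
#' are events / non-events in the treated arm, `c` / `d` in the control
#' arm, `n = a + b + c + d`. `informative` marks strata that contribute to
#' a Mantel-Haenszel analysis (both arms and both outcomes represented,
#' i.e. `a*d > 0` or `b*c > 0`).
#'
#' @inheritParams unadjusted_logistic
#' @param strata Factor of stratum labels, e.g. from [build_strata()].
#' @return Data frame with one row per non-empty stratum.
#' @export
stratum_table <- function(data, strata) {
  v <- trial_vectors(data)
  s <- as.integer(factor(strata))
  ns <- max(s)
  a <- tabulate_sum(v$y * v$x, s, ns)
  b <- tabulate_sum((1 - v$y) * v$x, s, ns)
  cc <- tabulate_sum(v$y * (1 - v$x), s, ns)
  d <- tabulate_sum((1 - v$y) * (1 - v$x), s, ns)
  data.frame(stratum = levels(factor(strata)), a = a, b = b, c = cc, d = d,
             n = a + b + cc + d,
             informative = (a * d > 0) | (b * cc > 0),
             stringsAsFactors = FALSE)
}

#' Mantel-Haenszel stratified odds ratio
#'
#' Combines per-stratum 2x2 tables into the Mantel-Haenszel odds ratio
#' `OR_MH = sum_j (a_j d_j / n_j) / sum_j (b_j c_j / n_j)`. The confidence
#' interval uses the Robins-Breslow-Greenland variance of `log(OR_MH)`; the
#' p-value comes from the Mantel-Haenszel chi-square test (1 df, no
#' continuity correction), so - as in routine stratified reporting - the
#' test and the interval rest on different information and can disagree
#' near the significance boundary. Strata in which all patients share one
#' outcome or one arm contribute nothing and their patients are excluded
#' from `n_included`.
#'
#' @inheritParams build_strata
#' @param strata Optional precomputed factor of stratum labels; overrides
#'   `stratify_on` / `cut_rules` when supplied.
#' @return An `estimate_result`; `n_strata_included` counts informative
#'   strata.
#' @export
mantel_haenszel <- function(data, stratify_on = "centre", cut_rules = NULL,
                            strata = NULL) {
  v <- trial_vectors(data)
  if (is.null(strata)) strata <- build_strata(data, stratify_on, cut_rules)
  s <- as.integer(factor(strata))
  as_estimate_result(fit_mh_core(v$y, v$x, s, max(s)), "mh")
}
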